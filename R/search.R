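# -- internal search representation -------------------------------------------
#
# During tree search a tree over n taxa is a rooted binary structure: leaves
# 1..n, internal nodes allocated from n+1 upwards, `root` an internal node
# whose first child is the "base" leaf (the first taxon of the addition
# sequence).  Fitch length is invariant to this rooting, so the search is an
# unrooted search in effect.  `kids` is a list of integer child pairs.

srep_new <- function(n, t1, t2, t3) {
  kids <- vector("list", 2L * n)
  root <- n + 1L
  w <- n + 2L
  kids[[root]] <- c(t1, w)
  kids[[w]] <- c(t2, t3)
  list(kids = kids, root = root, n = n, next_node = n + 3L, base = t1)
}

# all edges (parent, child) excluding the root->base duplicate of the
# root->w unrooted edge
srep_edges <- function(tr) {
  ps <- integer(0)
  cs <- integer(0)
  for (p in seq_along(tr$kids)) {
    ks <- tr$kids[[p]]
    if (is.null(ks)) next
    for (ch in ks) {
      if (p == tr$root && ch == tr$base) next
      ps <- c(ps, p)
      cs <- c(cs, ch)
    }
  }
  cbind(ps, cs)
}

srep_insert <- function(tr, p, v, leaf) {
  u <- tr$next_node
  tr$kids[[u]] <- c(v, leaf)
  ks <- tr$kids[[p]]
  ks[ks == v] <- u
  tr$kids[[p]] <- ks
  tr$next_node <- u + 1L
  tr
}

srep_postorder <- function(tr) {
  # iterative DFS; returns internal nodes, children before parents
  out <- integer(0)
  stack <- tr$root
  visited <- integer(0)
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    ks <- tr$kids[[v]]
    kint <- ks[ks > tr$n]
    todo <- setdiff(kint, visited)
    if (length(todo) == 0) {
      out <- c(out, v)
      visited <- c(visited, v)
      stack <- stack[-length(stack)]
    } else {
      stack <- c(stack, todo)
    }
  }
  out
}

srep_score <- function(tr, masks, scorer) {
  post <- srep_postorder(tr)
  res <- fitch_steps_engine(tr$kids, post, masks, length(tr$kids))
  scorer(res$steps)
}

# canonical split hash for duplicate detection
srep_hash <- function(tr) {
  n <- tr$n
  post <- srep_postorder(tr)
  clus <- vector("list", length(tr$kids))
  for (i in seq_len(n)) clus[[i]] <- i
  for (v in post) {
    clus[[v]] <- sort(unlist(clus[tr$kids[[v]]]))
  }
  parts <- character(0)
  for (v in post) {
    if (v == tr$root) next
    cl <- clus[[v]]
    if (length(cl) < 2 || length(cl) > n - 2) next
    parts <- c(parts, paste(cl, collapse = "."))
  }
  paste(sort(unique(parts)), collapse = ";")
}

# NNI neighbours across every internal edge of the unrooted topology
srep_nni <- function(tr) {
  out <- list()
  for (p in seq_along(tr$kids)) {
    if (is.null(tr$kids[[p]]) || p == tr$root) next
    for (v in tr$kids[[p]]) {
      if (v <= tr$n) next
      sib <- setdiff(tr$kids[[p]], v)
      ab <- tr$kids[[v]]
      for (sw in 1:2) {
        # exchange v's child ab[sw] with v's sibling across edge (p, v)
        t2 <- tr
        t2$kids[[v]] <- c(sib, ab[-sw])
        t2$kids[[p]] <- c(v, ab[sw])
        out[[length(out) + 1L]] <- t2
      }
    }
  }
  out
}

srep_to_phylo <- function(tr, labels) {
  n <- tr$n
  # preorder over internal nodes so the root maps to n+1
  stack <- tr$root
  ord <- integer(0)
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(ord, v)
    kint <- tr$kids[[v]][tr$kids[[v]] > n]
    stack <- c(stack, rev(kint))
  }
  new_id <- integer(length(tr$kids))
  new_id[ord] <- n + seq_along(ord)
  e1 <- integer(0)
  e2 <- integer(0)
  for (v in ord) {
    for (ch in tr$kids[[v]]) {
      e1 <- c(e1, new_id[v])
      e2 <- c(e2, if (ch > n) new_id[ch] else ch)
    }
  }
  edge <- cbind(e1, e2, deparse.level = 0)
  storage.mode(edge) <- "integer"
  phy <- list(edge = edge, tip.label = labels, Nnode = length(ord))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

# -- search drivers -----------------------------------------------------------

random_addition_tree <- function(n, order_taxa, masks, scorer) {
  tr <- srep_new(n, order_taxa[1], order_taxa[2], order_taxa[3])
  for (leaf in order_taxa[-(1:3)]) {
    ed <- srep_edges(tr)
    best <- NULL
    best_score <- Inf
    cand_order <- sample.int(nrow(ed)) # random tie-break among placements
    for (i in cand_order) {
      cand <- srep_insert(tr, ed[i, 1], ed[i, 2], leaf)
      sc <- srep_score(cand, masks, scorer)
      if (sc < best_score - 1e-12) {
        best_score <- sc
        best <- cand
      }
    }
    tr <- best
  }
  tr
}

hill_climb <- function(tr, masks, scorer, max_rounds = 200L) {
  cur_score <- srep_score(tr, masks, scorer)
  for (round in seq_len(max_rounds)) {
    improved <- FALSE
    for (nb in srep_nni(tr)) {
      sc <- srep_score(nb, masks, scorer)
      if (sc < cur_score - 1e-12) {
        tr <- nb
        cur_score <- sc
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(tree = tr, score = cur_score)
}

# breadth-first walk across equal-score NNI neighbours to gather co-optimal
# topologies (heuristic stand-in for exhaustively retaining all MP trees)
plateau_walk <- function(tr, score, masks, scorer, limit) {
  seen <- new.env(parent = emptyenv())
  queue <- list(tr)
  assign(srep_hash(tr), TRUE, envir = seen)
  found <- list(tr)
  while (length(queue) > 0 && length(found) < limit) {
    cur <- queue[[1]]
    queue <- queue[-1]
    for (nb in srep_nni(cur)) {
      sc <- srep_score(nb, masks, scorer)
      if (sc > score + 1e-12) next
      h <- srep_hash(nb)
      if (!is.null(seen[[h]])) next
      assign(h, TRUE, envir = seen)
      found[[length(found) + 1L]] <- nb
      queue[[length(queue) + 1L]] <- nb
      if (length(found) >= limit) break
    }
  }
  found
}

exhaustive_trees <- function(n) {
  # recursively generate every unrooted topology on leaves 1..n
  res <- list()
  recurse <- function(tr, nxt) {
    if (nxt > n) {
      res[[length(res) + 1L]] <<- tr
      return(invisible(NULL))
    }
    ed <- srep_edges(tr)
    for (i in seq_len(nrow(ed))) {
      recurse(srep_insert(tr, ed[i, 1], ed[i, 2], nxt), nxt + 1L)
    }
  }
  recurse(srep_new(n, 1L, 2L, 3L), 4L)
  res
}

#' Maximum-parsimony tree search
#'
#' Finds most-parsimonious trees for a character matrix under equal or
#' implied weighting.  For 7 or fewer taxa (or `method = "exhaustive"`,
#' allowed up to 9) every unrooted topology is scored, so the returned
#' optimum is exact.  Otherwise the search is heuristic: random
#' addition-sequence starting trees followed by steepest-descent NNI
#' branch swapping, plus a bounded walk across equal-score NNI neighbours
#' to collect co-optimal topologies.  Deterministic given `seed`.
#'
#' @param m A `char_matrix` with at least 4 taxa.
#' @param weights `"equal"` or `"implied"`.
#' @param k Concavity constant, used when `weights = "implied"`.
#' @param replicates Number of random-addition starting trees.
#' @param seed Integer seed.
#' @param method `"auto"`, `"exhaustive"` or `"heuristic"`.
#' @param max_trees Cap on retained co-optimal trees.
#' @param plateau Cap on the equal-score neighbour walk per replicate.
#' @return An object of class `mp_search`: list with `trees` (`multiPhylo`
#'   of distinct optimal trees), `score`, `consensus` (their strict
#'   consensus), and `settings`.
#' @export
mp_search <- function(m, weights = c("equal", "implied"), k = 3,
                      replicates = 10, seed = 1L,
                      method = c("auto", "exhaustive", "heuristic"),
                      max_trees = 200L, plateau = 50L) {
  weights <- match.arg(weights)
  method <- match.arg(method)
  taxa <- m$taxa
  n <- length(taxa)
  if (n < 4) abort("Need at least 4 taxa.")
  all_missing <- apply(m$data, 1, function(r) all(r == "?" | r == "-"))
  if (any(all_missing)) {
    warn(sprintf(
      "Taxon/taxa with no scored characters retained: %s",
      paste(taxa[all_missing], collapse = ", ")
    ))
  }
  enc <- encode_matrix(m)
  scorer <- if (weights == "equal") {
    function(steps) sum(steps)
  } else {
    minsteps <- min_possible_steps(m)
    function(steps) {
      e <- pmax(0L, steps - minsteps)
      sum(e / (e + k))
    }
  }
  if (method == "auto") method <- if (n <= 7) "exhaustive" else "heuristic"
  if (method == "exhaustive" && n > 9) {
    abort("Exhaustive search supported only up to 9 taxa.")
  }

  best_score <- Inf
  best <- list()
  hashes <- character(0)
  keep_tree <- function(tr, sc) {
    if (sc < best_score - 1e-12) {
      best_score <<- sc
      best <<- list(tr)
      hashes <<- srep_hash(tr)
    } else if (sc < best_score + 1e-12 && length(best) < max_trees) {
      h <- srep_hash(tr)
      if (!h %in% hashes) {
        best <<- c(best, list(tr))
        hashes <<- c(hashes, h)
      }
    }
  }

  with_local_seed(seed, {
    if (method == "exhaustive") {
      for (tr in exhaustive_trees(n)) {
        keep_tree(tr, srep_score(tr, enc$masks, scorer))
      }
    } else {
      for (rep in seq_len(replicates)) {
        ord <- sample.int(n)
        tr0 <- random_addition_tree(n, ord, enc$masks, scorer)
        # remap: addition used leaf ids directly, base = ord[1]
        hc <- hill_climb(tr0, enc$masks, scorer)
        keep_tree(hc$tree, hc$score)
        if (hc$score < best_score + 1e-12 && plateau > 1) {
          for (tr in plateau_walk(hc$tree, best_score, enc$masks, scorer, plateau)) {
            keep_tree(tr, srep_score(tr, enc$masks, scorer))
          }
        }
      }
    }
  })

  trees <- lapply(best, srep_to_phylo, labels = taxa)
  class(trees) <- "multiPhylo"
  cons <- strict_consensus(trees)
  structure(
    list(
      trees = trees,
      score = best_score,
      consensus = cons,
      settings = list(
        weights = weights, k = if (weights == "implied") k else NA_real_,
        replicates = replicates, seed = seed, method = method,
        max_trees = max_trees, plateau = plateau, n_taxa = n,
        n_char = ncol(m$data)
      )
    ),
    class = "mp_search"
  )
}

#' @export
print.mp_search <- function(x, ...) {
  cat(sprintf(
    "<mp_search> %s weights%s: score %.6g, %d optimal tree(s), %d taxa, %d characters (%s)\n",
    x$settings$weights,
    if (x$settings$weights == "implied") sprintf(" (k = %g)", x$settings$k) else "",
    x$score, length(x$trees), x$settings$n_taxa, x$settings$n_char,
    x$settings$method
  ))
  invisible(x)
}

#' @method glance mp_search
#' @export
glance.mp_search <- function(x, ...) {
  tibble(
    score = x$score,
    n_optimal = length(x$trees),
    weights = x$settings$weights,
    k = x$settings$k,
    method = x$settings$method,
    n_taxa = x$settings$n_taxa,
    n_char = x$settings$n_char,
    seed = x$settings$seed
  )
}
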