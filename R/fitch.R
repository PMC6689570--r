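# -- bitmask encoding ---------------------------------------------------------
#
# Each character column gets its own alphabet (observed state symbols); a cell
# is encoded as an integer bitmask over that alphabet.  MISSING and
# INAPPLICABLE cells take the full mask.  Columns with fewer than two observed
# states can never imply change and carry a full-zero contribution.

encode_matrix <- function(m, taxa = m$taxa) {
  stopifnot(inherits(m, "char_matrix"))
  idx <- match(taxa, m$taxa)
  if (anyNA(idx)) {
    abort(sprintf(
      "Taxa without a matrix row: %s",
      paste(taxa[is.na(idx)], collapse = ", ")
    ))
  }
  alph <- column_alphabets(m)
  nch <- ncol(m$data)
  nst <- lengths(alph)
  if (any(nst > 30)) abort("More than 30 states in one character is unsupported.")
  full <- as.integer(2^pmax(nst, 1L) - 1L)
  masks <- matrix(0L, length(taxa), nch)
  for (j in seq_len(nch)) {
    cells <- m$data[idx, j]
    enc <- rep(full[j], length(cells))
    known <- cells != "?" & cells != "-"
    if (any(known)) {
      enc[known] <- vapply(strsplit(cells[known], ""), function(s) {
        as.integer(sum(2^(match(s, alph[[j]]) - 1L)))
      }, integer(1))
    }
    masks[, j] <- enc
  }
  list(
    masks = masks, full = full, nstates = nst, alphabets = alph,
    taxa = taxa, partition = m$partition
  )
}

# Fitch downpass over an arbitrary (possibly polytomous) rooted structure
# described by a children list and a postorder of internal nodes.  Polytomies
# are handled by iterated pairwise intersection/union (the uncorrected
# convention); `exact = TRUE` in user-facing wrappers switches to the
# unit-cost Sankoff recursion, which is exact on polytomies.
fitch_steps_engine <- function(kids, post_internal, leaf_masks, n_nodes) {
  nch <- ncol(leaf_masks)
  nleaf <- nrow(leaf_masks)
  state <- matrix(0L, n_nodes, nch)
  state[seq_len(nleaf), ] <- leaf_masks
  steps <- integer(nch)
  for (v in post_internal) {
    ks <- kids[[v]]
    s <- state[ks[1L], ]
    for (k in ks[-1L]) {
      sk <- state[k, ]
      a <- bitwAnd(s, sk)
      z <- a == 0L
      if (any(z)) {
        steps[z] <- steps[z] + 1L
        a[z] <- bitwOr(s, sk)[z]
      }
      s <- a
    }
    state[v, ] <- s
  }
  list(steps = steps, state = state)
}

# children list + internal-node postorder from a phylo object
phylo_structure <- function(phy) {
  n <- length(phy$tip.label)
  post <- ape::reorder.phylo(phy, "postorder")
  n_nodes <- n + phy$Nnode
  kids <- vector("list", n_nodes)
  for (i in seq_len(nrow(post$edge))) {
    p <- post$edge[i, 1]
    kids[[p]] <- c(kids[[p]], post$edge[i, 2])
  }
  post_internal <- unique(post$edge[, 1]) # postorder visits children first
  list(kids = kids, post_internal = post_internal, n_nodes = n_nodes, n = n)
}

#' Fitch parsimony length of a tree
#'
#' Minimum number of unordered character-state changes implied by `phy` for
#' each column of `m`, via the Fitch downpass.  Missing (`?`) and
#' inapplicable (`-`) cells contribute the full state set; the score is
#' invariant to rooting.  On polytomous trees the default iterated-pairwise
#' downpass scores a binary (caterpillar) resolution of each polytomy and so
#' can undercount the exact multifurcating optimum; `exact = TRUE` uses the
#' unit-cost Sankoff recursion, which treats polytomies as hard.
#'
#' @param phy A `phylo` whose leaves all have matrix rows.
#' @param m A `char_matrix`.
#' @param exact Use the exact (Sankoff) recursion, required only for
#'   polytomies.
#' @return A list with `steps` (integer per character) and `total`.
#' @examples
#' m <- char_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
#' fitch_length(parse_tree("((A,B),(C,D));"), m)$total
#' @export
fitch_length <- function(phy, m, exact = FALSE) {
  validate_tree(phy)
  enc <- encode_matrix(m, taxa = phy$tip.label)
  st <- phylo_structure(phy)
  if (exact) {
    steps <- sankoff_steps(st, enc)
  } else {
    steps <- fitch_steps_engine(st$kids, st$post_internal, enc$masks, st$n_nodes)$steps
  }
  list(steps = steps, total = sum(steps))
}

# exact minimum steps per character via unit-cost Sankoff (handles polytomies)
sankoff_steps <- function(st, enc) {
  nch <- ncol(enc$masks)
  steps <- integer(nch)
  for (j in seq_len(nch)) {
    k <- enc$nstates[j]
    if (k < 2) next
    g <- sankoff_down(st, enc$masks[, j], k)
    root <- st$post_internal[length(st$post_internal)]
    steps[j] <- as.integer(min(g[root, ]))
  }
  steps
}

sankoff_down <- function(st, cell_masks, k) {
  INF <- .Machine$integer.max %/% 4L
  g <- matrix(INF, st$n_nodes, k)
  nleaf <- st$n
  for (i in seq_len(nleaf)) {
    allowed <- bitwAnd(cell_masks[i], 2^(seq_len(k) - 1L)) > 0
    g[i, allowed] <- 0L
  }
  for (v in st$post_internal) {
    acc <- numeric(k)
    for (c in st$kids[[v]]) {
      acc <- acc + pmin(g[c, ], min(g[c, ]) + 1L)
    }
    g[v, ] <- acc
  }
  g
}

# theoretical minimum steps of each character on *any* tree: one fewer than
# the number of states that must be realized (singleton-cell states)
min_possible_steps <- function(m) {
  vapply(seq_len(ncol(m$data)), function(j) {
    cells <- m$data[, j]
    cells <- cells[cells != "?" & cells != "-"]
    obs <- unique(unlist(strsplit(cells, "")))
    max(0L, length(obs) - 1L)
  }, integer(1))
}

#' Implied-weights parsimony score
#'
#' Goloboff-style concave fit: `sum_i e_i / (e_i + k)`, where `e_i` is the
#' homoplasy excess of character `i` -- its Fitch length on `phy` minus its
#' theoretical minimum on any tree (number of observed states minus one).
#' Lower is better.  As `k` grows the ranking of trees converges to the
#' equal-weights ranking.
#'
#' @inheritParams fitch_length
#' @param k Concavity constant (> 0); typical values 2--12.
#' @return A single numeric fit score.
#' @export
implied_weights_score <- function(phy, m, k) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) abort("`k` must be > 0.")
  fl <- fitch_length(phy, m)
  e <- pmax(0L, fl$steps - min_possible_steps(m))
  sum(e / (e + k))
}
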