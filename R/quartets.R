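#' Quartet status counts for a pair of trees
#'
#' Classifies every 4-leaf subset of the shared leaf set by the topology
#' each tree induces on it: `s` resolved identically in both, `d` resolved
#' differently in both, `r1`/`r2` resolved in only one tree, `u` unresolved
#' in both.  `Q = choose(n, 4) = s + d + r1 + r2 + u`.
#'
#' The implementation determines each quartet's topology in O(1) from a
#' precomputed MRCA table and node-cluster matrix: the pairing `ab|cd` is
#' induced iff the smallest cluster containing `a` and `b` excludes `c` and
#' `d`, or vice versa.  This agrees exactly with brute-force enumeration of
#' pruned four-leaf subtrees.
#'
#' @param t1,t2 `phylo` objects over an identical leaf set (prune first;
#'   see [prune_to_common()]); at least 4 leaves.
#' @return An object of class `quartet_status`: named list with `Q`, `s`,
#'   `d`, `r1`, `r2`, `u` and `n`.
#' @examples
#' qc <- quartet_status_counts(
#'   parse_tree("((A,B),C,(D,E));"),
#'   parse_tree("((A,C),B,(D,E));")
#' )
#' unlist(qc[c("Q", "s", "d")])
#' @export
quartet_status_counts <- function(t1, t2) {
  validate_tree(t1)
  validate_tree(t2)
  labs <- sort(t1$tip.label)
  if (!identical(labs, sort(t2$tip.label))) {
    abort("Trees must share an identical leaf set (prune to common taxa first).")
  }
  n <- length(labs)
  if (n < 4) abort("Quartet metrics need at least 4 leaves.")

  topo1 <- quartet_topologies(t1, labs)
  topo2 <- quartet_topologies(t2, labs)

  res1 <- topo1 > 0L
  res2 <- topo2 > 0L
  counts <- list(
    Q = length(topo1),
    s = sum(res1 & res2 & topo1 == topo2),
    d = sum(res1 & res2 & topo1 != topo2),
    r1 = sum(res1 & !res2),
    r2 = sum(!res1 & res2),
    u = sum(!res1 & !res2),
    n = n
  )
  structure(counts, class = "quartet_status")
}

#' @export
print.quartet_status <- function(x, ...) {
  cat(sprintf(
    "<quartet_status> n = %d, Q = %d: s = %d, d = %d, r1 = %d, r2 = %d, u = %d\n",
    x$n, x$Q, x$s, x$d, x$r1, x$r2, x$u
  ))
  invisible(x)
}

# topology code for every quartet (leaves in the common label order `labs`):
# 0 unresolved, 1 = ab|cd, 2 = ac|bd, 3 = ad|bc with a<b<c<d
quartet_topologies <- function(phy, labs) {
  n <- length(labs)
  tipidx <- match(labs, phy$tip.label)
  M <- ape::mrca(phy)[tipidx, tipidx, drop = FALSE]
  post <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  n_nodes <- ntip + phy$Nnode
  L <- matrix(FALSE, n_nodes, n)
  L[cbind(tipidx, seq_len(n))] <- TRUE
  for (i in seq_len(nrow(post$edge))) {
    L[post$edge[i, 1], ] <- L[post$edge[i, 1], ] | L[post$edge[i, 2], ]
  }

  q <- combn(n, 4L)
  a <- q[1, ]
  b <- q[2, ]
  c_ <- q[3, ]
  d <- q[4, ]
  pair_sep <- function(x1, x2, y1, y2) {
    mx <- M[cbind(x1, x2)]
    my <- M[cbind(y1, y2)]
    (!L[cbind(mx, y1)] & !L[cbind(mx, y2)]) |
      (!L[cbind(my, x1)] & !L[cbind(my, x2)])
  }
  t_ab <- pair_sep(a, b, c_, d)
  t_ac <- pair_sep(a, c_, b, d)
  t_ad <- pair_sep(a, d, b, c_)
  1L * t_ab + 2L * t_ac + 3L * t_ad
}
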