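#' Quartet divergence (normalized symmetric difference)
#'
#' `(2 d + r1 + r2) / (2 Q)`: conflicting quartets carry full penalty,
#' quartets resolved in only one tree half penalty, so the measure is
#' normalized against the maximum information attainable.  0 for identical
#' binary trees; 1 when every quartet is resolved oppositely; 0.5 for a
#' fully resolved tree against a star.
#'
#' @param counts A `quartet_status` object (or anything with fields
#'   `Q`, `s`, `d`, `r1`, `r2`).
#' @return Proportion in `[0, 1]`.
#' @export
quartet_divergence <- function(counts) {
  if (counts$Q == 0) abort("No quartets (Q = 0).")
  (2 * counts$d + counts$r1 + counts$r2) / (2 * counts$Q)
}

#' Shared-quartet proportion relative to a reference tree
#'
#' `s / (s + d + r2)`: quartets resolved identically in both trees,
#' normalized against the number of quartets the *reference* (tree 2)
#' resolves.  Quartets the reference leaves unresolved (its polytomies) are
#' excluded from the denominator by construction.  Not symmetric in its two
#' trees.
#'
#' @inheritParams quartet_divergence
#' @return Proportion in `[0, 1]`.
#' @export
shared_quartet_proportion <- function(counts) {
  denom <- counts$s + counts$d + counts$r2
  if (denom == 0) abort("Reference tree resolves no quartets.")
  counts$s / denom
}

#' Robinson-Foulds distance scaled by the test tree's resolution
#'
#' Raw RF is the size of the symmetric difference of the two trees'
#' non-trivial split sets.  The normalized value divides raw RF by the test
#' tree's resolution fraction (its non-trivial split count over the binary
#' maximum `n - 3`), so that poorly resolved consensus trees are not
#' rewarded for conflicting with fewer splits.  A completely unresolved
#' test tree has no defined value and raises an error.
#'
#' @param test,ref `phylo` objects over an identical leaf set.
#' @param raw Return the raw symmetric-difference count instead.
#' @return A single non-negative number.
#' @export
normalized_rf <- function(test, ref, raw = FALSE) {
  s1 <- bipartition_set(test)
  s2 <- bipartition_set(ref)
  if (!identical(attr(s1, "leaves"), attr(s2, "leaves"))) {
    abort("Trees must share an identical leaf set.")
  }
  rf <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  if (raw) {
    return(rf)
  }
  n <- length(attr(s1, "leaves"))
  resolution <- length(s1) / (n - 3)
  if (resolution == 0) {
    abort("Test tree is completely unresolved; normalized RF undefined.")
  }
  rf / resolution
}

#' Count of shared (bi)partitions
#'
#' Number of non-trivial splits present in both trees.  The default counts
#' unrooted bipartitions; `rooted = TRUE` counts matched rooted clades
#' instead (both trees must then be rooted), a convention some clade
#' counting tools use.
#'
#' @param test,ref `phylo` objects over an identical leaf set.
#' @param rooted Count rooted clades rather than unrooted splits.
#' @return Integer count.
#' @export
shared_partitions <- function(test, ref, rooted = FALSE) {
  if (!rooted) {
    s1 <- bipartition_set(test)
    s2 <- bipartition_set(ref)
    if (!identical(attr(s1, "leaves"), attr(s2, "leaves"))) {
      abort("Trees must share an identical leaf set.")
    }
    return(length(intersect(s1, s2)))
  }
  if (!ape::is.rooted(test) || !ape::is.rooted(ref)) {
    abort("Rooted clade counting requires rooted trees.")
  }
  length(intersect(clade_set(test), clade_set(ref)))
}

clade_set <- function(phy) {
  n <- length(phy$tip.label)
  post <- ape::reorder.phylo(phy, "postorder")
  clus <- vector("list", n + phy$Nnode)
  for (i in seq_len(n)) clus[[i]] <- phy$tip.label[i]
  for (i in seq_len(nrow(post$edge))) {
    p <- post$edge[i, 1]
    clus[[p]] <- c(clus[[p]], clus[[post$edge[i, 2]]])
  }
  root <- n + 1L
  internal <- setdiff(unique(post$edge[, 1]), root)
  out <- vapply(
    clus[internal],
    function(x) paste(sort(x), collapse = ","),
    character(1)
  )
  sizes <- lengths(clus[internal])
  unique(out[sizes >= 2 & sizes <= n - 1])
}

#' All congruence metrics for a test tree against a reference
#'
#' Convenience wrapper: optionally prunes both trees to their common taxa,
#' then computes quartet status counts, quartet divergence, shared-quartet
#' proportion, raw and resolution-normalized RF, and shared partition
#' counts.  The normalized RF is `NA` for a completely unresolved test
#' tree.
#'
#' @param test Test tree (`phylo`), e.g. a strict consensus of MP trees.
#' @param ref Reference tree (`phylo`).
#' @param prune Prune both trees to their shared taxa first.
#' @return One-row tibble of counts and metrics.
#' @export
tree_congruence <- function(test, ref, prune = TRUE) {
  if (prune) {
    pr <- prune_to_common(test, ref)
    test <- pr$t1
    ref <- pr$t2
  }
  qc <- quartet_status_counts(test, ref)
  resolved_ref <- qc$s + qc$d + qc$r2
  tibble(
    n_common = qc$n,
    Q = qc$Q, s = qc$s, d = qc$d, r1 = qc$r1, r2 = qc$r2, u = qc$u,
    quartet_divergence = quartet_divergence(qc),
    shared_quartet_proportion = if (resolved_ref > 0) {
      shared_quartet_proportion(qc)
    } else {
      NA_real_
    },
    rf_raw = normalized_rf(test, ref, raw = TRUE),
    rf_normalized = tryCatch(
      normalized_rf(test, ref),
      error = function(e) NA_real_
    ),
    shared_partitions = shared_partitions(test, ref)
  )
}
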