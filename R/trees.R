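#' Parse a Newick tree string
#'
#' Thin, validating wrapper around [ape::read.tree()].  Polytomies are
#' preserved; branch lengths and node support labels are parsed but ignored
#' by all congruence metrics in this package.
#'
#' @param text A single Newick string (terminating `;` optional).
#' @return A `phylo` object.
#' @examples
#' parse_tree("((A,B),(C,D));")
#' @export
parse_tree <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    abort(sprintf(
      "Malformed Newick: %d '(' but %d ')'.", n_open, n_close
    ))
  }
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("Malformed Newick: ", conditionMessage(e)))
  )
  if (is.null(phy)) abort("Malformed Newick: could not parse tree text.")
  validate_tree(phy)
}

validate_tree <- function(phy) {
  if (!inherits(phy, "phylo")) abort("Not a 'phylo' object.")
  labs <- phy$tip.label
  if (any(is.na(labs) | labs == "")) abort("Empty leaf label.")
  dup <- labs[duplicated(labs)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate leaf label(s): %s", paste(unique(dup), collapse = ", ")))
  }
  phy
}

#' Serialize a tree to Newick
#'
#' Leaf order within each node is canonicalized (rotation by smallest
#' descendant label) so that serialization is deterministic: two trees with
#' the same bipartition set and branch lengths serialize identically.
#'
#' @param phy A `phylo` object.
#' @param digits Number of digits for branch lengths.
#' @return A Newick string.
#' @export
write_tree <- function(phy, digits = 10) {
  validate_tree(phy)
  phy <- ape::rotateConstr(phy, sort(phy$tip.label))
  ape::write.tree(phy, digits = digits)
}

#' Read trees from a NEXUS TREES block
#'
#' @param file Path to a NEXUS file containing a TREES block.
#' @return A `multiPhylo` (even for a single tree).
#' @export
read_nexus_trees <- function(file) {
  trees <- ape::read.nexus(file)
  if (inherits(trees, "phylo")) trees <- c(trees)
  for (t in trees) validate_tree(t)
  trees
}

#' Prune a tree to a taxon subset and root it on an outgroup
#'
#' Taxa outside `keep` are dropped, degree-2 nodes created by pruning are
#' suppressed, and the result is rooted so that `outgroup` is sister to all
#' remaining taxa.  Congruence metrics in this package operate on unrooted
#' topologies; rooting matters only for display, serialization and the
#' rooted clade-count variant.
#'
#' @param phy A `phylo` object.
#' @param keep Character vector of leaf labels to retain (must be a subset
#'   of the tree's labels).
#' @param outgroup Single label in `keep` used to root the result; `NULL`
#'   leaves the pruned tree unrooted.
#' @return A `phylo` object with leaves exactly `keep`.
#' @export
prune_and_root <- function(phy, keep, outgroup = NULL) {
  validate_tree(phy)
  missing <- setdiff(keep, phy$tip.label)
  if (length(missing) > 0) {
    abort(sprintf("Taxa not in tree: %s", paste(missing, collapse = ", ")))
  }
  if (!is.null(outgroup) && !outgroup %in% keep) {
    abort(sprintf("Outgroup '%s' is not in `keep`.", outgroup))
  }
  if (length(keep) < 3) abort("Need at least 3 taxa after pruning.")
  phy <- ape::keep.tip(phy, keep)
  phy <- ape::collapse.singles(phy)
  if (!is.null(outgroup)) {
    phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  }
  validate_tree(phy)
}

#' Prune two trees to their shared taxa
#'
#' @param t1,t2 `phylo` objects.
#' @param min_taxa Minimum number of shared taxa required.
#' @return A list with elements `t1` and `t2` restricted to common leaves.
#' @export
prune_to_common <- function(t1, t2, min_taxa = 4) {
  common <- intersect(t1$tip.label, t2$tip.label)
  if (length(common) < min_taxa) {
    abort(sprintf(
      "Trees share only %d taxa (need >= %d).", length(common), min_taxa
    ))
  }
  list(
    t1 = ape::collapse.singles(ape::keep.tip(t1, common)),
    t2 = ape::collapse.singles(ape::keep.tip(t2, common))
  )
}

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge of the unrooted topology splits the leaf set in two;
#' trivial splits (one block a singleton or empty) are excluded.  A split is
#' canonically encoded as the comma-joined sorted block *not* containing the
#' lexicographically smallest leaf label, so split sets from different trees
#' over the same taxa are directly comparable with set operations.
#'
#' @param phy A `phylo` object with >= 4 leaves.
#' @return Character vector (possibly empty) of canonical split encodings,
#'   with the full leaf set attached as attribute `leaves`.
#' @export
bipartition_set <- function(phy) {
  validate_tree(phy)
  n <- length(phy$tip.label)
  if (n < 4) abort("Bipartitions require >= 4 leaves.")
  labs <- phy$tip.label
  ref <- sort(labs)[1]
  post <- ape::reorder.phylo(phy, "postorder")
  nnode <- n + phy$Nnode
  clus <- matrix(FALSE, nnode, n)
  clus[cbind(seq_len(n), seq_len(n))] <- TRUE
  for (i in seq_len(nrow(post$edge))) {
    p <- post$edge[i, 1]
    ch <- post$edge[i, 2]
    clus[p, ] <- clus[p, ] | clus[ch, ]
  }
  root <- n + 1L
  internal <- setdiff(unique(post$edge[, 2]), seq_len(n))
  out <- character(0)
  for (v in internal) {
    size <- sum(clus[v, ])
    if (size < 2 || size > n - 2) next
    block <- labs[clus[v, ]]
    if (ref %in% block) block <- labs[!clus[v, ]]
    out <- c(out, paste(sort(block), collapse = ","))
  }
  out <- unique(out)
  # the root's "virtual" split is covered by its children; for rooted binary
  # trees one child of the root duplicates the other's complement, handled
  # by unique() above.
  structure(sort(out), leaves = sort(labs))
}

#' Strict and majority-rule consensus
#'
#' Strict consensus retains exactly the splits present in every input tree;
#' the majority-rule variant (`p = 0.5`) retains splits present in more than
#' half of them.  Construction is delegated to [ape::consensus()]; the
#' resulting split set is the exact intersection of the inputs' split sets.
#'
#' @param trees A list / `multiPhylo` of trees over an identical leaf set.
#' @param p Split-frequency threshold: 1 for strict, 0.5 for majority rule.
#' @return An (unrooted) `phylo` consensus tree.
#' @export
strict_consensus <- function(trees, p = 1) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, validate_tree)
  if (length(trees) == 0) abort("No trees supplied.")
  labsets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(labsets, identical, logical(1), labsets[[1]]))) {
    abort("All trees must share an identical leaf set.")
  }
  if (length(trees) == 1) {
    return(ape::unroot(trees[[1]]))
  }
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = p, check.labels = TRUE)
  validate_tree(cons)
}

#' @rdname strict_consensus
#' @export
majority_consensus <- function(trees) strict_consensus(trees, p = 0.5)
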