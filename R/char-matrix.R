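#' Character matrices for mixed morphology + molecular data
#'
#' A `char_matrix` is a taxa-by-characters table of state sets.  Each cell
#' is a string: a single state symbol (`"0"`, `"a"`, ...), a sorted
#' concatenation of symbols for a polymorphic / ambiguous cell (`"01"`),
#' `"?"` for missing, or `"-"` for inapplicable.  Every column carries a
#' partition tag (`morphology`, `dna` or `indel`).  All characters are
#' treated as unordered.
#'
#' Missing and inapplicable cells are scored identically by the parsimony
#' engine (both contribute the full state set), but are kept distinct so
#' that exported hypothetical-ancestor rows can preserve inapplicability.
#'
#' @param data Character matrix (taxa x characters) of cell strings.
#' @param taxa Character vector of unique taxon labels (defaults to
#'   rownames of `data`).
#' @param partition Character vector, one tag per column, each one of
#'   `"morphology"`, `"dna"`, `"indel"`.
#' @param char_names Optional character names (defaults to colnames).
#' @return An object of class `char_matrix`.
#' @export
char_matrix <- function(data, taxa = rownames(data), partition = "morphology",
                        char_names = colnames(data)) {
  data <- as.matrix(data)
  mode(data) <- "character"
  if (is.null(taxa)) abort("Taxon labels are required.")
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) {
    abort(sprintf(
      "Duplicate taxon label(s): %s",
      paste(unique(taxa[duplicated(taxa)]), collapse = ", ")
    ))
  }
  if (length(taxa) != nrow(data)) abort("length(taxa) != nrow(data).")
  if (length(partition) == 1) partition <- rep(partition, ncol(data))
  if (length(partition) != ncol(data)) abort("One partition tag per column required.")
  bad <- setdiff(unique(partition), c("morphology", "dna", "indel"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown partition tag(s): %s", paste(bad, collapse = ", ")))
  }
  if (is.null(char_names)) char_names <- paste0("c", seq_len(ncol(data)))
  data[is.na(data) | data == ""] <- "?"
  data <- normalize_cells(data)
  dimnames(data) <- list(taxa, char_names)
  structure(
    list(
      data = data,
      taxa = taxa,
      partition = as.character(partition)
    ),
    class = "char_matrix"
  )
}

# sort symbols within multi-state cells so "10" and "01" compare equal
normalize_cells <- function(data) {
  multi <- nchar(data) > 1 & data != "?" & data != "-"
  if (any(multi)) {
    data[multi] <- vapply(
      strsplit(data[multi], ""),
      function(s) paste(sort(unique(s)), collapse = ""),
      character(1)
    )
  }
  data
}

#' @export
dim.char_matrix <- function(x) dim(x$data)

#' @export
print.char_matrix <- function(x, ...) {
  tab <- table(factor(x$partition, levels = c("morphology", "dna", "indel")))
  cat(sprintf(
    "<char_matrix> %d taxa x %d characters (morphology %d, dna %d, indel %d)\n",
    nrow(x$data), ncol(x$data), tab[["morphology"]], tab[["dna"]], tab[["indel"]]
  ))
  n_show <- min(6L, nrow(x$data))
  c_show <- min(10L, ncol(x$data))
  blk <- x$data[seq_len(n_show), seq_len(c_show), drop = FALSE]
  cells <- apply(blk, 1, function(r) {
    paste(ifelse(nchar(r) > 1, paste0("{", r, "}"), r), collapse = "")
  })
  for (i in seq_len(n_show)) {
    cat(sprintf("  %-12s %s%s\n", x$taxa[i], cells[i], if (c_show < ncol(x$data)) "..." else ""))
  }
  if (n_show < nrow(x$data)) cat(sprintf("  ... %d more taxa\n", nrow(x$data) - n_show))
  invisible(x)
}

#' @export
`[.char_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$data))
  if (missing(j)) j <- seq_len(ncol(x$data))
  if (is.character(i)) {
    miss <- setdiff(i, x$taxa)
    if (length(miss) > 0) {
      abort(sprintf("Unknown taxa: %s", paste(miss, collapse = ", ")))
    }
    i <- match(i, x$taxa)
  }
  char_matrix(
    x$data[i, j, drop = FALSE],
    taxa = x$taxa[i],
    partition = x$partition[j],
    char_names = colnames(x$data)[j]
  )
}

#' Restrict a character matrix to a set of taxa
#'
#' @param m A `char_matrix`.
#' @param taxa Labels to keep, in the requested order.
#' @return A `char_matrix` over `taxa`.
#' @export
subset_taxa <- function(m, taxa) m[taxa, ]

#' Columns carrying given partition tags
#'
#' @param m A `char_matrix`.
#' @param tags Partition tags to select.
#' @return Integer column indices.
#' @export
partition_columns <- function(m, tags) which(m$partition %in% tags)

#' @importFrom tibble as_tibble
#' @method as_tibble char_matrix
#' @export
as_tibble.char_matrix <- function(x, ...) {
  tibble(
    taxon = rep(x$taxa, times = ncol(x$data)),
    character = rep(colnames(x$data), each = nrow(x$data)),
    partition = rep(x$partition, each = nrow(x$data)),
    cell = as.vector(x$data)
  )
}

#' Column alphabets of a character matrix
#'
#' The alphabet of a column is the sorted set of state symbols observed in
#' non-missing, non-inapplicable cells (polymorphic cells contribute each of
#' their symbols).
#'
#' @param m A `char_matrix`.
#' @return List of character vectors, one per column.
#' @export
column_alphabets <- function(m) {
  lapply(seq_len(ncol(m$data)), function(j) {
    cells <- m$data[, j]
    cells <- cells[cells != "?" & cells != "-"]
    sort(unique(unlist(strsplit(cells, ""))))
  })
}

#' Subsample character columns within a partition
#'
#' Draws `round(fraction * n)` distinct columns (round-half-up) uniformly
#' without replacement from the columns carrying the requested tags, where
#' `n` is the number of tagged columns.  Other partitions are dropped.
#' Deterministic given `seed`.
#'
#' @param m A `char_matrix`.
#' @param tags Partition tags to sample from (default: dna + indel).
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed.
#' @return A `char_matrix` containing only the sampled columns (original
#'   column order preserved when `fraction == 1`, sampled order otherwise).
#' @export
subsample_sites <- function(m, tags = c("dna", "indel"), fraction, seed) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must be in (0, 1].")
  }
  cols <- partition_columns(m, tags)
  if (length(cols) == 0) {
    abort(sprintf("No columns tagged %s.", paste(tags, collapse = "/")))
  }
  if (fraction == 1) {
    return(m[, cols])
  }
  k <- round_half_up(fraction * length(cols))
  k <- max(1L, min(length(cols), as.integer(k)))
  pick <- with_local_seed(seed, sample(cols, k, replace = FALSE))
  m[, pick]
}

#' Append taxa that share the same characters
#'
#' Row-binds character matrices over an identical character set -- the
#' operation that adds hypothetical-ancestor terminals (or any extra taxa
#' scored for the same characters) to an existing matrix.  Compare
#' [combine_partitions()], which concatenates *characters* across a shared
#' taxon set.
#'
#' @param ... `char_matrix` objects with identical columns and disjoint
#'   taxa.
#' @return A `char_matrix` with the union of the rows.
#' @export
bind_taxa <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && !inherits(parts[[1]], "char_matrix")) {
    parts <- parts[[1]]
  }
  stopifnot(length(parts) >= 1)
  first <- parts[[1]]
  for (p in parts[-1]) {
    if (!identical(colnames(p$data), colnames(first$data)) ||
      !identical(p$partition, first$partition)) {
      abort("All parts must share identical characters and partition tags.")
    }
  }
  taxa <- unlist(lapply(parts, function(p) p$taxa))
  if (anyDuplicated(taxa)) {
    abort(sprintf(
      "Duplicate taxa across parts: %s",
      paste(unique(taxa[duplicated(taxa)]), collapse = ", ")
    ))
  }
  char_matrix(
    do.call(rbind, lapply(parts, function(p) p$data)),
    taxa = taxa,
    partition = first$partition,
    char_names = colnames(first$data)
  )
}

#' Combine character-matrix partitions into one matrix
#'
#' Column counts add and partition tags are preserved.  Taxa present in one
#' part but absent from another are filled with MISSING (`?`) across the
#' absent part -- this is how morphology-only fossils join a combined
#' morphology + DNA matrix.
#'
#' @param ... `char_matrix` objects (or a single list of them).
#' @return A combined `char_matrix` whose taxa are the union of the inputs'
#'   taxa (in order of first appearance).
#' @export
combine_partitions <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && !inherits(parts[[1]], "char_matrix")) {
    parts <- parts[[1]]
  }
  stopifnot(length(parts) >= 1)
  for (p in parts) {
    if (!inherits(p, "char_matrix")) abort("All parts must be char_matrix objects.")
  }
  if (length(parts) == 1) {
    return(parts[[1]])
  }
  taxa <- Reduce(union, lapply(parts, function(p) p$taxa))
  blocks <- lapply(parts, function(p) {
    blk <- matrix("?", length(taxa), ncol(p$data),
      dimnames = list(taxa, colnames(p$data))
    )
    blk[p$taxa, ] <- p$data
    blk
  })
  nm <- unlist(lapply(blocks, colnames))
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  char_matrix(
    do.call(cbind, blocks),
    taxa = taxa,
    partition = unlist(lapply(parts, function(p) p$partition)),
    char_names = nm
  )
}
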