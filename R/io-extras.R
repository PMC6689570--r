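#' Read aligned FASTA sequences as a DNA character matrix
#'
#' Convenience reader for aligned nucleotide FASTA: each sequence becomes a
#' taxon row of single-site `dna` columns.  Gaps and ambiguity codes other
#' than `acgt` are read as missing.
#'
#' @param file Path to an aligned FASTA file.
#' @return A `char_matrix` with partition `dna`.
#' @export
read_fasta_matrix <- function(file) {
  dna <- ape::read.dna(file, format = "fasta", as.character = TRUE)
  if (is.list(dna)) abort("Sequences are not aligned (unequal lengths).")
  dna <- tolower(dna)
  dna[!dna %in% c("a", "c", "g", "t")] <- "?"
  char_matrix(dna,
    taxa = rownames(dna), partition = "dna",
    char_names = sprintf("d%05d", seq_len(ncol(dna)))
  )
}

#' Export a character matrix as CSV for inspection
#'
#' One row per taxon, one column per character, cells as their state
#' strings (`01` for a polymorphic cell); a leading `partition` header row
#' records the partition tags.
#'
#' @param m A `char_matrix`.
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_matrix_csv <- function(m, file) {
  stopifnot(inherits(m, "char_matrix"))
  out <- rbind(partition = m$partition, m$data)
  utils::write.csv(out, file, quote = TRUE)
  invisible(file)
}

#' Serialize a search result to NEXUS trees plus JSON metadata
#'
#' Writes the retained optimal trees and their strict consensus as a NEXUS
#' TREES file, and the score/settings as a JSON sidecar.
#'
#' @param x An `mp_search` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_search_result <- function(x, dir) {
  stopifnot(inherits(x, "mp_search"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  trees <- c(unclass(x$trees), list(x$consensus))
  names(trees) <- c(
    sprintf("optimal_%03d", seq_along(x$trees)),
    "strict_consensus"
  )
  class(trees) <- "multiPhylo"
  ape::write.nexus(trees, file = file.path(dir, "trees.nex"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      c(list(score = x$score, n_optimal = length(x$trees)), x$settings),
      file.path(dir, "search.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
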