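#' Read a character matrix from a NEXUS CHARACTERS/DATA block
#'
#' Supports the dialect used for morphological and molecular matrices:
#' `DIMENSIONS NTAX/NCHAR`, `FORMAT` with `MISSING`, `GAP`, `SYMBOLS` and
#' `INTERLEAVE`, sequential or interleaved `MATRIX` sections, quoted taxon
#' labels, bracketed comments, and polymorphic / ambiguous cells written as
#' `{01}` or `(01)`.  Polymorphic cells are preserved as state sets rather
#' than collapsed to missing, which general-purpose readers tend to do and
#' which would destroy the ambiguity sets carried by hypothetical-ancestor
#' rows.
#'
#' The gap symbol is recorded as inapplicable (`-`) for morphology columns
#' and as missing for DNA, matching how indel-aware parsimony matrices are
#' conventionally scored; both contribute the full state set to the Fitch
#' engine either way.
#'
#' @param file Path to a NEXUS file (or a character vector of lines via
#'   `text`).
#' @param text Optional character scalar/vector with NEXUS content.
#' @param partition Partition tag(s) for the columns: a single tag or a
#'   vector of length NCHAR.  Defaults to `"morphology"` for STANDARD data
#'   and `"dna"` for DNA data.
#' @return A `char_matrix`.
#' @export
read_nexus_matrix <- function(file, text = NULL, partition = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else unlist(strsplit(text, "\n"))
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt) # strip [comments]
  if (!grepl("#NEXUS", txt, ignore.case = TRUE)) {
    abort("Not a NEXUS file (missing #NEXUS header).")
  }

  block <- regmatches(
    txt,
    regexpr("(?is)BEGIN\\s+(DATA|CHARACTERS)\\s*;.*?END\\s*;",
      txt,
      perl = TRUE
    )
  )
  if (length(block) == 0) abort("No DATA or CHARACTERS block found.")
  block <- block[[1]]

  grab <- function(pattern) {
    m <- regmatches(block, regexpr(pattern, block, ignore.case = TRUE, perl = TRUE))
    if (length(m) == 0) NA_character_ else m
  }
  ntax <- grab("NTAX\\s*=\\s*\\d+")
  nchar_ <- grab("NCHAR\\s*=\\s*\\d+")
  if (is.na(ntax) || is.na(nchar_)) abort("DIMENSIONS must declare NTAX and NCHAR.")
  ntax <- as.integer(sub(".*=\\s*", "", ntax))
  nchar_ <- as.integer(sub(".*=\\s*", "", nchar_))

  fmt <- regmatches(block, regexpr("FORMAT[^;]*;", block, ignore.case = TRUE))
  fmt <- if (length(fmt)) fmt[[1]] else ""
  get_sym <- function(key, default) {
    m <- regmatches(fmt, regexpr(paste0(key, "\\s*=\\s*\\S"), fmt, ignore.case = TRUE))
    if (length(m) == 0) default else substring(m, nchar(m), nchar(m))
  }
  missing_sym <- get_sym("MISSING", "?")
  gap_sym <- get_sym("GAP", "-")
  datatype <- toupper(sub(".*DATATYPE\\s*=\\s*(\\w+).*", "\\1",
    fmt,
    ignore.case = TRUE
  ))
  if (!datatype %in% c("STANDARD", "DNA")) datatype <- "STANDARD"
  symbols <- regmatches(fmt, regexpr('SYMBOLS\\s*=\\s*"[^"]*"', fmt, ignore.case = TRUE))
  alphabet <- if (length(symbols)) {
    setdiff(strsplit(gsub('.*"([^"]*)".*', "\\1", symbols), "")[[1]], " ")
  } else if (datatype == "DNA") {
    c("a", "c", "g", "t")
  } else {
    as.character(0:9)
  }

  mat_txt <- regmatches(
    block,
    regexpr("(?is)MATRIX\\s(.*?);", block, perl = TRUE)
  )
  if (length(mat_txt) == 0) abort("No MATRIX section found.")
  mat_lines <- strsplit(sub(";\\s*$", "", sub("^MATRIX", "", mat_txt,
    ignore.case = TRUE
  )), "\n")[[1]]
  mat_lines <- trimws(mat_lines)
  mat_lines <- mat_lines[mat_lines != ""]

  rows <- list()
  order_seen <- character(0)
  for (ln in mat_lines) {
    if (grepl("^'", ln)) {
      label <- sub("^'([^']*)'.*", "\\1", ln)
      rest <- sub("^'[^']*'\\s*", "", ln)
    } else {
      label <- sub("\\s.*", "", ln)
      rest <- sub("^\\S+\\s*", "", ln)
    }
    if (label == "" || rest == "") next
    cells <- tokenize_nexus_row(gsub("\\s", "", rest))
    if (!label %in% names(rows)) {
      rows[[label]] <- cells
      order_seen <- c(order_seen, label)
    } else {
      rows[[label]] <- c(rows[[label]], cells) # interleaved continuation
    }
  }
  if (length(rows) != ntax) {
    abort(sprintf("Declared NTAX=%d but found %d taxa.", ntax, length(rows)))
  }
  lens <- lengths(rows)
  if (any(lens != nchar_)) {
    bad <- order_seen[lens[order_seen] != nchar_][1]
    abort(sprintf(
      "Declared NCHAR=%d but taxon '%s' has %d characters.",
      nchar_, bad, lens[[bad]]
    ))
  }

  data <- do.call(rbind, rows[order_seen])
  # map missing/gap onto canonical symbols
  data[data == missing_sym] <- "?"
  if (datatype == "DNA") {
    data[data == gap_sym] <- "?"
  } else {
    data[data == gap_sym] <- "-"
  }
  data <- tolower_if_dna(data, datatype)
  obs <- unique(unlist(strsplit(data[data != "?" & data != "-"], "")))
  bad <- setdiff(obs, c(alphabet, toupper(alphabet)))
  if (length(bad) > 0) {
    abort(sprintf(
      "Symbol(s) outside declared alphabet: %s",
      paste(bad, collapse = ", ")
    ))
  }
  if (is.null(partition)) {
    partition <- if (datatype == "DNA") "dna" else "morphology"
  }
  char_matrix(data, taxa = order_seen, partition = partition)
}

tolower_if_dna <- function(data, datatype) {
  if (datatype == "DNA") {
    out <- tolower(data)
    dim(out) <- dim(data)
    out
  } else {
    data
  }
}

# split a run like "01{01}2(12)?" into per-character cells
tokenize_nexus_row <- function(s) {
  out <- character(0)
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "{" || ch == "(") {
      close <- if (ch == "{") "}" else ")"
      j <- i + 1L
      while (j <= n && substr(s, j, j) != close) j <- j + 1L
      if (j > n) abort("Unclosed polymorphism bracket in MATRIX row.")
      out <- c(out, substr(s, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

#' Write a character matrix as a NEXUS DATA block
#'
#' Polymorphic cells are written `{01}`; missing and inapplicable cells use
#' `?` and `-`.  A `CHARPARTITION` command records the partition tags so the
#' file round-trips through [read_nexus_matrix()] (tags are re-attachable
#' via its `partition` argument).
#'
#' @param m A `char_matrix`.
#' @param file Path to write to; `NULL` returns the lines invisibly.
#' @return The file lines, invisibly.
#' @export
write_nexus_matrix <- function(m, file = NULL) {
  stopifnot(inherits(m, "char_matrix"))
  cells <- m$data
  multi <- nchar(cells) > 1
  cells[multi] <- paste0("{", cells[multi], "}")
  body <- apply(cells, 1, paste, collapse = "")
  labs <- m$taxa
  quoted <- ifelse(grepl("[^A-Za-z0-9_.]", labs), paste0("'", labs, "'"), labs)
  width <- max(nchar(quoted)) + 2L
  symbols <- sort(unique(unlist(column_alphabets(m))))
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(cells), ncol(cells)),
    sprintf(
      "  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"%s\";",
      paste(symbols, collapse = " ")
    ),
    "  MATRIX",
    paste0("    ", formatC(quoted, width = -width), body),
    "  ;",
    "END;",
    "",
    "BEGIN SETS;",
    sprintf(
      "  [ partition: %s ]",
      paste(sprintf("%s=%d", names(table(m$partition)), table(m$partition)),
        collapse = " "
      )
    ),
    "END;"
  )
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
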