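#' Ancestral-state reconstruction under acctran and deltran
#'
#' Unit-cost (Fitch/Sankoff) most-parsimonious reconstruction of every
#' character at every internal node of a rooted tree, with explicit
#' acctran ("accelerate transformations": prefer a state change on the
#' earliest possible branch) and deltran ("delay": retain the parental
#' state whenever doing so is most parsimonious) resolutions.  Polytomies
#' are handled exactly by the Sankoff recursion.
#'
#' Tie-breaking is a three-level hierarchy: (1) minimal implied changes,
#' always; (2) the mode's preference (change now vs. keep parent state);
#' (3) any states still tied form the mode's *ambiguity set*, and the
#' single resolved state is the alphabetically smallest member.  At the
#' root both modes share the full set of optimal states.  By construction
#' every resolution is a most-parsimonious reconstruction, so the implied
#' change count of either mode equals the character's minimum length.
#'
#' @param phy A rooted `phylo`; polytomies allowed.
#' @param m A `char_matrix` covering all leaves of `phy`.
#' @return An object of class `ancestral_states`: a list with
#'   \describe{
#'     \item{states}{tibble with one row per internal node x character:
#'       downpass set, MPR set (states attained at that node by at least
#'       one most-parsimonious reconstruction), acctran / deltran resolved
#'       states and ambiguity sets, and an `all_inapplicable` flag.}
#'     \item{steps}{integer vector of per-character minimum change counts.}
#'   }
#' @export
reconstruct_ancestral_states <- function(phy, m) {
  validate_tree(phy)
  if (!ape::is.rooted(phy)) abort("Tree must be rooted.")
  enc <- encode_matrix(m, taxa = phy$tip.label)
  st <- phylo_structure(phy)
  n <- st$n
  root <- st$post_internal[length(st$post_internal)]
  internal <- st$post_internal
  pre_internal <- rev(internal)
  parent <- integer(st$n_nodes)
  for (p in seq_along(st$kids)) {
    for (ch in st$kids[[p]] %||% integer(0)) parent[ch] <- p
  }

  nch <- ncol(enc$masks)
  steps <- integer(nch)
  rows <- vector("list", nch)
  # propagate "all descendants inapplicable" upward once
  inap <- m$data[match(phy$tip.label, m$taxa), , drop = FALSE] == "-"
  inap_node <- matrix(FALSE, st$n_nodes, nch)
  inap_node[seq_len(n), ] <- inap
  for (v in internal) {
    inap_node[v, ] <- apply(inap_node[st$kids[[v]], , drop = FALSE], 2, all)
  }

  for (j in seq_len(nch)) {
    k <- enc$nstates[j]
    alpha <- enc$alphabets[[j]]
    if (k == 0) {
      rows[[j]] <- tibble(
        node = internal, character = colnames(m$data)[j],
        downpass = "?", mpr = "?",
        acctran = "?", deltran = "?",
        acctran_set = "?", deltran_set = "?",
        all_inapplicable = inap_node[internal, j]
      )
      next
    }
    g <- sankoff_down(st, enc$masks[, j], k)
    total <- min(g[root, ])
    steps[j] <- as.integer(total)
    # outside costs h for the MPR set
    INF <- .Machine$integer.max %/% 4L
    h <- matrix(INF, st$n_nodes, k)
    h[root, ] <- 0L
    for (p in pre_internal) {
      ks <- st$kids[[p]]
      tot_p <- h[p, ]
      for (c in ks) tot_p <- tot_p + pmin(g[c, ], min(g[c, ]) + 1L)
      for (c in ks) {
        rest <- tot_p - pmin(g[c, ], min(g[c, ]) + 1L)
        h[c, ] <- pmin(rest, min(rest) + 1L)
      }
    }

    down_set <- character(length(internal))
    mpr_set <- character(length(internal))
    acc_state <- character(length(internal))
    del_state <- character(length(internal))
    acc_set <- character(length(internal))
    del_set <- character(length(internal))
    # resolved states for propagation, indexed by node id
    res_acc <- integer(st$n_nodes)
    res_del <- integer(st$n_nodes)

    set_str <- function(idx) paste(alpha[sort(idx)], collapse = "")

    for (v in pre_internal) {
      i <- match(v, internal)
      # downpass (Fitch-style set from the Sankoff costs): states of cost
      # min over the subtree
      down_set[i] <- set_str(which(g[v, ] == min(g[v, ])))
      mpr <- which(g[v, ] + h[v, ] == total)
      mpr_set[i] <- set_str(mpr)
      if (v == root) {
        amb <- which(g[v, ] == min(g[v, ]))
        res_acc[v] <- amb[1]
        res_del[v] <- amb[1]
        acc_state[i] <- alpha[amb[1]]
        del_state[i] <- alpha[amb[1]]
        acc_set[i] <- set_str(amb)
        del_set[i] <- set_str(amb)
      } else {
        p <- parent[v]
        for (mode in c("acc", "del")) {
          sp <- if (mode == "acc") res_acc[p] else res_del[p]
          vals <- g[v, ] + as.integer(seq_len(k) != sp)
          A <- which(vals == min(vals))
          pref <- if (mode == "del") {
            if (sp %in% A) sp else A
          } else {
            if (any(A != sp)) A[A != sp] else A
          }
          r <- pref[1]
          if (mode == "acc") {
            res_acc[v] <- r
            acc_state[i] <- alpha[r]
            acc_set[i] <- set_str(pref)
          } else {
            res_del[v] <- r
            del_state[i] <- alpha[r]
            del_set[i] <- set_str(pref)
          }
        }
      }
    }
    rows[[j]] <- tibble(
      node = internal, character = colnames(m$data)[j],
      downpass = down_set, mpr = mpr_set,
      acctran = acc_state, deltran = del_state,
      acctran_set = acc_set, deltran_set = del_set,
      all_inapplicable = inap_node[internal, j]
    )
  }

  structure(
    list(
      states = dplyr::bind_rows(rows),
      steps = steps,
      tree = phy
    ),
    class = "ancestral_states"
  )
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat(sprintf(
    "<ancestral_states> %d internal nodes x %d characters, total length %d\n",
    length(unique(x$states$node)), length(x$steps), sum(x$steps)
  ))
  invisible(x)
}

#' Tally implied changes of a mode's resolution (internal audit helper)
#'
#' Counts branch changes implied by the resolved single states of a mode,
#' which for binary trees must equal the Fitch length of each character.
#'
#' @param phy Rooted `phylo` used for the reconstruction.
#' @param m The `char_matrix`.
#' @param anc An `ancestral_states` object.
#' @param mode `"acctran"` or `"deltran"`.
#' @return Integer vector of per-character implied change counts.
#' @export
implied_changes <- function(phy, m, anc, mode = c("acctran", "deltran")) {
  mode <- match.arg(mode)
  st <- phylo_structure(phy)
  n <- st$n
  chars <- unique(anc$states$character)
  res <- matrix(NA_character_, st$n_nodes, length(chars))
  idx <- cbind(
    anc$states$node,
    match(anc$states$character, chars)
  )
  res[idx] <- anc$states[[mode]]
  leaf_cells <- m$data[match(phy$tip.label, m$taxa), chars, drop = FALSE]
  counts <- integer(length(chars))
  for (j in seq_along(chars)) {
    cnt <- 0L
    for (p in seq_along(st$kids)) {
      ks <- st$kids[[p]]
      if (is.null(ks)) next
      sp <- res[p, j]
      for (ch in ks) {
        s_ch <- if (ch <= n) leaf_cells[ch, j] else res[ch, j]
        if (is.na(sp) || is.na(s_ch)) next
        if (s_ch %in% c("?", "-")) next
        # leaf polymorphic/ambiguous cells count no change if the parental
        # state is among their states
        if (!grepl(sp, s_ch, fixed = TRUE)) cnt <- cnt + 1L
      }
    }
    counts[j] <- cnt
  }
  counts
}

#' Synthesize hypothetical-ancestor terminals from a reference tree
#'
#' Optimizes the (morphology) characters of `m` onto the rooted reference
#' topology and returns one new terminal row per internal node, ready to be
#' appended to a character matrix with [bind_taxa()] and analysed
#' as ordinary taxa.  Cells are the mode's resolved state, or the mode's
#' ambiguity set written as a polymorphic cell when the tie-break hierarchy
#' leaves more than one state (the root keeps its full optimal-state set).
#' A node all of whose descendant leaves are inapplicable for a character
#' is exported inapplicable.
#'
#' @param ref Rooted reference `phylo` whose leaves all occur in `m`.
#' @param m A `char_matrix` (typically the morphology partition).
#' @param mode `"acctran"` or `"deltran"`.
#' @param prefix Name prefix for ancestor rows; node `v` becomes
#'   `<prefix><v>`.
#' @return A `char_matrix` of ancestor rows (partition `morphology`).
#' @export
export_hypothetical_ancestors <- function(ref, m, mode = c("acctran", "deltran"),
                                          prefix = "hta_") {
  mode <- match.arg(mode)
  missing <- setdiff(ref$tip.label, m$taxa)
  if (length(missing) > 0) {
    abort(sprintf(
      "Reference leaves without matrix rows: %s",
      paste(missing, collapse = ", ")
    ))
  }
  mm <- m[ref$tip.label, ]
  anc <- reconstruct_ancestral_states(ref, mm)
  set_col <- paste0(sub("tran$", "", mode), "tran_set")
  st <- anc$states
  cell <- st[[set_col]]
  cell[st$all_inapplicable] <- "-"
  nodes <- sort(unique(st$node))
  out <- matrix("?", length(nodes), ncol(mm$data),
    dimnames = list(
      paste0(prefix, nodes),
      colnames(mm$data)
    )
  )
  out[cbind(
    match(st$node, nodes),
    match(st$character, colnames(mm$data))
  )] <- cell
  char_matrix(out, partition = mm$partition)
}
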