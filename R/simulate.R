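#' Configuration for synthetic total-evidence data sets
#'
#' Bundles the parameters of the generator that emulates the structure of a
#' combined morphology + molecular Glires-style data set: a clock-like tree
#' of extant taxa (long root-to-tip paths), short-branched morphology-only
#' fossil tips attached near internal nodes, a reference topology known
#' only for a "core" subset of extant taxa, and three character partitions
#' evolved under symmetric Mk models with discrete-gamma rate
#' heterogeneity.
#'
#' Default sizes mirror the structure of the empirical study the generator
#' emulates: 60 extant taxa of which 41 form the reference core, plus
#' morphology-only fossils; 219 morphological characters; a molecular
#' partition orders of magnitude larger than morphology; complete-ish
#' molecular data for extant taxa and no molecular data for fossils.  Rates
#' are expressed as expected changes per character per unit of tree height
#' (trees are rescaled to mean root-to-tip depth 1): morphology evolves
#' fast enough to accumulate appreciable homoplasy across the tree, as real
#' morphological matrices do, while the molecular partition is sized so
#' congruence saturates as more sites are sampled.
#'
#' @param n_extant Number of extant taxa (>= 4).
#' @param n_core Size of the extant "core" with well-corroborated
#'   affinities; the reference tree covers exactly these taxa.
#' @param n_fossil Number of fossil tips.
#' @param n_morph,n_dna,n_indel Characters per partition.
#' @param morph_states Named weights for morphology state counts
#'   (names "2", "3", ...).
#' @param rate_morph,rate_dna,rate_indel Expected changes per character
#'   along a root-to-tip path of length 1.
#' @param gamma_shape Shape of the discretized gamma (4 categories) for
#'   among-character rate variation.
#' @param extant_missing Missing-cell fraction in morphology for all taxa.
#' @param dna_missing Missing-cell fraction in the molecular partitions of
#'   extant taxa.
#' @param fossil_missing *Additional* missing fraction applied to fossil
#'   morphology cells (incomplete preservation).
#' @param fossil_attach_depth Attachment point along the chosen internal
#'   edge, as a fraction from its rootward end.
#' @param fossil_branch_scale Fossil terminal-branch length as a fraction
#'   of the mean extant terminal branch (must be < 1: fossils sit close to
#'   the internal nodes they attach near).
#' @param lineage_rate_sd Standard deviation (log scale) of lognormal
#'   lineage-specific rate multipliers applied to every extant terminal
#'   branch when characters are evolved.  Real clades mix slow- and
#'   fast-evolving lineages; the resulting long terminal branches are what
#'   fossils can break up and what rogue taxa attract.  0 disables.
#' @param rogue_terminal_extra Extra apparent branch length (in units of
#'   tree height) added to the terminal branches of *non-core* extant taxa
#'   when characters are evolved.  Taxa excluded from a well-corroborated
#'   core are typically those with unstable, long-branched positions;
#'   the added length gives them the elevated, largely saturated apparent
#'   change that makes such taxa disruptive (long-branch attraction).
#'   Set to 0 for homogeneous extant tips.
#' @param polytomy_fraction Fraction of reference-tree internal edges
#'   collapsed into polytomies (the reference is imperfectly resolved).
#' @param tree_model `"coalescent"` (ultrametric) or `"yule"`.
#' @param seed Integer seed recorded in the config.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_extant = 60, n_core = 41, n_fossil = 20,
                              n_morph = 219, n_dna = 4000, n_indel = 50,
                              morph_states = c(`2` = 0.6, `3` = 0.3, `4` = 0.1),
                              rate_morph = 1.5, rate_dna = 0.5,
                              rate_indel = 0.15, gamma_shape = 1,
                              extant_missing = 0.05, dna_missing = 0.02,
                              fossil_missing = 0.3,
                              fossil_attach_depth = 0.5,
                              fossil_branch_scale = 0.1,
                              lineage_rate_sd = 0.8,
                              rogue_terminal_extra = 0.75,
                              polytomy_fraction = 0.1,
                              tree_model = c("coalescent", "yule"),
                              seed = 1L) {
  tree_model <- match.arg(tree_model)
  cfg <- list(
    n_extant = n_extant, n_core = n_core, n_fossil = n_fossil,
    n_morph = n_morph, n_dna = n_dna, n_indel = n_indel,
    morph_states = morph_states,
    rate_morph = rate_morph, rate_dna = rate_dna, rate_indel = rate_indel,
    gamma_shape = gamma_shape,
    extant_missing = extant_missing, dna_missing = dna_missing,
    fossil_missing = fossil_missing,
    fossil_attach_depth = fossil_attach_depth,
    fossil_branch_scale = fossil_branch_scale,
    lineage_rate_sd = lineage_rate_sd,
    rogue_terminal_extra = rogue_terminal_extra,
    polytomy_fraction = polytomy_fraction,
    tree_model = tree_model, seed = as.integer(seed)
  )
  counts <- c(
    cfg$n_extant, cfg$n_fossil, cfg$n_morph, cfg$n_dna, cfg$n_indel,
    cfg$n_core
  )
  if (any(counts < 0)) abort("Counts must be non-negative.")
  if (cfg$n_extant < 4) abort("Need n_extant >= 4.")
  if (cfg$n_core > cfg$n_extant) abort("n_core cannot exceed n_extant.")
  fracs <- c(
    cfg$extant_missing, cfg$dna_missing, cfg$fossil_missing,
    cfg$fossil_attach_depth, cfg$polytomy_fraction
  )
  if (any(fracs < 0 | fracs > 1)) abort("Fractions must lie in [0, 1].")
  if (cfg$fossil_branch_scale <= 0 || cfg$fossil_branch_scale >= 1) {
    abort("fossil_branch_scale must lie in (0, 1).")
  }
  if (cfg$rogue_terminal_extra < 0) abort("rogue_terminal_extra must be >= 0.")
  if (cfg$lineage_rate_sd < 0) abort("lineage_rate_sd must be >= 0.")
  if (any(c(cfg$rate_morph, cfg$rate_dna, cfg$rate_indel) < 0)) {
    abort("Rates must be non-negative.")
  }
  structure(cfg, class = "sim_config")
}

# clock-like extant tree, rescaled to mean root-to-tip depth 1
sim_extant_tree <- function(cfg) {
  phy <- switch(cfg$tree_model,
    coalescent = ape::rcoal(cfg$n_extant),
    yule = ape::rtree(cfg$n_extant)
  )
  phy$tip.label <- sprintf("ext_%02d", seq_len(cfg$n_extant))
  depths <- ape::node.depth.edgelength(phy)[seq_len(cfg$n_extant)]
  phy$edge.length <- phy$edge.length / mean(depths)
  phy
}

#' Simulate a reference tree
#'
#' Rooted tree over the extant taxa with branch lengths (mean root-to-tip
#' depth 1), with a configured fraction of internal edges collapsed into
#' polytomies to emulate an imperfectly resolved reference topology.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return A `phylo`.
#' @export
simulate_reference_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, {
    collapse_edges(sim_extant_tree(cfg), cfg$polytomy_fraction)
  })
}

# collapse a fraction of internal edges, transferring each collapsed
# length onto the child's outgoing edges so node heights are preserved
collapse_edges <- function(phy, fraction) {
  if (fraction <= 0) {
    return(phy)
  }
  n <- length(phy$tip.label)
  internal <- which(phy$edge[, 2] > n)
  k <- floor(fraction * length(internal))
  if (k == 0) {
    return(phy)
  }
  drop <- sample(internal, k)
  for (i in drop) {
    child <- phy$edge[i, 2]
    len <- phy$edge.length[i]
    out <- which(phy$edge[, 1] == child)
    phy$edge.length[out] <- phy$edge.length[out] + len
    phy$edge.length[i] <- 0
  }
  ape::di2multi(phy, tol = 1e-12)
}

#' Attach short-branched fossil tips to a tree
#'
#' Each fossil attaches to a uniformly chosen internal edge, at
#' `fossil_attach_depth` of the way along it (from the rootward end), with
#' a terminal branch of length `fossil_branch_scale` x the mean extant
#' terminal branch x Uniform(0.5, 1).  Fossil root-to-tip depths are
#' therefore stochastically much shorter than extant depths: fossils sit
#' close in time to the ancestors whose morphology they record.  A fossil
#' on a terminal edge is an extinct stem-lineage relative of that extant
#' taxon; the default restricts attachment to internal edges.
#'
#' @param phy A `phylo` with branch lengths.
#' @param cfg A [simulation_config()].
#' @param labels Optional fossil tip labels.
#' @param where `"any"` (default) or `"internal"`: the edge set fossils
#'   may attach to.
#' @return A `phylo` with `cfg$n_fossil` extra leaves.
#' @export
attach_fossil_tips <- function(phy, cfg, labels = NULL,
                               where = c("internal", "any")) {
  stopifnot(inherits(cfg, "sim_config"))
  where <- match.arg(where)
  if (is.null(phy$edge.length)) abort("Tree must have branch lengths.")
  if (cfg$n_fossil == 0) {
    return(phy)
  }
  if (is.null(labels)) labels <- sprintf("fos_%02d", seq_len(cfg$n_fossil))
  n0 <- length(phy$tip.label)
  term_mean <- mean(phy$edge.length[phy$edge[, 2] <= n0])
  for (i in seq_len(cfg$n_fossil)) {
    n <- length(phy$tip.label)
    internal <- if (where == "internal") {
      which(phy$edge[, 2] > n)
    } else {
      seq_len(nrow(phy$edge))
    }
    e <- if (length(internal) == 1) internal else sample(internal, 1)
    child <- phy$edge[e, 2]
    elen <- phy$edge.length[e]
    pos <- (1 - cfg$fossil_attach_depth) * elen
    tiplen <- cfg$fossil_branch_scale * term_mean * runif(1, 0.5, 1)
    phy <- phytools::bind.tip(
      phy, labels[i],
      edge.length = tiplen,
      where = child, position = pos
    )
  }
  phy
}

# discretized gamma rates (4 categories, equal weights)
gamma_rates <- function(shape, ncat = 4L) {
  if (!is.finite(shape) || shape <= 0) {
    return(rep(1, ncat))
  }
  phangorn::discrete.gamma(shape, ncat)
}

#' Evolve characters along a tree under symmetric Mk models
#'
#' Characters evolve independently under a k-state symmetric Markov model
#' (uniform root state), with per-character rates drawn from a 4-category
#' discretized gamma.  DNA sites are 4-state (`acgt`), indels binary, and
#' morphology state counts are drawn from `cfg$morph_states`.  Per-cell
#' missingness is applied per partition (`extant_missing` for morphology,
#' `dna_missing` for dna/indel); fossil-specific extra missingness and the
#' removal of fossil molecular data are applied by
#' [build_synthetic_dataset()], where taxon roles are known.
#'
#' @param phy Tree with branch lengths (expected changes = rate x length).
#' @param cfg A [simulation_config()].
#' @param partitions Which partitions to generate.
#' @return A `char_matrix` over the tree's tips.
#' @export
evolve_characters <- function(phy, cfg,
                              partitions = c("morphology", "dna", "indel")) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(phy$edge.length)) abort("Tree must have branch lengths.")
  if (all(phy$edge.length == 0) &&
    any(c(cfg$rate_morph, cfg$rate_dna, cfg$rate_indel) > 0)) {
    warn("All branch lengths are zero; characters will be constant.")
  }
  rates <- gamma_rates(cfg$gamma_shape)
  parts <- list()

  if ("morphology" %in% partitions && cfg$n_morph > 0) {
    ks <- as.integer(sample(names(cfg$morph_states), cfg$n_morph,
      replace = TRUE, prob = cfg$morph_states
    ))
    cat_i <- sample.int(length(rates), cfg$n_morph, replace = TRUE)
    cols <- sim_mk_block(phy, ks, cfg$rate_morph * rates[cat_i],
      levels_fun = function(k) as.character(seq_len(k) - 1L)
    )
    cols <- mask_missing(cols, cfg$extant_missing)
    parts$morphology <- char_matrix(cols,
      taxa = phy$tip.label,
      partition = "morphology",
      char_names = sprintf("m%03d", seq_len(ncol(cols)))
    )
  }
  if ("dna" %in% partitions && cfg$n_dna > 0) {
    cat_i <- sample.int(length(rates), cfg$n_dna, replace = TRUE)
    cols <- sim_mk_block(phy, rep(4L, cfg$n_dna), cfg$rate_dna * rates[cat_i],
      levels_fun = function(k) c("a", "c", "g", "t")
    )
    cols <- mask_missing(cols, cfg$dna_missing)
    parts$dna <- char_matrix(cols,
      taxa = phy$tip.label, partition = "dna",
      char_names = sprintf("d%05d", seq_len(ncol(cols)))
    )
  }
  if ("indel" %in% partitions && cfg$n_indel > 0) {
    cat_i <- sample.int(length(rates), cfg$n_indel, replace = TRUE)
    cols <- sim_mk_block(phy, rep(2L, cfg$n_indel), cfg$rate_indel * rates[cat_i],
      levels_fun = function(k) c("0", "1")
    )
    cols <- mask_missing(cols, cfg$dna_missing)
    parts$indel <- char_matrix(cols,
      taxa = phy$tip.label, partition = "indel",
      char_names = sprintf("i%03d", seq_len(ncol(cols)))
    )
  }
  combine_partitions(parts)
}

# simulate a block of unordered Mk characters with per-character state
# count `ks` and per-character rate `rs`; grouped calls to phangorn::simSeq
sim_mk_block <- function(phy, ks, rs, levels_fun) {
  stopifnot(length(ks) == length(rs))
  out <- matrix(NA_character_, length(phy$tip.label), length(ks))
  rownames(out) <- phy$tip.label
  for (grp in split(seq_along(ks), paste(ks, signif(rs, 10)))) {
    k <- ks[grp[1]]
    r <- rs[grp[1]]
    lv <- levels_fun(k)
    if (r == 0) {
      # rate zero: every taxon inherits the (uniform) root state
      root_states <- sample(lv, length(grp), replace = TRUE)
      out[, grp] <- matrix(root_states,
        nrow(out), length(grp),
        byrow = TRUE
      )
      next
    }
    sim <- phangorn::simSeq(phy,
      l = length(grp), type = "USER", levels = lv,
      rate = r
    )
    out[, grp] <- as.character(sim)[phy$tip.label, , drop = FALSE]
  }
  out
}

mask_missing <- function(cols, fraction) {
  if (fraction <= 0) {
    return(cols)
  }
  mask <- matrix(
    runif(length(cols)) < fraction,
    nrow(cols), ncol(cols)
  )
  cols[mask] <- "?"
  cols
}

#' Build a complete synthetic total-evidence data set
#'
#' End-to-end generator: simulates the extant tree, attaches fossil tips,
#' evolves all three character partitions on the full tree, blanks the
#' molecular partitions of fossils (morphology-only fossils), applies extra
#' fossil morphology missingness, and restricts + partially collapses the
#' true tree to the designated core subset to form the reference topology.
#' Byte-reproducible given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return An object of class `synth_dataset`: list with `reference`
#'   (core-taxon reference tree), `true_tree` (binary extant tree),
#'   `full_tree` (extant + fossils), `matrix` (`char_matrix`), `roles`
#'   (tibble: taxon, role in core / other_extant / fossil) and `config`.
#' @export
build_synthetic_dataset <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, {
    true_tree <- sim_extant_tree(cfg)
    core <- sort(sample(true_tree$tip.label, cfg$n_core))
    full_tree <- attach_fossil_tips(true_tree, cfg)
    fossils <- setdiff(full_tree$tip.label, true_tree$tip.label)
    # characters evolve on a tree whose extant terminals carry
    # lineage-specific rates, and whose non-core extant terminals carry
    # extra apparent length (rogue long-branch taxa); topology unchanged
    evo_tree <- full_tree
    if (cfg$lineage_rate_sd > 0) {
      xi <- match(true_tree$tip.label, evo_tree$tip.label)
      ei <- match(xi, evo_tree$edge[, 2])
      mult <- exp(stats::rnorm(length(ei), 0, cfg$lineage_rate_sd))
      evo_tree$edge.length[ei] <- evo_tree$edge.length[ei] * mult
    }
    if (cfg$rogue_terminal_extra > 0) {
      rogue <- setdiff(true_tree$tip.label, core)
      ri <- match(rogue, evo_tree$tip.label)
      ei <- match(ri, evo_tree$edge[, 2])
      evo_tree$edge.length[ei] <- evo_tree$edge.length[ei] + cfg$rogue_terminal_extra
    }
    m <- evolve_characters(evo_tree, cfg)

    # fossils: no molecular data at all, extra morphology missingness
    if (length(fossils) > 0) {
      mol <- partition_columns(m, c("dna", "indel"))
      fi <- match(fossils, m$taxa)
      m$data[fi, mol] <- "?"
      if (cfg$fossil_missing > 0) {
        mo <- partition_columns(m, "morphology")
        blk <- m$data[fi, mo, drop = FALSE]
        extra <- matrix(
          runif(length(blk)) < cfg$fossil_missing,
          nrow(blk), ncol(blk)
        )
        blk[extra] <- "?"
        m$data[fi, mo] <- blk
      }
    }

    reference <- collapse_edges(
      ape::keep.tip(true_tree, core),
      cfg$polytomy_fraction
    )

    roles <- tibble(
      taxon = m$taxa,
      role = dplyr::case_when(
        m$taxa %in% core ~ "core",
        m$taxa %in% fossils ~ "fossil",
        TRUE ~ "other_extant"
      )
    )
    structure(
      list(
        reference = reference, true_tree = true_tree,
        full_tree = full_tree, matrix = m, roles = roles, config = cfg
      ),
      class = "synth_dataset"
    )
  })
}

#' @export
print.synth_dataset <- function(x, ...) {
  tab <- table(x$roles$role)
  cat(sprintf(
    "<synth_dataset> %d taxa (core %d, other extant %d, fossil %d), %d characters; reference over %d core taxa\n",
    nrow(x$matrix$data),
    if ("core" %in% names(tab)) tab[["core"]] else 0L,
    if ("other_extant" %in% names(tab)) tab[["other_extant"]] else 0L,
    if ("fossil" %in% names(tab)) tab[["fossil"]] else 0L,
    ncol(x$matrix$data),
    length(x$reference$tip.label)
  ))
  invisible(x)
}

#' Write a synthetic data set to disk
#'
#' Emits the character matrix as NEXUS, the three trees as Newick, and a
#' JSON manifest with taxon roles and the full configuration.
#'
#' @param x A `synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(x, dir) {
  stopifnot(inherits(x, "synth_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_nexus_matrix(x$matrix, file.path(dir, "matrix.nex"))
  ape::write.tree(x$reference, file.path(dir, "reference.nwk"))
  ape::write.tree(x$true_tree, file.path(dir, "true_tree.nwk"))
  ape::write.tree(x$full_tree, file.path(dir, "full_tree.nwk"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(
        roles = x$roles,
        config = unclass(x$config)
      ),
      file.path(dir, "manifest.json"),
      auto_unbox = TRUE
    )
  }
  invisible(dir)
}
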