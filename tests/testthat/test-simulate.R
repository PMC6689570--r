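small_cfg <- function(...) {
  simulation_config(
    n_extant = 12, n_core = 8, n_fossil = 4,
    n_morph = 40, n_dna = 150, n_indel = 10, seed = 5, ...
  )
}

test_that("simulation_config validates its inputs", {
  expect_s3_class(small_cfg(), "sim_config")
  expect_error(simulation_config(n_extant = 3), "n_extant")
  expect_error(simulation_config(n_core = 99, n_extant = 50), "n_core")
  expect_error(simulation_config(fossil_branch_scale = 1.5), "fossil_branch_scale")
  expect_error(simulation_config(extant_missing = 1.2), "Fractions")
  expect_error(simulation_config(rate_dna = -1), "Rates")
})

test_that("reference-tree simulation is seeded and respects the collapse bound", {
  cfg <- small_cfg()
  r1 <- simulate_reference_tree(cfg)
  r2 <- simulate_reference_tree(cfg)
  expect_identical(write_tree(r1), write_tree(r2))
  expect_equal(length(r1$tip.label), 12)
  # collapsing can only reduce the internal-edge count below the binary max
  expect_lte(r1$Nnode, 11)
  expect_true(all(r1$edge.length >= 0))
  # clock-like: root-to-tip depths all equal under the coalescent model
  cfg0 <- simulation_config(
    n_extant = 10, n_core = 8, polytomy_fraction = 0, seed = 2
  )
  tr <- simulate_reference_tree(cfg0)
  depths <- ape::node.depth.edgelength(tr)[1:10]
  expect_lt(diff(range(depths)), 1e-8)
  expect_equal(mean(depths), 1, tolerance = 1e-8)
})

test_that("rate zero gives constant characters; high rates approach saturation", {
  cfg <- simulation_config(
    n_extant = 8, n_core = 8, n_fossil = 0, n_morph = 100, n_dna = 0,
    n_indel = 0, rate_morph = 0, extant_missing = 0, seed = 3
  )
  ds <- build_synthetic_dataset(cfg)
  expect_true(all(apply(ds$matrix$data, 2, function(col) length(unique(col)) == 1)))

  # two-state characters on two very distant taxa differ ~50% of the time
  two <- ape::read.tree(text = "(A:8,B:8);")
  cfgb <- simulation_config(
    n_extant = 4, n_core = 4, n_fossil = 0, n_morph = 0, n_dna = 0,
    n_indel = 800, rate_indel = 1, gamma_shape = Inf, dna_missing = 0, seed = 9
  )
  m <- withr::with_seed(9, evolve_characters(two, cfgb, partitions = "indel"))
  diff_frac <- mean(m$data["A", ] != m$data["B", ])
  # saturation: P(diff) = (1 - exp(-2 * r * t)) / 2 -> 0.5; 3 SD band
  expect_lt(abs(diff_frac - 0.5), 3 * sqrt(0.25 / 800))

  # two sister taxa at tiny distance barely differ
  close <- ape::read.tree(text = "(A:0.001,B:0.001);")
  mc <- withr::with_seed(10, evolve_characters(close, cfgb, partitions = "indel"))
  expect_lt(mean(mc$data["A", ] != mc$data["B", ]), 0.02)
})

test_that("abundant clock-like characters let the search recover the generating tree", {
  cfg <- simulation_config(
    n_extant = 8, n_core = 8, n_fossil = 0, n_morph = 0, n_dna = 6000,
    n_indel = 0, dna_missing = 0, polytomy_fraction = 0,
    lineage_rate_sd = 0, seed = 31
  )
  ds <- build_synthetic_dataset(cfg)
  s <- mp_search(ds$matrix, seed = 1, method = "exhaustive")
  expect_setequal(
    as.character(bipartition_set(s$consensus)),
    as.character(bipartition_set(ds$true_tree))
  )
})

test_that("fossil tips attach with short branches near internal nodes", {
  cfg <- small_cfg()
  base <- withr::with_seed(1, {
    t <- ape::rcoal(12)
    t$tip.label <- sprintf("ext_%02d", 1:12)
    t$edge.length <- t$edge.length / mean(ape::node.depth.edgelength(t)[1:12])
    t
  })
  expect_identical(
    write_tree(attach_fossil_tips(base, simulation_config(
      n_extant = 12, n_core = 8, n_fossil = 0, seed = 1
    ))),
    write_tree(base)
  )

  grown <- withr::with_seed(2, attach_fossil_tips(base, cfg))
  fossils <- setdiff(grown$tip.label, base$tip.label)
  expect_length(fossils, 4)
  term_mean <- mean(base$edge.length[base$edge[, 2] <= 12])
  fi <- match(fossils, grown$tip.label)
  flen <- grown$edge.length[match(fi, grown$edge[, 2])]
  expect_true(all(flen <= cfg$fossil_branch_scale * term_mean * 1.0001))

  # fossils lie closer to the root than extant tips on average
  depths <- ape::node.depth.edgelength(grown)
  expect_lt(
    mean(depths[fi]),
    mean(depths[match(base$tip.label, grown$tip.label)])
  )

  # dropping the fossils recovers the original splits exactly
  back <- ape::collapse.singles(ape::drop.tip(grown, fossils))
  expect_setequal(
    as.character(bipartition_set(back)),
    as.character(bipartition_set(base))
  )
})

test_that("build_synthetic_dataset assembles roles, missingness and partitions", {
  cfg <- small_cfg()
  ds <- build_synthetic_dataset(cfg)
  expect_equal(nrow(ds$matrix$data), 16)
  expect_equal(sort(unique(ds$roles$role)), c("core", "fossil", "other_extant"))
  expect_equal(sum(ds$roles$role == "core"), 8)
  expect_equal(length(ds$reference$tip.label), 8)

  fos <- ds$roles$taxon[ds$roles$role == "fossil"]
  mol <- partition_columns(ds$matrix, c("dna", "indel"))
  expect_true(all(ds$matrix$data[fos, mol] == "?"))

  # fossil morphology carries roughly the configured extra missingness
  mo <- partition_columns(ds$matrix, "morphology")
  fos_missing <- mean(ds$matrix$data[fos, mo] == "?")
  expected <- cfg$fossil_missing + (1 - cfg$fossil_missing) * cfg$extant_missing
  n_cells <- length(fos) * length(mo)
  expect_lt(
    abs(fos_missing - expected),
    3 * sqrt(expected * (1 - expected) / n_cells)
  )

  # byte-identical regeneration from the same config
  ds2 <- build_synthetic_dataset(cfg)
  expect_identical(ds$matrix$data, ds2$matrix$data)
  expect_identical(write_tree(ds$full_tree), write_tree(ds2$full_tree))

  d <- withr::local_tempdir()
  write_synth_dataset(ds, d)
  expect_true(file.exists(file.path(d, "matrix.nex")))
  back <- read_nexus_matrix(file.path(d, "matrix.nex"))
  expect_equal(dim(back), dim(ds$matrix))
})
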