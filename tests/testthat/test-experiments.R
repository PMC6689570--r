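# a small shared dataset keeps the experiment tests fast
exp_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) {
      ds <<- build_synthetic_dataset(simulation_config(
        n_extant = 12, n_core = 9, n_fossil = 5,
        n_morph = 60, n_dna = 250, n_indel = 10, seed = 17
      ))
    }
    ds
  }
})

fast_search <- list(replicates = 2, plateau = 8)

test_that("site resampling produces the full record grid with the right matrices", {
  ds <- exp_dataset()
  extant <- ds$roles$taxon[ds$roles$role != "fossil"]
  mext <- subset_taxa(ds$matrix, extant)
  rec <- run_site_resampling(mext, ds$reference,
    levels = 1.0, reps = 1,
    seed = 4, search_args = fast_search
  )
  expect_equal(nrow(rec), 2)
  # the with-morphology arm has exactly the morphology partition extra
  expect_equal(
    rec$n_char[rec$morphology] - rec$n_char[!rec$morphology],
    sum(mext$partition == "morphology")
  )

  rec3 <- run_site_resampling(mext, ds$reference,
    levels = c(0.1, 0.4), reps = 3,
    seed = 4, search_args = fast_search
  )
  expect_equal(nrow(rec3), 12) # 2 levels x 2 arms x 3 reps
  expect_equal(
    dplyr::count(rec3, level, morphology)$n,
    rep(3, 4)
  )
  expect_error(
    run_site_resampling(mext, ds$reference, levels = c(0, 0.5), seed = 1),
    "Levels"
  )
})

test_that("experiments are reproducible bit-for-bit from (config, seed)", {
  ds <- exp_dataset()
  extant <- ds$roles$taxon[ds$roles$role != "fossil"]
  mext <- subset_taxa(ds$matrix, extant)
  r1 <- run_site_resampling(mext, ds$reference,
    levels = 0.3, reps = 2,
    seed = 99, search_args = fast_search
  )
  r2 <- run_site_resampling(mext, ds$reference,
    levels = 0.3, reps = 2,
    seed = 99, search_args = fast_search
  )
  expect_identical(
    dplyr::select(r1, -consensus),
    dplyr::select(r2, -consensus)
  )
  expect_identical(
    vapply(r1$consensus, write_tree, character(1)),
    vapply(r2$consensus, write_tree, character(1))
  )
})

test_that("stored metrics equal metrics recomputed from the stored consensus", {
  ds <- exp_dataset()
  extant <- ds$roles$taxon[ds$roles$role != "fossil"]
  mext <- subset_taxa(ds$matrix, extant)
  rec <- run_site_resampling(mext, ds$reference,
    levels = c(0.2, 0.8), reps = 2,
    seed = 21, search_args = fast_search
  )
  for (i in seq_len(nrow(rec))) {
    again <- tree_congruence(rec$consensus[[i]], ds$reference)
    expect_equal(rec$quartet_divergence[i], again$quartet_divergence)
    expect_equal(rec$shared_partitions[i], again$shared_partitions)
    expect_equal(rec$rf_raw[i], again$rf_raw)
  }
})

test_that("taxon addition draws pools correctly and exhausts them at N = |pool|", {
  ds <- exp_dataset()
  morph <- ds$matrix[, partition_columns(ds$matrix, "morphology")]
  core <- ds$roles$taxon[ds$roles$role == "core"]
  fossils <- ds$roles$taxon[ds$roles$role == "fossil"]

  rec <- run_taxon_addition(morph, ds$reference,
    base = core, pool = fossils,
    counts = c(0, 2, 5), reps = 2, seed = 8,
    search_args = fast_search, pool_label = "fossil"
  )
  expect_equal(nrow(rec), 6)
  expect_equal(rec$n_taxa, length(core) + rec$n_added)

  # N = |pool| leaves a single possible draw: all replicates identical
  full <- rec[rec$n_added == 5, ]
  expect_identical(full$added[[1]], full$added[[2]])
  expect_identical(sort(full$added[[1]]), sort(fossils))

  # N = 0 equals a plain base-only analysis
  base_rec <- rec[rec$n_added == 0, ]
  solo <- mp_search(subset_taxa(morph, core),
    seed = base_rec$seed[1],
    replicates = fast_search$replicates, plateau = fast_search$plateau
  )
  expect_equal(base_rec$mp_score[1], solo$score)

  expect_error(
    run_taxon_addition(morph, ds$reference,
      base = core, pool = c(core[1], fossils), seed = 1
    ),
    "overlap"
  )
  expect_error(
    run_taxon_addition(morph, ds$reference,
      base = core, pool = fossils, counts = 99, seed = 1
    ),
    "pool"
  )
})

test_that("summarize_and_fit recovers exact linear trends and bookkeeping", {
  records <- tibble::tibble(
    level = rep(c(1, 2, 3, 4), each = 5),
    metric = 0.1 + 0.2 * rep(c(1, 2, 3, 4), each = 5)
  )
  tr <- summarize_and_fit(records, level, metric)
  g <- suppressWarnings(glance(tr)) # lm warns on an exactly perfect fit
  expect_equal(g$slope, 0.2, tolerance = 1e-10)
  expect_equal(g$adj_r_squared, 1, tolerance = 1e-10)
  expect_equal(tr$summary$mean, c(0.3, 0.5, 0.7, 0.9))
  expect_equal(tr$summary$sd, rep(0, 4))
  expect_equal(tr$summary$n, rep(5L, 4))

  td <- suppressWarnings(tidy(tr))
  expect_equal(td$estimate[td$term == "level"], 0.2,
    tolerance = 1e-10, ignore_attr = TRUE
  )

  expect_error(summarize_and_fit(records, missing_col, metric), "not found")
  expect_error(
    summarize_and_fit(dplyr::mutate(records, level = 1), level, metric),
    "distinct"
  )

  p <- autoplot(tr)
  expect_s3_class(p, "ggplot")
})

test_that("slope p-values are calibrated under the null (permutation check)", {
  n_sig <- 0
  n_perm <- 400
  withr::with_seed(123, {
    for (i in seq_len(n_perm)) {
      records <- tibble::tibble(
        x = rep(1:5, each = 4),
        y = stats::rnorm(20)
      )
      g <- glance(summarize_and_fit(records, x, y))
      if (g$p_value < 0.05) n_sig <- n_sig + 1
    }
  })
  # binomial 3-SD band around the nominal 5% rate
  expect_lt(abs(n_sig / n_perm - 0.05), 3 * sqrt(0.05 * 0.95 / n_perm))
})

test_that("plot_congruence builds grouped summary plots", {
  ds <- exp_dataset()
  extant <- ds$roles$taxon[ds$roles$role != "fossil"]
  mext <- subset_taxa(ds$matrix, extant)
  rec <- run_site_resampling(mext, ds$reference,
    levels = c(0.2, 0.5, 1), reps = 1,
    seed = 2, search_args = fast_search
  )
  p <- plot_congruence(rec, level, quartet_divergence, group = morphology)
  expect_s3_class(p, "ggplot")
})
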