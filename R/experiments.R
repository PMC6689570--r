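#' Molecular site-resampling experiment, with and without morphology
#'
#' For each sampling level, arm and replicate: draw a random subsample of
#' the DNA + indel sites, optionally append the full (unsubsampled)
#' morphology partition, run an MP search, take the strict consensus of
#' the optimal trees, prune it to the taxa shared with the reference, and
#' compute all congruence metrics.  The canonical protocol of 11 levels
#' (2%--90%) x 25 replicates x 2 arms gives 550 records; smaller designs
#' are obtained by shrinking `levels` and `reps`.
#'
#' Per-replicate seeds derive from `seed` by a counter scheme, so any
#' level/arm can be recomputed independently and the whole experiment is
#' reproducible bit-for-bit.
#'
#' @param m Combined `char_matrix` (morphology + dna + indel) over the
#'   analysis taxa (conventionally the extant taxa).
#' @param ref Reference tree; congruence is computed after pruning each
#'   consensus to the taxa it shares with `ref`.
#' @param levels Sampling fractions in (0, 1].
#' @param reps Replicates per level per arm.
#' @param arms Which arms to run: with and/or without morphology.
#' @param seed Master seed.
#' @param search_args List of arguments forwarded to [mp_search()]
#'   (e.g. `replicates`, `plateau`).
#' @return Tibble of experiment records: one row per replicate with the
#'   condition, seed, MP score, all metrics, and the consensus tree in a
#'   list column.
#' @export
run_site_resampling <- function(m, ref,
                                levels = c(
                                  0.02, 0.05, seq(0.1, 0.9, by = 0.1)
                                ),
                                reps = 25,
                                arms = c(TRUE, FALSE),
                                seed = 1L,
                                search_args = list()) {
  if (any(levels <= 0 | levels > 1)) abort("Levels must lie in (0, 1].")
  morph <- m[, partition_columns(m, "morphology")]
  grid <- tidyr::expand_grid(
    level = levels,
    morphology = arms,
    replicate = seq_len(reps)
  )
  grid$counter <- seq_len(nrow(grid))
  records <- purrr::pmap(grid, function(level, morphology, replicate, counter) {
    rep_seed <- derive_seed(seed, counter)
    mm <- subsample_sites(m,
      tags = c("dna", "indel"),
      fraction = level, seed = rep_seed
    )
    if (morphology) mm <- combine_partitions(mm, morph)
    mm <- mm[m$taxa, ]
    one_search_record(mm, ref, rep_seed, search_args) |>
      dplyr::mutate(
        level = level, morphology = morphology, replicate = replicate,
        .before = 1
      )
  })
  dplyr::bind_rows(records)
}

#' Incremental taxon-addition experiment
#'
#' For each pool size `N` and replicate: draw `N` taxa from `pool` without
#' replacement, analyse `base` plus the drawn taxa (typically with a
#' morphology-only matrix), take the strict consensus, prune to the taxa
#' shared with the reference, and compute all metrics.  The pool is any
#' disjoint set of additional terminals: fossils, exported hypothetical
#' ancestors, or extra extant taxa.
#'
#' @param m `char_matrix` covering `base` and `pool` taxa (rows for
#'   hypothetical ancestors come from [export_hypothetical_ancestors()]
#'   via [bind_taxa()]).
#' @param ref Reference tree.
#' @param base Character vector: always-included taxa.
#' @param pool Character vector: candidate additions (disjoint from base).
#' @param counts Values of `N` to run (0 allowed: base-only analysis).
#' @param reps Replicates per `N`.
#' @param seed Master seed.
#' @param search_args Arguments forwarded to [mp_search()].
#' @param pool_label Optional label stored in the `pool` column.
#' @return Tibble of experiment records (one row per replicate).
#' @export
run_taxon_addition <- function(m, ref, base, pool,
                               counts = seq_len(min(18, length(pool))),
                               reps = 25, seed = 1L,
                               search_args = list(),
                               pool_label = "pool") {
  overlap <- intersect(base, pool)
  if (length(overlap) > 0) {
    abort(sprintf(
      "base and pool overlap: %s",
      paste(head(overlap, 5), collapse = ", ")
    ))
  }
  if (any(counts > length(pool))) abort("N exceeds pool size.")
  miss <- setdiff(c(base, pool), m$taxa)
  if (length(miss) > 0) {
    abort(sprintf("Taxa without matrix rows: %s", paste(head(miss, 5), collapse = ", ")))
  }
  grid <- tidyr::expand_grid(n_added = counts, replicate = seq_len(reps))
  grid$counter <- seq_len(nrow(grid))
  records <- purrr::pmap(grid, function(n_added, replicate, counter) {
    rep_seed <- derive_seed(seed, counter)
    drawn <- if (n_added == 0) {
      character(0)
    } else {
      with_local_seed(rep_seed, sample(pool, n_added, replace = FALSE))
    }
    mm <- m[c(base, drawn), ]
    one_search_record(mm, ref, rep_seed, search_args) |>
      dplyr::mutate(
        pool = pool_label, n_added = n_added, replicate = replicate,
        added = list(sort(drawn)),
        .before = 1
      )
  })
  dplyr::bind_rows(records)
}

# shared per-replicate worker: search, consensus, prune, metrics
one_search_record <- function(mm, ref, rep_seed, search_args) {
  search <- do.call(mp_search, c(list(m = mm, seed = rep_seed), search_args))
  cons <- search$consensus
  metrics <- tree_congruence(cons, ref, prune = TRUE)
  dplyr::mutate(metrics,
    seed = rep_seed,
    mp_score = search$score,
    n_taxa = length(mm$taxa),
    n_char = ncol(mm$data),
    n_optimal = length(search$trees),
    consensus = list(cons)
  )
}

#' Per-condition summary and linear trend fit
#'
#' Per-level means and standard deviations of a congruence metric plus an
#' ordinary least-squares fit of metric on condition, reporting slope,
#' adjusted R-squared and the slope's p-value -- the summary used to judge
#' whether congruence rises or falls as sampling increases.
#'
#' @param records Tibble of experiment records.
#' @param x Condition column (bare name or string), e.g. `level` or
#'   `n_added`.
#' @param y Metric column, e.g. `quartet_divergence`.
#' @return Object of class `congruence_trend` with `summary` (per-level
#'   tibble), `fit` (the `lm`), and the variable names; supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @export
summarize_and_fit <- function(records, x, y) {
  x_name <- rlang::as_name(rlang::ensym(x))
  y_name <- rlang::as_name(rlang::ensym(y))
  xs <- records[[x_name]]
  ys <- records[[y_name]]
  if (is.null(xs) || is.null(ys)) abort("x / y columns not found in records.")
  if (length(unique(xs)) < 3) abort("Need >= 3 distinct x values.")
  summary <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(x_name))) |>
    dplyr::summarise(
      mean = mean(.data[[y_name]], na.rm = TRUE),
      sd = stats::sd(.data[[y_name]], na.rm = TRUE),
      n = dplyr::n(),
      .groups = "drop"
    )
  fit <- lm(stats::reformulate(x_name, response = y_name), data = records)
  structure(
    list(summary = summary, fit = fit, x = x_name, y = y_name),
    class = "congruence_trend"
  )
}

#' @export
print.congruence_trend <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<congruence_trend> %s ~ %s: slope %.4g (p = %.3g), adj. R^2 = %.3f\n",
    x$y, x$x, g$slope, g$p_value, g$adj_r_squared
  ))
  print(x$summary)
  invisible(x)
}

#' @method tidy congruence_trend
#' @export
tidy.congruence_trend <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p_value = s[, "Pr(>|t|)"]
  )
}

#' @method glance congruence_trend
#' @export
glance.congruence_trend <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble(
    slope = co[2, "Estimate"],
    intercept = co[1, "Estimate"],
    adj_r_squared = s$adj.r.squared,
    r_squared = s$r.squared,
    p_value = co[2, "Pr(>|t|)"],
    n = length(s$residuals)
  )
}

#' @method autoplot congruence_trend
#' @export
autoplot.congruence_trend <- function(object, ...) {
  s <- object$summary
  names(s)[1] <- "x"
  ggplot2::ggplot(s, ggplot2::aes(x = .data$x, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean - .data$sd,
        ymax = .data$mean + .data$sd
      ),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(
      method = "lm", formula = y ~ x, se = FALSE,
      linetype = "dashed", linewidth = 0.4, colour = "grey40"
    ) +
    ggplot2::labs(x = object$x, y = object$y) +
    ggplot2::theme_minimal()
}

#' Mean +/- SD congruence curves by experimental group
#'
#' Figure-style summary plot of experiment records: per-condition mean with
#' a one-standard-deviation ribbon, optionally coloured by a grouping
#' column (e.g. the with/without-morphology arm or the addition pool).
#'
#' @param records Tibble of experiment records.
#' @param x,y Condition and metric columns (bare names).
#' @param group Optional grouping column (bare name).
#' @return A ggplot object.
#' @export
plot_congruence <- function(records, x, y, group = NULL) {
  x_name <- rlang::as_name(rlang::ensym(x))
  y_name <- rlang::as_name(rlang::ensym(y))
  g_quo <- rlang::enquo(group)
  keys <- c(x_name, if (!rlang::quo_is_null(g_quo)) rlang::as_name(rlang::ensym(group)))
  s <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean = mean(.data[[y_name]], na.rm = TRUE),
      sd = stats::sd(.data[[y_name]], na.rm = TRUE),
      .groups = "drop"
    )
  aes <- if (length(keys) == 2) {
    ggplot2::aes(
      x = .data[[x_name]], y = .data$mean,
      colour = factor(.data[[keys[2]]]), fill = factor(.data[[keys[2]]])
    )
  } else {
    ggplot2::aes(x = .data[[x_name]], y = .data$mean)
  }
  p <- ggplot2::ggplot(s, aes) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = x_name, y = y_name, colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  p
}
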