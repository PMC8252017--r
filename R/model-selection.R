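#' Two-pass autocovariate regression
#'
#' Least-squares regression of a per-bin response on predictor columns plus
#' a temporal autocovariate defined as the *preceding bin's residual from a
#' preliminary regression that ignored autocorrelation*. Pass 1 fits
#' `y ~ X` by OLS on the complete rows and stores residuals; pass 2 refits
#' with the lagged residual appended. The oldest retained bin (no
#' predecessor) is dropped; where interior bins are missing, the
#' autocovariate of the next retained bin uses the nearest available older
#' residual. The log-likelihood is the Gaussian profile likelihood, and `k`
#' counts the intercept, the predictors, the autocovariate coefficient and
#' the residual variance.
#'
#' @param data Tibble with a `bin` column (sorted internally), the response
#'   and the predictors.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names (may be
#'   empty for an intercept-plus-autocovariate model).
#' @return List: `coefficients` (named; `autocov` last), `loglik`, `k`,
#'   `n`, `residuals` (pass-2), `bins_used`.
#' @export
autocov_regression <- function(data, response, predictors) {
  if (!"bin" %in% names(data)) stop_invalid("`data` needs a `bin` column.")
  dat <- dplyr::arrange(as.data.frame(data), .data$bin)
  cols <- c(response, predictors)
  ok <- complete.cases(dat[, cols, drop = FALSE])
  dat <- dat[ok, , drop = FALSE]
  p <- length(predictors)
  if (nrow(dat) < p + 3) {
    abort("Too few complete bins for the autocovariate regression.",
          class = "lagoceiling_insufficient_data")
  }
  f1 <- stats::as.formula(paste(
    response, "~", if (p == 0) "1" else paste(predictors, collapse = " + ")
  ))
  m1 <- lm(f1, data = dat)
  dat$.resid1 <- residuals(m1)
  # A numerically perfect first pass leaves only rounding noise; zero it so
  # the autocovariate drops out instead of fitting that noise.
  if (max(abs(dat$.resid1)) < 1e-10 * max(1, sd(dat[[response]]))) {
    dat$.resid1 <- 0
  }
  # Nearest available older residual
  dat$.lag_resid <- c(NA_real_, dat$.resid1[-nrow(dat)])
  dat2 <- dat[-1, , drop = FALSE]
  f2 <- stats::as.formula(paste(
    response, "~",
    if (p == 0) ".lag_resid" else paste(c(predictors, ".lag_resid"),
                                        collapse = " + ")
  ))
  m2 <- lm(f2, data = dat2)
  cf <- coef(m2)
  cf[is.na(cf)] <- 0
  names(cf)[names(cf) == ".lag_resid"] <- "autocov"
  ll <- as.numeric(logLik(m2))
  list(
    coefficients = cf,
    loglik = ll,
    k = p + 3L,
    n = nrow(dat2),
    residuals = unname(residuals(m2)),
    bins_used = dat2$bin
  )
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Parameter count, including the residual variance.
#' @param n Number of observations.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) {
    abort("AICc correction undefined: need n > k + 1.",
          class = "lagoceiling_undefined_correction")
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' The candidate-model roster
#'
#' Eleven autocovariate regression models of log10 maximum lagomorph body
#' mass: one per single predictor (competitive ceiling, minimum
#' perissodactyl mass, benthic d18O, ungulate hypsodonty, glires sampling
#' probability), plus the six pairs combining the ceiling or the minimum
#' perissodactyl mass with each of the sampling, hypsodonty and d18O terms.
#'
#' @return Tibble `model_id`, `label`, `predictors` (list-column).
#' @export
model_roster <- function() {
  preds <- list(
    "m_ceiling", "m_minper", "d18o", "h_ung", "r_glires",
    c("m_ceiling", "r_glires"), c("m_minper", "r_glires"),
    c("m_ceiling", "h_ung"), c("m_minper", "h_ung"),
    c("m_ceiling", "d18o"), c("m_minper", "d18o")
  )
  tibble::tibble(
    model_id = seq_along(preds),
    label = vapply(preds, paste, character(1), collapse = " + "),
    predictors = preds
  )
}

#' Compare candidate models by AICc
#'
#' Fits every roster model by [autocov_regression()] on the same row set
#' (complete cases across the union of all models' variables, restricted to
#' the analysis window), so AICc values are comparable. Reports delta-AICc
#' to the best model and evidence ratios `exp(0.5 * delta)`; ties are broken
#' towards fewer predictors.
#'
#' @param series Output of [build_series()].
#' @param roster Model roster (default [model_roster()]).
#' @param window `c(older, younger)` Ma; bins whose midpoints fall inside
#'   (inclusive) are analysed. Default 37.5-1.5 Ma (the most recent bin
#'   excluded).
#' @param response Response column, default `"m_maxlag"`.
#' @return A `model_comparison`: tibble of per-model fits plus metadata.
#' @export
compare_models <- function(series, roster = model_roster(),
                           window = c(37.5, 1.5), response = "m_maxlag") {
  if (nrow(roster) == 0) stop_invalid("`roster` is empty.")
  lo <- min(window)
  hi <- max(window)
  dat <- dplyr::filter(series, .data$midpoint >= lo - 1e-9,
                       .data$midpoint <= hi + 1e-9)
  all_vars <- unique(c(response, unlist(roster$predictors)))
  ok <- complete.cases(dat[, all_vars, drop = FALSE])
  dat <- dat[ok, , drop = FALSE]

  fits <- purrr::map(roster$predictors, function(pr) {
    autocov_regression(dat, response, pr)
  })
  tab <- tibble::tibble(
    model_id = roster$model_id,
    label = roster$label,
    n_predictors = lengths(roster$predictors),
    k = vapply(fits, `[[`, integer(1), "k"),
    n = vapply(fits, `[[`, integer(1), "n"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    coefficients = purrr::map(fits, "coefficients")
  )
  tab$aicc <- mapply(aicc, tab$loglik, tab$k, tab$n)
  ord <- order(tab$aicc, tab$n_predictors)
  best <- ord[1]
  tab$delta_aicc <- tab$aicc - tab$aicc[best]
  tab$evidence_ratio <- exp(0.5 * tab$delta_aicc)
  structure(
    list(table = tab, best_model = tab$model_id[best],
         window = c(lo, hi), response = response, n_bins = nrow(dat)),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison over %d bins (%.1f-%.1f Ma midpoints)\n",
              x$n_bins, max(x$window), min(x$window)))
  tb <- dplyr::arrange(x$table, .data$delta_aicc)
  for (i in seq_len(min(5, nrow(tb)))) {
    cat(sprintf("  %2d. %-22s AICc %8.2f  dAICc %6.2f  ER %8.2f\n",
                tb$model_id[i], tb$label[i], tb$aicc[i], tb$delta_aicc[i],
                tb$evidence_ratio[i]))
  }
  invisible(x)
}

#' @export
tidy.model_comparison <- function(x, ...) {
  dplyr::select(x$table, "model_id", "label", "k", "n", "loglik", "aicc",
                "delta_aicc", "evidence_ratio") |>
    dplyr::arrange(.data$delta_aicc)
}

#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(best_model = x$best_model, n_bins = x$n_bins,
                 n_models = nrow(x$table))
}

#' @export
autoplot.model_comparison <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = stats::reorder(.data$label,
                                                  -.data$delta_aicc),
                               y = .data$delta_aicc)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(Delta * "AICc"))
}

#' Monte-Carlo propagation of age and mass uncertainty
#'
#' Repeats the full series-building and model-comparison analysis over
#' pseudo-replicates: in each replicate one age per locality is drawn
#' uniformly within its age bounds (shared by all taxa of the locality, so
#' within-locality co-occurrence is preserved) and each taxon's log10 mass
#' is drawn normally around its point estimate with its reported standard
#' error. Per-replicate sub-seeds are derived from the master seed by
#' counter, so increasing `n_reps` never reshuffles earlier replicates.
#'
#' @param occurrences Occurrence tibble (with `age_max`, `age_min`).
#' @param mass_estimates Tibble `taxon`, `mean_log10`, `se_log10`.
#' @param line_lag,line_ung [energy_line()] objects.
#' @param d18o,h_ung Proxy series, or `NULL`.
#' @param grid A [bin_grid()].
#' @param regimes Regime table.
#' @param roster Model roster.
#' @param n_reps Number of pseudo-replicates (>= 1).
#' @param seed Master seed.
#' @param window Analysis window `c(older, younger)` Ma.
#' @param max_uncertainty Locality age-uncertainty filter, Myr.
#' @return A `replicate_ensemble`: per-model win counts, the per-replicate
#'   delta-AICc table, and the count of failed replicates.
#' @export
pseudoreplicate_analysis <- function(occurrences, mass_estimates,
                                     line_lag, line_ung,
                                     d18o = NULL, h_ung = NULL,
                                     grid = bin_grid(),
                                     regimes = default_regimes(),
                                     roster = model_roster(),
                                     n_reps = 1000, seed = 1L,
                                     window = c(37.5, 1.5),
                                     max_uncertainty = 4.2) {
  if (n_reps < 1) stop_invalid("`n_reps` must be at least 1.")
  occ <- filter_localities(occurrences, max_uncertainty)
  locs <- occ |>
    dplyr::group_by(.data$locality_id) |>
    dplyr::summarise(age_max = max(.data$age_max),
                     age_min = min(.data$age_min), .groups = "drop")
  me <- mass_estimates
  me$se_log10 <- dplyr::coalesce(me$se_log10, 0)

  reps <- purrr::map(seq_len(n_reps), function(r) {
    sub <- derive_seed(seed, r)
    res <- tryCatch(
      with_seed(sub, {
        ages <- setNames(
          runif(nrow(locs), locs$age_min, locs$age_max),
          locs$locality_id
        )
        me_r <- me
        me_r$mean_log10 <- rnorm(nrow(me), me$mean_log10, me$se_log10)
        ser <- build_series(occ, me_r, line_lag, line_ung, d18o, h_ung,
                            grid, regimes, ages = ages,
                            max_uncertainty = max_uncertainty)
        compare_models(ser, roster, window)
      }),
      error = function(e) NULL
    )
    if (is.null(res)) {
      return(tibble::tibble(rep = r, model_id = NA_integer_,
                            delta_aicc = NA_real_, best = NA))
    }
    tibble::tibble(rep = r, model_id = res$table$model_id,
                   delta_aicc = res$table$delta_aicc,
                   best = res$table$model_id == res$best_model)
  })
  deltas <- dplyr::bind_rows(reps)
  failed <- deltas |>
    dplyr::filter(is.na(.data$model_id)) |>
    dplyr::distinct(.data$rep) |>
    nrow()
  wins <- deltas |>
    dplyr::filter(!is.na(.data$model_id), .data$best) |>
    dplyr::count(.data$model_id, name = "wins")
  best_counts <- roster |>
    dplyr::select("model_id", "label") |>
    dplyr::left_join(wins, by = "model_id") |>
    dplyr::mutate(wins = dplyr::coalesce(.data$wins, 0L))
  structure(
    list(best_counts = best_counts,
         deltas = dplyr::filter(deltas, !is.na(.data$model_id)),
         n_reps = n_reps, n_failed = failed, seed = seed, window = window),
    class = "replicate_ensemble"
  )
}

#' @export
print.replicate_ensemble <- function(x, ...) {
  cat(sprintf("Pseudo-replicate ensemble: %d replicates (%d failed)\n",
              x$n_reps, x$n_failed))
  bc <- dplyr::arrange(x$best_counts, dplyr::desc(.data$wins))
  for (i in seq_len(min(5, nrow(bc)))) {
    cat(sprintf("  model %2d (%-22s): best in %d replicates\n",
                bc$model_id[i], bc$label[i], bc$wins[i]))
  }
  invisible(x)
}

#' @export
tidy.replicate_ensemble <- function(x, ...) {
  x$deltas |>
    dplyr::group_by(.data$model_id) |>
    dplyr::summarise(
      wins = sum(.data$best),
      delta_aicc_median = stats::median(.data$delta_aicc),
      delta_aicc_q025 = quantile(.data$delta_aicc, 0.025),
      delta_aicc_q975 = quantile(.data$delta_aicc, 0.975),
      .groups = "drop"
    ) |>
    dplyr::left_join(dplyr::select(x$best_counts, "model_id", "label"),
                     by = "model_id") |>
    dplyr::relocate("label", .after = "model_id") |>
    dplyr::arrange(dplyr::desc(.data$wins))
}

#' @export
glance.replicate_ensemble <- function(x, ...) {
  tibble::tibble(
    n_reps = x$n_reps, n_failed = x$n_failed,
    best_model = x$best_counts$model_id[which.max(x$best_counts$wins)],
    best_model_wins = max(x$best_counts$wins)
  )
}

#' @export
autoplot.replicate_ensemble <- function(object, ...) {
  ggplot2::ggplot(object$best_counts,
                  ggplot2::aes(x = stats::reorder(.data$label, .data$wins),
                               y = .data$wins)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Replicates with most support")
}
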