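#' Per-species means of specimen measurements
#'
#' Collapses specimen-level records (one row per measured individual with an
#' associated body mass) to species means on the log10 scale, carrying the
#' within-species variances and sample sizes needed for measurement-error
#' weighting downstream. Singleton species get variance 0 and a flag.
#'
#' @param specimens Tibble `species`, `dimension_mm` (a dental or mandibular
#'   dimension), `mass_kg`.
#' @return Tibble `species`, `n`, `mean_log10_dim`, `mean_log10_mass`,
#'   `var_log10_dim`, `var_log10_mass`, `single_specimen`.
#' @export
species_means <- function(specimens) {
  need <- c("species", "dimension_mm", "mass_kg")
  if (!all(need %in% names(specimens))) {
    stop_invalid("`specimens` needs columns species, dimension_mm, mass_kg.")
  }
  if (any(specimens$dimension_mm <= 0, na.rm = TRUE) ||
      any(specimens$mass_kg <= 0, na.rm = TRUE) ||
      anyNA(specimens$dimension_mm) || anyNA(specimens$mass_kg)) {
    stop_invalid("Measurements and masses must be positive and complete.")
  }
  specimens |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_log10_dim = mean(log10(.data$dimension_mm)),
      mean_log10_mass = mean(log10(.data$mass_kg)),
      var_log10_dim = ifelse(dplyr::n() > 1, var(log10(.data$dimension_mm)), 0),
      var_log10_mass = ifelse(dplyr::n() > 1, var(log10(.data$mass_kg)), 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(single_specimen = .data$n == 1)
}

#' Fit an allometric body-mass prediction model
#'
#' PGLS regression of species-mean log10 body mass on a log10 skeletal or
#' dental dimension, with phylogenetic covariance (Pagel's lambda) and
#' intraspecific variation entering as per-species variance inflation
#' `pooled_within_species_var / n_i`. Predictive accuracy is reported as the
#' mean absolute percent prediction error |D| from leave-one-out refits.
#'
#' @param species_table Output of [species_means()] (>= 4 species).
#' @param tree [ape::phylo] covering the species.
#' @param predictor_name Label for the measured dimension (e.g. "lower
#'   toothrow length, mm").
#' @param lambda Optional fixed lambda passed to [pgls_fit()].
#' @param loo If `TRUE` (default) compute the leave-one-out |D| accuracy.
#' @return A `mass_model`: the underlying `pgls_fit`, the pooled
#'   intraspecific variance, and the |D| accuracy (percent).
#' @export
fit_mass_model <- function(species_table, tree, predictor_name = "dimension",
                           lambda = NULL, loo = TRUE) {
  if (nrow(species_table) < 4) {
    abort("Need at least 4 species to fit a mass model.",
          class = "lagoceiling_insufficient_data")
  }
  dfn <- pmax(species_table$n - 1, 0)
  intraspecific_var <- if (sum(dfn) > 0) {
    sum(dfn * species_table$var_log10_mass) / sum(dfn)
  } else {
    0
  }
  dat <- tibble::tibble(
    species = species_table$species,
    x = species_table$mean_log10_dim,
    y = species_table$mean_log10_mass,
    w = intraspecific_var / species_table$n
  )
  fit <- pgls_fit(dat, tree, y ~ x, weights = "w", lambda = lambda)

  accuracy <- NA_real_
  if (loo) {
    used <- dat[dat$species %in% fit$species, , drop = FALSE]
    errs <- vapply(seq_len(nrow(used)), function(i) {
      train <- used[-i, , drop = FALSE]
      f_i <- pgls_fit(train, ape::keep.tip(tree, train$species), y ~ x,
                      weights = "w", lambda = fit$lambda)
      pr <- pgls_predict_newtip(
        f_i, ape::keep.tip(tree, used$species),
        tibble::tibble(species = used$species[i], x = used$x[i])
      )
      m_obs <- 10^used$y[i]
      abs(10^pr$.pred - m_obs) / m_obs * 100
    }, numeric(1))
    accuracy <- mean(errs)
  }

  structure(
    list(predictor_name = predictor_name, fit = fit,
         intraspecific_var = intraspecific_var, accuracy = accuracy),
    class = "mass_model"
  )
}

#' @export
print.mass_model <- function(x, ...) {
  cat(sprintf("Body-mass model on %s\n", x$predictor_name))
  cat(sprintf("  log10 mass = %.4f %+.4f * log10 dim, lambda = %.3f\n",
              x$fit$intercept, x$fit$slope, x$fit$lambda))
  cat(sprintf("  intraspecific var = %.5f; LOO |D| = %s%%\n",
              x$intraspecific_var,
              ifelse(is.na(x$accuracy), "NA", sprintf("%.2f", x$accuracy))))
  invisible(x)
}

#' @export
tidy.mass_model <- function(x, ...) tidy(x$fit)

#' @export
glance.mass_model <- function(x, ...) {
  dplyr::mutate(glance(x$fit), intraspecific_var = x$intraspecific_var,
                accuracy_pct = x$accuracy)
}

#' Estimate fossil body masses from measurements
#'
#' Applies a fitted [fit_mass_model()] to fossil measurements. Taxa present
#' on the supplied tree are predicted by conditional-normal PGLS prediction
#' (phylogenetically informed); taxa without a placement use the
#' fixed-effect line with the full prediction variance (residual plus
#' parameter-uncertainty terms) - the conservative default for fossils of
#' uncertain affinity. Estimates are carried on the log10 scale.
#'
#' @param model A `mass_model`.
#' @param new_data Tibble `taxon`, `measurement_mm`.
#' @param tree Optional tree containing the model's species plus any placed
#'   fossil taxa.
#' @return Tibble `taxon`, `measurement_mm`, `mean_log10`, `se_log10`,
#'   `model_used`, `placed`.
#' @export
estimate_fossil_mass <- function(model, new_data, tree = NULL) {
  stopifnot(inherits(model, "mass_model"))
  if (!all(c("taxon", "measurement_mm") %in% names(new_data))) {
    stop_invalid("`new_data` needs columns taxon and measurement_mm.")
  }
  if (any(new_data$measurement_mm <= 0) || anyNA(new_data$measurement_mm)) {
    stop_invalid("Measurements must be positive.")
  }
  fit <- model$fit
  x0 <- log10(new_data$measurement_mm)
  placed <- if (is.null(tree)) {
    rep(FALSE, nrow(new_data))
  } else {
    new_data$taxon %in% tree$tip.label & all(fit$species %in% tree$tip.label)
  }

  out <- vector("list", nrow(new_data))
  for (i in seq_len(nrow(new_data))) {
    if (placed[i]) {
      pr <- pgls_predict_newtip(
        fit, tree, tibble::tibble(species = new_data$taxon[i], x = x0[i])
      )
      out[[i]] <- tibble::tibble(mean_log10 = pr$.pred, se_log10 = pr$.pred_se)
    } else {
      xv <- c(1, x0[i])
      # df-corrected residual variance, matching the parameter covariance
      v <- fit$sigma2 * fit$n / (fit$n - 2) + drop(xv %*% fit$param_cov %*% xv)
      out[[i]] <- tibble::tibble(
        mean_log10 = fit$intercept + fit$slope * x0[i],
        se_log10 = sqrt(max(v, 0))
      )
    }
  }
  dplyr::bind_cols(
    dplyr::select(new_data, "taxon", "measurement_mm"),
    dplyr::bind_rows(out)
  ) |>
    dplyr::mutate(model_used = model$predictor_name, placed = placed)
}

#' Combine specimen-level mass estimates per taxon
#'
#' Inverse-variance-weighted mean of multiple log10 mass estimates for the
#' same taxon (e.g. from several specimens or predictors). Exact estimates
#' (zero standard error) dominate; the combined standard error is
#' `1 / sqrt(sum(1 / var))`.
#'
#' @param estimates Tibble `taxon`, `mean_log10`, `se_log10`.
#' @return Tibble `taxon`, `mean_log10`, `se_log10`, `n_estimates`.
#' @export
combine_estimates <- function(estimates) {
  estimates |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      mean_log10 = {
        v <- .data$se_log10^2
        if (any(v < 1e-12)) {
          mean(.data$mean_log10[v < 1e-12])
        } else {
          sum(.data$mean_log10 / v) / sum(1 / v)
        }
      },
      se_log10 = {
        v <- .data$se_log10^2
        if (any(v < 1e-12)) 0 else 1 / sqrt(sum(1 / v))
      },
      n_estimates = dplyr::n(),
      .groups = "drop"
    )
}
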