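#' Guild extrema per ecoregion
#'
#' From a per-ecoregion species list, finds the largest leporid lagomorph
#' (`m_maxlag`) and the smallest ungulate-type herbivore (`m_minuth`). The
#' UTH set comprises artiodactyls, perissodactyls and ungulate-like
#' caviomorph rodents; omnivorous or semiaquatic taxa (suids, tayassuids,
#' hippopotamids, capybara) are excluded via the `exclude` flag. A guild
#' absent from an ecoregion yields `NA`.
#'
#' @param species_list Tibble with `ecoregion_id` (optional; a single
#'   implicit ecoregion otherwise), `species`, `guild` (one of `lagomorph`,
#'   `artiodactyl`, `perissodactyl`, `caviomorph`), `exclude` (logical,
#'   optional) and `mass_kg`.
#' @return Tibble `ecoregion_id`, `m_maxlag`, `m_minuth` (kg).
#' @export
#' @examples
#' sp <- tibble::tibble(
#'   species = c("Lepus", "Sylvilagus", "Tragulus", "Sus"),
#'   guild = c("lagomorph", "lagomorph", "artiodactyl", "artiodactyl"),
#'   exclude = c(FALSE, FALSE, FALSE, TRUE),
#'   mass_kg = c(3, 1, 2, 80)
#' )
#' guild_extrema(sp) # m_maxlag 3, m_minuth 2
guild_extrema <- function(species_list) {
  sl <- species_list
  if (!"ecoregion_id" %in% names(sl)) sl$ecoregion_id <- "all"
  if (!"exclude" %in% names(sl)) sl$exclude <- FALSE
  if (nrow(sl) == 0) {
    return(tibble::tibble(ecoregion_id = character(), m_maxlag = numeric(),
                          m_minuth = numeric()))
  }
  if (any(sl$mass_kg <= 0, na.rm = TRUE)) {
    stop_invalid("`mass_kg` must be positive.")
  }
  uth_guilds <- c("artiodactyl", "perissodactyl", "caviomorph")
  sl |>
    dplyr::group_by(.data$ecoregion_id) |>
    dplyr::summarise(
      m_maxlag = {
        v <- .data$mass_kg[.data$guild == "lagomorph" & !.data$exclude]
        if (length(v) == 0) NA_real_ else max(v)
      },
      m_minuth = {
        v <- .data$mass_kg[.data$guild %in% uth_guilds & !.data$exclude]
        if (length(v) == 0) NA_real_ else min(v)
      },
      .groups = "drop"
    )
}

#' Sample-size-adjusted Fisher-Pearson skewness (G1)
#'
#' `G1 = sqrt(n (n - 1)) / (n - 2) * m3 / m2^(3/2)` with central sample
#' moments `m2`, `m3`. Negative values indicate a left-skewed distribution,
#' as in the body-mass distribution of extant lagomorphs.
#'
#' @param values Numeric vector, `n >= 3`, finite.
#' @return One-row tibble `g1`, `n`.
#' @export
#' @examples
#' skewness_g1(c(1, 2, 3))$g1      # 0
#' skewness_g1(c(1, 2, 3, 10))$g1  # 1.7636...
skewness_g1 <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3) {
    abort("Need at least 3 values for G1 skewness.",
          class = "lagoceiling_insufficient_data")
  }
  if (any(!is.finite(values))) stop_invalid("`values` must be finite.")
  n <- length(values)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  g1 <- if (m2 == 0) 0 else sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5
  tibble::tibble(g1 = g1, n = n)
}

#' Mean residual of neighbouring ecoregions
#'
#' The spatial autocovariate: for each ecoregion, the mean of the supplied
#' residuals over its adjacency neighbours. Ecoregions with no neighbours
#' get 0, with a warning.
#'
#' @param residuals Tibble `ecoregion_id`, `residual`.
#' @param adjacency Edge tibble `from`, `to` (undirected; each edge may be
#'   listed once).
#' @return Tibble `ecoregion_id`, `autocov`.
#' @export
neighbor_mean_residual <- function(residuals, adjacency) {
  ids <- residuals$ecoregion_id
  bad <- setdiff(c(adjacency$from, adjacency$to), ids)
  if (length(bad) > 0) {
    stop_invalid(sprintf("Adjacency references unknown ecoregion id(s): %s.",
                         paste(head(bad, 5), collapse = ", ")))
  }
  nb <- neighbor_index(ids, adjacency)
  iso <- lengths(nb) == 0
  if (any(iso)) {
    warn(sprintf("%d ecoregion(s) have no neighbours; autocovariate set to 0.",
                 sum(iso)))
  }
  autocov <- vapply(seq_along(ids), function(i) {
    if (length(nb[[i]]) == 0) 0 else mean(residuals$residual[nb[[i]]])
  }, numeric(1))
  tibble::tibble(ecoregion_id = ids, autocov = autocov)
}

#' Boosted regression trees for maximum lagomorph body mass
#'
#' Two-pass gradient-boosting model of `log10 m_maxlag` over ecoregions:
#' (1) fit without the spatial term and compute residuals; (2) refit with
#' the neighbour-mean-residual autocovariate added. Hyperparameters default
#' to tree complexity 3, learning rate 0.005 and bag fraction 0.75; the
#' number of trees is chosen by k-fold cross-validation. Boosting is
#' delegated to xgboost; relative influences (summing to 100%) come from
#' split gain and partial dependence from grid-averaged prediction.
#'
#' @param table Ecoregion tibble (>= 50 rows) containing `response` and
#'   `predictors`.
#' @param adjacency Edge tibble `from`, `to` over `table$ecoregion_id`.
#' @param response Response column (default `"log10_m_maxlag"`).
#' @param predictors Predictor columns; default: minimum-UTH mass plus the
#'   environmental covariates of [simulate_ecoregion_table()].
#' @param tree_complexity Maximum tree depth.
#' @param learning_rate Shrinkage per tree.
#' @param bag_fraction Row subsample fraction per tree.
#' @param max_trees Upper bound on boosting rounds searched by CV.
#' @param nfold Cross-validation folds.
#' @param seed Integer seed (controls CV folds and bagging).
#' @return A `brt_fit`: fitted booster, chosen rounds, relative influences,
#'   CV deviance explained, and the data needed for partial dependence.
#' @export
brt_model <- function(table, adjacency,
                      response = "log10_m_maxlag",
                      predictors = c("log10_m_minuth", "temperature",
                                     "precipitation", "precip_var",
                                     "soil_nutrient", "tree_cover",
                                     "elevation", "introduced"),
                      tree_complexity = 3, learning_rate = 0.005,
                      bag_fraction = 0.75, max_trees = 3000, nfold = 5,
                      seed = 1L) {
  if (nrow(table) < 50) {
    abort("Need at least 50 ecoregions for the boosted model.",
          class = "lagoceiling_insufficient_data")
  }
  if (!response %in% names(table)) stop_invalid("Response column missing.")
  if (!all(predictors %in% names(table))) {
    stop_invalid("Predictor column(s) missing from `table`.")
  }
  y <- table[[response]]
  if (isTRUE(all.equal(var(y), 0)) || var(y) == 0) {
    abort("Response is constant; boosting design is degenerate.",
          class = "lagoceiling_degenerate_design")
  }

  fit_pass <- function(preds) {
    X <- as.matrix(dplyr::select(table, dplyr::all_of(preds)))
    params <- list(
      objective = "reg:squarederror", max_depth = tree_complexity,
      eta = learning_rate, subsample = bag_fraction, nthread = 1
    )
    with_seed(seed, {
      dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      cv <- xgboost::xgb.cv(
        params = params, data = dm, nrounds = max_trees,
        nfold = nfold, early_stopping_rounds = 50, verbose = 0
      )
      best <- cv$early_stop$best_iteration %||%
        which.min(cv$evaluation_log$test_rmse_mean)
      cv_rmse <- cv$evaluation_log$test_rmse_mean[best]
      booster <- xgboost::xgb.train(
        params = params, data = dm, nrounds = best, verbose = 0
      )
      list(booster = booster, nrounds = best, X = X, preds = preds,
           cv_rmse = cv_rmse)
    })
  }

  pass1 <- fit_pass(predictors)
  resid1 <- y - predict(pass1$booster, pass1$X)
  ac <- neighbor_mean_residual(
    tibble::tibble(ecoregion_id = table$ecoregion_id, residual = resid1),
    adjacency
  )
  table$spatial_autocov <- ac$autocov
  pass2 <- fit_pass(c(predictors, "spatial_autocov"))

  imp <- xgboost::xgb.importance(model = pass2$booster)
  infl <- tibble::tibble(feature = pass2$preds) |>
    dplyr::left_join(tibble::as_tibble(imp[, c("Feature", "Gain")]),
                     by = c(feature = "Feature")) |>
    dplyr::mutate(Gain = dplyr::coalesce(.data$Gain, 0)) |>
    dplyr::mutate(relative_influence = 100 * .data$Gain / sum(.data$Gain)) |>
    dplyr::select("feature", "relative_influence") |>
    dplyr::arrange(dplyr::desc(.data$relative_influence))

  cv_dev_expl <- 1 - pass2$cv_rmse^2 / var(y) * (length(y) - 1) / length(y)

  structure(
    list(booster = pass2$booster, nrounds = pass2$nrounds,
         first_pass = pass1$booster, autocovariate = ac,
         relative_influence = infl,
         cv_deviance_explained = cv_dev_expl,
         X = pass2$X, y = y, response = response,
         predictors = pass2$preds,
         hyperparams = list(tree_complexity = tree_complexity,
                            learning_rate = learning_rate,
                            bag_fraction = bag_fraction)),
    class = "brt_fit"
  )
}

#' @export
print.brt_fit <- function(x, ...) {
  cat(sprintf("Boosted regression trees: %s ~ %d predictors, %d trees\n",
              x$response, length(x$predictors), x$nrounds))
  cat(sprintf("  CV deviance explained: %.3f\n", x$cv_deviance_explained))
  top <- head(x$relative_influence, 3)
  cat("  Top influences:",
      paste(sprintf("%s (%.1f%%)", top$feature, top$relative_influence),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.brt_fit <- function(x, ...) x$relative_influence

#' @export
glance.brt_fit <- function(x, ...) {
  tibble::tibble(
    nrounds = x$nrounds,
    cv_deviance_explained = x$cv_deviance_explained,
    tree_complexity = x$hyperparams$tree_complexity,
    learning_rate = x$hyperparams$learning_rate,
    bag_fraction = x$hyperparams$bag_fraction,
    nobs = length(x$y)
  )
}

#' Partial dependence of a boosted model
#'
#' Grid-averaged prediction: the feature of interest is swept over a grid
#' while all other columns keep their observed values, and predictions are
#' averaged over rows.
#'
#' @param fit A `brt_fit`.
#' @param feature Feature name.
#' @param grid_n Grid size.
#' @return Tibble `feature`, `value`, `yhat`.
#' @export
partial_dependence <- function(fit, feature, grid_n = 25) {
  stopifnot(inherits(fit, "brt_fit"))
  if (!feature %in% colnames(fit$X)) stop_invalid("Unknown feature.")
  grid <- seq(min(fit$X[, feature]), max(fit$X[, feature]),
              length.out = grid_n)
  yhat <- vapply(grid, function(v) {
    Xg <- fit$X
    Xg[, feature] <- v
    mean(predict(fit$booster, Xg))
  }, numeric(1))
  tibble::tibble(feature = feature, value = grid, yhat = yhat)
}

#' @export
autoplot.brt_fit <- function(object, ...) {
  ggplot2::ggplot(object$relative_influence,
                  ggplot2::aes(x = stats::reorder(.data$feature,
                                                  .data$relative_influence),
                               y = .data$relative_influence)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Relative influence (%)")
}
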