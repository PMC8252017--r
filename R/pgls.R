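#' Pagel's lambda tip-correlation matrix
#'
#' Builds the among-species correlation matrix implied by Brownian motion on a
#' time-calibrated tree, with off-diagonal entries multiplied by Pagel's
#' `lambda`. Under Brownian motion the correlation between two tips is the
#' fraction of root-to-tip path they share; `lambda` scales that shared
#' fraction towards zero (star phylogeny) without touching the unit diagonal.
#'
#' @param tree An [ape::phylo] tree with branch lengths. Non-ultrametric trees
#'   are accepted with a warning (correlations are then computed from the
#'   standardized Brownian covariance).
#' @param lambda Scalar in `[0, 1]`.
#' @return A symmetric matrix with unit diagonal, rows/columns named by tip
#'   label.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' lambda_correlation(tr, 0.5)["A", "B"] # 0.5 * (1/2) = 0.25
lambda_correlation <- function(tree, lambda) {
  if (!inherits(tree, "phylo")) stop_invalid("`tree` must be a phylo object.")
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop_invalid("`lambda` must be a single number in [0, 1].")
  }
  if (!ape::is.ultrametric(tree, tol = 1e-6)) {
    warn("Tree is not ultrametric; correlations use the standardized Brownian covariance.")
  }
  C <- ape::vcv(tree, corr = TRUE)
  Cl <- lambda * C
  diag(Cl) <- 1
  Cl
}

# Negative profile log-likelihood machinery ---------------------------------

# Eigen path (no measurement-error weights): C = U diag(ev) U', and the
# lambda transform preserves eigenvectors because the diagonal is constant 1:
# C_lambda = U diag(lambda * (ev - 1) + 1) U'.
pgls_ll_eigen <- function(lambda, eig, ty, tX) {
  d <- lambda * (eig - 1) + 1
  if (any(d <= 0)) return(list(ll = -Inf))
  w <- 1 / d
  XtWX <- crossprod(tX * w, tX)
  XtWy <- crossprod(tX * w, ty)
  beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
  if (is.null(beta)) return(list(ll = -Inf))
  r <- ty - tX %*% beta
  n <- length(ty)
  rss <- sum(r^2 * w)
  sigma2 <- rss / n
  ll <- if (sigma2 <= 0) {
    Inf # perfect fit; handled by caller
  } else {
    -0.5 * (n * log(2 * pi * sigma2) + n + sum(log(d)))
  }
  list(ll = ll, beta = drop(beta), sigma2 = sigma2, XtWX = XtWX, d = d)
}

# Dense path with per-species variance inflation: Sigma = sigma2 * C_lambda
# + diag(w); sigma2 is profiled numerically on log scale.
pgls_ll_dense <- function(lambda, log_sigma2, C, wts, X, y) {
  sigma2 <- exp(log_sigma2)
  Cl <- lambda * C
  diag(Cl) <- 1
  Sigma <- sigma2 * Cl + diag(wts, nrow(Cl))
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  Si_X <- backsolve(ch, forwardsolve(t(ch), X))
  Si_y <- backsolve(ch, forwardsolve(t(ch), y))
  XtSX <- crossprod(Si_X)
  beta <- tryCatch(solve(XtSX, crossprod(Si_X, Si_y)), error = function(e) NULL)
  if (is.null(beta)) return(list(ll = -Inf))
  r <- Si_y - Si_X %*% beta
  n <- length(y)
  ll <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r^2))
  list(ll = ll, beta = drop(beta), sigma2 = sigma2, XtWX = XtSX)
}

#' Phylogenetic generalized least squares allometric fit
#'
#' Fits `response ~ predictor` by GLS under the covariance
#' `sigma2 * C(lambda) + diag(weights)`, where `C(lambda)` is the Pagel-lambda
#' correlation matrix of the tree and `weights` are optional known per-species
#' variances (e.g. intraspecific sampling variance of a species mean). Both
#' variables are expected on the log10 scale for allometric use, though the
#' fit itself is scale-agnostic. `lambda` is estimated by full maximum
#' likelihood over `[0, 1]` (bounded scalar optimization with boundary and
#' grid fallbacks) unless fixed.
#'
#' @param data Data frame with one row per species.
#' @param tree [ape::phylo] tree whose tip labels cover the species. Species
#'   present in `data` but not on the tree are dropped with a warning.
#' @param formula Two-sided formula `response ~ predictor` (one predictor).
#' @param species Name of the species-identifier column (default `"species"`).
#' @param weights Optional name of a column holding known per-species error
#'   variances on the response scale, or a numeric vector (one per row).
#' @param lambda Optional fixed lambda in `[0, 1]`; `NULL` (default) estimates
#'   it by maximum likelihood.
#' @return An object of class `pgls_fit`: coefficients, `lambda`, `sigma2`,
#'   2x2 parameter covariance, log-likelihood and the ingredients needed for
#'   prediction. Use [tidy()], [glance()], [pgls_confband()],
#'   [pgls_predict_newtip()].
#' @export
pgls_fit <- function(data, tree, formula, species = "species",
                     weights = NULL, lambda = NULL) {
  stopifnot(inherits(tree, "phylo"))
  data <- as.data.frame(data)
  if (!species %in% names(data)) {
    stop_invalid(sprintf("Column '%s' not found in `data`.", species))
  }
  vars <- all.vars(formula)
  if (length(vars) != 2) {
    stop_invalid("`formula` must be `response ~ predictor` with one predictor.")
  }
  yname <- vars[1]
  xname <- vars[2]

  wts <- NULL
  if (!is.null(weights)) {
    wts <- if (is.character(weights)) data[[weights]] else as.numeric(weights)
    if (length(wts) != nrow(data)) {
      stop_invalid("`weights` must supply one variance per row of `data`.")
    }
    if (any(is.na(wts)) || any(wts < 0)) {
      stop_invalid("`weights` must be non-negative variances.")
    }
  }

  keep <- data[[species]] %in% tree$tip.label
  if (!all(keep)) {
    warn(sprintf(
      "Dropping %d species absent from the tree: %s",
      sum(!keep), paste(head(data[[species]][!keep], 5), collapse = ", ")
    ))
    data <- data[keep, , drop = FALSE]
    if (!is.null(wts)) wts <- wts[keep]
  }
  if (anyDuplicated(data[[species]])) {
    stop_invalid("`data` has duplicated species; aggregate to one row per species first.")
  }
  sp <- data[[species]]
  if (length(sp) < 3) {
    abort("Fewer than 3 species shared between data and tree.",
          class = "lagoceiling_insufficient_data")
  }
  tree <- ape::keep.tip(tree, sp)
  ord <- match(tree$tip.label, sp)
  data <- data[ord, , drop = FALSE]
  if (!is.null(wts)) wts <- wts[ord]
  sp <- data[[species]]

  y <- as.numeric(data[[yname]])
  x <- as.numeric(data[[xname]])
  if (anyNA(y) || anyNA(x)) stop_invalid("Missing values in response or predictor.")
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0) {
    abort("Predictor is constant; design is degenerate.",
          class = "lagoceiling_degenerate_design")
  }
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, x)
  colnames(X)[2] <- xname

  C <- suppressWarnings(lambda_correlation(tree, 1))
  if (!ape::is.ultrametric(tree, tol = 1e-6)) {
    warn("Tree is not ultrametric; proceeding with standardized correlations.")
  }

  use_dense <- !is.null(wts) && any(wts > 0)

  if (!use_dense) {
    eg <- eigen(C, symmetric = TRUE)
    ty <- drop(crossprod(eg$vectors, y))
    tX <- crossprod(eg$vectors, X)
    obj <- function(l) {
      ll <- pgls_ll_eigen(l, eg$values, ty, tX)$ll
      if (is.infinite(ll) && ll > 0) 1e12 else ll
    }
    if (is.null(lambda)) {
      opt <- optimize(obj, interval = c(0, 1), maximum = TRUE, tol = 1e-6)
      cand <- c(opt$maximum, 0, 0.25, 0.5, 0.75, 1)
      lls <- vapply(cand, obj, numeric(1))
      lambda_hat <- cand[which.max(lls)]
    } else {
      if (lambda < 0 || lambda > 1) stop_invalid("`lambda` must be in [0, 1].")
      lambda_hat <- lambda
    }
    fitted <- pgls_ll_eigen(lambda_hat, eg$values, ty, tX)
    beta <- fitted$beta
    sigma2 <- max(fitted$sigma2, 0)
    # df-corrected residual variance for the parameter covariance (as in
    # OLS practice); sigma2 itself stays the ML estimate.
    param_cov <- sigma2 * n / (n - 2) * solve(fitted$XtWX)
    loglik <- if (is.infinite(fitted$ll)) Inf else fitted$ll
  } else {
    v0 <- stats::var(stats::resid(lm(y ~ x)))
    ls2_bounds <- log(c(max(v0, 1e-8) * 1e-6, max(v0, 1e-8) * 1e3))
    prof_sigma <- function(l) {
      o <- optimize(function(ls2) pgls_ll_dense(l, ls2, C, wts, X, y)$ll,
                    interval = ls2_bounds, maximum = TRUE, tol = 1e-8)
      list(ll = o$objective, log_sigma2 = o$maximum)
    }
    if (is.null(lambda)) {
      opt <- optimize(function(l) prof_sigma(l)$ll,
                      interval = c(0, 1), maximum = TRUE, tol = 1e-6)
      cand <- c(opt$maximum, 0, 0.25, 0.5, 0.75, 1)
      lls <- vapply(cand, function(l) prof_sigma(l)$ll, numeric(1))
      lambda_hat <- cand[which.max(lls)]
    } else {
      if (lambda < 0 || lambda > 1) stop_invalid("`lambda` must be in [0, 1].")
      lambda_hat <- lambda
    }
    ps <- prof_sigma(lambda_hat)
    fitted <- pgls_ll_dense(lambda_hat, ps$log_sigma2, C, wts, X, y)
    beta <- fitted$beta
    sigma2 <- fitted$sigma2
    param_cov <- n / (n - 2) * solve(fitted$XtWX)
    loglik <- fitted$ll
  }

  names(beta) <- colnames(X)
  dimnames(param_cov) <- list(colnames(X), colnames(X))
  resids <- drop(y - X %*% beta)

  structure(
    list(
      intercept = unname(beta[1]),
      slope = unname(beta[2]),
      lambda = lambda_hat,
      lambda_fixed = !is.null(lambda),
      sigma2 = sigma2,
      param_cov = param_cov,
      loglik = loglik,
      n = n,
      species = sp,
      response = yname,
      predictor = xname,
      x = x,
      y = y,
      weights = if (is.null(wts)) rep(0, n) else wts,
      residuals = resids,
      tree = tree,
      C = C
    ),
    class = "pgls_fit"
  )
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS fit (Pagel's lambda)\n")
  cat(sprintf("  %s ~ %s, n = %d species\n", x$response, x$predictor, x$n))
  cat(sprintf("  intercept = %.4f, slope = %.4f\n", x$intercept, x$slope))
  cat(sprintf("  lambda = %.4f%s, sigma2 = %.5f, logLik = %.3f\n",
              x$lambda, if (x$lambda_fixed) " (fixed)" else "",
              x$sigma2, x$loglik))
  invisible(x)
}

#' @export
tidy.pgls_fit <- function(x, ...) {
  se <- sqrt(diag(x$param_cov))
  tibble::tibble(
    term = c("(Intercept)", x$predictor),
    estimate = c(x$intercept, x$slope),
    std.error = se,
    statistic = c(x$intercept, x$slope) / se,
    p.value = 2 * stats::pnorm(-abs(c(x$intercept, x$slope) / se))
  )
}

#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, sigma2 = x$sigma2, logLik = x$loglik,
    nobs = x$n
  )
}

#' Confidence band for a PGLS regression line
#'
#' Pointwise band for the fitted mean `intercept + slope * x` from the
#' parameter covariance of a [pgls_fit()]; optionally widened by the residual
#' variance to give a prediction band.
#'
#' @param fit A `pgls_fit`.
#' @param x_grid Numeric vector of predictor values.
#' @param level Coverage probability in (0, 1).
#' @param include_residual If `TRUE`, adds `sigma2` to the variance
#'   (prediction band for a new, phylogenetically independent observation).
#'   Default `FALSE`: band for the regression mean only.
#' @return Tibble with columns `x`, `estimate`, `lower`, `upper`.
#' @export
pgls_confband <- function(fit, x_grid, level = 0.95, include_residual = FALSE) {
  stopifnot(inherits(fit, "pgls_fit"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop_invalid("`level` must be in (0, 1).")
  }
  G <- cbind(1, x_grid)
  v <- rowSums((G %*% fit$param_cov) * G)
  if (include_residual) v <- v + fit$sigma2
  z <- stats::qt((1 + level) / 2, df = max(fit$n - 2, 1))
  est <- fit$intercept + fit$slope * x_grid
  tibble::tibble(
    x = x_grid,
    estimate = est,
    lower = est - z * sqrt(v),
    upper = est + z * sqrt(v)
  )
}

#' Predict the response of a new tip under a PGLS fit
#'
#' Conditional-normal (best linear unbiased) prediction for species grafted
#' onto the reference tree: the fixed-effect value plus a covariance-weighted
#' adjustment from the observed residuals of phylogenetic relatives. The
#' prediction variance combines the residual variance, the reduction from
#' conditioning, and parameter uncertainty.
#'
#' @param fit A `pgls_fit`.
#' @param tree Tree containing all of `fit$species` plus the new tip(s).
#' @param new_data Data frame with the species column and the fit's predictor
#'   column for each new tip.
#' @param species Name of the species column in `new_data`.
#' @return Tibble with `species`, `x`, `.pred`, `.pred_var`, `.pred_se`.
#' @export
pgls_predict_newtip <- function(fit, tree, new_data, species = "species") {
  stopifnot(inherits(fit, "pgls_fit"), inherits(tree, "phylo"))
  new_data <- as.data.frame(new_data)
  if (!all(fit$species %in% tree$tip.label)) {
    stop_invalid("`tree` must contain every species used in the fit.")
  }
  new_sp <- new_data[[species]]
  if (!all(new_sp %in% tree$tip.label)) {
    stop_invalid("New tip(s) not found on `tree`.")
  }
  xnew <- as.numeric(new_data[[fit$predictor]])

  sub <- ape::keep.tip(tree, c(fit$species, new_sp))
  Cfull <- suppressWarnings(lambda_correlation(sub, 1))
  refs <- fit$species
  # Residual covariance among references under the fitted model
  Cl <- fit$lambda * Cfull[refs, refs, drop = FALSE]
  diag(Cl) <- 1
  Sigma <- fit$sigma2 * Cl + diag(fit$weights, length(refs))
  Sinv <- tryCatch(solve(Sigma), error = function(e) NULL)
  X <- cbind(1, fit$x)
  P <- fit$param_cov
  r <- fit$residuals

  out <- purrr::map2(new_sp, xnew, function(spn, x0) {
    x0v <- c(1, x0)
    fe <- sum(x0v * c(fit$intercept, fit$slope))
    cvec <- fit$sigma2 * fit$lambda * Cfull[spn, refs]
    if (is.null(Sinv) || fit$sigma2 <= 0) {
      # Degenerate residual covariance: fall back to the fixed-effect line.
      return(tibble::tibble(
        species = spn, x = x0, .pred = fe,
        .pred_var = drop(x0v %*% P %*% x0v), .pred_se = sqrt(drop(x0v %*% P %*% x0v))
      ))
    }
    adj <- drop(cvec %*% Sinv %*% r)
    d <- x0v - drop(crossprod(X, Sinv %*% cvec))
    v <- fit$sigma2 - drop(cvec %*% Sinv %*% cvec) + drop(d %*% P %*% d)
    tibble::tibble(
      species = spn, x = x0, .pred = fe + adj,
      .pred_var = max(v, 0), .pred_se = sqrt(max(v, 0))
    )
  })
  dplyr::bind_rows(out)
}

#' @export
#' @rdname pgls_fit
#' @param x,object A `pgls_fit`.
#' @param ... Unused.
autoplot.pgls_fit <- function(object, ...) {
  dat <- tibble::tibble(x = object$x, y = object$y)
  grid <- seq(min(dat$x), max(dat$x), length.out = 100)
  band <- pgls_confband(object, grid)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$x, ymin = .data$lower, ymax = .data$upper),
      inherit.aes = FALSE, alpha = 0.2
    ) +
    ggplot2::geom_abline(
      intercept = object$intercept, slope = object$slope,
      linewidth = 0.6
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = object$predictor, y = object$response,
      title = sprintf("PGLS fit (lambda = %.2f)", object$lambda)
    )
}
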