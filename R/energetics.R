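#' Construct a local-population energy-use line
#'
#' The energy use of a local population is E = R * D, the product of
#' individual basal metabolic rate R = a * M^b and local population density
#' D = c * M^d. On the log10 scale this is a straight line
#' `log10 E = alpha + beta * log10 M` with `alpha = log10(a) + log10(c)` and
#' `beta = b + d`.
#'
#' @param alpha Intercept (log10 energy units).
#' @param beta Slope (unitless).
#' @param alpha_var,beta_var,alpha_beta_cov First-order uncertainty of the
#'   line parameters (default 0).
#' @param guild Label, e.g. `"lagomorph"` or `"ungulate"`.
#' @return An `energy_line` object.
#' @export
energy_line <- function(alpha, beta, alpha_var = 0, beta_var = 0,
                        alpha_beta_cov = 0, guild = "unspecified") {
  vals <- c(alpha, beta, alpha_var, beta_var, alpha_beta_cov)
  if (any(!is.finite(vals))) stop_invalid("Energy-line parameters must be finite.")
  if (alpha_var < 0 || beta_var < 0) stop_invalid("Variances must be non-negative.")
  structure(
    list(alpha = alpha, beta = beta, alpha_var = alpha_var,
         beta_var = beta_var, alpha_beta_cov = alpha_beta_cov, guild = guild),
    class = "energy_line"
  )
}

#' @export
print.energy_line <- function(x, ...) {
  cat(sprintf("Energy-use line (%s): log10 E = %.4f %+.4f * log10 M\n",
              x$guild, x$alpha, x$beta))
  invisible(x)
}

#' Compose an energy-use line from metabolic-rate and density fits
#'
#' Sums the intercepts and slopes of the two log10-log10 allometries
#' (metabolic rate and population density against body mass), treating the two
#' fits as independent when propagating parameter uncertainty.
#'
#' @param fit_r,fit_d [pgls_fit()] objects (or `energy_line`-like lists with
#'   `intercept`, `slope`, `param_cov`) for metabolic rate and density. Both
#'   must be on the log10 scale with the same mass units.
#' @param guild Guild label carried onto the line.
#' @return An `energy_line`.
#' @export
#' @examples
#' # R-scaling (0.6, 0.7) and D-scaling (2.0, -1.5) compose to (2.6, -0.8)
compose_energy_line <- function(fit_r, fit_d, guild = "unspecified") {
  part <- function(f) {
    if (inherits(f, "pgls_fit") ||
        (is.list(f) && all(c("intercept", "slope") %in% names(f)))) {
      pc <- f$param_cov %||% matrix(0, 2, 2)
      list(a = f$intercept, b = f$slope, va = pc[1, 1], vb = pc[2, 2],
           cab = pc[1, 2])
    } else {
      stop_invalid("Fits must carry `intercept` and `slope`.")
    }
  }
  r <- part(fit_r)
  d <- part(fit_d)
  energy_line(
    alpha = r$a + d$a,
    beta = r$b + d$b,
    alpha_var = r$va + d$va,
    beta_var = r$vb + d$vb,
    alpha_beta_cov = r$cab + d$cab,
    guild = guild
  )
}

#' Evaluate an energy-use line
#'
#' @param line An `energy_line`.
#' @param mass_kg Body mass(es) in kg.
#' @return log10 population energy use at each mass.
#' @export
energy_at <- function(line, mass_kg) {
  stopifnot(inherits(line, "energy_line"))
  if (any(mass_kg <= 0)) stop_invalid("`mass_kg` must be positive.")
  line$alpha + line$beta * log10(mass_kg)
}

#' @export
tidy.energy_line <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    std.error = sqrt(c(x$alpha_var, x$beta_var)),
    guild = x$guild
  )
}

#' Equilibrial body mass of two energy-use lines
#'
#' The mass at which two guilds' local-population energy-use lines intersect:
#' below it the steeper-declining guild uses more energy per local population
#' at equal mass; above it, less. On the log10 scale,
#' `log10 M* = (alpha_ung - alpha_lag) / (beta_lag - beta_ung)`.
#' Uncertainty is first-order (delta-method), treating the two lines as
#' independent.
#'
#' @param line_lag,line_ung `energy_line` objects (e.g. lagomorph, ungulate).
#' @return One-row tibble: `log10_mass`, `mass_kg`, `se_log10`.
#' @export
#' @examples
#' lag <- energy_line(2.8, -1.2, guild = "lagomorph")
#' ung <- energy_line(2.2, -0.45, guild = "ungulate")
#' equilibrial_mass(lag, ung)$mass_kg # ~6.31 kg
equilibrial_mass <- function(line_lag, line_ung) {
  stopifnot(inherits(line_lag, "energy_line"), inherits(line_ung, "energy_line"))
  den <- line_lag$beta - line_ung$beta
  if (abs(den) < 1e-12) {
    abort("Lines have equal slopes: no (unique) intersection.",
          class = "lagoceiling_no_intersection")
  }
  num <- line_ung$alpha - line_lag$alpha
  m <- num / den
  # Gradient wrt (alpha_lag, beta_lag, alpha_ung, beta_ung)
  g <- c(-1 / den, -num / den^2, 1 / den, num / den^2)
  V <- matrix(0, 4, 4)
  V[1:2, 1:2] <- matrix(c(line_lag$alpha_var, line_lag$alpha_beta_cov,
                          line_lag$alpha_beta_cov, line_lag$beta_var), 2, 2)
  V[3:4, 3:4] <- matrix(c(line_ung$alpha_var, line_ung$alpha_beta_cov,
                          line_ung$alpha_beta_cov, line_ung$beta_var), 2, 2)
  se <- sqrt(drop(g %*% V %*% g))
  tibble::tibble(log10_mass = m, mass_kg = 10^m, se_log10 = se)
}

#' Energy-equivalent body mass
#'
#' The body mass at which one guild's local-population energy use equals
#' another guild's energy use at a given mass: solving
#' `alpha_lag + beta_lag * log10 M_eq = alpha_ung + beta_ung * log10 m_ung`.
#' Used to translate the smallest contemporary perissodactyl into the
#' lagomorph body mass with equal population energy use. Because the ungulate
#' slope is much shallower than the lagomorph slope, `M_eq` varies far less
#' than proportionally with `m_ung`.
#'
#' @param line_lag Line to solve on (slope must be non-zero).
#' @param line_ung Line evaluated at `m_ung`.
#' @param m_ung Ungulate body mass(es), kg.
#' @return Tibble with one row per `m_ung`: `m_ung_kg`, `log10_m_eq`,
#'   `m_eq_kg`, `se_log10`.
#' @export
#' @examples
#' lag <- energy_line(2.8, -1.2)
#' ung <- energy_line(2.2, -0.45)
#' energy_equivalent_mass(lag, ung, 100)$m_eq_kg # ~17.78 kg
energy_equivalent_mass <- function(line_lag, line_ung, m_ung) {
  stopifnot(inherits(line_lag, "energy_line"), inherits(line_ung, "energy_line"))
  if (abs(line_lag$beta) < 1e-12) {
    abort("Lagomorph line has zero slope: energy equivalence unsolvable.",
          class = "lagoceiling_unsolvable")
  }
  if (any(m_ung <= 0)) stop_invalid("`m_ung` must be positive.")
  x <- log10(m_ung)
  g10 <- (line_ung$alpha + line_ung$beta * x - line_lag$alpha) / line_lag$beta
  V <- matrix(0, 4, 4)
  V[1:2, 1:2] <- matrix(c(line_lag$alpha_var, line_lag$alpha_beta_cov,
                          line_lag$alpha_beta_cov, line_lag$beta_var), 2, 2)
  V[3:4, 3:4] <- matrix(c(line_ung$alpha_var, line_ung$alpha_beta_cov,
                          line_ung$alpha_beta_cov, line_ung$beta_var), 2, 2)
  se <- vapply(seq_along(x), function(i) {
    g <- c(-1 / line_lag$beta, -g10[i] / line_lag$beta,
           1 / line_lag$beta, x[i] / line_lag$beta)
    sqrt(drop(g %*% V %*% g))
  }, numeric(1))
  tibble::tibble(
    m_ung_kg = m_ung, log10_m_eq = g10, m_eq_kg = 10^g10, se_log10 = se
  )
}

#' Plot a pair of energy-use lines and their intersection
#'
#' @param line_lag,line_ung `energy_line` objects.
#' @param mass_range Plot range in kg.
#' @return A ggplot.
#' @export
plot_energy_lines <- function(line_lag, line_ung, mass_range = c(0.05, 1000)) {
  grid <- 10^seq(log10(mass_range[1]), log10(mass_range[2]), length.out = 200)
  df <- dplyr::bind_rows(
    tibble::tibble(mass_kg = grid, log10_E = energy_at(line_lag, grid),
                   guild = line_lag$guild),
    tibble::tibble(mass_kg = grid, log10_E = energy_at(line_ung, grid),
                   guild = line_ung$guild)
  )
  eq <- tryCatch(equilibrial_mass(line_lag, line_ung), error = function(e) NULL)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$mass_kg),
                                        y = .data$log10_E,
                                        colour = .data$guild)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "log10 body mass (kg)",
                  y = "log10 local-population energy use")
  if (!is.null(eq)) {
    p <- p + ggplot2::geom_vline(xintercept = eq$log10_mass, linetype = 2)
  }
  p
}
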