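test_that("AICc follows the corrected formula", {
  # k = 4, n = 24: correction term 2*4*5/19 = 40/19
  expect_equal(aicc(0, 4, 24), 8 + 40 / 19)
  # Brute force over random inputs
  set.seed(3)
  for (i in 1:50) {
    ll <- rnorm(1, -20, 10)
    k <- sample(2:6, 1)
    n <- k + 1 + sample(1:40, 1)
    expect_equal(aicc(ll, k, n),
                 -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1),
                 tolerance = 1e-12)
  }
  # Large-n limit approaches AIC
  expect_equal(aicc(-10, 3, 1e7), -2 * -10 + 2 * 3, tolerance = 1e-5)
  # Equal likelihood: smaller k wins
  expect_lt(aicc(-10, 3, 24), aicc(-10, 4, 24))
  expect_error(aicc(0, 5, 6), class = "lagoceiling_undefined_correction")
})

test_that("two-pass autocovariate regression matches the normal-equations oracle", {
  set.seed(5)
  n <- 12
  dat <- tibble::tibble(
    bin = 0:(n - 1),
    x1 = rnorm(n), x2 = rnorm(n),
    y = 1 + 0.8 * rnorm(n)
  )
  dat$y <- 1 + 0.5 * dat$x1 - 0.3 * dat$x2 + rnorm(n, 0, 0.2)
  fit <- autocov_regression(dat, "y", c("x1", "x2"))
  o <- two_pass_oracle(dat$y, cbind(dat$x1, dat$x2))
  expect_equal(unname(fit$coefficients), unname(o$coef), tolerance = 1e-10)
  expect_equal(fit$loglik, o$loglik, tolerance = 1e-10)
  expect_equal(fit$n, o$n)
  expect_equal(fit$k, 5L)
  # Order invariance: shuffled rows, same fit
  sh <- dat[sample(n), ]
  fit2 <- autocov_regression(sh, "y", c("x1", "x2"))
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_error(autocov_regression(dat[1:3, ], "y", c("x1", "x2")),
               class = "lagoceiling_insufficient_data")
})

test_that("a perfect first-pass fit leaves coefficients unchanged", {
  dat <- tibble::tibble(bin = 0:9, x = seq(0, 1, length.out = 10))
  dat$y <- 2 + 3 * dat$x
  fit <- autocov_regression(dat, "y", "x")
  expect_equal(unname(fit$coefficients["(Intercept)"]), 2, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["x"]), 3, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["autocov"]), 0)
})

test_that("missing interior bins use the nearest older residual", {
  set.seed(6)
  dat <- tibble::tibble(bin = 0:9, x = rnorm(10))
  dat$y <- 1 + 0.5 * dat$x + rnorm(10, 0, 0.3)
  dat$y[dat$bin == 5] <- NA
  fit <- autocov_regression(dat, "y", "x")
  # bins retained: 0..4, 6..9; pass-2 drops the first; the lag for bin 6 is
  # bin 4's residual
  expect_equal(fit$bins_used, c(1:4, 6:9))
  expect_equal(fit$n, 8L)
})

test_that("the default roster comprises the eleven stated models", {
  r <- model_roster()
  expect_equal(nrow(r), 11)
  expect_equal(sum(lengths(r$predictors) == 1), 5)
  expect_equal(sum(lengths(r$predictors) == 2), 6)
  expect_equal(r$predictors[[6]], c("m_ceiling", "r_glires"))
  expect_equal(r$predictors[[9]], c("m_minper", "h_ung"))
  expect_equal(r$predictors[[11]], c("m_minper", "d18o"))
  singles <- unlist(r$predictors[1:5])
  expect_setequal(singles, c("m_ceiling", "m_minper", "d18o", "h_ung",
                             "r_glires"))
})

test_that("model comparison normalizes deltas and evidence ratios", {
  g <- bin_grid()
  sc <- ceiling_scenario(g, seed = 91)
  sim <- simulate_fossil_record(sc$trajectories, g, age_halfwidth = 0,
                                mass_se = 0, seed = 92)
  ser <- build_series(sim$occurrences, sim_mass_estimates(sim),
                      sc$line_lag, sc$line_ung, sc$d18o, sc$h_ung, g)
  cmp <- compare_models(ser)
  expect_equal(min(cmp$table$delta_aicc), 0)
  expect_equal(cmp$table$evidence_ratio[cmp$table$delta_aicc == 0], 1)
  expect_equal(cmp$table$evidence_ratio,
               exp(0.5 * cmp$table$delta_aicc), tolerance = 1e-12)
  expect_true(all(cmp$table$n == cmp$table$n[1])) # same rows for all models
  # Single-model roster
  cmp1 <- compare_models(ser, model_roster()[1, ])
  expect_equal(cmp1$table$delta_aicc, 0)
  expect_equal(cmp1$table$evidence_ratio, 1)
  # A delta of exactly 2 gives an evidence ratio of e
  expect_equal(exp(0.5 * 2), exp(1))
})

test_that("each single-predictor generator is recovered as the best model", {
  g <- bin_grid()
  sc <- ceiling_scenario(g, seed = 101)
  sim <- simulate_fossil_record(sc$trajectories, g, age_halfwidth = 0,
                                mass_se = 0, seed = 102)
  ser <- build_series(sim$occurrences, sim_mass_estimates(sim),
                      sc$line_lag, sc$line_ung, sc$d18o, sc$h_ung, g)
  preds <- c("m_ceiling", "m_minper", "d18o", "h_ung", "r_glires")
  set.seed(103)
  hits <- vapply(seq_along(preds), function(i) {
    p <- preds[i]
    z <- scale(ser[[p]])[, 1]
    best <- vapply(1:15, function(rep) {
      ser2 <- ser
      ser2$m_maxlag <- 0.2 + 0.6 * z + rnorm(nrow(ser), 0, 0.05)
      compare_models(ser2)$best_model
    }, numeric(1))
    tab <- table(best)
    as.integer(names(tab)[which.max(tab)]) == i
  }, logical(1))
  expect_true(all(hits))
})

test_that("pure-noise responses do not crown the ceiling model", {
  g <- bin_grid()
  sc <- ceiling_scenario(g, seed = 111)
  sim <- simulate_fossil_record(sc$trajectories, g, age_halfwidth = 0,
                                mass_se = 0, seed = 112)
  ser <- build_series(sim$occurrences, sim_mass_estimates(sim),
                      sc$line_lag, sc$line_ung, sc$d18o, sc$h_ung, g)
  set.seed(113)
  wins <- vapply(1:30, function(i) {
    ser2 <- ser
    ser2$m_maxlag <- rnorm(nrow(ser), 0.3, 0.1)
    compare_models(ser2)$best_model
  }, numeric(1))
  expect_lt(mean(wins == 1), 0.5)
  expect_gt(dplyr::n_distinct(wins), 1)
})

test_that("degenerate pseudo-replicates equal the deterministic run", {
  g <- bin_grid()
  sc <- ceiling_scenario(g, seed = 121)
  sim <- simulate_fossil_record(sc$trajectories, g, age_halfwidth = 0,
                                mass_se = 0, seed = 122)
  me <- sim_mass_estimates(sim)
  point <- compare_models(
    build_series(sim$occurrences, me, sc$line_lag, sc$line_ung,
                 sc$d18o, sc$h_ung, g)
  )
  ens <- pseudoreplicate_analysis(sim$occurrences, me, sc$line_lag,
                                  sc$line_ung, sc$d18o, sc$h_ung, g,
                                  n_reps = 1, seed = 5)
  expect_equal(ens$n_failed, 0)
  d <- dplyr::arrange(ens$deltas, model_id)
  expect_equal(d$delta_aicc,
               dplyr::arrange(point$table, model_id)$delta_aicc,
               tolerance = 1e-10)
  expect_equal(ens$best_counts$wins[point$best_model], 1L)
})

test_that("replicate ensembles are reproducible under a fixed seed", {
  g <- bin_grid()
  sc <- ceiling_scenario(g, seed = 131)
  sim <- simulate_fossil_record(sc$trajectories, g, age_halfwidth = 0.4,
                                mass_se = 0.04, seed = 132)
  me <- sim_mass_estimates(sim)
  run <- function() {
    suppressWarnings(pseudoreplicate_analysis(
      sim$occurrences, me, sc$line_lag, sc$line_ung, sc$d18o, sc$h_ung,
      g, n_reps = 10, seed = 99
    ))
  }
  e1 <- run()
  e2 <- run()
  expect_identical(e1$best_counts, e2$best_counts)
  expect_identical(e1$deltas, e2$deltas)
  expect_error(
    pseudoreplicate_analysis(sim$occurrences, me, sc$line_lag, sc$line_ung,
                             n_reps = 0),
    class = "lagoceiling_invalid_argument"
  )
})
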