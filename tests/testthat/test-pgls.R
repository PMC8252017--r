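test_that("lambda correlation matches its defining geometry", {
  tr <- cherry_plus_one()
  C0 <- lambda_correlation(tr, 0)
  expect_equal(unname(C0), diag(3))
  C1 <- lambda_correlation(tr, 1)
  expect_equal(C1["A", "B"], 0.5)
  expect_equal(C1["A", "C"], 0)
  Ch <- lambda_correlation(tr, 0.5)
  expect_equal(Ch["A", "B"], 0.25)
  expect_equal(Ch["A", "C"], 0)
  expect_equal(diag(Ch), setNames(rep(1, 3), c("A", "B", "C")))
  expect_error(lambda_correlation(tr, 1.2), class = "lagoceiling_invalid_argument")
})

test_that("pgls at fixed lambda reproduces dense matrix-algebra GLS", {
  tr <- simulate_tree(8, 0.2, seed = 11)
  td <- simulate_scaling_traits(tr, 1.0, -0.8, lambda_true = 1, sigma_resid = 0.3,
                                seed = 12)
  for (lam in c(0, 0.5, 1)) {
    f <- pgls_fit(td, tr, response ~ log10_mass, lambda = lam)
    V <- lambda_correlation(tr, lam)
    idx <- match(f$species, td$species)
    X <- cbind(1, td$log10_mass[idx])
    o <- dense_gls(X, V[f$species, f$species], td$response[idx])
    expect_equal(f$intercept, o$beta[1], tolerance = 1e-8)
    expect_equal(f$slope, o$beta[2], tolerance = 1e-8)
    expect_equal(f$sigma2, o$sigma2, tolerance = 1e-8)
    expect_equal(unname(f$param_cov), unname(o$param_cov), tolerance = 1e-8)
  }
})

test_that("star tree and lambda = 0 both reduce to OLS", {
  tr <- star_tree(12)
  set.seed(3)
  td <- tibble::tibble(
    species = tr$tip.label,
    log10_mass = runif(12, 0, 2)
  )
  td$response <- 1.5 - 0.7 * td$log10_mass + rnorm(12, 0, 0.1)
  ols <- coef(lm(response ~ log10_mass, td))
  f_star <- pgls_fit(td, tr, response ~ log10_mass)
  expect_equal(f_star$intercept, unname(ols[1]), tolerance = 1e-8)
  expect_equal(f_star$slope, unname(ols[2]), tolerance = 1e-8)

  tr2 <- simulate_tree(12, 0.3, seed = 4)
  td$species <- tr2$tip.label
  f0 <- pgls_fit(td, tr2, response ~ log10_mass, lambda = 0)
  expect_equal(f0$intercept, unname(ols[1]), tolerance = 1e-8)
  expect_equal(f0$slope, unname(ols[2]), tolerance = 1e-8)
})

test_that("noiseless data are recovered exactly with zero residual variance", {
  tr <- simulate_tree(10, 0.2, seed = 21)
  td <- tibble::tibble(species = tr$tip.label,
                       log10_mass = seq(-1, 2, length.out = 10))
  td$response <- 2 + 0.75 * td$log10_mass
  f <- pgls_fit(td, tr, response ~ log10_mass)
  expect_equal(f$intercept, 2, tolerance = 1e-6)
  expect_equal(f$slope, 0.75, tolerance = 1e-6)
  expect_lt(f$sigma2, 1e-10)
})

test_that("estimated lambda dominates the likelihood grid", {
  for (s in 1:3) {
    tr <- simulate_tree(60, 0.1, seed = 30 + s)
    td <- simulate_scaling_traits(tr, 1, -1, lambda_true = 0.7,
                                  sigma_resid = 0.25, seed = 40 + s)
    f <- pgls_fit(td, tr, response ~ log10_mass)
    for (lam in c(0, 0.25, 0.5, 0.75, 1)) {
      fg <- pgls_fit(td, tr, response ~ log10_mass, lambda = lam)
      expect_gte(f$loglik, fg$loglik - 1e-6)
    }
  }
})

test_that("degenerate and undersized designs are rejected", {
  tr <- simulate_tree(6, 0.2, seed = 1)
  td <- tibble::tibble(species = tr$tip.label, x = rep(1, 6),
                       y = rnorm(6))
  expect_error(pgls_fit(td, tr, y ~ x), class = "lagoceiling_degenerate_design")
  td2 <- tibble::tibble(species = c("zz1", "zz2", tr$tip.label[1:2]),
                        x = 1:4, y = 1:4)
  expect_warning(
    expect_error(pgls_fit(td2, tr, y ~ x),
                 class = "lagoceiling_insufficient_data"),
    "absent from the tree"
  )
})

test_that("species missing from the tree are dropped with a warning", {
  tr <- simulate_tree(10, 0.2, seed = 7)
  td <- tibble::tibble(species = c(tr$tip.label, "ghost"),
                       x = c(seq(0, 2, length.out = 10), 1))
  td$y <- 1 + td$x
  expect_warning(f <- pgls_fit(td, tr, y ~ x), "ghost")
  expect_equal(f$n, 10)
})

test_that("confidence bands are nested, centred, and collapse at sigma2 = 0", {
  tr <- simulate_tree(20, 0.2, seed = 51)
  td <- simulate_scaling_traits(tr, 1, -1, lambda_true = 0.5,
                                sigma_resid = 0.2, seed = 52)
  f <- pgls_fit(td, tr, response ~ log10_mass)
  grid <- seq(-1, 3, length.out = 201)
  b95 <- pgls_confband(f, grid, 0.95)
  b99 <- pgls_confband(f, grid, 0.99)
  expect_true(all(b99$lower <= b95$lower & b95$upper <= b99$upper))
  # Width is minimized at the GLS-weighted mean of x (= -cov/var from the
  # parameter covariance).
  w <- b95$upper - b95$lower
  xmin_expected <- -f$param_cov[1, 2] / f$param_cov[2, 2]
  expect_lt(abs(grid[which.min(w)] - xmin_expected), diff(grid[1:2]) + 1e-9)
  # Zero residual variance: zero-width band.
  td0 <- tibble::tibble(species = tr$tip.label,
                        log10_mass = seq(0, 2, length.out = 20))
  td0$response <- 1 + td0$log10_mass
  f0 <- pgls_fit(td0, tr, response ~ log10_mass)
  b0 <- pgls_confband(f0, grid)
  expect_lt(max(b0$upper - b0$lower), 1e-6)
  expect_error(pgls_confband(f, grid, level = 1.2),
               class = "lagoceiling_invalid_argument")
})

test_that("new-tip prediction matches the conditional-normal oracle", {
  # 4 references plus one new tip, lambda fixed at 1.
  txt <- "(((A:1,B:1):1,(C:1,N:1):1):1,D:3);"
  tr <- read_newick(txt)
  refs <- c("A", "B", "C", "D")
  set.seed(9)
  td <- tibble::tibble(species = refs, x = c(0.2, 1.1, 0.7, 1.9))
  td$y <- 1 + 0.5 * td$x + rnorm(4, 0, 0.3)
  f <- pgls_fit(td, ape::keep.tip(tr, refs), y ~ x, lambda = 1)
  pr <- pgls_predict_newtip(f, tr, tibble::tibble(species = "N", x = 1.0))

  Cfull <- ape::vcv(tr, corr = TRUE)
  Sigma <- f$sigma2 * Cfull[f$species, f$species]
  cv <- f$sigma2 * Cfull["N", f$species]
  idx <- match(f$species, td$species)
  mu_obs <- f$intercept + f$slope * td$x[idx]
  oc <- conditional_normal(mu_obs, f$intercept + f$slope * 1.0,
                           Sigma, cv, f$sigma2, td$y[idx])
  expect_equal(pr$.pred, oc$mean, tolerance = 1e-8)
  # Variance additionally carries the parameter-uncertainty term.
  X <- cbind(1, td$x[idx])
  d <- c(1, 1.0) - drop(t(X) %*% solve(Sigma) %*% cv)
  expect_equal(pr$.pred_var, oc$var + drop(d %*% f$param_cov %*% d),
               tolerance = 1e-8)
})

test_that("new-tip prediction limits: independence and twin", {
  # Star tree: zero covariance to every reference -> fixed-effect line and
  # variance sigma2 + parameter term.
  tips <- paste0("s", 1:8)
  star9 <- read_newick(
    paste0("(", paste(c(paste0(tips, ":1"), "new:1"), collapse = ","), ");")
  )
  set.seed(13)
  td <- tibble::tibble(species = tips, x = runif(8, 0, 2))
  td$y <- 0.5 + 1.2 * td$x + rnorm(8, 0, 0.2)
  f <- pgls_fit(td, ape::keep.tip(star9, tips), y ~ x, lambda = 1)
  pr <- pgls_predict_newtip(f, star9, tibble::tibble(species = "new", x = 1))
  expect_equal(pr$.pred, f$intercept + f$slope, tolerance = 1e-8)
  xv <- c(1, 1)
  expect_equal(pr$.pred_var, f$sigma2 + drop(xv %*% f$param_cov %*% xv),
               tolerance = 1e-8)

  # Twin: a new tip at near-zero distance from reference tip A shrinks to
  # A's observed value under lambda = 1.
  tw <- read_newick(
    "(((A:0.000001,TW:0.000001):0.999999,B:1.0):1,(C:1,D:1):1);"
  )
  set.seed(14)
  td2 <- tibble::tibble(species = c("A", "B", "C", "D"),
                        x = c(0.3, 1.2, 0.8, 1.7))
  td2$y <- 1 - 0.6 * td2$x + rnorm(4, 0, 0.4)
  f2 <- pgls_fit(td2, ape::keep.tip(tw, td2$species), y ~ x, lambda = 1)
  pr2 <- pgls_predict_newtip(f2, tw,
                             tibble::tibble(species = "TW", x = td2$x[1]))
  expect_equal(pr2$.pred, td2$y[1], tolerance = 1e-3)
  expect_error(
    pgls_predict_newtip(f2, tw, tibble::tibble(species = "absent", x = 1)),
    class = "lagoceiling_invalid_argument"
  )
})

test_that("lambda-zero traits show no phylogenetic residual correlation", {
  # Sister-pair residual products average to ~0 when traits are iid across
  # tips; strongly positive when lambda = 1.
  tr <- simulate_tree(40, 0.2, seed = 61)
  pair_cor <- function(lambda_true, seeds) {
    prods <- vapply(seeds, function(s) {
      td <- simulate_scaling_traits(tr, 0, 0, lambda_true = lambda_true,
                                    sigma_resid = 1, seed = s)
      C <- lambda_correlation(tr, 1)
      diag(C) <- 0
      top <- which(C == max(C), arr.ind = TRUE)[1, ]
      td$response[top[1]] * td$response[top[2]]
    }, numeric(1))
    mean(prods)
  }
  m0 <- pair_cor(0, 1:400)
  m1 <- pair_cor(1, 1:400)
  expect_lt(abs(m0), 0.15)
  expect_gt(m1, 0.5)
})
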