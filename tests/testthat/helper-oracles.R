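# Independent oracles and small fixtures shared across tests.

# Dense matrix-algebra GLS: beta = (X' V^-1 X)^-1 X' V^-1 y, with the
# residual variance and (df-corrected) parameter covariance computed from
# explicit inversions. Deliberately naive.
dense_gls <- function(X, V, y) {
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X) %*% XtVi %*% y
  r <- y - X %*% beta
  n <- length(y)
  sigma2 <- drop(t(r) %*% Vi %*% r) / n
  list(
    beta = drop(beta),
    sigma2 = sigma2,
    param_cov = sigma2 * n / (n - 2) * solve(XtVi %*% X)
  )
}

# Conditional multivariate-normal mean/variance for a new observation with
# covariance vector cv to the observed vector (joint covariance assembled
# and partitioned explicitly).
conditional_normal <- function(mu_obs, mu_new, Sigma_obs, cv, v_new, y_obs) {
  Si <- solve(Sigma_obs)
  list(
    mean = mu_new + drop(cv %*% Si %*% (y_obs - mu_obs)),
    var = v_new - drop(cv %*% Si %*% cv)
  )
}

# Brute-force central-moment G1 skewness.
g1_bruteforce <- function(x) {
  n <- length(x)
  m2 <- sum((x - mean(x))^2) / n
  m3 <- sum((x - mean(x))^3) / n
  sqrt(n * (n - 1)) / (n - 2) * m3 / m2^(3 / 2)
}

# Two-pass autocovariate least squares via explicit normal equations.
two_pass_oracle <- function(y, X) {
  X1 <- cbind(1, X)
  b1 <- solve(crossprod(X1), crossprod(X1, y))
  e <- y - X1 %*% b1
  lag <- c(NA, e[-length(e)])
  keep <- !is.na(lag)
  X2 <- cbind(X1[keep, , drop = FALSE], lag[keep])
  y2 <- y[keep]
  b2 <- solve(crossprod(X2), crossprod(X2, y2))
  r2 <- y2 - X2 %*% b2
  n2 <- length(y2)
  s2 <- sum(r2^2) / n2
  ll <- -n2 / 2 * (log(2 * pi * s2) + 1)
  list(coef = drop(b2), loglik = ll, n = n2)
}

cherry_plus_one <- function() {
  lagoceiling::read_newick("((A:1,B:1):1,C:2);")
}

star_tree <- function(n) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- paste0("s", seq_len(n))
  tr
}

# Tiny deterministic occurrence table builder.
occ_row <- function(taxon, clade, locality, amax, amin, mass,
                    genus = taxon, se = 0) {
  tibble::tibble(
    taxon = taxon, genus = genus, clade = clade, locality_id = locality,
    age_max = amax, age_min = amin, mass_log10 = mass, mass_se_log10 = se
  )
}
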