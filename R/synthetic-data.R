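#' Simulation configuration
#'
#' Bundles and validates the knobs of the synthetic-data generators: tree
#' size and birth rate, the true Pagel's lambda and residual scatter of the
#' scaling traits, the default intercepts/slopes of the density and
#' metabolic-rate allometries, the fossil time grid, the maximum half-width
#' of locality age uncertainty, and the reported standard error of fossil
#' mass estimates. Defaults give a lagomorph and an ungulate energy-use line
#' crossing near 6.3 kg (metabolic rate shared between guilds, density
#' declining much more steeply in lagomorphs).
#'
#' @param n_tips Number of tree tips.
#' @param birth_rate Speciation rate (per Myr) of the pure-birth tree.
#' @param lambda_true True Pagel's lambda in `[0, 1]`.
#' @param bmr_intercept,bmr_slope Metabolic-rate allometry (log10 scale),
#'   shared between guilds.
#' @param density_intercept_lag,density_slope_lag Lagomorph density allometry.
#' @param density_intercept_ung,density_slope_ung Ungulate density allometry.
#' @param sigma_resid Residual SD of simulated traits (log10 units).
#' @param n_bins,bin_width Fossil time grid (bins of `bin_width` Myr).
#' @param locality_age_halfwidth_max Maximum half-width of locality age
#'   uncertainty (Myr).
#' @param mass_se Standard error of fossil mass estimates (log10 kg).
#' @param seed Integer seed; the same seed gives bit-identical outputs.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_tips = 64, birth_rate = 0.1, lambda_true = 0.5,
                       bmr_intercept = 0.6, bmr_slope = 0.7,
                       density_intercept_lag = 2.2, density_slope_lag = -1.9,
                       density_intercept_ung = 1.6, density_slope_ung = -1.15,
                       sigma_resid = 0.15,
                       n_bins = 29, bin_width = 1.5,
                       locality_age_halfwidth_max = 0.55,
                       mass_se = 0.05, seed = 1L) {
  if (n_tips < 2) stop_invalid("`n_tips` must be at least 2.")
  if (birth_rate <= 0) stop_invalid("`birth_rate` must be positive.")
  if (lambda_true < 0 || lambda_true > 1) stop_invalid("`lambda_true` must be in [0, 1].")
  if (sigma_resid < 0) stop_invalid("`sigma_resid` must be non-negative.")
  if (bin_width <= 0) stop_invalid("`bin_width` must be positive.")
  if (locality_age_halfwidth_max < 0) stop_invalid("`locality_age_halfwidth_max` must be >= 0.")
  if (mass_se < 0) stop_invalid("`mass_se` must be non-negative.")
  structure(
    list(n_tips = n_tips, birth_rate = birth_rate, lambda_true = lambda_true,
         bmr_intercept = bmr_intercept, bmr_slope = bmr_slope,
         density_intercept_lag = density_intercept_lag,
         density_slope_lag = density_slope_lag,
         density_intercept_ung = density_intercept_ung,
         density_slope_ung = density_slope_ung,
         sigma_resid = sigma_resid, n_bins = n_bins, bin_width = bin_width,
         locality_age_halfwidth_max = locality_age_halfwidth_max,
         mass_se = mass_se, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a time-calibrated ultrametric tree
#'
#' Pure-birth (Yule) tree via [ape::rphylo()]: the simplest generator of
#' ultrametric, binary, positively-branched trees, which is all the
#' lambda-GLS machinery requires of a stand-in supertree.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per Myr.
#' @param seed Integer seed.
#' @return An ultrametric [ape::phylo] with tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 0.1, seed = NULL) {
  if (!is.numeric(n_tips) || n_tips < 2) {
    stop_invalid("`n_tips` must be at least 2.")
  }
  if (birth_rate <= 0) stop_invalid("`birth_rate` must be positive.")
  with_seed(seed, ape::rphylo(n = n_tips, birth = birth_rate, death = 0))
}

#' Simulate allometric scaling traits on a tree
#'
#' Draws log10 body masses uniformly in `mass_range` (log-uniform masses
#' match the log-linear allometry domain) and a response
#' `intercept + slope * log10(M) + eps`, where `eps` is multivariate normal
#' with covariance `sigma_resid^2 * C(lambda_true)` from the tree.
#'
#' @param tree [ape::phylo].
#' @param intercept,slope True allometry (log10 scale).
#' @param lambda_true True Pagel's lambda in `[0, 1]`.
#' @param sigma_resid Residual SD (log10 units).
#' @param mass_range Interval of log10 mass (kg) for the uniform draw.
#' @param seed Integer seed.
#' @return Tibble `species`, `log10_mass`, `response`.
#' @export
simulate_scaling_traits <- function(tree, intercept, slope, lambda_true = 0.5,
                                    sigma_resid = 0.15,
                                    mass_range = c(-1, 3), seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (lambda_true < 0 || lambda_true > 1) {
    stop_invalid("`lambda_true` must be in [0, 1].")
  }
  if (sigma_resid < 0) stop_invalid("`sigma_resid` must be non-negative.")
  n <- length(tree$tip.label)
  with_seed(seed, {
    log10_mass <- runif(n, mass_range[1], mass_range[2])
    eps <- if (sigma_resid > 0) {
      Cl <- lambda_correlation(tree, lambda_true)
      drop(crossprod(chol(Cl), rnorm(n))) * sigma_resid
    } else {
      rep(0, n)
    }
    tibble::tibble(
      species = tree$tip.label,
      log10_mass = log10_mass,
      response = intercept + slope * log10_mass + eps
    )
  })
}

# Taxon range bookkeeping: collapse runs of identical per-bin extrema into
# multi-bin taxa so range-through reconstruction is exercised.
traj_to_taxa <- function(trajectories, clade_name, prefix) {
  tr <- trajectories |>
    dplyr::filter(.data$clade == clade_name) |>
    dplyr::arrange(.data$bin)
  if (nrow(tr) == 0) return(NULL)
  if (!all(diff(tr$bin) == 1)) {
    stop_invalid(sprintf("Trajectory bins for clade '%s' must be contiguous.", clade_name))
  }
  r <- rle(tr$value_log10)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  tibble::tibble(
    taxon = sprintf("%s_ext%02d", prefix, seq_along(r$values)),
    clade = clade_name,
    first_bin = tr$bin[starts],
    last_bin = tr$bin[ends],
    true_mass_log10 = r$values,
    role = "extremal"
  )
}

#' Simulate a fossil occurrence record with known ground truth
#'
#' Generates taxa, localities and occurrence records whose per-bin clade
#' extrema equal a supplied set of true trajectories. Each clade gets
#' "extremal" taxa realising the trajectory (runs of equal values become
#' multi-bin taxa, always sampled in the first and last bin of their range so
#' range-through presence reconstructs the truth) plus background taxa on the
#' safe side of the extremum. Rodent genera are added so glires sampling
#' probability is computable. Locality ages are uniform within their bin with
#' symmetric bounded uncertainty (so the locality midpoint age equals the
#' true age); taxon mass point estimates are normal around the truth with the
#' reported standard error.
#'
#' @param trajectories Tibble `bin`, `clade`
#'   (lagomorph/artiodactyl/perissodactyl), `value_log10`: the true per-bin
#'   extremum (max for lagomorphs, min for the ungulate clades) on log10 kg.
#' @param grid A [bin_grid()].
#' @param n_localities Localities generated per bin.
#' @param age_halfwidth Maximum half-width (Myr) of locality age bounds.
#' @param mass_se Reported standard error of mass estimates (log10 kg).
#' @param n_background Background taxa per clade.
#' @param sampling_prob Probability a taxon is sampled in an interior bin of
#'   its range (first and last bins are always sampled).
#' @param n_rodent_genera Number of rodent genera to scatter over the grid.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A `fossil_sim` list: `occurrences` (one row per taxon-by-locality
#'   record), `taxa` (taxon ranges with true and estimated masses), `truth`
#'   (per-bin extrema and glires sampling counts implied by the generated
#'   taxa), and `grid`.
#' @export
simulate_fossil_record <- function(trajectories, grid,
                                   n_localities = 8, age_halfwidth = 0.5,
                                   mass_se = 0.05, n_background = 8,
                                   sampling_prob = 0.85,
                                   n_rodent_genera = 12, seed = NULL) {
  if (is.null(trajectories) || nrow(trajectories) == 0) {
    stop_invalid("`trajectories` is empty.")
  }
  if (age_halfwidth < 0) stop_invalid("`age_halfwidth` must be >= 0.")
  if (mass_se < 0) stop_invalid("`mass_se` must be >= 0.")
  stopifnot(inherits(grid, "bin_grid"))
  clades <- unique(trajectories$clade)

  with_seed(seed, {
    taxa <- dplyr::bind_rows(
      traj_to_taxa(trajectories, "lagomorph", "Lago"),
      traj_to_taxa(trajectories, "artiodactyl", "Artio"),
      traj_to_taxa(trajectories, "perissodactyl", "Periss")
    )

    # Background taxa: bounded by the clade extremum over their whole range.
    bg <- purrr::map(clades, function(cl) {
      tr <- trajectories |> dplyr::filter(.data$clade == cl)
      if (n_background == 0) return(NULL)
      purrr::map(seq_len(n_background), function(i) {
        fb <- sample(tr$bin, 1)
        lb <- min(fb + sample(0:2, 1), max(tr$bin))
        vals <- tr$value_log10[tr$bin >= fb & tr$bin <= lb]
        # Close to the extremum: real assemblages carry several species near
        # the guild boundary, so a resampled bin never collapses far.
        margin <- runif(1, 0.05, 0.5)
        m <- if (cl == "lagomorph") min(vals) - margin else max(vals) + margin
        tibble::tibble(
          taxon = sprintf("%s_bg%02d", substr(cl, 1, 5), i), clade = cl,
          first_bin = fb, last_bin = lb, true_mass_log10 = m,
          role = "background"
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()

    all_bins <- sort(unique(trajectories$bin))
    rodents <- purrr::map(seq_len(n_rodent_genera), function(i) {
      fb <- sample(all_bins, 1)
      lb <- min(fb + sample(0:5, 1), max(all_bins))
      tibble::tibble(
        taxon = sprintf("Rodent_g%02d", i), clade = "rodent",
        first_bin = fb, last_bin = lb,
        true_mass_log10 = runif(1, -2, 0), role = "background"
      )
    }) |> dplyr::bind_rows()

    taxa <- dplyr::bind_rows(taxa, bg, rodents) |>
      dplyr::mutate(
        genus = .data$taxon,
        est_mass_log10 = .data$true_mass_log10 + rnorm(dplyr::n(), 0, mass_se),
        se_log10 = mass_se
      )

    # Localities per bin: true age uniform in the bin, bounds +/- h.
    upper <- grid$start - all_bins * grid$width          # older edge
    lower <- grid$start - (all_bins + 1) * grid$width    # younger edge
    localities <- purrr::map(seq_along(all_bins), function(i) {
      b <- all_bins[i]
      h <- runif(n_localities, 0, age_halfwidth)
      a <- runif(n_localities, lower[i] + 1e-9, upper[i] - 1e-9)
      h <- pmin(h, a)  # keep age_min >= 0
      tibble::tibble(
        bin = b,
        locality_id = sprintf("L%02d_%02d", b, seq_len(n_localities)),
        true_age = a, age_max = a + h, age_min = a - h
      )
    }) |> dplyr::bind_rows()

    occ <- purrr::pmap(taxa, function(taxon, clade, first_bin, last_bin,
                                      genus, est_mass_log10, se_log10,
                                      role, ...) {
      bins <- first_bin:last_bin
      take <- rep(TRUE, length(bins))
      # Extremum-defining taxa are well-sampled throughout their range;
      # background taxa can have range-through gaps.
      if (role != "extremal" && length(bins) > 2) {
        mid <- seq(2, length(bins) - 1)
        take[mid] <- runif(length(mid)) < sampling_prob
      }
      purrr::map(bins[take], function(b) {
        locs <- localities[localities$bin == b, ]
        k <- if (role == "extremal") {
          min(2, nrow(locs))
        } else {
          sample(seq_len(min(2, nrow(locs))), 1)
        }
        locs[sample(nrow(locs), k), ] |>
          dplyr::transmute(
            taxon = taxon, genus = genus, clade = clade,
            locality_id = .data$locality_id,
            age_max = .data$age_max, age_min = .data$age_min,
            mass_log10 = est_mass_log10, mass_se_log10 = se_log10,
            true_bin = .data$bin
          )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()

    # Ground truth per bin from taxon ranges (independent bookkeeping).
    truth <- purrr::map(all_bins, function(b) {
      inbin <- taxa[taxa$first_bin <= b & taxa$last_bin >= b, ]
      ext <- function(cl, f) {
        v <- inbin$true_mass_log10[inbin$clade == cl]
        if (length(v) == 0) NA_real_ else f(v)
      }
      glires <- taxa$clade %in% c("rodent", "lagomorph")
      rt <- taxa$genus[glires & taxa$first_bin <= b & taxa$last_bin >= b]
      sampled <- unique(occ$genus[occ$clade %in% c("rodent", "lagomorph") &
                                    occ$true_bin == b])
      k <- sum(unique(rt) %in% sampled)
      n <- length(unique(rt))
      tibble::tibble(
        bin = b,
        m_maxlag = ext("lagomorph", max),
        m_minart = ext("artiodactyl", min),
        m_minper = ext("perissodactyl", min),
        glires_n = n, glires_k = k,
        r_glires = if (n == 0) NA_real_ else log((k + 0.5) / (n - k + 0.5))
      )
    }) |> dplyr::bind_rows()

    structure(
      list(
        occurrences = dplyr::select(occ, -"true_bin"),
        taxa = taxa,
        localities = localities,
        truth = truth,
        grid = grid
      ),
      class = "fossil_sim"
    )
  })
}

#' Mass-estimate table of a simulated fossil record
#'
#' @param sim A `fossil_sim`.
#' @return Tibble `taxon`, `clade`, `genus`, `mean_log10`, `se_log10` as
#'   consumed by [bin_extrema()].
#' @export
sim_mass_estimates <- function(sim) {
  stopifnot(inherits(sim, "fossil_sim"))
  sim$taxa |>
    dplyr::transmute(
      taxon = .data$taxon, clade = .data$clade, genus = .data$genus,
      mean_log10 = .data$est_mass_log10, se_log10 = .data$se_log10
    )
}

#' Study-condition scenario for the fossil pipeline
#'
#' Builds trajectories in which the maximum lagomorph body mass tracks the
#' competitive ceiling: the minimum perissodactyl mass rises roughly
#' eightfold over the window (so its energy-equivalent lagomorph mass is a
#' compressed, affine transform of it), while the minimum artiodactyl mass
#' follows an independent dip-and-rise path that takes over as the ceiling in
#' the middle regime. Benthic d18O and ungulate hypsodonty proxy series are
#' generated as smooth random walks uncorrelated with the response.
#'
#' @param grid A [bin_grid()].
#' @param line_lag,line_ung Energy-use lines (defaults from [sim_config()]
#'   components, crossing near 6.3 kg).
#' @param effect Regression coefficient of `m_maxlag` on the ceiling.
#' @param noise_sd SD of the per-bin deviation of `m_maxlag` from the
#'   ceiling-driven expectation (log10 units).
#' @param regimes Regime table (see [default_regimes()]).
#' @param seed Integer seed.
#' @return List: `trajectories`, `truth_ceiling` (per-bin true ceiling),
#'   `d18o`, `h_ung`, `line_lag`, `line_ung`.
#' @export
ceiling_scenario <- function(grid,
                             line_lag = energy_line(2.8, -1.2, guild = "lagomorph"),
                             line_ung = energy_line(2.2, -0.45, guild = "ungulate"),
                             effect = 1.0, noise_sd = 0.03,
                             regimes = default_regimes(), seed = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  with_seed(seed, {
    bins <- seq_len(grid$n_bins) - 1L
    nb <- length(bins)
    mid <- grid$midpoints
    # Minimum perissodactyl: ~8-fold rise over the window, with wiggles.
    minper <- seq(1.15, 2.05, length.out = nb) +
      cumsum(rnorm(nb, 0, 0.02))
    eq <- energy_equivalent_mass(line_lag, line_ung, 10^minper)$log10_m_eq
    regime <- assign_regime(mid, regimes)
    art_regime <- !is.na(regime) & regime == "artiodactyl_minimum"
    # Minimum artiodactyl: sits above the perissodactyl-equivalent line
    # except in the middle regime, where it dips below and becomes the
    # binding ceiling. Wiggles are stationary (smoothed white noise), so
    # the regime geometry cannot drift away.
    wig <- stats::filter(rnorm(nb, 0, 1), rep(1 / 3, 3), sides = 2)
    wig[is.na(wig)] <- 0
    minart <- eq + ifelse(art_regime, -0.25, 0.3) +
      as.numeric(wig) * ifelse(art_regime, 0.08, 0.03)
    ceiling <- ifelse(art_regime, minart, eq)
    maxlag <- -0.15 + effect * ceiling + rnorm(nb, 0, noise_sd)
    # Lagomorphs stay strictly below the artiodactyl minimum.
    maxlag <- pmin(maxlag, minart - 0.05)
    trajectories <- dplyr::bind_rows(
      tibble::tibble(bin = bins, clade = "lagomorph", value_log10 = maxlag),
      tibble::tibble(bin = bins, clade = "artiodactyl", value_log10 = minart),
      tibble::tibble(bin = bins, clade = "perissodactyl", value_log10 = minper)
    )
    # Proxies are null predictors here: stationary smoothed noise, so they
    # do not chance-track the trending response the way a random walk would.
    smooth_noise <- function(n, sd) {
      z <- stats::filter(rnorm(n, 0, 1), rep(1 / 3, 3), sides = 2)
      z[is.na(z)] <- 0
      as.numeric(z) * sd
    }
    ages_d18o <- seq(grid$start, grid$start - grid$n_bins * grid$width + 0.1,
                     by = -0.25)
    d18o <- tibble::tibble(
      age = ages_d18o,
      value = 2 + smooth_noise(length(ages_d18o), 0.3)
    )
    h_ung <- tibble::tibble(
      age = mid,
      value = 1.5 + smooth_noise(nb, 0.2)
    )
    list(trajectories = trajectories,
         truth_ceiling = tibble::tibble(bin = bins, m_ceiling = ceiling),
         d18o = d18o, h_ung = h_ung,
         line_lag = line_lag, line_ung = line_ung)
  })
}

#' Rectangular-grid ecoregion adjacency
#'
#' @param n Number of ecoregions.
#' @param ids Optional ids (defaults `ER001..`).
#' @return Tibble `from`, `to` (each undirected edge listed once).
#' @export
grid_adjacency <- function(n, ids = sprintf("ER%03d", seq_len(n))) {
  ncol <- max(1, floor(sqrt(n)))
  row <- (seq_len(n) - 1) %/% ncol
  col <- (seq_len(n) - 1) %% ncol
  edges <- list()
  for (i in seq_len(n)) {
    right <- which(row == row[i] & col == col[i] + 1)
    down <- which(row == row[i] + 1 & col == col[i])
    for (j in c(right, down)) {
      edges[[length(edges) + 1]] <- c(i, j)
    }
  }
  em <- do.call(rbind, edges)
  tibble::tibble(from = ids[em[, 1]], to = ids[em[, 2]])
}

#' Simulate an ecoregion table with spatial structure
#'
#' Generates per-ecoregion guild extrema and environmental covariates, with
#' the response `log10_m_maxlag` built as a user-specified function of the
#' table (typically of `log10_m_minuth` and climate covariates) plus
#' spatially autocorrelated noise (neighbour-smoothed) and iid noise.
#'
#' @param n_ecoregions Number of ecoregions.
#' @param adjacency Edge tibble `from`, `to`; default [grid_adjacency()].
#'   Dangling ids are an error.
#' @param effect Function of the covariate table returning the expected
#'   `log10_m_maxlag`.
#' @param noise_sd SD of iid noise (log10 units).
#' @param spatial_sd SD of the spatially autocorrelated noise component.
#' @param seed Integer seed.
#' @return An `ecoregion_sim` list: `table` (one row per ecoregion),
#'   `adjacency`.
#' @export
simulate_ecoregion_table <- function(n_ecoregions, adjacency = NULL,
                                     effect = function(d) 0.2 + 0.45 * d$log10_m_minuth,
                                     noise_sd = 0.05, spatial_sd = 0,
                                     seed = NULL) {
  ids <- sprintf("ER%03d", seq_len(n_ecoregions))
  if (is.null(adjacency)) adjacency <- grid_adjacency(n_ecoregions, ids)
  bad <- setdiff(c(adjacency$from, adjacency$to), ids)
  if (length(bad) > 0) {
    stop_invalid(sprintf("Adjacency references unknown ecoregion id(s): %s.",
                         paste(head(bad, 5), collapse = ", ")))
  }
  with_seed(seed, {
    tab <- tibble::tibble(
      ecoregion_id = ids,
      realm = sample(c("Nearctic", "Neotropic", "Palearctic", "Afrotropic",
                       "Indo-Malay"), n_ecoregions, replace = TRUE),
      log10_m_minuth = runif(n_ecoregions, 0, 2.3),
      temperature = rnorm(n_ecoregions, 15, 8),
      precipitation = exp(rnorm(n_ecoregions, 6.5, 0.7)),
      precip_var = exp(rnorm(n_ecoregions, 3, 0.8)),
      soil_nutrient = sample(1:5, n_ecoregions, replace = TRUE),
      tree_cover = runif(n_ecoregions, 0, 100),
      elevation = exp(rnorm(n_ecoregions, 6, 1)),
      introduced = as.integer(runif(n_ecoregions) < 0.1)
    )
    s <- rnorm(n_ecoregions, 0, spatial_sd)
    if (spatial_sd > 0) {
      nb <- neighbor_index(ids, adjacency)
      for (it in 1:2) {
        nbm <- vapply(seq_len(n_ecoregions), function(i) {
          if (length(nb[[i]]) == 0) 0 else mean(s[nb[[i]]])
        }, numeric(1))
        s <- 0.5 * s + 0.5 * nbm
      }
      s <- s * spatial_sd / max(sd(s), 1e-12)
    }
    tab$log10_m_maxlag <- effect(tab) + s + rnorm(n_ecoregions, 0, noise_sd)
    tab$m_minuth <- 10^tab$log10_m_minuth
    tab$m_maxlag <- 10^tab$log10_m_maxlag
    structure(list(table = tab, adjacency = adjacency),
              class = "ecoregion_sim")
  })
}

# Neighbour lookup: list of integer indices per id (undirected).
neighbor_index <- function(ids, adjacency) {
  nb <- vector("list", length(ids))
  names(nb) <- ids
  fi <- match(adjacency$from, ids)
  ti <- match(adjacency$to, ids)
  for (e in seq_along(fi)) {
    nb[[fi[e]]] <- c(nb[[fi[e]]], ti[e])
    nb[[ti[e]]] <- c(nb[[ti[e]]], fi[e])
  }
  lapply(nb, unique)
}
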