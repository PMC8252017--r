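#' Time-bin grid for the fossil record
#'
#' Contiguous bins of equal width counting down from an oldest boundary
#' (default: 1.5-Myr bins starting at 43.5 Ma, covering to the present with
#' 29 bins). Bin indices are 0-based, oldest first; bin `k` spans ages
#' `[start - (k+1)*width, start - k*width]` with boundary ages assigned to
#' the older bin (see [assign_bin()]).
#'
#' @param start Oldest bin boundary, Ma.
#' @param width Bin width, Myr.
#' @param n_bins Number of bins.
#' @return A `bin_grid` list with `start`, `width`, `n_bins`, `midpoints`.
#' @export
bin_grid <- function(start = 43.5, width = 1.5, n_bins = 29) {
  if (width <= 0) stop_invalid("`width` must be positive.")
  if (n_bins < 1) stop_invalid("`n_bins` must be at least 1.")
  if (start - n_bins * width < -1e-9) {
    stop_invalid("Grid extends below 0 Ma; reduce `n_bins` or `width`.")
  }
  structure(
    list(start = start, width = width, n_bins = as.integer(n_bins),
         midpoints = start - (seq_len(n_bins) - 0.5) * width),
    class = "bin_grid"
  )
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("Time grid: %d bins of %.2f Myr from %.2f Ma to %.2f Ma\n",
              x$n_bins, x$width, x$start, x$start - x$n_bins * x$width))
  invisible(x)
}

#' Assign ages to time bins
#'
#' Bin `k` (0-based, oldest first) receives ages in
#' `[start - (k+1)*width, start - k*width)`, with the oldest boundary age
#' (`start`) mapped to bin 0 and internal boundary ages assigned to the
#' older of their two adjoining bins.
#'
#' @param age Numeric ages, Ma.
#' @param grid A [bin_grid()].
#' @return Integer bin indices (0-based).
#' @export
#' @examples
#' g <- bin_grid(43.5, 1.5, 29)
#' assign_bin(c(43.5, 42.0, 2.0), g) # 0, 0, 27
assign_bin <- function(age, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  if (any(is.na(age))) stop_invalid("`age` contains missing values.")
  if (any(age < -1e-9)) stop_invalid("`age` must be non-negative.")
  if (any(age > grid$start + 1e-9)) {
    abort(sprintf("Age(s) older than the grid start (%.2f Ma).", grid$start),
          class = "lagoceiling_out_of_range")
  }
  k <- pmax(0L, as.integer(ceiling((grid$start - age) / grid$width - 1e-9) - 1))
  if (any(k >= grid$n_bins)) {
    abort("Age(s) younger than the grid's youngest bin.",
          class = "lagoceiling_out_of_range")
  }
  k
}

#' Filter occurrence records by locality age uncertainty
#'
#' Drops records whose locality age range exceeds `max_uncertainty` Myr
#' (default 4.2, the duration of the longest North American Land Mammal Age
#' subage). The bound is strict: a range of exactly 4.2 Myr is kept.
#'
#' @param occurrences Occurrence tibble with `age_max`, `age_min`.
#' @param max_uncertainty Maximum allowed `age_max - age_min`, Myr.
#' @return Filtered tibble.
#' @export
filter_localities <- function(occurrences, max_uncertainty = 4.2) {
  if (max_uncertainty < 0) stop_invalid("`max_uncertainty` must be >= 0.")
  dplyr::filter(occurrences,
                .data$age_max - .data$age_min <= max_uncertainty + 1e-12)
}

#' Range-through bin occupancy of one taxon
#'
#' A taxon is assumed present in every bin between its oldest and youngest
#' occurrence bins, inclusive.
#'
#' @param bins Integer bin indices of the taxon's occurrences (>= 1 value).
#' @return Sorted integer vector of occupied bins.
#' @export
range_through <- function(bins) {
  if (length(bins) == 0) stop_invalid("Taxon has no occurrences.")
  seq(min(bins), max(bins))
}

#' Per-taxon presence table from binned occurrences
#'
#' Bins each occurrence by a single locality age (locality midpoint by
#' default, or externally sampled ages for pseudo-replicates) and expands
#' each taxon to its range-through bin interval. Records whose age falls
#' outside the grid are dropped with a warning.
#'
#' @param occurrences Occurrence tibble (`taxon`, `genus`, `clade`,
#'   `locality_id`, `age_max`, `age_min`).
#' @param grid A [bin_grid()].
#' @param ages Optional named vector of locality ages (Ma) overriding the
#'   midpoint rule, e.g. one uniform draw per locality.
#' @return Tibble `taxon`, `genus`, `clade`, `bin`, `sampled` (`TRUE` where
#'   the taxon has an in-bin occurrence, `FALSE` for interpolated
#'   range-through presence).
#' @export
build_presence <- function(occurrences, grid, ages = NULL) {
  stopifnot(inherits(grid, "bin_grid"))
  occ <- occurrences
  occ$age <- if (is.null(ages)) {
    (occ$age_max + occ$age_min) / 2
  } else {
    unname(ages[occ$locality_id])
  }
  if (anyNA(occ$age)) stop_invalid("Missing locality age(s).")
  inside <- occ$age <= grid$start + 1e-9 &
    occ$age >= grid$start - grid$n_bins * grid$width - 1e-9 &
    occ$age >= 0
  if (!all(inside)) {
    warn(sprintf("Dropping %d occurrence(s) dated outside the grid.",
                 sum(!inside)))
    occ <- occ[inside, , drop = FALSE]
  }
  occ$age <- pmax(occ$age, 0)
  if (nrow(occ) == 0) {
    return(tibble::tibble(taxon = character(), genus = character(),
                          clade = character(), bin = integer(),
                          sampled = logical()))
  }
  occ$bin <- assign_bin(occ$age, grid)
  occ |>
    dplyr::group_by(.data$taxon, .data$genus, .data$clade) |>
    dplyr::reframe({
      occ_bins <- unique(.data$bin)
      rt <- range_through(occ_bins)
      tibble::tibble(bin = rt, sampled = rt %in% occ_bins)
    }) |>
    dplyr::ungroup()
}

#' Per-bin guild extrema from presence and mass estimates
#'
#' For every bin: the maximum lagomorph and the minimum artiodactyl and
#' perissodactyl log10 body mass over taxa present (range-through) in that
#' bin. Bins where a clade is absent get `NA`.
#'
#' @param presence Output of [build_presence()].
#' @param mass_estimates Tibble `taxon`, `mean_log10` (log10 kg point
#'   estimates; e.g. [sim_mass_estimates()] or [estimate_fossil_mass()]
#'   output).
#' @param grid A [bin_grid()].
#' @return Tibble with one row per bin: `bin`, `m_maxlag`, `m_minart`,
#'   `m_minper`.
#' @export
bin_extrema <- function(presence, mass_estimates, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  dat <- dplyr::inner_join(presence,
                           dplyr::select(mass_estimates, "taxon", "mean_log10"),
                           by = "taxon")
  ext <- function(cl, f) {
    sub <- dplyr::filter(dat, .data$clade == cl, !is.na(.data$mean_log10))
    if (nrow(sub) == 0) {
      return(tibble::tibble(bin = integer(), v = numeric()))
    }
    sub |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(v = f(.data$mean_log10), .groups = "drop")
  }
  out <- tibble::tibble(bin = seq_len(grid$n_bins) - 1L)
  out |>
    dplyr::left_join(dplyr::rename(ext("lagomorph", max), m_maxlag = "v"),
                     by = "bin") |>
    dplyr::left_join(dplyr::rename(ext("artiodactyl", min), m_minart = "v"),
                     by = "bin") |>
    dplyr::left_join(dplyr::rename(ext("perissodactyl", min), m_minper = "v"),
                     by = "bin")
}

#' Glires range-through sampling probability per bin
#'
#' For each bin, `p = k / n` where `n` is the number of glires (rodent +
#' lagomorph) genera inferred present by range-through and `k` the number
#' actually sampled in the bin (`k <= n` by construction). Returned on the
#' empirical-logit scale `log((k + 0.5) / (n - k + 0.5))`, which stays finite
#' when every genus is sampled. Bins with `n = 0` get `NA`.
#'
#' @param presence Output of [build_presence()] (genus column used).
#' @param grid A [bin_grid()].
#' @return Tibble `bin`, `glires_n`, `glires_k`, `r_glires`.
#' @export
sampling_probability_glires <- function(presence, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  gl <- presence |>
    dplyr::filter(.data$clade %in% c("rodent", "lagomorph")) |>
    dplyr::group_by(.data$genus, .data$bin) |>
    dplyr::summarise(sampled = any(.data$sampled), .groups = "drop")
  counts <- gl |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(glires_n = dplyr::n_distinct(.data$genus),
                     glires_k = sum(.data$sampled), .groups = "drop")
  tibble::tibble(bin = seq_len(grid$n_bins) - 1L) |>
    dplyr::left_join(counts, by = "bin") |>
    dplyr::mutate(
      glires_n = dplyr::coalesce(.data$glires_n, 0L),
      glires_k = dplyr::coalesce(.data$glires_k, 0L),
      r_glires = dplyr::if_else(
        .data$glires_n == 0, NA_real_,
        log((.data$glires_k + 0.5) / (.data$glires_n - .data$glires_k + 0.5))
      )
    )
}

#' Align proxy series to the time grid
#'
#' Benthic d18O records are averaged within each bin (boundary ages follow
#' the [assign_bin()] rule); interval hypsodonty means are linearly
#' interpolated to bin midpoints, with no extrapolation beyond the series
#' range.
#'
#' @param d18o Tibble `age`, `value` of d18O records.
#' @param h_ung Tibble `age`, `value` of interval-mean hypsodonty indices
#'   (ages at interval midpoints).
#' @param grid A [bin_grid()].
#' @return Tibble `bin`, `d18o`, `h_ung` (NA where unavailable).
#' @export
align_proxies <- function(d18o, h_ung, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  out <- tibble::tibble(bin = seq_len(grid$n_bins) - 1L)
  if (!is.null(d18o) && nrow(d18o) > 0) {
    keep <- d18o$age <= grid$start + 1e-9 & d18o$age >= 0 &
      d18o$age >= grid$start - grid$n_bins * grid$width - 1e-9
    dd <- d18o[keep, , drop = FALSE]
    if (nrow(dd) > 0) {
      dd$bin <- assign_bin(dd$age, grid)
      out <- dplyr::left_join(
        out,
        dd |> dplyr::group_by(.data$bin) |>
          dplyr::summarise(d18o = mean(.data$value), .groups = "drop"),
        by = "bin"
      )
    }
  }
  if (!"d18o" %in% names(out)) out$d18o <- NA_real_
  if (!is.null(h_ung) && nrow(h_ung) >= 2) {
    ip <- approx(h_ung$age, h_ung$value, xout = grid$midpoints, rule = 1,
                 ties = mean)
    out$h_ung <- ip$y
  } else if (!is.null(h_ung) && nrow(h_ung) == 1) {
    out$h_ung <- ifelse(abs(grid$midpoints - h_ung$age) < 1e-9,
                        h_ung$value, NA_real_)
  } else {
    out$h_ung <- NA_real_
  }
  out
}

#' Competitive-ceiling regime windows
#'
#' The default regimes: the ceiling is the energy-equivalent lagomorph mass
#' for the contemporary minimum perissodactyl during 37.5-24.0 and
#' 15.0-1.5 Ma, and the minimum artiodactyl mass during 24.0-15.0 Ma.
#'
#' @return Tibble `older`, `younger` (Ma), `source`.
#' @export
default_regimes <- function() {
  tibble::tibble(
    older = c(37.5, 24.0, 15.0),
    younger = c(24.0, 15.0, 1.5),
    source = c("perissodactyl_equivalent", "artiodactyl_minimum",
               "perissodactyl_equivalent")
  )
}

# Regime lookup at bin midpoints; regimes are half-open (younger, older],
# so a bin whose midpoint sits on a shared boundary joins the older regime.
assign_regime <- function(midpoints, regimes) {
  vapply(midpoints, function(m) {
    hit <- which(m > regimes$younger - 1e-9 & m <= regimes$older + 1e-9)
    if (length(hit) == 0) NA_character_ else regimes$source[hit[1]]
  }, character(1))
}

#' Competitive-ceiling body mass per bin
#'
#' In perissodactyl regimes the ceiling is the energy-equivalent lagomorph
#' body mass for the bin's minimum perissodactyl mass; in artiodactyl
#' regimes it is the minimum artiodactyl mass directly. Bins outside all
#' regimes, or lacking the regime's source value, get `NA`.
#'
#' @param extrema Output of [bin_extrema()].
#' @param line_lag,line_ung [energy_line()] objects.
#' @param grid A [bin_grid()].
#' @param regimes Regime table (see [default_regimes()]).
#' @return `extrema` with an added `m_ceiling` column (log10 kg).
#' @export
build_ceiling <- function(extrema, line_lag, line_ung, grid,
                          regimes = default_regimes()) {
  stopifnot(inherits(grid, "bin_grid"))
  if (any(regimes$older <= regimes$younger)) {
    stop_invalid("Each regime needs `older` > `younger`.")
  }
  regime <- assign_regime(grid$midpoints[extrema$bin + 1L], regimes)
  eq <- rep(NA_real_, nrow(extrema))
  has_per <- !is.na(extrema$m_minper)
  if (any(has_per)) {
    eq[has_per] <- energy_equivalent_mass(
      line_lag, line_ung, 10^extrema$m_minper[has_per]
    )$log10_m_eq
  }
  extrema$m_ceiling <- dplyr::case_when(
    is.na(regime) ~ NA_real_,
    regime == "perissodactyl_equivalent" ~ eq,
    regime == "artiodactyl_minimum" ~ extrema$m_minart
  )
  extrema
}

#' Build the full per-bin predictor series
#'
#' One-stop composition of the time-series stage: filters records by
#' locality-age uncertainty, bins them (locality midpoint ages by default,
#' or supplied sampled ages), reconstructs range-through presence, computes
#' guild extrema, glires sampling probability, aligned proxies, and the
#' competitive-ceiling predictor.
#'
#' @param occurrences Occurrence tibble.
#' @param mass_estimates Tibble `taxon`, `mean_log10`.
#' @param line_lag,line_ung [energy_line()] objects.
#' @param d18o,h_ung Proxy series tibbles (`age`, `value`), or `NULL`.
#' @param grid A [bin_grid()].
#' @param regimes Regime table.
#' @param ages Optional named locality-age vector (see [build_presence()]).
#' @param max_uncertainty Locality age-uncertainty filter, Myr.
#' @return Tibble with one row per bin: `bin`, `midpoint`, `m_maxlag`,
#'   `m_minart`, `m_minper`, `m_ceiling`, `d18o`, `h_ung`, `r_glires`.
#' @export
build_series <- function(occurrences, mass_estimates, line_lag, line_ung,
                         d18o = NULL, h_ung = NULL, grid = bin_grid(),
                         regimes = default_regimes(), ages = NULL,
                         max_uncertainty = 4.2) {
  occ <- filter_localities(occurrences, max_uncertainty)
  pres <- build_presence(occ, grid, ages = ages)
  ext <- bin_extrema(pres, mass_estimates, grid)
  ext <- build_ceiling(ext, line_lag, line_ung, grid, regimes)
  gl <- sampling_probability_glires(pres, grid)
  px <- align_proxies(d18o, h_ung, grid)
  ext |>
    dplyr::left_join(dplyr::select(gl, "bin", "r_glires"), by = "bin") |>
    dplyr::left_join(px, by = "bin") |>
    dplyr::mutate(midpoint = grid$midpoints[.data$bin + 1L],
                  .after = "bin")
}

#' Plot per-bin guild extrema and the ceiling
#'
#' @param series Output of [build_series()].
#' @return A ggplot (age increasing to the left, as in deep-time convention).
#' @export
plot_series <- function(series) {
  long <- series |>
    dplyr::select("midpoint", "m_maxlag", "m_minart", "m_minper",
                  "m_ceiling") |>
    tidyr::pivot_longer(-"midpoint", names_to = "series",
                        values_to = "log10_mass") |>
    dplyr::filter(!is.na(.data$log10_mass))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$midpoint,
                                     y = .data$log10_mass,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Age (Ma)", y = "log10 body mass (kg)")
}
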