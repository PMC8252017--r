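#' Read a Newick tree with validation
#'
#' Thin, validating wrapper around [ape::read.tree()]: accepts a file path or
#' a literal Newick string, and rejects trees with duplicated tip labels or
#' missing branch lengths (both break the phylogenetic covariance
#' construction downstream).
#'
#' @param x Path to a Newick file, or a Newick string (contains `"("`).
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(x) {
  tr <- if (grepl("\\(", x)) {
    tryCatch(ape::read.tree(text = x), error = function(e) NULL)
  } else {
    if (!file.exists(x)) stop_invalid(sprintf("File not found: %s", x))
    tryCatch(ape::read.tree(x), error = function(e) NULL)
  }
  if (is.null(tr) || !inherits(tr, "phylo")) {
    abort("Failed to parse Newick input (check parenthesis balance and ';' terminator).",
          class = "lagoceiling_parse_error")
  }
  if (is.null(tr$edge.length)) {
    abort("Newick tree has no branch lengths.", class = "lagoceiling_parse_error")
  }
  if (anyNA(tr$edge.length)) {
    abort(sprintf("Branch length missing near edge %d.",
                  which(is.na(tr$edge.length))[1]),
          class = "lagoceiling_parse_error")
  }
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicated tip label(s): %s.", paste(unique(dup), collapse = ", ")),
          class = "lagoceiling_parse_error")
  }
  tr
}

#' Write a tree as Newick
#'
#' @param tree [ape::phylo].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Column mapping for occurrence files
#'
#' Maps the package's canonical occurrence fields to the column names used in
#' a particular CSV export (e.g. a Paleobiology Database download uses
#' different headers than a MIOMAP one).
#'
#' @param taxon,genus,clade,locality_id,age_max,age_min,mass_log10,mass_se_log10
#'   Column names in the file for each canonical field. `mass_log10` and
#'   `mass_se_log10` may be `NULL` if absent.
#' @return A named list used by [read_occurrences()].
#' @export
occurrence_schema <- function(taxon = "taxon", genus = "genus",
                              clade = "clade", locality_id = "locality_id",
                              age_max = "age_max", age_min = "age_min",
                              mass_log10 = "mass_log10",
                              mass_se_log10 = "mass_se_log10") {
  list(taxon = taxon, genus = genus, clade = clade, locality_id = locality_id,
       age_max = age_max, age_min = age_min, mass_log10 = mass_log10,
       mass_se_log10 = mass_se_log10)
}

occ_clades <- c("lagomorph", "artiodactyl", "perissodactyl", "rodent")

#' Read fossil occurrence records
#'
#' Reads a CSV of taxon occurrences (one row per taxon-by-locality record)
#' and validates every row: ages must satisfy `age_max >= age_min >= 0`, the
#' clade must be one of lagomorph / artiodactyl / perissodactyl / rodent, and
#' mass standard errors must be non-negative. Invalid rows are dropped with a
#' row-numbered warning rather than silently coerced.
#'
#' @param path CSV path (UTF-8, comma-separated, header row).
#' @param schema An [occurrence_schema()] mapping canonical fields to the
#'   file's column names.
#' @return Tibble of validated occurrence records with canonical column
#'   names. Ages are Ma before present (larger = older); masses log10 kg.
#' @export
read_occurrences <- function(path, schema = occurrence_schema()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) {
    warn(sprintf("Occurrence file '%s' is empty.", path))
    return(tibble::tibble(
      taxon = character(), genus = character(), clade = character(),
      locality_id = character(), age_max = numeric(), age_min = numeric(),
      mass_log10 = numeric(), mass_se_log10 = numeric()
    ))
  }
  required <- c("taxon", "genus", "clade", "locality_id", "age_max", "age_min")
  for (f in required) {
    if (!schema[[f]] %in% names(raw)) {
      stop_invalid(sprintf("Required column '%s' (field %s) missing from %s.",
                           schema[[f]], f, path))
    }
  }
  out <- tibble::tibble(
    taxon = as.character(raw[[schema$taxon]]),
    genus = as.character(raw[[schema$genus]]),
    clade = as.character(raw[[schema$clade]]),
    locality_id = as.character(raw[[schema$locality_id]]),
    age_max = as.numeric(raw[[schema$age_max]]),
    age_min = as.numeric(raw[[schema$age_min]]),
    mass_log10 = if (!is.null(schema$mass_log10) &&
                     schema$mass_log10 %in% names(raw)) {
      as.numeric(raw[[schema$mass_log10]])
    } else {
      NA_real_
    },
    mass_se_log10 = if (!is.null(schema$mass_se_log10) &&
                        schema$mass_se_log10 %in% names(raw)) {
      as.numeric(raw[[schema$mass_se_log10]])
    } else {
      NA_real_
    }
  )
  bad <- is.na(out$age_max) | is.na(out$age_min) |
    out$age_min < 0 | out$age_max < out$age_min |
    !(out$clade %in% occ_clades) |
    (!is.na(out$mass_se_log10) & out$mass_se_log10 < 0)
  if (any(bad)) {
    warn(sprintf("Rejected %d invalid occurrence row(s): %s",
                 sum(bad),
                 paste(head(which(bad), 10), collapse = ", ")))
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Write occurrence records to CSV
#'
#' @param occurrences Tibble as returned by [read_occurrences()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occurrences, path) {
  readr::write_csv(occurrences, path, progress = FALSE)
  invisible(path)
}

#' Read a proxy series (age, value)
#'
#' For benthic d18O records and per-interval hypsodonty means: a two-column
#' numeric CSV of `(age Ma, value)`. Output is sorted by age descending
#' (oldest first), with ties kept in input order.
#'
#' @param path CSV path with two numeric columns (first = age Ma, second =
#'   value).
#' @return Tibble `age`, `value`, sorted oldest-first.
#' @export
read_series <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2) stop_invalid("Series file must have two columns (age, value).")
  age <- suppressWarnings(as.numeric(raw[[1]]))
  value <- suppressWarnings(as.numeric(raw[[2]]))
  if (anyNA(age) || anyNA(value)) {
    bad <- which(is.na(age) | is.na(value))
    stop_invalid(sprintf("Non-numeric cell(s) in series rows: %s.",
                         paste(head(bad, 10), collapse = ", ")))
  }
  tibble::tibble(age = age, value = value) |>
    dplyr::arrange(dplyr::desc(.data$age))
}

#' Read a species trait table
#'
#' Trait table for the scaling stage: species, body mass (kg) and optionally
#' population density (individuals per square km) and basal metabolic rate
#' (units as given by the source compilation; treated as an opaque positive
#' quantity that must be consistent within a run).
#'
#' @param path CSV with columns `species`, `mass`, optionally `density`,
#'   `bmr`.
#' @return Validated tibble; rows with non-positive mass/density/bmr are
#'   dropped with a warning.
#' @export
read_trait_table <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("species", "mass") %in% names(raw))) {
    stop_invalid("Trait table needs at least `species` and `mass` columns.")
  }
  out <- tibble::tibble(
    species = as.character(raw$species),
    mass = as.numeric(raw$mass),
    density = if ("density" %in% names(raw)) as.numeric(raw$density) else NA_real_,
    bmr = if ("bmr" %in% names(raw)) as.numeric(raw$bmr) else NA_real_
  )
  bad <- is.na(out$mass) | out$mass <= 0 |
    (!is.na(out$density) & out$density <= 0) |
    (!is.na(out$bmr) & out$bmr <= 0)
  if (any(bad)) {
    warn(sprintf("Rejected %d trait row(s) with non-positive values: %s",
                 sum(bad), paste(head(which(bad), 10), collapse = ", ")))
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Read / write a simulation configuration (YAML)
#'
#' @param path YAML path.
#' @return For the reader, a validated `sim_config` list.
#' @seealso [sim_config()]
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(sim_config, cfg)
}

#' @rdname read_sim_config
#' @param config A [sim_config()] list.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
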