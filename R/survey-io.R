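#' @keywords internal
"_PACKAGE"

## Core table contracts -------------------------------------------------------
##
## SurveyTable: one row per (region, site, transect, species[, year]) with
##   latitude in signed degrees and biomass in g/m^2. Transect is the sampling
##   unit; repeat-visit years are kept as distinct sampling units.
## TraitTable: one row per species with the five functional traits
##   (diet, habitat_association, body_size, aggregation, depth_range) plus
##   thermal_guild and an optional realised upper thermal limit.

.survey_required <- c("region", "site", "latitude", "transect", "species", "biomass")
.trait_required  <- c("species", "diet", "habitat_association", "body_size",
                      "aggregation", "depth_range", "thermal_guild")

#' Validate a transect-level survey table
#'
#' Checks the SurveyTable contract: required columns, non-negative finite
#' biomass, latitudes within +/-90 degrees, and uniqueness of the
#' (region, site, transect, species, year) key. Violations are reported with
#' the offending row numbers; nothing is silently coerced.
#'
#' @param survey data.frame with columns `region`, `site`, `latitude`,
#'   `transect`, `species`, `biomass` and optionally `year`.
#' @return The validated data.frame, invisibly usable downstream.
#' @export
validate_survey <- function(survey) {
  missing_cols <- setdiff(.survey_required, names(survey))
  if (length(missing_cols) > 0L)
    stop("survey table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!is.numeric(survey$biomass))
    stop("survey column 'biomass' must be numeric", call. = FALSE)
  if (!is.numeric(survey$latitude))
    stop("survey column 'latitude' must be numeric", call. = FALSE)
  bad <- which(!is.finite(survey$biomass) | survey$biomass < 0)
  if (length(bad) > 0L)
    stop("negative or non-finite biomass in survey row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  bad_lat <- which(abs(survey$latitude) > 90)
  if (length(bad_lat) > 0L)
    stop("latitude outside [-90, 90] in survey row(s): ",
         paste(utils::head(bad_lat, 10L), collapse = ", "), call. = FALSE)
  year <- if ("year" %in% names(survey)) survey$year else ""
  key <- paste(survey$region, survey$site, survey$transect, survey$species,
               year, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L)
    stop("duplicated (region, site, transect, species, year) key in survey row(s): ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  survey
}

#' Validate a species trait table
#'
#' Checks the TraitTable contract: unique species, thermal guild present for
#' every species and restricted to tropical/temperate, positive body sizes,
#' and positive (or missing) depth ranges.
#'
#' @param traits data.frame with one row per species.
#' @return The validated data.frame.
#' @export
validate_traits <- function(traits) {
  missing_cols <- setdiff(.trait_required, names(traits))
  if (length(missing_cols) > 0L)
    stop("trait table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dup <- which(duplicated(traits$species))
  if (length(dup) > 0L)
    stop("duplicated species in trait table row(s): ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  guild <- as.character(traits$thermal_guild)
  bad <- which(is.na(guild) | !guild %in% c("tropical", "temperate"))
  if (length(bad) > 0L)
    stop("thermal_guild must be 'tropical' or 'temperate' (never missing); ",
         "bad row(s): ", paste(utils::head(bad, 10L), collapse = ", "),
         call. = FALSE)
  bad_bs <- which(!is.na(traits$body_size) & traits$body_size <= 0)
  if (length(bad_bs) > 0L)
    stop("non-positive body_size in trait row(s): ",
         paste(utils::head(bad_bs, 10L), collapse = ", "), call. = FALSE)
  bad_dr <- which(!is.na(traits$depth_range) & traits$depth_range <= 0)
  if (length(bad_dr) > 0L)
    stop("non-positive depth_range in trait row(s): ",
         paste(utils::head(bad_dr, 10L), collapse = ", "), call. = FALSE)
  traits
}

#' Read a survey table from CSV
#'
#' UTF-8, comma-separated, header row, "." decimal; missing values are empty
#' fields. The table is validated on read.
#'
#' @param path file path.
#' @return A validated SurveyTable data.frame.
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path, call. = FALSE)
  validate_survey(utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE))
}

#' Read a species trait table from CSV
#' @param path file path.
#' @return A validated TraitTable data.frame.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("trait file not found: ", path, call. = FALSE)
  validate_traits(utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE))
}

#' Write a survey or trait table as CSV
#'
#' Missing values are written as empty fields so that a write/read round trip
#' reproduces the table.
#'
#' @param x data.frame.
#' @param path file path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Biomass from fish length
#'
#' Standard length-weight allometry `B = a * length^b` with species-specific
#' coefficients (e.g. from FishBase).
#'
#' @param length fish length in cm, > 0.
#' @param a coefficient, > 0.
#' @param b exponent, in (1, 4).
#' @return biomass in g.
#' @export
biomass_from_length <- function(length, a, b) {
  if (any(!is.finite(length)) || any(length <= 0))
    stop("length must be positive", call. = FALSE)
  if (any(a <= 0)) stop("length-weight coefficient a must be > 0", call. = FALSE)
  if (any(b <= 1) || any(b >= 4))
    stop("length-weight exponent b must lie in (1, 4)", call. = FALSE)
  a * length^b
}

#' Standardise counted fish to biomass per unit transect area
#'
#' Converts raw counts and lengths to species biomass per transect in g/m^2:
#' individual biomasses from the length-weight allometry are summed per
#' (region, site, transect, species) and divided by the transect area.
#'
#' @param obs data.frame of observations with columns `region`, `site`,
#'   `latitude`, `transect`, `species`, `count`, `length` (cm); `year` optional.
#' @param params data.frame of length-weight parameters with columns
#'   `species`, `a`, `b`.
#' @param transect_length,transect_width transect dimensions in m, > 0.
#' @return A validated SurveyTable (one row per transect x species, g/m^2).
#' @export
standardise_biomass <- function(obs, params, transect_length = 25,
                                transect_width = 5) {
  if (transect_length <= 0 || transect_width <= 0)
    stop("transect dimensions must be positive", call. = FALSE)
  unknown <- setdiff(unique(obs$species), params$species)
  if (length(unknown) > 0L)
    stop("no length-weight parameters for species: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  idx <- match(obs$species, params$species)
  g <- obs$count * biomass_from_length(obs$length, params$a[idx], params$b[idx])
  area <- transect_length * transect_width
  key <- data.frame(region = obs$region, site = obs$site,
                    latitude = obs$latitude, transect = obs$transect,
                    species = obs$species, stringsAsFactors = FALSE)
  if ("year" %in% names(obs)) key$year <- obs$year
  agg <- stats::aggregate(list(biomass = g), by = key, FUN = sum)
  agg$biomass <- agg$biomass / area
  validate_survey(agg[order(agg$site, agg$transect, agg$species), ,
                      drop = FALSE])
}

#' Table of transects in a survey
#'
#' One row per sampling unit (region, site, transect[, year]) with its latitude.
#' Used by downstream tabulations so that transects where a species group is
#' absent appear as explicit zero totals, never as missing rows.
#'
#' @param survey SurveyTable.
#' @return data.frame with columns region, site, latitude, transect, id.
#' @export
transect_table <- function(survey) {
  year <- if ("year" %in% names(survey)) survey$year else ""
  id <- paste(survey$region, survey$site, survey$transect, year, sep = "\r")
  keep <- !duplicated(id)
  out <- data.frame(region = survey$region[keep], site = survey$site[keep],
                    latitude = survey$latitude[keep],
                    transect = survey$transect[keep],
                    id = id[keep], stringsAsFactors = FALSE)
  out[order(out$region, out$site, out$transect), , drop = FALSE]
}

#' Sum guild/group biomass per transect
#'
#' @param survey SurveyTable.
#' @param species character vector of species to total (e.g. the tropical
#'   members of one functional group).
#' @return Named numeric vector over all transects of `survey` (zeros where
#'   none of `species` occur), names being transect ids of [transect_table()].
#' @export
transect_totals <- function(survey, species) {
  tt <- transect_table(survey)
  year <- if ("year" %in% names(survey)) survey$year else ""
  id <- paste(survey$region, survey$site, survey$transect, year, sep = "\r")
  sel <- survey$species %in% species
  tot <- stats::setNames(numeric(nrow(tt)), tt$id)
  if (any(sel)) {
    s <- tapply(survey$biomass[sel], id[sel], sum)
    tot[names(s)] <- s
  }
  tot
}
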