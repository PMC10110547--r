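## Latitudinal community zonation: log(1+x) biomass, Bray-Curtis distances,
## UPGMA, zones ordered by mean absolute site latitude with the lowest-latitude
## zone designated the reference (Tropical Coral Reef) zone.

#' Site-by-species matrix of log-transformed standardised biomass
#'
#' Cells hold `log(1 + mean transect biomass)` of each species at each site
#' (mean over all of the site's transects, absent species contributing zeros).
#'
#' @param survey SurveyTable (typically one region).
#' @return numeric matrix, sites x species, with a `latitude` attribute giving
#'   each site's latitude.
#' @export
site_species_matrix <- function(survey) {
  validate_survey(survey)
  tt <- transect_table(survey)
  n_tr <- table(tt$site)
  year <- if ("year" %in% names(survey)) survey$year else ""
  tot <- tapply(survey$biomass, list(survey$site, survey$species), sum,
                default = 0)
  m <- log1p(tot / as.numeric(n_tr[rownames(tot)]))
  lat <- tapply(tt$latitude, tt$site, function(x) x[1])
  attr(m, "latitude") <- as.numeric(lat[rownames(m)])
  m
}

#' Bray-Curtis dissimilarity between sites
#'
#' `d(x, y) = sum|x - y| / sum(x + y)`, in [0, 1]. Pairs of all-zero rows have
#' undefined distance; they receive a configurable sentinel (default 0) with a
#' warning rather than propagating NaN.
#'
#' @param m non-negative site-by-species matrix.
#' @param zero_sentinel distance assigned to pairs of empty rows.
#' @return `dist` object.
#' @export
bray_curtis <- function(m, zero_sentinel = 0) {
  if (any(m < 0)) stop("Bray-Curtis requires non-negative input", call. = FALSE)
  d <- suppressWarnings(vegan::vegdist(m, method = "bray"))
  if (anyNA(d)) {
    warning("all-zero row pair(s): Bray-Curtis undefined, using sentinel ",
            zero_sentinel, call. = FALSE)
    d[is.na(d)] <- zero_sentinel
  }
  d
}

#' Cluster sites into latitudinal transition zones
#'
#' Average-linkage (UPGMA) hierarchical clustering of the site dissimilarity
#' matrix, cut into `n_zones` groups. Zones are relabelled A, B, C, ... in
#' order of increasing mean absolute site latitude; the first (lowest-latitude)
#' zone is the reference zone.
#'
#' @param d `dist` of sites (e.g. from [bray_curtis()]).
#' @param n_zones number of zones, between 2 and the number of sites.
#' @param latitude site latitudes in the order of `d`'s labels.
#' @param representative how the representative latitude of a zone is derived
#'   from its member sites.
#' @return object of class `zone_partition`: list with `sites` (site -> zone
#'   label), `zone_order`, `reference_zone`, `zone_latitude`, `tree`.
#' @export
cluster_zones <- function(d, n_zones, latitude,
                          representative = c("mean", "min", "max")) {
  labels <- attr(d, "Labels")
  n <- attr(d, "Size")
  if (n_zones < 2 || n_zones > n)
    stop("n_zones must lie between 2 and the number of sites", call. = FALSE)
  if (length(latitude) != n)
    stop("latitude must match the number of sites", call. = FALSE)
  representative <- match.arg(representative)
  tree <- stats::hclust(d, method = "average")
  raw <- stats::cutree(tree, k = n_zones)
  mean_abs <- tapply(abs(latitude), raw, mean)
  ord <- order(mean_abs)
  relabel <- stats::setNames(LETTERS[seq_len(n_zones)], names(mean_abs)[ord])
  zones <- stats::setNames(as.character(relabel[as.character(raw)]), labels)
  stat <- switch(representative, mean = mean, min = min, max = max)
  zone_lat <- tapply(abs(latitude), zones, stat)
  out <- list(sites = zones,
              zone_order = LETTERS[seq_len(n_zones)],
              reference_zone = "A",
              zone_latitude = zone_lat[LETTERS[seq_len(n_zones)]],
              tree = tree)
  class(out) <- "zone_partition"
  out
}

#' Build a zone partition from known site-zone labels
#'
#' Wraps an externally supplied site -> zone map (e.g. the generator's ground
#' truth) in the same `zone_partition` structure as [cluster_zones()], with
#' zones re-ordered by mean absolute latitude.
#'
#' @param site character vector of site names.
#' @param zone zone label per site.
#' @param latitude latitude per site.
#' @export
zone_partition <- function(site, zone, latitude) {
  mean_abs <- tapply(abs(latitude), zone, mean)
  ord <- names(sort(mean_abs))
  relabel <- stats::setNames(LETTERS[seq_along(ord)], ord)
  zones <- stats::setNames(as.character(relabel[as.character(zone)]), site)
  zone_lat <- tapply(abs(latitude), zones, mean)
  out <- list(sites = zones, zone_order = LETTERS[seq_along(ord)],
              reference_zone = "A",
              zone_latitude = zone_lat[LETTERS[seq_along(ord)]],
              tree = NULL)
  class(out) <- "zone_partition"
  out
}

#' @export
print.zone_partition <- function(x, ...) {
  cat("Zone partition:", length(x$sites), "sites in",
      length(x$zone_order), "zones\n")
  print(zone_summary(x))
  invisible(x)
}

#' Per-zone summary of a zone partition
#' @param partition a `zone_partition`.
#' @return data.frame with zone, number of sites and representative latitude.
#' @export
zone_summary <- function(partition) {
  data.frame(zone = partition$zone_order,
             n_sites = as.integer(table(factor(partition$sites,
                                               partition$zone_order))),
             latitude = as.numeric(partition$zone_latitude),
             row.names = NULL)
}

#' Zone label of each site's survey transects
#' @param survey SurveyTable.
#' @param partition a `zone_partition` covering the survey's sites.
#' @return character vector over rows of [transect_table()].
#' @keywords internal
.transect_zones <- function(survey, partition) {
  tt <- transect_table(survey)
  z <- partition$sites[tt$site]
  if (anyNA(z))
    stop("zone partition does not cover site(s): ",
         paste(unique(tt$site[is.na(z)]), collapse = ", "), call. = FALSE)
  as.character(z)
}
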