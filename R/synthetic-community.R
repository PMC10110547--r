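## Synthetic metacommunity generator
##
## Emulates a two-region tropical-temperate survey design: sites stratified
## across contiguous latitude zones, 3-5 transects per site, species organised
## into trait-defined functional groups, each group's tropical biomass
## declining log-linearly poleward (parameterised by the latitude of its
## 20-fold decline) while temperate biomass rises. All randomness flows from a
## single seed through fixed sub-streams, so identical configs give
## byte-identical tables.

#' Scenario configuration for the synthetic community generator
#'
#' Builds (and validates) the full parameter set of the generator. Defaults
#' describe the reference study conditions: two regions of 30 sites stratified
#' over six 2-degree latitude zones spanning 23-35 degrees absolute latitude,
#' four transects per site, 300 species in nine trait archetypes, group-level
#' 20-fold decline latitudes spread from zone B to zone F, and lognormal
#' biomass noise.
#'
#' @param regions data.frame with columns `name` and `hemisphere` (+1 north,
#'   -1 south).
#' @param n_sites sites per region (stratified evenly over zones).
#' @param latitude_range absolute latitude span, degrees.
#' @param n_zones number of contiguous latitude bands.
#' @param transects_per_site integer in 3..5.
#' @param n_species,n_groups community size and number of functional groups.
#' @param group_sizes species per group (recycled/scaled to `n_species` if
#'   NULL).
#' @param tropical_fraction per-group fraction of tropical species in [0, 1].
#' @param decline_latitude per-group absolute latitude at which tropical
#'   biomass reaches 1/20 of its reference-zone mean; `NA` means "never
#'   declines".
#' @param base_biomass per-group tropical biomass scale (g/m^2) at the
#'   reference zone.
#' @param temperate_base per-group temperate biomass scale at the equatorward
#'   end (zero where a group has no temperate species).
#' @param temperate_slope per-degree exponential increase of temperate
#'   biomass.
#' @param archetypes data.frame of per-group modal trait values with columns
#'   `diet`, `habitat_association`, `body_size`, `aggregation`, `depth_range`.
#' @param trait_flip probability a species' nominal trait deviates from its
#'   archetype.
#' @param size_sdlog,depth_sdlog lognormal spread of body size / depth range
#'   around the archetype.
#' @param aggregation_jitter probability of a +/-1 step away from the modal
#'   aggregation level.
#' @param missingness named vector of per-trait missing-value rates in [0, 1].
#' @param biomass_sigma lognormal sigma of transect-level biomass noise.
#' @param site_sigma lognormal sigma of the shared site effect.
#' @param species_presence per-transect detection probability of a species
#'   whose group is present.
#' @param seed integer master seed.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(regions = data.frame(name = c("north", "south"),
                                                 hemisphere = c(1, -1)),
                            n_sites = 30,
                            latitude_range = c(23, 35),
                            n_zones = 6,
                            transects_per_site = 4,
                            n_species = 300,
                            n_groups = 9,
                            group_sizes = NULL,
                            tropical_fraction = c(0.6, 0.65, 0.6, 0.7, 0.6,
                                                  0.7, 0.65, 0.6, 1),
                            decline_latitude = c(33.2, 33.2, 33.2, 33.2, 25.3,
                                                 29.3, 29.3, 31.3, 29.3),
                            base_biomass = c(35, 25, 15, 11.5, 8, 2.5, 2.5,
                                             3, 2),
                            temperate_base = NULL,
                            temperate_slope = 0.15,
                            archetypes = NULL,
                            trait_flip = 0.02,
                            size_sdlog = 0.12,
                            depth_sdlog = 0.12,
                            aggregation_jitter = 0.1,
                            missingness = c(diet = 0.002,
                                            habitat_association = 0,
                                            body_size = 0, aggregation = 0,
                                            depth_range = 0.03),
                            biomass_sigma = 0.25,
                            site_sigma = 0.05,
                            species_presence = 0.95,
                            seed = 1) {
  if (is.null(group_sizes)) {
    base_sizes <- c(60, 50, 40, 35, 30, 25, 25, 20, 15)
    if (n_groups != 9L)
      base_sizes <- rep(ceiling(n_species / n_groups), n_groups)
    group_sizes <- round(base_sizes / sum(base_sizes) * n_species)
    group_sizes[1] <- group_sizes[1] + (n_species - sum(group_sizes))
  }
  if (is.null(archetypes)) {
    archetypes <- data.frame(
      diet = c("predator", "predator", "herbivore_omnivore", "planktivore",
               "herbivore", "predator", "planktivore", "omnivore",
               "corallivore"),
      habitat_association = c("benthic", "upper_benthic", "benthic",
                              "upper_benthic", "upper_benthic", "demersal",
                              "benthic", "upper_benthic", "benthic"),
      body_size = c(35, 40, 20, 10, 25, 60, 8, 15, 12),
      aggregation = c(1, 2, 2, 4, 4, 1, 2, 3, 2),
      depth_range = c(40, 35, 18, 20, 15, 50, 30, 25, 12),
      stringsAsFactors = FALSE)
    if (n_groups != 9L)
      archetypes <- archetypes[rep_len(seq_len(9L), n_groups), , drop = FALSE]
  }
  if (is.null(temperate_base))
    temperate_base <- ifelse(tropical_fraction >= 1, 0, base_biomass * 0.3)
  cfg <- list(regions = regions, n_sites = n_sites,
              latitude_range = latitude_range, n_zones = n_zones,
              transects_per_site = transects_per_site,
              n_species = n_species, n_groups = n_groups,
              group_sizes = group_sizes,
              tropical_fraction = rep_len(tropical_fraction, n_groups),
              decline_latitude = rep_len(decline_latitude, n_groups),
              base_biomass = rep_len(base_biomass, n_groups),
              temperate_base = rep_len(temperate_base, n_groups),
              temperate_slope = temperate_slope,
              archetypes = archetypes, trait_flip = trait_flip,
              size_sdlog = size_sdlog, depth_sdlog = depth_sdlog,
              aggregation_jitter = aggregation_jitter,
              missingness = missingness, biomass_sigma = biomass_sigma,
              site_sigma = site_sigma, species_presence = species_presence,
              seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
}

#' @rdname scenario_config
#' @param config a `scenario_config` list.
#' @export
validate_scenario_config <- function(config) {
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid scenario config field '", field, "': ", msg,
                  call. = FALSE)
  chk(is.data.frame(config$regions) &&
        all(c("name", "hemisphere") %in% names(config$regions)),
      "regions", "needs columns name, hemisphere")
  chk(config$n_sites >= config$n_zones, "n_sites",
      "must be a positive integer >= n_zones")
  chk(length(config$latitude_range) == 2 &&
        diff(config$latitude_range) > 0 &&
        all(config$latitude_range > 0 & config$latitude_range <= 90),
      "latitude_range", "must be increasing absolute degrees in (0, 90]")
  chk(config$n_zones >= 2, "n_zones", "must be >= 2")
  chk(config$transects_per_site %in% 3:5, "transects_per_site",
      "must be an integer in 3..5")
  chk(config$n_groups <= config$n_species, "n_groups",
      "must not exceed n_species")
  chk(length(config$group_sizes) == config$n_groups &&
        sum(config$group_sizes) == config$n_species &&
        all(config$group_sizes > 0),
      "group_sizes", "must be n_groups positive integers summing to n_species")
  chk(all(config$tropical_fraction >= 0 & config$tropical_fraction <= 1),
      "tropical_fraction", "fractions must lie in [0, 1]")
  ref_centre <- .zone_centres(config)[1]
  dl <- config$decline_latitude
  chk(all(is.na(dl) | (dl > ref_centre & dl <= config$latitude_range[2])),
      "decline_latitude",
      "must lie poleward of the reference-zone centre and within the range, or NA")
  chk(all(config$base_biomass > 0), "base_biomass", "must be positive")
  chk(all(config$temperate_base >= 0), "temperate_base",
      "must be non-negative")
  chk(nrow(config$archetypes) == config$n_groups, "archetypes",
      "must supply one archetype row per group")
  chk(all(config$missingness >= 0 & config$missingness <= 1), "missingness",
      "rates must lie in [0, 1]")
  chk(config$trait_flip >= 0 && config$trait_flip <= 1, "trait_flip",
      "must lie in [0, 1]")
  chk(config$species_presence > 0 && config$species_presence <= 1,
      "species_presence", "must lie in (0, 1]")
  chk(config$biomass_sigma >= 0, "biomass_sigma", "must be >= 0")
  chk(config$site_sigma >= 0, "site_sigma", "must be >= 0")
  config
}

#' Read a scenario configuration from a YAML file
#'
#' Scalar fields override [scenario_config()] defaults; `regions` and
#' `archetypes` may be given as YAML maps of columns.
#'
#' @param path YAML file path.
#' @return A validated `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML scenarios requires the 'yaml' package", call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (f in c("regions", "archetypes"))
    if (!is.null(raw[[f]])) raw[[f]] <- as.data.frame(raw[[f]])
  if (!is.null(raw$missingness)) raw$missingness <- unlist(raw$missingness)
  do.call(scenario_config, raw)
}

.zone_breaks <- function(config)
  seq(config$latitude_range[1], config$latitude_range[2],
      length.out = config$n_zones + 1)

.zone_centres <- function(config) {
  b <- .zone_breaks(config)
  (b[-1] + b[-length(b)]) / 2
}

.zone_of <- function(abslat, config) {
  b <- .zone_breaks(config)
  i <- findInterval(abslat, b, rightmost.closed = TRUE)
  LETTERS[pmin(pmax(i, 1L), config$n_zones)]
}

## per-group decline rate so that biomass falls 20-fold between the
## reference-zone centre and the configured decline latitude
.decline_rate <- function(config) {
  ref <- .zone_centres(config)[1]
  ifelse(is.na(config$decline_latitude), 0,
         log(20) / (config$decline_latitude - ref))
}

.derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

## deterministic per-species attributes shared by both output tables
.species_attributes <- function(config, seed) {
  set.seed(seed)
  n <- config$n_species
  g <- rep(seq_len(config$n_groups), config$group_sizes)
  species <- sprintf("sp%03d", seq_len(n))
  guild <- character(n)
  for (i in seq_len(config$n_groups)) {
    idx <- which(g == i)
    n_trop <- round(config$tropical_fraction[i] * length(idx))
    guild[idx] <- c(rep("tropical", n_trop),
                    rep("temperate", length(idx) - n_trop))
  }
  ## relative biomass weights within group x guild (lognormal dominance)
  w <- stats::rlnorm(n, 0, 0.8)
  ## occupancy windows: tropical species terminate at (or slightly before)
  ## their group's edge zone; temperate species switch on mid-gradient
  edge_zone <- findInterval(ifelse(is.na(config$decline_latitude),
                                   config$latitude_range[2],
                                   config$decline_latitude),
                            .zone_breaks(config), rightmost.closed = TRUE)
  terminal <- pmax(1L, edge_zone[g] -
                     sample(0:2, n, replace = TRUE, prob = c(0.6, 0.25, 0.15)))
  onset <- sample(2:min(5, config$n_zones), n, replace = TRUE)
  list(species = species, group = g, guild = guild, w = w,
       terminal = ifelse(guild == "tropical", terminal, NA),
       onset = ifelse(guild == "temperate", onset, NA))
}

#' Generate a species trait table with group-archetype structure
#'
#' Draws each species' five functional traits around its group archetype:
#' nominal traits deviate with probability `trait_flip`, body size and depth
#' range are lognormal around the modal value, aggregation takes occasional
#' single-level steps, and per-trait missingness is injected at the configured
#' rates. A realised upper thermal limit is attached per thermal guild.
#'
#' @param config a `scenario_config`.
#' @return A validated TraitTable data.frame with a `group_truth` attribute.
#' @export
generate_trait_clusters <- function(config) {
  validate_scenario_config(config)
  seeds <- .derive_seeds(config$seed, 3L)
  attrs <- .species_attributes(config, seeds[1])
  set.seed(seeds[2])
  n <- config$n_species
  g <- attrs$group
  arch <- config$archetypes
  diet_levels <- unique(arch$diet)
  hab_levels <- unique(arch$habitat_association)
  flip <- function(modal, levels) {
    out <- modal
    hit <- stats::runif(n) < config$trait_flip
    if (any(hit))
      out[hit] <- vapply(modal[hit], function(m)
        sample(setdiff(levels, m), 1L), character(1))
    out
  }
  diet <- flip(arch$diet[g], diet_levels)
  habitat <- flip(arch$habitat_association[g], hab_levels)
  body_size <- arch$body_size[g] * stats::rlnorm(n, 0, config$size_sdlog)
  depth_range <- arch$depth_range[g] * stats::rlnorm(n, 0, config$depth_sdlog)
  step <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                 prob = c(config$aggregation_jitter / 2,
                          1 - config$aggregation_jitter,
                          config$aggregation_jitter / 2))
  aggregation <- pmin(5L, pmax(1L, arch$aggregation[g] + step))
  limit <- ifelse(attrs$guild == "tropical",
                  stats::rnorm(n, 30.5, 1.2), stats::rnorm(n, 26.5, 1.5))
  traits <- data.frame(species = attrs$species, diet = diet,
                       habitat_association = habitat,
                       body_size = body_size, aggregation = aggregation,
                       depth_range = depth_range,
                       thermal_guild = attrs$guild,
                       thermal_limit = round(limit, 2),
                       stringsAsFactors = FALSE)
  miss <- config$missingness
  for (tr in names(miss)) {
    if (miss[[tr]] <= 0) next
    hole <- stats::runif(n) < miss[[tr]]
    traits[[tr]][hole] <- NA
  }
  traits$body_size <- round(traits$body_size, 2)
  traits$depth_range <- round(traits$depth_range, 2)
  attr(traits, "group_truth") <- stats::setNames(g, attrs$species)
  validate_traits(traits)
}

#' Generate a synthetic survey, trait table and ground truth
#'
#' Produces a full metacommunity realisation under the configured study
#' conditions. Tropical biomass of group *i* declines exponentially with
#' absolute latitude at the rate implied by its 20-fold-decline latitude;
#' temperate biomass rises exponentially; per-transect group presence is
#' Bernoulli with probability collapsing beyond the group's edge so that
#' zero-footprint transects occur. Expected biomass is preserved under all
#' thinning and noise (presence, detection and lognormal terms are
#' mean-compensated), so the configured decline profile is the expectation of
#' the generated data.
#'
#' @param config a `scenario_config`.
#' @return list with elements `survey` (SurveyTable), `traits` (TraitTable)
#'   and `truth` (list: `species_group`, `species_guild`, `site_zone`,
#'   `group_edge`, `community_edge_zone`, `reference_zone`, `zone_breaks`).
#' @export
generate_metacommunity <- function(config) {
  validate_scenario_config(config)
  seeds <- .derive_seeds(config$seed, 3L)
  attrs <- .species_attributes(config, seeds[1])
  traits <- generate_trait_clusters(config)
  ## environmental filtering acts on functionally marginal species first:
  ## within each group, the tropical species most deviant from the trait
  ## archetype terminate one or two zones before the group's leading edge,
  ## so tropical niche area contracts poleward as biomass declines
  edge_zone_g <- findInterval(ifelse(is.na(config$decline_latitude),
                                     config$latitude_range[2],
                                     config$decline_latitude),
                              .zone_breaks(config), rightmost.closed = TRUE)
  arch <- config$archetypes
  g <- attrs$group
  rng_bs <- diff(range(log(traits$body_size), na.rm = TRUE))
  rng_dr <- diff(range(log(traits$depth_range), na.rm = TRUE))
  comp <- cbind(
    as.numeric(traits$diet != arch$diet[g]),
    as.numeric(traits$habitat_association != arch$habitat_association[g]),
    abs(log(traits$body_size) - log(arch$body_size[g])) / rng_bs,
    abs(traits$aggregation - arch$aggregation[g]) / 4,
    abs(log(traits$depth_range) - log(arch$depth_range[g])) / rng_dr)
  dev <- rowMeans(comp, na.rm = TRUE)
  for (i in seq_len(config$n_groups)) {
    idx <- which(attrs$group == i & attrs$guild == "tropical")
    if (length(idx) == 0) next
    q <- rank(dev[idx], ties.method = "first") / length(idx)
    attrs$terminal[idx] <- pmax(1L, edge_zone_g[i] -
                                  ifelse(q <= 0.6, 0L, ifelse(q <= 0.85, 1L, 2L)))
  }
  set.seed(seeds[3])

  breaks <- .zone_breaks(config)
  centres <- .zone_centres(config)
  rate <- .decline_rate(config)
  n_zones <- config$n_zones
  per_zone <- diff(round(seq(0, config$n_sites, length.out = n_zones + 1)))
  rows <- vector("list", nrow(config$regions) * config$n_sites)
  site_zone <- list()
  ri <- 0L
  for (r in seq_len(nrow(config$regions))) {
    rname <- config$regions$name[r]
    hemi <- config$regions$hemisphere[r]
    ## sites stratified over zones: evenly spread within each band with a
    ## small placement jitter, as a designed survey would space them
    abslat <- unlist(lapply(seq_len(n_zones), function(z) {
      width <- breaks[z + 1] - breaks[z]
      centres <- breaks[z] + (seq_len(per_zone[z]) - 0.5) /
        per_zone[z] * width
      sort(pmin(breaks[z + 1], pmax(breaks[z],
        centres + stats::runif(per_zone[z], -0.1, 0.1))))
    }))
    site <- sprintf("%s_s%02d", rname, seq_len(config$n_sites))
    site_zone[[rname]] <- data.frame(region = rname, site = site,
                                     latitude = hemi * abslat,
                                     zone = .zone_of(abslat, config),
                                     stringsAsFactors = FALSE)
    site_eff <- stats::rlnorm(config$n_sites,
                              -config$site_sigma^2 / 2, config$site_sigma)
    for (s in seq_len(config$n_sites)) {
      la <- abslat[s]
      z <- findInterval(la, breaks, rightmost.closed = TRUE)
      ## expected guild totals per group at this latitude
      m_trop <- config$base_biomass *
        exp(-rate * (la - centres[1]))
      m_temp <- config$temperate_base *
        exp(config$temperate_slope * (la - config$latitude_range[1]))
      p_grp <- 0.9985 * stats::plogis(
        6 - 3 * pmax(0, la - ifelse(is.na(config$decline_latitude),
                                    config$latitude_range[2],
                                    config$decline_latitude)))
      ## expected per-species biomass at this site: group totals split over
      ## the window-occupying species with renormalised weights, giving
      ## compositional turnover at zone boundaries without changing totals
      occ_trop <- attrs$guild == "tropical" & attrs$terminal >= z
      occ_temp <- attrs$guild == "temperate" & attrs$onset <= z
      mu0 <- numeric(config$n_species)
      for (i in seq_len(config$n_groups)) {
        it <- which(occ_trop & attrs$group == i)
        if (length(it) > 0)
          mu0[it] <- m_trop[i] * attrs$w[it] / sum(attrs$w[it])
        ie <- which(occ_temp & attrs$group == i)
        if (length(ie) > 0)
          mu0[ie] <- m_temp[i] * attrs$w[ie] / sum(attrs$w[ie])
      }
      ## visual-survey detection: rare species are missed more often
      p_det <- ifelse(mu0 > 0, config$species_presence *
                        stats::plogis(2 + 1.2 * log10(pmax(mu0, 1e-12))), 0)
      p_both <- p_det * p_grp[attrs$group]
      for (tr in seq_len(config$transects_per_site)) {
        present_grp <- stats::runif(config$n_groups) < p_grp
        det <- present_grp[attrs$group] &
          stats::runif(config$n_species) < p_det
        idx <- which(det & mu0 > 0)
        if (length(idx) == 0) next
        ## mean-compensated so E[biomass] = mu0 under all thinning and noise
        b <- mu0[idx] / p_both[idx] * site_eff[s] *
          stats::rlnorm(length(idx), -config$biomass_sigma^2 / 2,
                        config$biomass_sigma)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(region = rname, site = site[s],
                                 latitude = hemi * la,
                                 transect = sprintf("t%d", tr),
                                 species = attrs$species[idx],
                                 biomass = round(b, 6),
                                 stringsAsFactors = FALSE)
      }
    }
  }
  survey <- do.call(rbind, rows[seq_len(ri)])
  rownames(survey) <- NULL
  truth <- list(
    species_group = stats::setNames(attrs$group, attrs$species),
    species_guild = stats::setNames(attrs$guild, attrs$species),
    site_zone = do.call(rbind, site_zone),
    group_edge = data.frame(
      group = seq_len(config$n_groups),
      edge_latitude = config$decline_latitude,
      edge_zone = ifelse(is.na(config$decline_latitude), "never",
                         .zone_of(config$decline_latitude, config)),
      stringsAsFactors = FALSE),
    community_edge_zone = .community_edge_truth(config),
    reference_zone = "A",
    zone_breaks = breaks)
  rownames(truth$site_zone) <- NULL
  list(survey = validate_survey(survey), traits = traits, truth = truth)
}

## analytic community leading edge implied by the configuration: first zone
## whose zone-centre expected community footprint falls below 1/20
.community_edge_truth <- function(config, threshold = 0.05) {
  centres <- .zone_centres(config)
  rate <- .decline_rate(config)
  edge_zone <- findInterval(ifelse(is.na(config$decline_latitude),
                                   config$latitude_range[2],
                                   config$decline_latitude),
                            .zone_breaks(config), rightmost.closed = TRUE)
  bt <- vapply(seq_len(config$n_zones), function(z)
    sum(config$base_biomass * exp(-rate * (centres[z] - centres[1])) *
          (edge_zone >= z)) / sum(config$base_biomass), numeric(1))
  hit <- which(bt[-1] < threshold) + 1L
  if (length(hit) == 0) "never" else LETTERS[hit[1]]
}
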