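## End-to-end driver: generate (or accept) survey + trait tables, zone the
## sites, identify functional groups, compute footprints, leading edges,
## niche metrics and driver tests per region.

#' Build a functional grouping from known assignments
#'
#' Wraps an externally supplied species -> group map (e.g. the synthetic
#' ground truth, or a deposited assignment table) in the same structure that
#' [cluster_species()] returns.
#'
#' @param assignments named vector, species -> group id.
#' @param traits optional TraitTable for guild counts.
#' @param major_threshold minimum species share of a "major" group.
#' @return a `functional_grouping`.
#' @export
as_functional_grouping <- function(assignments, traits = NULL,
                                   major_threshold = 0.02) {
  sizes <- table(assignments)
  guild_counts <- NULL
  if (!is.null(traits)) {
    guild <- traits$thermal_guild[match(names(assignments), traits$species)]
    guild_counts <- table(group = assignments, guild = guild)
  }
  out <- list(assignments = assignments,
              k = length(sizes), sizes = as.integer(sizes),
              guild_counts = guild_counts,
              major_groups = sort(unique(assignments))[
                sizes / length(assignments) >= major_threshold],
              tree = NULL)
  class(out) <- "functional_grouping"
  out
}

#' Site-level mean footprints per group
#'
#' @param fp a `footprint_table`.
#' @return data.frame site, zone, latitude, group, bt (mean over the site's
#'   transects).
#' @export
site_footprints <- function(fp) {
  agg <- stats::aggregate(bt ~ site + zone + latitude + group, data = fp,
                          FUN = mean)
  agg[order(agg$group, agg$site), , drop = FALSE]
}

#' Run the full tropicalisation analysis
#'
#' Generates a synthetic metacommunity under `config` (or analyses supplied
#' tables), then per region: clusters sites into zones, computes
#' tropicalisation footprints and zone-level mixed-model estimates, locates
#' leading edges, evaluates site-level functional-niche metrics, and finally
#' combines regions in the leading-edge driver-test battery.
#'
#' @param config a `scenario_config`.
#' @param survey,traits optional externally supplied tables (both or
#'   neither); when supplied the generator is bypassed and no ground truth is
#'   available.
#' @param k number of functional groups to cut (default: `config$n_groups`).
#' @param use_true_zones use the generator's zone labels instead of
#'   rediscovering them by clustering (isolates downstream stages).
#' @param use_true_groups use the generator's species -> group map instead of
#'   Gower/UPGMA clustering.
#' @param niche compute kernel niche metrics (the slowest stage).
#' @param grid_n kernel grid resolution per axis.
#' @return list with the generated tables, ground truth, per-region results
#'   (`zones`, `footprints`, `estimates`, `edges`, `niche`, `kendall`) and
#'   combined `driver_data` / `driver_tests`.
#' @export
run_scenario <- function(config = scenario_config(), survey = NULL,
                         traits = NULL, k = NULL, use_true_zones = FALSE,
                         use_true_groups = FALSE, niche = TRUE,
                         grid_n = 150) {
  truth <- NULL
  if (is.null(survey) != is.null(traits))
    stop("supply both 'survey' and 'traits', or neither", call. = FALSE)
  if (is.null(survey)) {
    sim <- generate_metacommunity(config)
    survey <- sim$survey
    traits <- sim$traits
    truth <- sim$truth
  }
  if (is.null(k)) k <- config$n_groups
  d <- gower_distance(traits)
  grouping <- if (use_true_groups && !is.null(truth))
    as_functional_grouping(truth$species_group, traits)
  else cluster_species(d, k, traits)
  space <- set_space_guilds(pcoa_cailliez(d, m = 4), traits)

  regions <- unique(survey$region)
  per_region <- list()
  driver_rows <- list()
  chars <- characterise_groups(grouping, traits)
  for (r in regions) {
    sv <- survey[survey$region == r, , drop = FALSE]
    if (use_true_zones && !is.null(truth)) {
      sz <- truth$site_zone[truth$site_zone$region == r, , drop = FALSE]
      partition <- zone_partition(sz$site, sz$zone, sz$latitude)
    } else {
      m <- site_species_matrix(sv)
      partition <- cluster_zones(bray_curtis(m), config$n_zones,
                                 attr(m, "latitude"))
    }
    fp <- footprints(sv, partition, grouping, traits)
    est <- zone_footprint_estimates(fp, partition)
    edges <- leading_edge(est, partition)
    nm <- NULL
    kendall <- NULL
    if (niche) {
      nm <- site_group_niche_metrics(sv, partition, grouping, space,
                                     grid_n = grid_n)
      sf <- site_footprints(fp)
      kendall <- do.call(rbind, lapply(
        intersect(unique(nm$group), sf$group), function(g) {
          key <- sf$group == g
          idx <- match(sf$site[key], nm$site[nm$group == g])
          sub <- nm[nm$group == g, , drop = FALSE][idx, , drop = FALSE]
          ko <- kendall_with_zero_removal(sf$bt[key], sub$overlap)
          ka <- kendall_with_zero_removal(sf$bt[key],
                                          sub$tropical_area_proportion)
          data.frame(group = g,
                     metric = c("overlap", "area_proportion"),
                     tau = c(ko$tau, ka$tau), p = c(ko$p, ka$p),
                     n = c(ko$n, ka$n), stringsAsFactors = FALSE)
        }))
    }
    maxima <- zone_guild_max_biomass(sv, partition, grouping, traits)
    for (g in grouping$major_groups) {
      ge <- edges[edges$group == as.character(g), , drop = FALSE]
      if (nrow(ge) == 0) next
      sp_g <- names(grouping$assignments)[grouping$assignments == g]
      present <- intersect(sp_g, unique(sv$species))
      trop_limit <- traits$thermal_limit[
        traits$species %in% sp_g & traits$thermal_guild == "tropical"]
      dom <- function(trait) {
        cg <- chars[chars$group == g & chars$trait == trait &
                      chars$dominant, , drop = FALSE]
        if (nrow(cg) == 0) NA_character_ else cg$level[1]
      }
      nm_g <- if (is.null(nm)) NULL else nm[nm$group == g, , drop = FALSE]
      driver_rows[[paste(r, g)]] <- data.frame(
        region = r, group = g, class = ge$class,
        max_tropical = maxima$max_biomass[maxima$group == g &
                                            maxima$guild == "tropical"],
        max_temperate = maxima$max_biomass[maxima$group == g &
                                             maxima$guild == "temperate"],
        overlap = if (is.null(nm_g)) NA_real_ else
          mean(nm_g$overlap, na.rm = TRUE),
        area_proportion = if (is.null(nm_g)) NA_real_ else
          mean(pmin(nm_g$tropical_area_proportion, 1), na.rm = TRUE),
        richness = length(present),
        thermal_limit = mean(trop_limit, na.rm = TRUE),
        diet = dom("diet"), position = dom("habitat_association"),
        stringsAsFactors = FALSE)
    }
    per_region[[r]] <- list(zones = partition, footprints = fp,
                            estimates = est, edges = edges, niche = nm,
                            kendall = kendall, maxima = maxima)
  }
  driver_data <- do.call(rbind, driver_rows)
  rownames(driver_data) <- NULL
  driver_tests <- tryCatch(leading_edge_driver_tests(driver_data),
                           error = function(e) NULL)
  list(config = config, survey = survey, traits = traits, truth = truth,
       grouping = grouping, space = space, regions = per_region,
       characterisation = chars, driver_data = driver_data,
       driver_tests = driver_tests)
}
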