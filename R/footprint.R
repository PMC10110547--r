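## Tropicalisation footprints.
##
## For functional group i at transect j, BT_ij = b_ij / b_bar_i where b_ij is
## the summed biomass of the group's tropical species on the transect and
## b_bar_i the mean of those totals over all reference-zone transects (zeros
## included). Community rows use all tropical species regardless of group.
## Footprints are fourth-root transformed before modelling; zone-level means
## come from linear mixed models with a site random intercept, groups tested
## against the community baseline; the leading edge is the first zone
## (scanning poleward) whose modelled mean falls below a 20-fold decline.

#' Fourth-root transform
#'
#' Monotone variance-taming transform for biomass proportions; respects zeros.
#'
#' @param bt non-negative footprint values.
#' @return `bt^(1/4)`.
#' @export
transform_fourth_root <- function(bt) {
  if (any(bt < 0, na.rm = TRUE))
    stop("fourth-root transform requires non-negative input", call. = FALSE)
  bt^0.25
}

#' Tropicalisation footprints per transect and functional group
#'
#' @param survey SurveyTable (one region).
#' @param partition `zone_partition` covering the survey's sites.
#' @param grouping `functional_grouping` covering the surveyed species.
#' @param traits TraitTable supplying thermal guilds.
#' @param guild guild whose biomass is tracked (default "tropical").
#' @param groups functional groups to include (default: major groups).
#' @return data.frame of class `footprint_table`: one row per transect x
#'   group (plus "community" rows) with `biomass`, `bt` and fourth-root
#'   `bt_q`; reference means are attached as the `reference_means` attribute.
#'   Groups with zero reference-zone biomass are excluded with a warning.
#' @export
footprints <- function(survey, partition, grouping, traits,
                       guild = "tropical", groups = NULL) {
  validate_survey(survey)
  if (is.null(groups)) groups <- grouping$major_groups
  tt <- transect_table(survey)
  zone <- .transect_zones(survey, partition)
  is_ref <- zone == partition$reference_zone
  if (!any(is_ref))
    stop("no transects in the reference zone", call. = FALSE)
  guild_sp <- traits$species[traits$thermal_guild == guild]
  grp_of <- grouping$assignments
  member <- c(list(community = guild_sp),
              stats::setNames(lapply(groups, function(g)
                intersect(guild_sp, names(grp_of)[grp_of == g])),
                as.character(groups)))
  rows <- list()
  ref_means <- numeric(0)
  for (nm in names(member)) {
    tot <- transect_totals(survey, member[[nm]])
    b_bar <- mean(tot[is_ref])
    if (b_bar <= 0) {
      warning("group ", nm, " has zero reference-zone biomass; excluded",
              call. = FALSE)
      next
    }
    ref_means[nm] <- b_bar
    rows[[nm]] <- data.frame(region = tt$region, zone = zone, site = tt$site,
                             latitude = tt$latitude, transect = tt$transect,
                             group = nm, biomass = as.numeric(tot),
                             bt = as.numeric(tot) / b_bar,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$bt_q <- transform_fourth_root(out$bt)
  attr(out, "reference_means") <- ref_means
  attr(out, "reference_zone") <- partition$reference_zone
  class(out) <- c("footprint_table", "data.frame")
  out
}

#' Zone-level footprint estimates from a linear mixed model
#'
#' Within one (non-reference) zone, fourth-root footprints are modelled
#' against functional group — the community total being the baseline level —
#' with a site random intercept. Per-group means (back-transformed for
#' reporting) carry standard errors, and the group-vs-community contrast
#' flags significant departures from the community expectation at
#' `alpha = 0.05`. A singular or degenerate fit falls back to ordinary least
#' squares with a warning.
#'
#' @param fp `footprint_table`.
#' @param zone zone label to model (not the reference zone).
#' @param alpha departure significance level.
#' @return data.frame: zone, group, `estimate_q` (transformed scale), `se_q`,
#'   `estimate` (back-transformed), `p_vs_community`, `departure`
#'   (-1, 0, +1).
#' @export
zone_mixed_model <- function(fp, zone, alpha = 0.05) {
  if (zone == attr(fp, "reference_zone"))
    stop("the reference zone is the baseline, not modelled", call. = FALSE)
  dat <- fp[fp$zone == zone, , drop = FALSE]
  if (nrow(dat) == 0) stop("no footprint rows in zone ", zone, call. = FALSE)
  dat$group <- stats::relevel(factor(dat$group), ref = "community")
  dat$site <- factor(dat$site)
  if (nlevels(dat$site) < 2)
    stop("zone ", zone, " has fewer than 2 sites", call. = FALSE)
  fit <- tryCatch(
    nlme::lme(bt_q ~ group, random = ~ 1 | site, data = dat,
              control = nlme::lmeControl(returnObject = TRUE)),
    error = function(e) {
      warning("mixed model failed in zone ", zone,
              " (", conditionMessage(e), "); ordinary least squares used",
              call. = FALSE)
      stats::lm(bt_q ~ group, data = dat)
    })
  beta <- if (inherits(fit, "lme")) nlme::fixef(fit) else stats::coef(fit)
  vc <- stats::vcov(fit)
  tab <- if (inherits(fit, "lme")) summary(fit)$tTable else
    summary(fit)$coefficients
  lv <- levels(dat$group)
  est <- se <- p <- numeric(length(lv))
  for (i in seq_along(lv)) {
    cvec <- as.numeric(lv[i] != "community") *
      (names(beta) == paste0("group", lv[i]))
    cvec[1] <- 1
    est[i] <- sum(cvec * beta)
    se[i] <- sqrt(drop(t(cvec) %*% as.matrix(vc) %*% cvec))
    p[i] <- if (lv[i] == "community") NA_real_ else
      tab[paste0("group", lv[i]), ncol(tab)]
  }
  ## a contrast that is zero to numerical precision is no departure, however
  ## small its (equally degenerate) standard error makes the p-value
  contrast <- est - est[lv == "community"]
  negligible <- abs(contrast) <= 1e-8 * max(1, abs(est[lv == "community"]))
  departure <- ifelse(is.na(p) | p >= alpha | negligible, 0L,
                      ifelse(contrast > 0, 1L, -1L))
  data.frame(zone = zone, group = lv, estimate_q = est, se_q = se,
             estimate = pmax(est, 0)^4,
             p_vs_community = p, departure = departure,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Zone-level footprint estimates across all non-reference zones
#'
#' @param fp `footprint_table`.
#' @param partition the `zone_partition` used to build `fp`.
#' @param alpha departure significance level.
#' @return stacked [zone_mixed_model()] results, reference zone omitted.
#' @export
zone_footprint_estimates <- function(fp, partition, alpha = 0.05) {
  zones <- setdiff(partition$zone_order, partition$reference_zone)
  zones <- intersect(zones, unique(fp$zone))
  out <- do.call(rbind, lapply(zones, function(z)
    zone_mixed_model(fp, z, alpha = alpha)))
  rownames(out) <- NULL
  out
}

#' Tropicalisation leading edges and expectation classes
#'
#' The leading edge of a group is the first zone, scanning poleward through
#' the zone order, whose modelled mean footprint falls below `threshold`
#' (default 0.05, a 20-fold biomass decline). Groups are classed against the
#' community-level leading edge: same zone (or poleward of it) is
#' "as_expected", one zone equatorward "below_expectation", two or more
#' "well_below_expectation"; a group never crossing the threshold "does not
#' decline".
#'
#' @param estimates output of [zone_footprint_estimates()].
#' @param partition the `zone_partition` (for zone order and latitudes).
#' @param threshold footprint threshold (default 1/20).
#' @return data.frame: group, edge_zone, edge_latitude, class.
#' @export
leading_edge <- function(estimates, partition, threshold = 0.05) {
  if (!"community" %in% estimates$group)
    stop("community estimates are required", call. = FALSE)
  zones <- setdiff(partition$zone_order, partition$reference_zone)
  edge_of <- function(g) {
    for (z in zones) {
      e <- estimates$estimate[estimates$zone == z & estimates$group == g]
      if (length(e) == 1 && !is.na(e) && e < threshold) return(z)
    }
    NA_character_
  }
  grps <- unique(estimates$group)
  edges <- vapply(grps, edge_of, character(1))
  comm_idx <- match(edges[grps == "community"], partition$zone_order)
  if (is.na(comm_idx))
    comm_idx <- length(partition$zone_order) + 1L
  cls <- vapply(seq_along(grps), function(i) {
    if (grps[i] == "community") return("community")
    if (is.na(edges[i])) return("does_not_decline")
    gap <- comm_idx - match(edges[i], partition$zone_order)
    if (gap <= 0) "as_expected"
    else if (gap == 1) "below_expectation"
    else "well_below_expectation"
  }, character(1))
  data.frame(group = grps, edge_zone = edges,
             edge_latitude = as.numeric(partition$zone_latitude[edges]),
             class = cls, stringsAsFactors = FALSE, row.names = NULL)
}
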