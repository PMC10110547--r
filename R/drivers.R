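## Driver inference: within-group Kendall correlations between footprints and
## niche metrics (with the zero-removal rule), per-zone guild biomass maxima,
## and the battery of tests relating leading-edge classes to candidate
## drivers (gamma / quasi-binomial / quasi-Poisson GLMs, a linear model and
## chi-square association tests).

#' Kendall correlation with zero-footprint removal
#'
#' Pairs where the footprint is zero (which force the niche metrics to zero
#' as well) are removed before the two-sided Kendall rank correlation, to
#' prevent inflated correlation from structural zeros.
#'
#' @param footprint per-site footprint values.
#' @param metric per-site niche metric values.
#' @param min_pairs minimum retained pairs (default 5).
#' @return list with `tau`, `p`, `n`, `computed`.
#' @export
kendall_with_zero_removal <- function(footprint, metric, min_pairs = 5) {
  keep <- !is.na(footprint) & !is.na(metric) & footprint != 0
  if (sum(keep) < min_pairs)
    return(list(tau = NA_real_, p = NA_real_, n = sum(keep),
                computed = FALSE))
  ct <- suppressWarnings(stats::cor.test(footprint[keep], metric[keep],
                                         method = "kendall",
                                         alternative = "two.sided"))
  list(tau = unname(ct$estimate), p = ct$p.value, n = sum(keep),
       computed = TRUE)
}

#' Maximum zone-mean guild biomass per functional group
#'
#' For each functional group and thermal guild: the mean over transects of
#' the guild's summed biomass within each zone, and the maximum of those zone
#' means with the zone (and its representative latitude) attaining it.
#'
#' @param survey SurveyTable (one region).
#' @param partition `zone_partition`.
#' @param grouping `functional_grouping`.
#' @param traits TraitTable.
#' @param groups groups to evaluate (default: major groups).
#' @return data.frame: group, guild, max_biomass, zone, latitude.
#' @export
zone_guild_max_biomass <- function(survey, partition, grouping, traits,
                                   groups = NULL) {
  if (is.null(groups)) groups <- grouping$major_groups
  zone <- .transect_zones(survey, partition)
  grp_of <- grouping$assignments
  rows <- list()
  for (g in groups) {
    for (gu in c("tropical", "temperate")) {
      sp <- intersect(traits$species[traits$thermal_guild == gu],
                      names(grp_of)[grp_of == g])
      tot <- transect_totals(survey, sp)
      zm <- tapply(tot, zone, mean)
      zm <- zm[partition$zone_order[partition$zone_order %in% names(zm)]]
      best <- which.max(zm)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, guild = gu,
        max_biomass = as.numeric(zm[best]),
        zone = names(zm)[best],
        latitude = as.numeric(partition$zone_latitude[names(zm)[best]]),
        flag_absent = all(zm == 0),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.anova_f_row <- function(fit) {
  an <- stats::anova(fit, test = "F")
  i <- if (inherits(fit, "glm")) 2L else 1L
  fcol <- grep("^F", names(an), value = TRUE)[1]
  pcol <- grep("^Pr", names(an), value = TRUE)[1]
  resid_df <- if (inherits(fit, "glm")) an[["Resid. Df"]][i] else an$Df[nrow(an)]
  list(statistic = an[[fcol]][i], df1 = an$Df[i], df2 = resid_df,
       p = an[[pcol]][i])
}

#' Battery of leading-edge driver tests
#'
#' Each candidate driver is taken in turn as the response in a model against
#' the leading-edge class (as_expected / below_expectation /
#' well_below_expectation), combining regions: gamma GLMs (log link) for the
#' maximum tropical and temperate biomass, quasi-binomial GLMs for the
#' site-averaged overlap and tropical-area proportions, a quasi-Poisson GLM
#' for species richness, a linear model for the realised upper thermal limit,
#' and chi-square association tests (no continuity correction) for diet,
#' habitat position and region. Quasi-family inference uses
#' analysis-of-deviance F with Pearson dispersion. Rows with an undefined
#' response are dropped per test; a test whose response leaves fewer than two
#' classes is skipped with a note. No multiplicity correction is applied
#' (`p_adjusted` adds Benjamini-Hochberg values for optional use).
#'
#' @param data data.frame with one row per functional group x region:
#'   `class` plus any of `max_tropical`, `max_temperate`, `overlap`,
#'   `area_proportion`, `richness`, `thermal_limit`, `diet`, `position`,
#'   `region`. Rows with class "does_not_decline" are excluded by default.
#' @param include_nondeclining merge "does_not_decline" into "as_expected"
#'   instead of dropping those rows.
#' @param bh_adjust append Benjamini-Hochberg adjusted p-values.
#' @return data.frame of class `driver_tests`: test, family, statistic, df1,
#'   df2, p, n, note; per-class response summaries in the `class_summary`
#'   attribute.
#' @export
leading_edge_driver_tests <- function(data, include_nondeclining = FALSE,
                                      bh_adjust = TRUE) {
  data$class <- as.character(data$class)
  if (include_nondeclining) {
    data$class[data$class == "does_not_decline"] <- "as_expected"
  } else {
    data <- data[data$class != "does_not_decline", , drop = FALSE]
  }
  specs <- list(
    list(test = "max_tropical_biomass", response = "max_tropical",
         family = "gamma"),
    list(test = "max_temperate_biomass", response = "max_temperate",
         family = "gamma"),
    list(test = "niche_overlap", response = "overlap",
         family = "quasibinomial"),
    list(test = "tropical_area_proportion", response = "area_proportion",
         family = "quasibinomial"),
    list(test = "species_richness", response = "richness",
         family = "quasipoisson"),
    list(test = "thermal_limit", response = "thermal_limit",
         family = "gaussian"),
    list(test = "diet", response = "diet", family = "chisq"),
    list(test = "habitat_position", response = "position", family = "chisq"),
    list(test = "region", response = "region", family = "chisq"))
  rows <- list()
  summaries <- list()
  for (sp in specs) {
    if (!sp$response %in% names(data)) next
    y <- data[[sp$response]]
    keep <- !is.na(y) & !is.na(data$class)
    if (sp$family == "gamma") {
      bad <- which(keep & y <= 0)
      if (length(bad) > 0) {
        warning("non-positive response for gamma test '", sp$test,
                "' in row(s): ", paste(bad, collapse = ", "),
                "; dropped", call. = FALSE)
        keep[bad] <- FALSE
      }
    }
    d <- data[keep, , drop = FALSE]
    note <- ""
    if (length(unique(d$class)) < 2) {
      rows[[sp$test]] <- data.frame(test = sp$test, family = sp$family,
                                    statistic = NA_real_, df1 = NA, df2 = NA,
                                    p = NA_real_, n = nrow(d),
                                    note = "skipped: fewer than two classes",
                                    stringsAsFactors = FALSE)
      next
    }
    d$class <- factor(d$class)
    if (sp$family == "chisq") {
      tab <- table(d$class, d[[sp$response]])
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      if (any(ct$expected < 5)) note <- "expected counts < 5"
      res <- list(statistic = unname(ct$statistic),
                  df1 = unname(ct$parameter), df2 = NA, p = ct$p.value)
    } else {
      fit <- switch(sp$family,
        gamma = stats::glm(d[[sp$response]] ~ class, data = d,
                           family = stats::Gamma(link = "log")),
        quasibinomial = stats::glm(d[[sp$response]] ~ class, data = d,
                                   family = stats::quasibinomial()),
        quasipoisson = stats::glm(d[[sp$response]] ~ class, data = d,
                                  family = stats::quasipoisson()),
        gaussian = stats::lm(d[[sp$response]] ~ class, data = d))
      res <- .anova_f_row(fit)
    }
    rows[[sp$test]] <- data.frame(test = sp$test, family = sp$family,
                                  statistic = res$statistic, df1 = res$df1,
                                  df2 = res$df2, p = res$p, n = nrow(d),
                                  note = note, stringsAsFactors = FALSE)
    if (sp$family != "chisq")
      summaries[[sp$test]] <- do.call(rbind, lapply(
        split(d[[sp$response]], d$class), function(v)
          data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (bh_adjust) out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  attr(out, "class_summary") <- summaries
  class(out) <- c("driver_tests", "data.frame")
  out
}
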