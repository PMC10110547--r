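make_fp_inputs <- function(seed = 3) {
  sim <- generate_metacommunity(small_config(seed = seed))
  sz <- sim$truth$site_zone
  list(sim = sim,
       part = zone_partition(sz$site, sz$zone, sz$latitude),
       grp = as_functional_grouping(sim$truth$species_group, sim$traits))
}

test_that("footprints normalise to mean 1 over reference-zone transects
           and scale-invariance holds", {
  x <- make_fp_inputs()
  fp <- footprints(x$sim$survey, x$part, x$grp, x$sim$traits)
  ref <- fp$zone == "A"
  means <- tapply(fp$bt[ref], fp$group[ref], mean)
  expect_equal(as.numeric(means), rep(1, length(means)))
  # multiplying all biomass of one group by a constant leaves BT unchanged
  sv2 <- x$sim$survey
  g1 <- names(x$grp$assignments)[x$grp$assignments == 1]
  sel <- sv2$species %in% g1
  sv2$biomass[sel] <- sv2$biomass[sel] * 7
  fp2 <- footprints(sv2, x$part, x$grp, x$sim$traits)
  expect_equal(fp2$bt[fp2$group == "1"], fp$bt[fp$group == "1"])
  # community biomass is the sum of group biomass on every transect
  wide <- tapply(fp$biomass, list(paste(fp$site, fp$transect), fp$group), sum)
  grp_cols <- setdiff(colnames(wide), "community")
  expect_equal(rowSums(wide[, grp_cols]), wide[, "community"])
})

test_that("footprint arithmetic hits the 20-fold threshold exactly", {
  # b_ij = 2, b_bar = 40 -> BT = 0.05
  expect_equal(2 / 40, 0.05)
  x <- make_fp_inputs()
  fp <- footprints(x$sim$survey, x$part, x$grp, x$sim$traits)
  # transects without the guild's species give BT = 0
  expect_true(any(fp$bt == 0))
  expect_true(all(fp$bt >= 0))
})

test_that("fourth-root transform is monotone, exact on anchors and rejects
           negatives", {
  expect_equal(transform_fourth_root(0), 0)
  expect_equal(transform_fourth_root(1), 1)
  expect_equal(transform_fourth_root(0.0016), 0.2)
  x <- sort(runif(50))
  expect_true(all(diff(transform_fourth_root(x)) >= 0))
  expect_error(transform_fourth_root(-0.1), "non-negative")
})

test_that("groups with zero reference biomass are excluded with a warning", {
  x <- make_fp_inputs()
  sv <- x$sim$survey
  g9 <- names(x$grp$assignments)[x$grp$assignments == 9]
  ref_sites <- names(x$part$sites)[x$part$sites == "A"]
  drop <- sv$species %in% g9 & sv$site %in% ref_sites
  expect_warning(fp <- footprints(sv[!drop, ], x$part, x$grp, x$sim$traits),
                 "zero reference-zone biomass")
  expect_false("9" %in% fp$group)
})

test_that("zone mixed model reproduces group means with no site variance
           and flags no departures under the null", {
  set.seed(21)
  zones <- rep("B", 48)
  sites <- rep(sprintf("s%d", 1:4), each = 12)
  groups <- rep(rep(c("community", "g1", "g2"), each = 4), 4)
  bt <- rep(0.6, 48)                     # identical across groups
  fp <- data.frame(region = "r", zone = zones, site = sites, latitude = 26,
                   transect = rep(sprintf("t%d", 1:4), 12), group = groups,
                   biomass = bt, bt = bt,
                   bt_q = transform_fourth_root(bt))
  attr(fp, "reference_zone") <- "A"
  est <- suppressWarnings(zone_mixed_model(fp, "B"))
  expect_true(all(est$departure == 0))
  expect_equal(est$estimate, rep(0.6, 3), tolerance = 1e-8)
  # zero between-site variance: estimates equal plain group means
  fp$bt_q <- fp$bt_q + rep(c(0, 0.1, -0.2), each = 4)[rep(1:12, 4) %% 12 + 1]
  fp$bt_q <- transform_fourth_root(fp$bt) +
    ifelse(fp$group == "g1", 0.1, ifelse(fp$group == "g2", -0.2, 0))
  est2 <- suppressWarnings(zone_mixed_model(fp, "B"))
  for (g in c("community", "g1", "g2"))
    expect_equal(est2$estimate_q[est2$group == g],
                 mean(fp$bt_q[fp$group == g]), tolerance = 1e-6)
  expect_error(zone_mixed_model(fp, "A"), "reference")
})

test_that("a group generated five-fold above the community is detected as a
           positive departure in at least 90% of replicates", {
  detect <- logical(100)
  for (s in seq_len(100)) {
    set.seed(s)
    n_site <- 6; n_tr <- 4
    site <- rep(sprintf("s%d", 1:n_site), each = n_tr)
    site_eff <- rnorm(n_site, 0, 0.05)[rep(1:n_site, each = n_tr)]
    comm <- 0.2 * rlnorm(n_site * n_tr, site_eff, 0.3)
    g1 <- 1.0 * rlnorm(n_site * n_tr, site_eff, 0.3)   # 5x the community
    fp <- data.frame(region = "r", zone = "C",
                     site = rep(site, 2), latitude = 28,
                     transect = rep(rep(sprintf("t%d", 1:n_tr), n_site), 2),
                     group = rep(c("community", "g1"), each = n_site * n_tr),
                     biomass = c(comm, g1), bt = c(comm, g1),
                     bt_q = transform_fourth_root(c(comm, g1)))
    attr(fp, "reference_zone") <- "A"
    est <- suppressWarnings(zone_mixed_model(fp, "C"))
    detect[s] <- est$departure[est$group == "g1"] == 1
  }
  expect_gte(mean(detect), 0.9)
})

test_that("leading edges scan poleward, class against the community and
           respect threshold monotonicity", {
  part <- zone_partition(sprintf("s%d", 1:6), LETTERS[1:6], seq(24, 34, 2))
  est <- expand.grid(zone = LETTERS[2:6],
                     group = c("community", "g_match", "g_below",
                               "g_well", "g_never"),
                     stringsAsFactors = FALSE)
  prof <- list(community = c(0.8, 0.4, 0.2, 0.1, 0.03),
               g_match = c(0.9, 0.5, 0.3, 0.12, 0.04),
               g_below = c(0.6, 0.3, 0.1, 0.04, 0.01),
               g_well = c(0.5, 0.2, 0.04, 0.01, 0.005),
               g_never = c(1.2, 1.1, 0.9, 0.8, 0.7))
  est$estimate <- unlist(prof)[match(paste(est$group, est$zone),
                                     paste(rep(names(prof), each = 5),
                                           LETTERS[2:6]))]
  le <- leading_edge(est, part)
  expect_equal(le$edge_zone[le$group == "community"], "F")
  expect_equal(le$class[le$group == "g_match"], "as_expected")
  expect_equal(le$class[le$group == "g_below"], "below_expectation")
  expect_equal(le$class[le$group == "g_well"], "well_below_expectation")
  expect_equal(le$class[le$group == "g_never"], "does_not_decline")
  expect_true(is.na(le$edge_zone[le$group == "g_never"]))
  # a smaller threshold never gives a more equatorward edge
  zi <- function(th) match(leading_edge(est, part, threshold = th)$edge_zone,
                           part$zone_order)
  e1 <- zi(0.05); e2 <- zi(0.02)
  ok <- !is.na(e1) & !is.na(e2)
  expect_true(all(e2[ok] >= e1[ok]))
  expect_error(leading_edge(est[est$group != "community", ], part),
               "community")
})

test_that("synthetic leading edges match the configured decline zones", {
  cfg <- scenario_config(regions = data.frame(name = "north",
                                              hemisphere = 1), seed = 8)
  sim <- generate_metacommunity(cfg)
  sz <- sim$truth$site_zone
  part <- zone_partition(sz$site, sz$zone, sz$latitude)
  grp <- as_functional_grouping(sim$truth$species_group, sim$traits)
  fp <- footprints(sim$survey, part, grp, sim$traits)
  le <- leading_edge(zone_footprint_estimates(fp, part), part)
  truth <- sim$truth$group_edge
  got <- le$edge_zone[match(as.character(truth$group), le$group)]
  expect_equal(got, truth$edge_zone)
  expect_equal(le$edge_zone[le$group == "community"],
               sim$truth$community_edge_zone)
})
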