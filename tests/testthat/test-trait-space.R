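test_that("PCoA reproduces Euclidean configurations exactly with c = 0", {
  set.seed(3)
  pts <- matrix(rnorm(30), ncol = 3)
  d <- dist(pts)
  sp <- pcoa_cailliez(d, m = 3)
  expect_equal(sp$cailliez_constant, 0)
  expect_equal(as.numeric(dist(sp$all_coordinates)), as.numeric(d),
               tolerance = 1e-8)
  expect_true(all(diff(sp$variance_fraction) <= 1e-12))
  # collinear input has a single positive axis: m = 2 must error
  expect_error(pcoa_cailliez(dist(cbind(c(0, 1, 3, 6), 0)), m = 2),
               "positive-eigenvalue")
})

test_that("Cailliez correction makes a non-Euclidean matrix Euclidean with
           corrected distances equal to input + c", {
  d <- matrix(1, 4, 4); diag(d) <- 0; d[1, 2] <- d[2, 1] <- 3
  sp <- pcoa_cailliez(as.dist(d), m = 2)
  expect_gt(sp$cailliez_constant, 0)
  emb <- as.matrix(dist(sp$all_coordinates))
  want <- d + sp$cailliez_constant; diag(want) <- 0
  expect_equal(unname(emb), unname(want), tolerance = 1e-6)
  expect_equal(sum(sp$axis_pairs$weight), 1)
})

test_that("axis pairs enumerate all combinations with normalised variance
           weights", {
  sim <- generate_metacommunity(small_config(seed = 5))
  sp <- pcoa_cailliez(gower_distance(sim$traits), m = 4)
  expect_equal(nrow(sp$axis_pairs), 6)
  expect_equal(sum(sp$axis_pairs$weight), 1)
  v <- sp$variance_fraction
  w <- (v[sp$axis_pairs$axis1] + v[sp$axis_pairs$axis2])
  expect_equal(sp$axis_pairs$weight, w / sum(w))
  expect_true(all(v >= 0 & v <= 1) && all(diff(v) <= 1e-12))
})

test_that("kernel 99% UD area approaches the analytic Gaussian region and
           obeys the quadratic scaling law", {
  set.seed(1)
  pts <- matrix(rnorm(4000), ncol = 2)
  analytic <- pi * qchisq(0.99, 2)
  k <- kernel_ud(pts)
  expect_lt(abs(k$area - analytic) / analytic, 0.2)
  k2 <- kernel_ud(pts * 2)
  expect_lt(abs(k2$area / k$area - 4) / 4, 0.1)
  # error shrinks from n = 500 to n = 2000 on average over replicates
  set.seed(2)
  err <- sapply(c(500, 2000), function(n) mean(replicate(8, {
    p <- matrix(rnorm(2 * n), ncol = 2)
    abs(kernel_ud(p)$area - analytic)
  })))
  expect_lt(err[2], err[1])
})

test_that("degenerate point sets yield an undefined niche, never zero", {
  two <- matrix(c(0, 1, 0, 1), 2)
  k <- kernel_ud(two, min_points = 3)
  expect_false(k$defined)
  expect_true(is.na(k$area))
  same <- matrix(rep(c(1, 2), each = 5), ncol = 2)
  expect_false(kernel_ud(same)$defined)
})

test_that("overlap proportion follows containment logic on shared grids", {
  a <- matrix(FALSE, 5, 5); a[2:3, 2:3] <- TRUE
  b <- a
  expect_equal(overlap_proportion(a, b), 1)
  disj <- matrix(FALSE, 5, 5); disj[5, 5] <- TRUE
  expect_equal(overlap_proportion(a, disj), 0)
  nest <- matrix(TRUE, 5, 5)
  expect_equal(overlap_proportion(a, nest), 1)
  expect_true(is.na(overlap_proportion(matrix(FALSE, 5, 5), nest)))
  expect_error(overlap_proportion(a, matrix(FALSE, 4, 4)), "grid")
})

test_that("adding temperate species never decreases overlap on a fixed
           grid and bandwidth", {
  set.seed(7)
  trop <- matrix(rnorm(60), ncol = 2)
  temp <- matrix(rnorm(80, sd = 1.2), ncol = 2)
  grid <- niche_grid(rbind(trop, temp), pad = c(1, 1), grid_n = 100)
  kt <- kernel_ud(trop, grid = grid)
  ov <- numeric(0)
  for (n in c(10, 20, 40)) {
    ke <- kernel_ud(temp[seq_len(n), ], grid = grid)
    # fix the bandwidth effect by comparing nested masks directly
    ov <- c(ov, overlap_proportion(kt$mask, ke$mask))
  }
  expect_true(all(ov >= 0 & ov <= 1))
})

test_that("pair averaging applies variance weights and the zero-forcing
           rule", {
  w <- c(0.3, 0.25, 0.2, 0.1, 0.1, 0.05)
  vals <- (1:6) / 10
  expect_equal(tropicalize:::.pair_average(vals, w), sum(vals * w))
  expect_equal(tropicalize:::.pair_average(rep(0.5, 6), w), 0.5)
  expect_equal(tropicalize:::.pair_average(c(0.2, 0.3, 0, 0.1, 0.2, 0.3), w,
                                           zero_force = TRUE), 0)
  expect_true(is.na(tropicalize:::.pair_average(rep(NA_real_, 6), w)))
})

test_that("site niche metrics flag undefined kernels and force zero
           overlap through the site average", {
  sim <- generate_metacommunity(small_config(seed = 9))
  tr <- sim$truth
  sz <- tr$site_zone
  part <- zone_partition(sz$site, sz$zone, sz$latitude)
  grp <- as_functional_grouping(tr$species_group, sim$traits)
  sp <- set_space_guilds(pcoa_cailliez(gower_distance(sim$traits), 4),
                         sim$traits)
  nm <- site_group_niche_metrics(sim$survey, part, grp, sp, grid_n = 60,
                                 groups = c(1, 9))
  expect_true(all(nm$overlap >= 0 & nm$overlap <= 1, na.rm = TRUE))
  expect_true(all(nm$tropical_area_proportion >= 0, na.rm = TRUE))
  # the all-tropical group (9) can never have overlap
  expect_true(all(is.na(nm$overlap[nm$group == 9])))
  # zero forcing: any zero pair overlap zeroes the average
  pair_cols <- grep("overlap_pair", names(nm))
  has_zero <- apply(nm[pair_cols] == 0, 1, any, na.rm = TRUE) &
    apply(!is.na(nm[pair_cols]), 1, any)
  expect_true(all(nm$overlap[has_zero] == 0, na.rm = TRUE))
})

test_that("environmental filtering contracts tropical niche area poleward
           when marginal species are removed", {
  # construct filtering directly: high-latitude sites retain only the
  # species closest to the group centroid
  set.seed(12)
  tr <- generate_trait_clusters(small_config(seed = 12))
  grp_truth <- attr(tr, "group_truth")
  sp1 <- names(grp_truth)[grp_truth == 1 & tr$thermal_guild == "tropical"]
  space <- set_space_guilds(pcoa_cailliez(gower_distance(tr), 4), tr)
  centre <- colMeans(space$coordinates[sp1, ])
  rank_dev <- order(sqrt(colSums((t(space$coordinates[sp1, ]) - centre)^2)))
  lats <- seq(24, 34, length.out = 8)
  keep_n <- round(seq(length(sp1), max(4, length(sp1) / 2),
                      length.out = 8))
  rows <- do.call(rbind, lapply(seq_along(lats), function(i) {
    sp <- sp1[rank_dev[seq_len(keep_n[i])]]
    data.frame(region = "r", site = sprintf("s%02d", i),
               latitude = lats[i], transect = "t1", species = sp,
               biomass = 1, stringsAsFactors = FALSE)
  }))
  part <- zone_partition(sprintf("s%02d", 1:8),
                         rep(c("A", "B", "C", "D"), each = 2), lats)
  grp <- as_functional_grouping(grp_truth, tr)
  nm <- site_group_niche_metrics(rows, part, grp, space, grid_n = 60,
                                 groups = 1)
  ef <- environmental_filtering_signal(nm)
  ct <- cor.test(ef$latitude, ef$area_proportion, method = "kendall")
  expect_lt(ct$estimate, 0)
  # parity at the site holding the full reference pool
  expect_equal(ef$area_proportion[1], 1, tolerance = 1e-6)
})
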