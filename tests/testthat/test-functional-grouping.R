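test_that("Gower distance matches hand arithmetic on canonical cases", {
  tr <- data.frame(species = c("a", "b"),
                   diet = c("herbivore", "predator"),
                   habitat_association = c("benthic", "benthic"),
                   body_size = c(10, 10), aggregation = c(2L, 2L),
                   depth_range = c(20, 20),
                   thermal_guild = "tropical", stringsAsFactors = FALSE)
  # identical rows -> 0
  same <- tr; same$diet <- "herbivore"
  expect_equal(as.numeric(gower_distance(same)), 0)
  # one mismatching trait of five -> 0.2
  expect_equal(as.numeric(gower_distance(tr)), 0.2)
  # one mismatch of four comparable traits after a missing depth -> 0.25
  miss <- tr; miss$depth_range[1] <- NA
  expect_equal(as.numeric(gower_distance(miss)), 0.25)
})

test_that("Gower agrees with the brute-force oracle and daisy to 1e-12", {
  set.seed(8)
  tr <- toy_traits()
  tr$depth_range[c(2, 7)] <- NA
  tr$diet[4] <- NA
  d <- gower_distance(tr)
  expect_equal(as.numeric(d), as.numeric(gower_brute(tr)), tolerance = 1e-12)
  expect_true(all(d >= 0 & d <= 1))
  dm <- as.matrix(d)
  expect_equal(dm, t(dm))
  # independent library cross-check: daisy on pre-transformed traits
  if (requireNamespace("cluster", quietly = TRUE)) {
    df <- data.frame(diet = factor(tr$diet),
                     hab = factor(tr$habitat_association),
                     bs = log(tr$body_size),
                     agg = ordered(tr$aggregation),
                     dr = log(tr$depth_range))
    dd <- cluster::daisy(df, metric = "gower")
    expect_equal(as.numeric(d), as.numeric(dd), tolerance = 1e-12)
  }
})

test_that("Gower errors on pairs with no comparable trait", {
  tr <- toy_traits(2)[1:2, ]
  tr[1, c("diet", "habitat_association", "body_size")] <- NA
  tr$aggregation[1] <- NA; tr$depth_range[1] <- NA
  expect_error(gower_distance(tr), "no comparable traits")
})

test_that("UPGMA species clustering recovers archetypes and handles
           degenerate cuts", {
  tr <- toy_traits()
  d <- gower_distance(tr)
  gr <- cluster_species(d, 2, tr)
  expect_equal(unname(gr$assignments[1:5]), rep(gr$assignments[[1]], 5))
  expect_equal(length(unique(gr$assignments)), 2)
  singletons <- cluster_species(d, nrow(tr))
  expect_equal(length(unique(singletons$assignments)), nrow(tr))
  expect_error(cluster_species(d, 1), "k")
  # invariance to species row order
  perm <- sample(nrow(tr))
  gr2 <- cluster_species(gower_distance(tr[perm, ]), 2, tr)
  expect_equal(rand_index(gr2$assignments[names(gr$assignments)],
                          gr$assignments), 1)
})

test_that("cophenetic fidelity is 1 for ultrametric input and matches the
           direct correlation otherwise", {
  # ultrametric: two tight pairs far apart
  u <- matrix(c(0, 1, 5, 5,
                1, 0, 5, 5,
                5, 5, 0, 1,
                5, 5, 1, 0), 4)
  du <- as.dist(u)
  tu <- hclust(du, method = "average")
  expect_equal(cophenetic_fidelity(du, tu), 1)
  set.seed(2)
  tr <- toy_traits()
  d <- gower_distance(tr)
  t2 <- hclust(d, method = "average")
  expect_equal(cophenetic_fidelity(d, t2),
               cor(as.numeric(d), as.numeric(cophenetic(t2))))
  expect_lte(abs(cophenetic_fidelity(d, t2)), 1)
})

test_that("Rand, adjusted Rand and clusterwise Jaccard match brute force
           and e1071", {
  set.seed(5)
  a <- sample(1:3, 30, replace = TRUE)
  b <- sample(1:4, 30, replace = TRUE)
  expect_equal(rand_index(a, b), rand_brute(a, b), tolerance = 1e-12)
  expect_equal(rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(jaccard_stability(a, a), 1)
  if (requireNamespace("e1071", quietly = TRUE)) {
    ca <- e1071::classAgreement(table(a, b))
    expect_equal(rand_index(a, b), ca$rand, tolerance = 1e-12)
    expect_equal(adjusted_rand_index(a, b), ca$crand, tolerance = 1e-12)
  }
  # hand case: one cluster split in two halves
  orig <- rep(1, 4); boot <- c(1, 1, 2, 2)
  expect_equal(jaccard_stability(orig, boot), 0.5)
})

test_that("bootstrap stability is deterministic, near-perfect on separated
           archetypes, and degrades without structure", {
  tr <- toy_traits(12)
  p1 <- bootstrap_stability(tr, k_range = 2:4, n_boot = 25, seed = 3)
  p2 <- bootstrap_stability(tr, k_range = 2:4, n_boot = 25, seed = 3)
  expect_identical(p1, p2)
  expect_gte(p1$jaccard[p1$k == 2], 0.99)
  expect_gte(p1$rand[p1$k == 2], 0.99)
  expect_true(all(p1$jaccard >= 0 & p1$jaccard <= 1))
  expect_true(all(p1$rand >= 0 & p1$rand <= 1))
  expect_true(all(abs(p1$silhouette) <= 1))
  # i.i.d. uniform traits: stability at k = 9 lower than for the structured
  # nine-archetype scenario at k = 9
  set.seed(6)
  n <- 120
  unstructured <- data.frame(
    species = sprintf("u%03d", 1:n),
    diet = sample(letters[1:6], n, TRUE),
    habitat_association = sample(letters[1:3], n, TRUE),
    body_size = runif(n, 5, 60), aggregation = sample(1:5, n, TRUE),
    depth_range = runif(n, 5, 50), thermal_guild = "tropical",
    stringsAsFactors = FALSE)
  structured <- generate_trait_clusters(small_config(seed = 6))
  pu <- bootstrap_stability(unstructured, k_range = 9, n_boot = 20, seed = 1)
  ps <- bootstrap_stability(structured, k_range = 9, n_boot = 20, seed = 1)
  expect_lt(pu$jaccard, ps$jaccard)
  expect_error(bootstrap_stability(toy_traits(3), k_range = 2:10), "retained")
})

test_that("select_k follows the silhouette/Jaccard rule with warning
           fallbacks", {
  prof <- data.frame(k = 2:6,
                     silhouette = c(0.2, 0.5, 0.7, 0.4, 0.3),
                     jaccard = c(0.9, 0.9, 0.9, 0.9, 0.9))
  expect_equal(select_k(prof), 4)
  flat <- data.frame(k = 2:4, silhouette = c(0.3, 0.3, 0.3),
                     jaccard = c(0.5, 0.5, 0.5))
  expect_warning(kf <- select_k(flat), "argmax")
  expect_equal(kf, 2)
  expect_warning(ku <- select_k(prof, jaccard_min = 1.01), "argmax")
  expect_equal(ku, 4)
})

test_that("group characterisation reports normalised frequencies and
           recovers archetype levels", {
  sim <- generate_metacommunity(small_config(seed = 4))
  grp <- as_functional_grouping(sim$truth$species_group, sim$traits)
  ch <- characterise_groups(grp, sim$traits)
  sums <- aggregate(freq ~ group + trait, data = ch, FUN = sum)
  expect_true(all(abs(sums$freq - 1) < 1e-12))
  arch <- small_config()$archetypes
  for (g in seq_len(9)) {
    dom <- ch[ch$group == g & ch$trait == "diet" & ch$dominant, "level"]
    expect_equal(dom[1], arch$diet[g])
  }
})

test_that("functional grouping recovers the generating archetypes on the
           default scenario", {
  sim <- generate_metacommunity(scenario_config(seed = 1))
  gr <- cluster_species(gower_distance(sim$traits), 9, sim$traits)
  truth <- sim$truth$species_group[names(gr$assignments)]
  expect_gte(rand_index(gr$assignments, truth), 0.95)
})

test_that("dendrograms export to Newick with all species as leaves", {
  tr <- toy_traits()
  gr <- cluster_species(gower_distance(tr), 2)
  txt <- dendrogram_newick(gr$tree)
  expect_match(txt, "^\\(")
  expect_true(all(vapply(tr$species, grepl, logical(1), x = txt,
                         fixed = TRUE)))
})
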