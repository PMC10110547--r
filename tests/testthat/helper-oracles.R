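# Brute-force oracles, kept deliberately naive and independent of the
# package implementations they check.

# Gower over the five traits: per-pair loop, pairwise deletion, range scaling
# on log body size / log depth range and on aggregation ranks.
gower_brute <- function(traits, ranges = NULL) {
  n <- nrow(traits)
  if (is.null(ranges))
    ranges <- list(body_size = range(log(traits$body_size), na.rm = TRUE),
                   depth_range = range(log(traits$depth_range), na.rm = TRUE),
                   aggregation = range(traits$aggregation, na.rm = TRUE))
  d <- matrix(0, n, n, dimnames = list(traits$species, traits$species))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0; cnt <- 0
    for (tr in c("diet", "habitat_association")) {
      a <- traits[[tr]][i]; b <- traits[[tr]][j]
      if (!is.na(a) && !is.na(b)) { num <- num + (a != b); cnt <- cnt + 1 }
    }
    for (tr in c("body_size", "aggregation", "depth_range")) {
      a <- traits[[tr]][i]; b <- traits[[tr]][j]
      if (!is.na(a) && !is.na(b)) {
        if (tr != "aggregation") { a <- log(a); b <- log(b) }
        span <- diff(ranges[[tr]])
        if (span > 0) num <- num + abs(a - b) / span
        cnt <- cnt + 1
      }
    }
    d[i, j] <- num / cnt
  }
  as.dist(d)
}

bray_brute <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Kendall tau by enumeration of all pairs (no ties expected in usage).
kendall_brute <- function(x, y) {
  s <- 0; n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
  s / choose(n, 2)
}

chisq_brute <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Rand index by explicit pair agreement.
rand_brute <- function(a, b) {
  n <- length(a); agree <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / choose(n, 2)
}

# Small complete trait table with two well-separated archetypes.
toy_traits <- function(n_per = 5) {
  n <- 2 * n_per
  data.frame(
    species = sprintf("sp%02d", seq_len(n)),
    diet = rep(c("herbivore", "predator"), each = n_per),
    habitat_association = rep(c("benthic", "demersal"), each = n_per),
    body_size = rep(c(10, 50), each = n_per) + rep(seq_len(n_per), 2),
    aggregation = rep(c(1L, 5L), each = n_per),
    depth_range = rep(c(12, 45), each = n_per) + rep(seq_len(n_per), 2),
    thermal_guild = rep(c("tropical", "temperate"), length.out = n),
    stringsAsFactors = FALSE)
}

# Minimal valid survey table: two sites x two transects x two species.
toy_survey <- function() {
  g <- expand.grid(species = c("spA", "spB"), transect = c("t1", "t2"),
                   site = c("s1", "s2"), stringsAsFactors = FALSE)
  data.frame(
    region = "r1", site = g$site,
    latitude = ifelse(g$site == "s1", 24, 30),
    transect = g$transect, species = g$species,
    biomass = c(2, 1, 4, 3, 0.5, 0.2, 0.3, 0.1),
    stringsAsFactors = FALSE)
}

# Fast scenario for pipeline tests: one region, fewer species.
small_config <- function(seed = 1, ...) {
  scenario_config(regions = data.frame(name = "north", hemisphere = 1),
                  n_sites = 18, n_species = 120, seed = seed, ...)
}
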