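## Functional-group identification: Gower distances over five mixed-type
## traits (body size and depth range log-transformed, aggregation ordinal),
## UPGMA clustering, and a bootstrap cluster-stability profile (silhouette,
## clusterwise Jaccard, Rand) over a range of cluster counts.

.gower_traits <- c("diet", "habitat_association", "body_size", "aggregation",
                   "depth_range")

#' Trait ranges used for Gower scaling
#'
#' Observed ranges of the quantitative traits on their analysis scales
#' (log body size, log depth range, aggregation ranks). Passing these ranges
#' back into [gower_distance()] fixes the scaling — the bootstrap-stability
#' procedure recomputes distances on species subsets while scaling by the
#' original full-table ranges so distances stay comparable across iterations.
#'
#' @param traits TraitTable.
#' @return named list of c(min, max) per quantitative trait.
#' @export
trait_ranges <- function(traits) {
  list(body_size = range(log(traits$body_size), na.rm = TRUE),
       depth_range = range(log(traits$depth_range), na.rm = TRUE),
       aggregation = range(as.numeric(traits$aggregation), na.rm = TRUE))
}

#' Gower distance between species from mixed-type traits
#'
#' Per species pair, the mean over comparable traits of: 0/1 mismatch for the
#' nominal traits (diet, habitat association); range-scaled absolute
#' difference of log body size and log depth range; and rank-scaled absolute
#' difference of the ordinal aggregation level. Traits missing in either
#' species of a pair are excluded and the mean renormalised over the remaining
#' traits (no imputation). A trait with zero range contributes zero but still
#' counts as comparable.
#'
#' @param traits TraitTable with at least the five functional traits.
#' @param ranges optional list from [trait_ranges()] fixing the quantitative
#'   scaling (defaults to the ranges observed in `traits`).
#' @return `dist` with species labels; values in [0, 1].
#' @export
gower_distance <- function(traits, ranges = NULL) {
  if (nrow(traits) < 2) stop("need at least two species", call. = FALSE)
  if (is.null(ranges)) ranges <- trait_ranges(traits)
  n <- nrow(traits)
  num <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  add_nominal <- function(x) {
    ok <- !is.na(x)
    comp <- outer(ok, ok, "&")
    mis <- outer(x, x, "!=") & comp
    num <<- num + ifelse(mis, 1, 0)
    cnt <<- cnt + comp
  }
  add_numeric <- function(x, rng) {
    ok <- is.finite(x)
    comp <- outer(ok, ok, "&")
    span <- diff(rng)
    if (span > 0) {
      dx <- abs(outer(x, x, "-")) / span
      dx[!comp] <- 0
      num <<- num + dx
    }
    cnt <<- cnt + comp
  }
  add_nominal(as.character(traits$diet))
  add_nominal(as.character(traits$habitat_association))
  add_numeric(log(traits$body_size), ranges$body_size)
  add_numeric(as.numeric(traits$aggregation), ranges$aggregation)
  add_numeric(log(traits$depth_range), ranges$depth_range)
  none <- cnt == 0
  diag(none) <- FALSE
  if (any(none)) {
    ij <- which(none, arr.ind = TRUE)[1, ]
    stop("species pair with no comparable traits: ",
         traits$species[ij[1]], " / ", traits$species[ij[2]], call. = FALSE)
  }
  d <- num / cnt
  diag(d) <- 0
  dimnames(d) <- list(traits$species, traits$species)
  stats::as.dist(d)
}

#' Cluster species into functional groups
#'
#' UPGMA (average-linkage) clustering of the Gower distance matrix, cut at
#' `k` groups. Groups holding at least `major_threshold` of the species are
#' flagged as major groups.
#'
#' @param d species `dist` (e.g. from [gower_distance()]).
#' @param k number of groups, 2..n.
#' @param traits optional TraitTable supplying thermal guilds for per-group
#'   guild counts.
#' @param major_threshold minimum species share of a "major" group.
#' @return object of class `functional_grouping`: list with `assignments`
#'   (named integer vector), `k`, `sizes`, `guild_counts`, `major_groups`,
#'   `tree`.
#' @export
cluster_species <- function(d, k, traits = NULL, major_threshold = 0.02) {
  n <- attr(d, "Size")
  if (k < 2 || k > n)
    stop("k must lie between 2 and the number of species", call. = FALSE)
  tree <- stats::hclust(d, method = "average")
  assignments <- stats::cutree(tree, k = k)
  sizes <- table(assignments)
  guild_counts <- NULL
  if (!is.null(traits)) {
    guild <- traits$thermal_guild[match(names(assignments), traits$species)]
    guild_counts <- table(group = assignments, guild = guild)
  }
  out <- list(assignments = assignments, k = k,
              sizes = as.integer(sizes),
              guild_counts = guild_counts,
              major_groups = as.integer(names(sizes)[sizes / n >=
                                                       major_threshold]),
              tree = tree)
  class(out) <- "functional_grouping"
  out
}

#' @export
print.functional_grouping <- function(x, ...) {
  cat("Functional grouping: ", length(x$assignments), " species in ", x$k,
      " groups (", length(x$major_groups), " major)\n", sep = "")
  print(x$sizes)
  invisible(x)
}

#' Cophenetic correlation between a tree and its source distances
#'
#' Measures how faithfully the dendrogram represents the original
#' dissimilarities; 1 for ultrametric input reproduced exactly by UPGMA.
#'
#' @param d the original `dist`.
#' @param tree an `hclust` built from `d`.
#' @return Pearson correlation over all pairs, in [-1, 1].
#' @export
cophenetic_fidelity <- function(d, tree) {
  stats::cor(as.numeric(d), as.numeric(stats::cophenetic(tree)))
}

#' Rand index between two partitions
#'
#' Unadjusted Rand: the fraction of species pairs on which the two partitions
#' agree (together in both, or apart in both).
#'
#' @param a,b cluster label vectors over the same elements.
#' @return value in [0, 1].
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length", call. = FALSE)
  tab <- table(a, b)
  n <- length(a)
  s_ij <- sum(choose(tab, 2))
  s_a <- sum(choose(rowSums(tab), 2))
  s_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * s_ij - s_a - s_b) / total
}

#' Adjusted Rand index between two partitions
#' @inheritParams rand_index
#' @return chance-corrected agreement, 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  s_ij <- sum(choose(tab, 2))
  s_a <- sum(choose(rowSums(tab), 2))
  s_b <- sum(choose(colSums(tab), 2))
  expected <- s_a * s_b / choose(n, 2)
  maximum <- (s_a + s_b) / 2
  if (maximum == expected) return(1)
  (s_ij - expected) / (maximum - expected)
}

#' Clusterwise Jaccard stability
#'
#' Each cluster of the original partition is matched to the bootstrap cluster
#' maximising Jaccard similarity |A∩B| / |A∪B|; the unweighted mean of these
#' best matches is returned (Hennig-style cluster stability).
#'
#' @param original,bootstrap cluster label vectors over the same elements.
#' @return mean best-match Jaccard, in [0, 1].
#' @export
jaccard_stability <- function(original, bootstrap) {
  tab <- table(original, bootstrap)
  ra <- rowSums(tab)
  cb <- colSums(tab)
  uni <- outer(ra, cb, "+") - tab
  mean(apply(tab / uni, 1, max))
}

#' Bootstrap cluster-stability profile over a range of cluster counts
#'
#' In each of `n_boot` iterations a fraction `omit_fraction` of the species is
#' dropped at random, Gower distances are recomputed on the retained species
#' using the full-table trait ranges for scaling, and the retained species are
#' re-clustered by UPGMA. For every `k` in `k_range` both the original tree
#' (restricted to the retained species) and the bootstrap tree are cut, and
#' the iteration records the mean silhouette width of the bootstrap partition,
#' the clusterwise Jaccard between original and bootstrap partitions, and
#' their (unadjusted and adjusted) Rand indices. Means and standard deviations
#' across iterations are returned per `k`.
#'
#' @param traits TraitTable.
#' @param k_range integer vector of cluster counts (default 2..30).
#' @param n_boot bootstrap iterations (default 1000).
#' @param omit_fraction fraction of species omitted per iteration.
#' @param seed integer seed.
#' @return data.frame of class `cluster_stability`, one row per `k`:
#'   `silhouette`, `jaccard`, `rand`, `adj_rand` with `*_sd` companions.
#' @export
bootstrap_stability <- function(traits, k_range = 2:30, n_boot = 1000,
                                omit_fraction = 0.05, seed = 1) {
  n <- nrow(traits)
  n_drop <- ceiling(omit_fraction * n)
  if (n - n_drop < max(k_range) + 1)
    stop("k_range exceeds the number of retained species", call. = FALSE)
  ranges <- trait_ranges(traits)
  d_full <- gower_distance(traits, ranges)
  tree_full <- stats::hclust(d_full, method = "average")
  cuts_full <- as.matrix(stats::cutree(tree_full, k = k_range))
  set.seed(seed)
  acc <- array(NA_real_, dim = c(n_boot, length(k_range), 4),
               dimnames = list(NULL, k_range,
                               c("silhouette", "jaccard", "rand", "adj_rand")))
  for (it in seq_len(n_boot)) {
    keep <- sort(sample.int(n, n - n_drop))
    d_b <- gower_distance(traits[keep, , drop = FALSE], ranges)
    tree_b <- stats::hclust(d_b, method = "average")
    cuts_b <- as.matrix(stats::cutree(tree_b, k = k_range))
    for (j in seq_along(k_range)) {
      part_o <- cuts_full[keep, j]
      part_b <- cuts_b[, j]
      sil <- cluster::silhouette(part_b, d_b)
      acc[it, j, "silhouette"] <- mean(sil[, "sil_width"])
      acc[it, j, "jaccard"] <- jaccard_stability(part_o, part_b)
      acc[it, j, "rand"] <- rand_index(part_o, part_b)
      acc[it, j, "adj_rand"] <- adjusted_rand_index(part_o, part_b)
    }
  }
  m_of <- function(stat) apply(acc[, , stat, drop = FALSE], 2, mean)
  sd_of <- function(stat) apply(acc[, , stat, drop = FALSE], 2, stats::sd)
  out <- data.frame(k = k_range,
                    silhouette = m_of("silhouette"), jaccard = m_of("jaccard"),
                    rand = m_of("rand"), adj_rand = m_of("adj_rand"),
                    silhouette_sd = sd_of("silhouette"),
                    jaccard_sd = sd_of("jaccard"), rand_sd = sd_of("rand"),
                    row.names = NULL)
  attr(out, "n_boot") <- n_boot
  attr(out, "omit_fraction") <- omit_fraction
  attr(out, "seed") <- seed
  class(out) <- c("cluster_stability", "data.frame")
  out
}

#' Select the number of functional groups from a stability profile
#'
#' Default rule: the smallest `k` at a local maximum of mean silhouette width
#' whose mean clusterwise Jaccard reaches `jaccard_min`. The full profile
#' should always be inspected alongside — the rule is an explicit, automatable
#' stand-in for visual selection. If no `k` satisfies the rule the silhouette
#' argmax is returned with a warning.
#'
#' @param profile a `cluster_stability` data.frame.
#' @param jaccard_min minimum mean Jaccard stability (default 0.75).
#' @return selected `k`.
#' @export
select_k <- function(profile, jaccard_min = 0.75) {
  if (nrow(profile) == 0) stop("empty stability profile", call. = FALSE)
  s <- profile$silhouette
  local_max <- vapply(seq_along(s), function(i) {
    left <- if (i == 1) -Inf else s[i - 1]
    right <- if (i == length(s)) -Inf else s[i + 1]
    s[i] >= left && s[i] >= right
  }, logical(1))
  ok <- which(local_max & profile$jaccard >= jaccard_min)
  if (length(ok) > 0) return(profile$k[ok[1]])
  warning("no k satisfies the selection rule; returning silhouette argmax",
          call. = FALSE)
  profile$k[which.max(s)]
}

#' Within-group trait-level frequencies
#'
#' For each functional group, the frequency of every level of the categorical
#' traits (diet, habitat association, aggregation) among the group's species,
#' ignoring missing values; the dominant diet and habitat levels (used for
#' naming groups) are flagged. Group medians of the continuous traits are
#' attached as an attribute.
#'
#' @param grouping a `functional_grouping`.
#' @param traits TraitTable.
#' @return data.frame (group, trait, level, freq, dominant) with a
#'   `numeric_summary` attribute.
#' @export
characterise_groups <- function(grouping, traits) {
  idx <- match(names(grouping$assignments), traits$species)
  g <- grouping$assignments
  rows <- list()
  for (tr in c("diet", "habitat_association", "aggregation")) {
    x <- as.character(traits[[tr]][idx])
    for (grp in sort(unique(g))) {
      xv <- x[g == grp & !is.na(x)]
      if (length(xv) == 0) next
      f <- table(xv) / length(xv)
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, trait = tr, level = names(f), freq = as.numeric(f),
        dominant = tr %in% c("diet", "habitat_association") &
          as.numeric(f) == max(as.numeric(f)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  num <- do.call(rbind, lapply(sort(unique(g)), function(grp) data.frame(
    group = grp,
    body_size = stats::median(traits$body_size[idx][g == grp], na.rm = TRUE),
    depth_range = stats::median(traits$depth_range[idx][g == grp],
                                na.rm = TRUE))))
  attr(out, "numeric_summary") <- num
  out
}

#' Export a dendrogram as a Newick string
#'
#' Species are leaves; branch lengths derive from UPGMA merge heights.
#'
#' @param tree an `hclust`.
#' @param path optional file to write to.
#' @return Newick string, invisibly if written to file.
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Summary numbers for a deposited species/trait/assignment table
#'
#' Computes, from any trait table with functional-group assignments in the
#' package's CSV dialect: the species share held by the nine largest groups,
#' the variance fractions of the leading PCoA axes of the Gower trait space,
#' and the per-trait missing-value counts.
#'
#' @param traits TraitTable.
#' @param group vector of functional-group assignments aligned with `traits`
#'   rows (defaults to a `group` column of `traits`).
#' @param n_major number of largest groups to pool (default 9).
#' @param m number of PCoA axes to report.
#' @return list with `major_share`, `axis_variance`, `n_missing`.
#' @export
deposited_table_summary <- function(traits, group = traits$group,
                                    n_major = 9, m = 4) {
  stopifnot(length(group) == nrow(traits))
  sizes <- sort(table(group), decreasing = TRUE)
  major_share <- sum(sizes[seq_len(min(n_major, length(sizes)))]) /
    nrow(traits)
  space <- pcoa_cailliez(gower_distance(traits), m = m)
  list(major_share = 100 * as.numeric(major_share),
       axis_variance = 100 * space$variance_fraction,
       n_missing = vapply(.gower_traits, function(tr)
         sum(is.na(traits[[tr]])), integer(1)))
}
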