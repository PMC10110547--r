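## Functional trait space and kernel niche metrics.
##
## Species are embedded by principal coordinates analysis of the Gower
## distances with the Cailliez correction; the first m axes (default 4) form
## all unordered axis pairs (m = 4 -> 6 two-dimensional spaces). Within each
## 2-D space the functional niche of a species set is the 99% utilisation
## distribution of a product-Gaussian kernel over the species' points, and
## tropical-temperate overlap is the fraction of the tropical niche covered by
## the temperate niche. Per-pair metrics are averaged with weights
## proportional to the summed variance fractions of each pair's axes.

## Cailliez constant: smallest c such that D + c (off-diagonal) is Euclidean,
## from the largest eigenvalue of the standard 2n x 2n companion matrix.
.cailliez_constant <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  ctr <- diag(n) - matrix(1 / n, n, n)
  delta1 <- ctr %*% (-0.5 * dm^2) %*% ctr
  delta2 <- ctr %*% (-0.5 * dm) %*% ctr
  big <- rbind(cbind(matrix(0, n, n), 2 * delta1),
               cbind(-diag(n), -4 * delta2))
  ev <- eigen(big, only.values = TRUE)$values
  max(0, max(Re(ev[abs(Im(ev)) < 1e-8])))
}

#' Principal coordinates trait space with Cailliez correction
#'
#' Classical PCoA of a dissimilarity matrix. If the double-centred matrix is
#' not positive semi-definite, the smallest Cailliez constant `c` is added to
#' all off-diagonal dissimilarities to make the configuration Euclidean. The
#' first `m` axes are retained, with variance fractions relative to the total
#' positive eigenvalue mass after correction, and all unordered axis pairs are
#' enumerated with normalised variance weights.
#'
#' @param d species `dist` (e.g. Gower).
#' @param m number of retained axes (default 4).
#' @return object of class `trait_space`: list with `coordinates` (n x m),
#'   `variance_fraction`, `cailliez_constant`, `axis_pairs` (data.frame
#'   axis1, axis2, weight summing to 1), `all_coordinates`.
#' @export
pcoa_cailliez <- function(d, m = 4) {
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  p <- ape::pcoa(d, correction = "cailliez")
  corrected <- identical(p$correction[1], "cailliez") &&
    !is.null(p$vectors.cor)
  if (corrected) {
    coords <- p$vectors.cor
    relative <- p$values$Rel_corr_eig
    cc <- .cailliez_constant(d)
  } else {
    coords <- p$vectors
    relative <- p$values$Relative_eig
    cc <- 0
  }
  if (m > ncol(coords))
    stop("m exceeds the number of positive-eigenvalue axes (",
         ncol(coords), ")", call. = FALSE)
  pairs <- t(utils::combn(m, 2))
  vf <- relative[seq_len(m)]
  w <- vf[pairs[, 1]] + vf[pairs[, 2]]
  out <- list(coordinates = coords[, seq_len(m), drop = FALSE],
              variance_fraction = vf,
              cailliez_constant = cc,
              axis_pairs = data.frame(axis1 = pairs[, 1], axis2 = pairs[, 2],
                                      weight = w / sum(w)),
              all_coordinates = coords)
  class(out) <- "trait_space"
  out
}

#' @export
print.trait_space <- function(x, ...) {
  cat("Trait space:", nrow(x$coordinates), "species on",
      ncol(x$coordinates), "axes\n")
  cat("variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  cat("Cailliez constant:", format(x$cailliez_constant, digits = 4), "\n")
  invisible(x)
}

#' Regular evaluation grid covering a point set
#'
#' @param points 2-column coordinate matrix.
#' @param pad padding beyond the point extent (typically one bandwidth).
#' @param grid_n cells per axis.
#' @return list with axis vectors `x`, `y` and `cell_area`.
#' @export
niche_grid <- function(points, pad, grid_n = 150) {
  x <- seq(min(points[, 1]) - pad[1], max(points[, 1]) + pad[1],
           length.out = grid_n)
  y <- seq(min(points[, 2]) - pad[2], max(points[, 2]) + pad[2],
           length.out = grid_n)
  list(x = x, y = y, cell_area = diff(x[1:2]) * diff(y[1:2]))
}

#' Per-axis normal-reference kernel bandwidth
#'
#' `h_j = sd_j * n^(-1/6)` per axis, the bivariate normal reference rule of
#' kernel home-range estimation, times an optional scalar multiplier.
#'
#' @param points 2-column coordinate matrix.
#' @param multiplier scalar bandwidth multiplier.
#' @return length-2 bandwidth vector (0 where an axis is degenerate).
#' @export
ud_bandwidth <- function(points, multiplier = 1) {
  n <- nrow(points)
  multiplier * apply(points, 2, stats::sd) * n^(-1 / 6)
}

#' Kernel utilisation-distribution niche area
#'
#' Product-Gaussian kernel density of the species' points evaluated on a
#' regular grid; the utilisation-distribution mask is the smallest set of
#' highest-density cells holding at least `iso` of the probability mass, and
#' the niche area is the masked cell count times the cell area. With fewer
#' than `min_points` distinct points (or a degenerate spread) the niche is
#' undefined and flagged — never silently zero.
#'
#' @param points 2-column coordinate matrix (species in one 2-D trait space).
#' @param iso isopleth probability (default 0.99).
#' @param bandwidth_multiplier scalar on the normal-reference bandwidth.
#' @param grid_n grid cells per axis (used when `grid` is NULL).
#' @param grid optional shared grid from [niche_grid()] so that two guilds'
#'   masks intersect cell-exactly.
#' @param min_points minimum number of distinct points (default 3).
#' @return list with `defined`, `area`, `mask` (logical matrix), `grid`,
#'   `bandwidth`, `n`.
#' @export
kernel_ud <- function(points, iso = 0.99, bandwidth_multiplier = 1,
                      grid_n = 150, grid = NULL, min_points = 3) {
  points <- as.matrix(points)
  undefined <- list(defined = FALSE, area = NA_real_, mask = NULL,
                    grid = grid, bandwidth = c(NA, NA),
                    n = nrow(points))
  if (nrow(points) < min_points ||
      nrow(unique(points)) < min_points) return(undefined)
  h <- ud_bandwidth(points, bandwidth_multiplier)
  if (any(!is.finite(h)) || any(h <= 0)) return(undefined)
  if (is.null(grid)) grid <- niche_grid(points, pad = h, grid_n = grid_n)
  ax <- outer(grid$x, points[, 1], function(g, p) stats::dnorm(g, p, h[1]))
  ay <- outer(grid$y, points[, 2], function(g, p) stats::dnorm(g, p, h[2]))
  dens <- ax %*% t(ay) / nrow(points)
  prob <- dens * grid$cell_area
  prob <- prob / sum(prob)
  ord <- order(prob, decreasing = TRUE)
  n_cells <- which(cumsum(prob[ord]) >= iso)[1]
  mask <- matrix(FALSE, length(grid$x), length(grid$y))
  mask[ord[seq_len(n_cells)]] <- TRUE
  list(defined = TRUE, area = n_cells * grid$cell_area, mask = mask,
       grid = grid, bandwidth = h, n = nrow(points))
}

#' Overlap proportion between two niche masks
#'
#' Fraction of the tropical niche area covered by the temperate niche, both
#' masks living on one shared grid.
#'
#' @param tropical_mask,temperate_mask logical matrices of equal dimension.
#' @return proportion in [0, 1]; NA when the tropical mask is empty.
#' @export
overlap_proportion <- function(tropical_mask, temperate_mask) {
  if (!identical(dim(tropical_mask), dim(temperate_mask)))
    stop("masks must share one grid", call. = FALSE)
  n_trop <- sum(tropical_mask)
  if (n_trop == 0) return(NA_real_)
  sum(tropical_mask & temperate_mask) / n_trop
}

#' Variance-weighted average over axis-pair spaces with zero forcing
#'
#' Weighted mean of per-pair overlap values; if any pair shows exactly zero
#' overlap the average is forced to zero.
#'
#' @param values per-pair values (NA allowed, dropped with its weight).
#' @param weights axis-pair weights.
#' @param zero_force apply the zero-forcing rule (for overlaps).
#' @return weighted mean, or NA when no pair is defined.
#' @keywords internal
.pair_average <- function(values, weights, zero_force = FALSE) {
  ok <- !is.na(values)
  if (!any(ok)) return(NA_real_)
  if (zero_force && any(values[ok] == 0)) return(0)
  sum(values[ok] * weights[ok]) / sum(weights[ok])
}

#' Site-level functional niche metrics per functional group
#'
#' For every site and major functional group: the species present at the site
#' (positive biomass on any transect) are split by thermal guild and, in each
#' of the six axis-pair trait spaces, the 99% kernel UD area of each guild and
#' the tropical-temperate overlap are computed on a shared grid. Per-pair
#' values are averaged with the axis-pair variance weights; a zero overlap in
#' any pair forces the site's average overlap to zero. Tropical niche area is
#' also expressed relative to the group's tropical area over the pooled
#' reference-zone sites (the environmental-filtering signal).
#'
#' @param survey SurveyTable (one region).
#' @param partition `zone_partition` covering the survey's sites.
#' @param grouping `functional_grouping` covering the surveyed species.
#' @param space `trait_space` with coordinates for the surveyed species.
#' @param iso isopleth probability.
#' @param grid_n grid cells per axis.
#' @param min_points minimum distinct points per kernel.
#' @param bandwidth_multiplier scalar on the normal-reference bandwidth.
#' @param groups functional groups to evaluate (default: the major groups).
#' @return data.frame with one row per site x group: areas, overlap (weighted,
#'   zero-forced), `tropical_area_proportion`, per-pair overlap columns,
#'   guild counts and a `defined` flag. Reference areas are attached as the
#'   `reference_area` attribute.
#' @export
site_group_niche_metrics <- function(survey, partition, grouping, space,
                                     iso = 0.99, grid_n = 150, min_points = 3,
                                     bandwidth_multiplier = 1,
                                     groups = NULL) {
  coords <- space$coordinates
  missing_sp <- setdiff(unique(survey$species), rownames(coords))
  if (length(missing_sp) > 0)
    stop("species without trait-space coordinates: ",
         paste(utils::head(missing_sp, 5), collapse = ", "), call. = FALSE)
  if (is.null(groups)) groups <- grouping$major_groups
  guild <- attr(space, "guild")
  if (is.null(guild))
    stop("trait_space lacks a 'guild' attribute; set it from the trait table",
         call. = FALSE)
  pairs <- space$axis_pairs
  tt <- transect_table(survey)
  site_lat <- tapply(abs(tt$latitude), tt$site, function(x) x[1])
  ## species pools per site (presence = positive biomass on any transect)
  pool <- split(survey$species[survey$biomass > 0],
                survey$site[survey$biomass > 0])
  pool <- lapply(pool, unique)
  ref_sites <- names(partition$sites)[partition$sites ==
                                        partition$reference_zone]
  ref_pool <- unique(unlist(pool[intersect(names(pool), ref_sites)]))
  grp_of <- grouping$assignments
  guild_of <- guild[rownames(coords)]

  kernel_area <- function(sp, p) {
    if (length(sp) < min_points) return(NA_real_)
    k <- kernel_ud(coords[sp, c(pairs$axis1[p], pairs$axis2[p]),
                          drop = FALSE],
                   iso = iso, grid_n = grid_n, min_points = min_points,
                   bandwidth_multiplier = bandwidth_multiplier)
    if (k$defined) k$area else NA_real_
  }
  ## reference tropical area per group x pair (pooled reference-zone sites)
  ref_area <- matrix(NA_real_, length(groups), nrow(pairs),
                     dimnames = list(groups, NULL))
  for (gi in seq_along(groups)) {
    sp <- ref_pool[grp_of[ref_pool] == groups[gi] &
                     guild_of[ref_pool] == "tropical"]
    sp <- sp[!is.na(sp)]
    for (p in seq_len(nrow(pairs)))
      ref_area[gi, p] <- kernel_area(sp, p)
  }

  rows <- list()
  for (s in names(pool)) {
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      sp <- pool[[s]][grp_of[pool[[s]]] == g]
      sp <- sp[!is.na(sp)]
      trop <- sp[guild_of[sp] == "tropical"]
      temp <- sp[guild_of[sp] == "temperate"]
      ov <- rep(NA_real_, nrow(pairs))
      ta <- rep(NA_real_, nrow(pairs))
      prop <- rep(NA_real_, nrow(pairs))
      for (p in seq_len(nrow(pairs))) {
        ax <- c(pairs$axis1[p], pairs$axis2[p])
        pts_t <- coords[trop, ax, drop = FALSE]
        pts_e <- coords[temp, ax, drop = FALSE]
        h_t <- if (nrow(pts_t) >= min_points) ud_bandwidth(pts_t, bandwidth_multiplier) else c(0, 0)
        h_e <- if (nrow(pts_e) >= min_points) ud_bandwidth(pts_e, bandwidth_multiplier) else c(0, 0)
        pad <- pmax(h_t, h_e)
        if (all(pad == 0)) next
        grid <- niche_grid(rbind(pts_t, pts_e), pad = pad, grid_n = grid_n)
        kt <- kernel_ud(pts_t, iso = iso, grid = grid,
                        min_points = min_points,
                        bandwidth_multiplier = bandwidth_multiplier)
        ke <- kernel_ud(pts_e, iso = iso, grid = grid,
                        min_points = min_points,
                        bandwidth_multiplier = bandwidth_multiplier)
        if (kt$defined) {
          ta[p] <- kt$area
          if (!is.na(ref_area[gi, p]) && ref_area[gi, p] > 0)
            prop[p] <- kt$area / ref_area[gi, p]
          if (ke$defined) ov[p] <- overlap_proportion(kt$mask, ke$mask)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        site = s, latitude = as.numeric(site_lat[s]),
        zone = as.character(partition$sites[s]), group = g,
        n_tropical = length(trop), n_temperate = length(temp),
        tropical_area = .pair_average(ta, pairs$weight),
        tropical_area_proportion = .pair_average(prop, pairs$weight),
        overlap = .pair_average(ov, pairs$weight, zero_force = TRUE),
        defined = any(!is.na(ta)),
        stringsAsFactors = FALSE)
      for (p in seq_len(nrow(pairs)))
        rows[[length(rows)]][[paste0("overlap_pair", p)]] <- ov[p]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference_area") <- ref_area
  out
}

#' Environmental-filtering signal per site and group
#'
#' The proportional change of tropical functional niche area between the
#' reference zone and each site: 1 at parity, below 1 under poleward
#' filtering, 0 where the group's tropical species are absent.
#'
#' @param metrics output of [site_group_niche_metrics()].
#' @return data.frame (site, latitude, zone, group, area_proportion).
#' @export
environmental_filtering_signal <- function(metrics) {
  prop <- ifelse(!metrics$defined & metrics$n_tropical == 0, 0,
                 metrics$tropical_area_proportion)
  data.frame(site = metrics$site, latitude = metrics$latitude,
             zone = metrics$zone, group = metrics$group,
             area_proportion = prop, stringsAsFactors = FALSE)
}

#' Attach thermal guilds to a trait space
#'
#' @param space `trait_space`.
#' @param traits TraitTable supplying `species` and `thermal_guild`.
#' @return the space with a `guild` attribute (named character vector).
#' @export
set_space_guilds <- function(space, traits) {
  attr(space, "guild") <- stats::setNames(as.character(traits$thermal_guild),
                                          traits$species)
  space
}
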