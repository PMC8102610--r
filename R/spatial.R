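#' Pairwise great-circle distances between samples
#'
#' Haversine distances (Earth radius 6371 km) from the decimal-degree
#' coordinates of the population map.
#'
#' @param map a population map with `lat`/`lon` columns.
#' @return symmetric matrix of distances in km, labelled by sample;
#'   samples with missing coordinates are dropped with a message.
#' @export
geo_distances <- function(map) {
  ok <- !is.na(map$lat) & !is.na(map$lon)
  if (any(!ok))
    message("excluded for missing coordinates: ",
            paste(map$sample[!ok], collapse = ", "))
  map <- map[ok, , drop = FALSE]
  xy <- cbind(map$lon, map$lat)
  n <- nrow(xy)
  d <- matrix(0, n, n, dimnames = list(map$sample, map$sample))
  for (i in seq_len(n - 1)) {
    d[i, (i + 1):n] <- geosphere::distHaversine(
      xy[i, , drop = FALSE], xy[(i + 1):n, , drop = FALSE],
      r = 6371000) / 1000
  }
  d + t(d)
}

#' Multilocus spatial autocorrelation correlogram
#'
#' The Smouse-Peakall multivariate autocorrelation coefficient: squared
#' individual genetic distances (Prevosti-based) are double-centered into
#' a covariance matrix `C` with
#' `c_ij = -(d2_ij - rowmean_i - colmean_j + grandmean) / 2`; for a
#' distance class the coefficient is the sum of `c_ij` over pairs in the
#' class divided by the sum of `c_ii` over the distinct individuals
#' participating in those pairs. The null distribution permutes whole
#' genotypes across geographic locations; the envelope is the 2.5/97.5
#' percentile of the permuted `r` per class and the p-value is rank-based
#' (two-tailed).
#'
#' @param g a [genotype_matrix()].
#' @param map a population map with coordinates.
#' @param class_edges strictly increasing distance-class edges in km
#'   (default `c(0, 1, 5, 10, 50, 100, 500, 1000)`, chosen to expose both
#'   a short-range drop and long-range persistence).
#' @param n_perm number of permutations (default 999).
#' @param region restrict to samples of this region (e.g. the mainland
#'   lineage, matching an isolation-by-distance analysis); `NULL` uses
#'   all samples.
#' @return data.frame of class `correlogram`: per class the edges, pair
#'   count, `r`, permutation envelope (`null_low`, `null_high`) and
#'   p-value. Classes without pairs have `NA` statistics.
#' @export
autocorrelation <- function(g, map, class_edges = c(0, 1, 5, 10, 50, 100, 500, 1000),
                            n_perm = 999, region = NULL) {
  stopifnot(all(diff(class_edges) > 0))
  map <- align_map(g, map)
  if (!is.null(region)) {
    keep <- map$region %in% region
    g <- g[keep, ]; map <- map[keep, , drop = FALSE]
  }
  ok <- !is.na(map$lat) & !is.na(map$lon)
  g <- g[ok, ]; map <- map[ok, , drop = FALSE]
  n <- nrow(g)
  if (n < 2) stop("need at least 2 individuals with genotypes and coordinates")
  gd2 <- prevosti_distance(g)^2
  C <- double_center(gd2)
  geo <- geo_distances(map)
  cls <- matrix(cut(geo, class_edges, labels = FALSE, right = TRUE,
                    include.lowest = TRUE), n, n)
  n_class <- length(class_edges) - 1
  r_of <- function(ord) {
    # ord maps location slot -> genotype index (genotypes permuted over places)
    Cp <- C[ord, ord]
    vapply(seq_len(n_class), function(k) {
      sel <- which(cls == k & upper.tri(cls), arr.ind = TRUE)
      if (nrow(sel) == 0) return(NA_real_)
      inds <- unique(c(sel))
      sum(Cp[sel]) / sum(diag(Cp)[inds])
    }, numeric(1))
  }
  obs <- r_of(seq_len(n))
  null_low <- null_high <- pval <- rep(NA_real_, n_class)
  if (n_perm > 0) {
    nulls <- vapply(seq_len(n_perm), function(i) r_of(sample(n)), numeric(n_class))
    nulls <- matrix(nulls, nrow = n_class)
    for (k in seq_len(n_class)) {
      if (is.na(obs[k])) next
      nk <- nulls[k, ]
      null_low[k] <- stats::quantile(nk, 0.025, na.rm = TRUE)
      null_high[k] <- stats::quantile(nk, 0.975, na.rm = TRUE)
      p_hi <- (1 + sum(nk >= obs[k], na.rm = TRUE)) / (n_perm + 1)
      p_lo <- (1 + sum(nk <= obs[k], na.rm = TRUE)) / (n_perm + 1)
      pval[k] <- min(1, 2 * min(p_hi, p_lo))
    }
  }
  pair_count <- vapply(seq_len(n_class),
                       function(k) sum(cls == k & upper.tri(cls), na.rm = TRUE),
                       numeric(1))
  structure(data.frame(class_low = class_edges[-length(class_edges)],
                       class_high = class_edges[-1],
                       n_pairs = pair_count, r = obs,
                       null_low = null_low, null_high = null_high,
                       p_value = pval),
            n_permutations = n_perm, class = c("correlogram", "data.frame"))
}

# Gower double-centering of a squared-distance matrix
double_center <- function(d2) {
  rm <- rowMeans(d2); gm <- mean(d2)
  -0.5 * (d2 - outer(rm, rm, "+") + gm)
}
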