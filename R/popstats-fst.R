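#' Pairwise population differentiation (Nei F_ST and Hedrick G''_ST)
#'
#' For each pair of populations, per-locus gene-diversity components are
#' estimated with the Nei-Chesser small-sample corrections (harmonic-mean
#' sample size `nh`, observed heterozygosity correction):
#' `Hs = nh/(nh-1) * (1 - mean_i(p_i^2 + q_i^2) - Ho/(2 nh))` and
#' `Ht = 1 - (pbar^2 + qbar^2) + Hs/(k nh) - Ho/(2 k nh)` with `k = 2`,
#' then Nei's (1987) finite-number-of-demes correction
#' `Dst' = k/(k-1) (Ht - Hs)` and `Ht' = Hs + Dst'`. The multilocus F_ST
#' is the ratio of sums, `1 - sum(Hs)/sum(Ht')` (per-locus ratios are
#' unstable at low diversity); under a two-deme drift model with
#' divergence `f` its expectation is `f` itself, while the uncorrected
#' `1 - Hs/Ht` would converge to `f/(2-f)`. G''_ST applies the
#' Meirmans-Hedrick standardisation `k (Ht' - Hs) / ((k Ht' - Hs) (1 - Hs))`
#' to the locus-averaged corrected components, so fixed differences give
#' exactly 1. Significance is assessed by permuting individuals between
#' the two populations (one-sided: observed >= permuted F_ST).
#'
#' Negative estimates (sampling noise around zero differentiation) are
#' reported as computed, not clamped.
#'
#' @param g a [genotype_matrix()].
#' @param map a population map.
#' @param n_perm permutations per pair (default 1000, so the smallest
#'   attainable p-value is 1/1001); 0 skips the test.
#' @param min_n populations with fewer individuals are excluded.
#' @return list of class `differentiation_matrices`: square matrices
#'   `fst`, `gst_pp` (G''_ST) and `p_value`, plus per-population `n`.
#' @export
pairwise_fst <- function(g, map, n_perm = 1000, min_n = 2) {
  map <- align_map(g, map)
  pops <- unique(map$population)
  if (length(pops) < 2) stop("need at least 2 populations")
  n_by_pop <- table(factor(map$population, levels = pops))
  usable <- names(n_by_pop)[n_by_pop >= max(2, min_n)]
  k <- length(pops)
  fst <- gpp <- pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  diag(fst) <- diag(gpp) <- 0
  m <- unclass(g)
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    if (!(pops[a] %in% usable) || !(pops[b] %in% usable)) next
    ra <- which(map$population == pops[a])
    rb <- which(map$population == pops[b])
    obs <- fst_pair(m[ra, , drop = FALSE], m[rb, , drop = FALSE])
    fst[a, b] <- fst[b, a] <- obs$fst
    gpp[a, b] <- gpp[b, a] <- obs$gst_pp
    if (n_perm > 0) {
      rows <- c(ra, rb)
      hits <- 0L
      for (it in seq_len(n_perm)) {
        perm <- sample(rows)
        f <- fst_pair(m[perm[seq_along(ra)], , drop = FALSE],
                      m[perm[-seq_along(ra)], , drop = FALSE])$fst
        if (!is.na(f) && f >= obs$fst) hits <- hits + 1L
      }
      pv[a, b] <- pv[b, a] <- (1 + hits) / (n_perm + 1)
    }
  }
  structure(list(fst = fst, gst_pp = gpp, p_value = pv,
                 n = as.integer(n_by_pop), populations = pops,
                 n_perm = n_perm),
            class = "differentiation_matrices")
}

#' @export
print.differentiation_matrices <- function(x, ...) {
  cat("Pairwise Nei F_ST (lower) / Hedrick G''_ST (upper):\n")
  m <- x$fst
  m[upper.tri(m)] <- x$gst_pp[upper.tri(m)]
  print(round(m, 3))
  invisible(x)
}

# Nei-Chesser corrected per-locus components and multilocus F_ST / G''_ST
# for two dosage sub-matrices (samples x loci)
fst_pair <- function(m1, m2) {
  n1 <- colSums(!is.na(m1)); n2 <- colSums(!is.na(m2))
  use <- n1 >= 2 & n2 >= 2
  if (!any(use)) return(list(fst = NA_real_, gst_pp = NA_real_))
  m1 <- m1[, use, drop = FALSE]; m2 <- m2[, use, drop = FALSE]
  n1 <- n1[use]; n2 <- n2[use]
  p1 <- colSums(m1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(m2, na.rm = TRUE) / (2 * n2)
  ho <- (colMeans(m1 == 1L, na.rm = TRUE) + colMeans(m2 == 1L, na.rm = TRUE)) / 2
  nh <- 2 / (1 / n1 + 1 / n2)
  het_within <- 1 - (p1^2 + (1 - p1)^2 + p2^2 + (1 - p2)^2) / 2
  hs <- nh / (nh - 1) * (het_within - ho / (2 * nh))
  pbar <- (p1 + p2) / 2
  ht <- 1 - (pbar^2 + (1 - pbar)^2) + hs / (2 * nh) - ho / (4 * nh)
  htp <- hs + 2 * (ht - hs)            # Ht' with k/(k-1) = 2 on Dst
  shtp <- sum(htp)
  fst <- if (shtp > 0) 1 - sum(hs) / shtp else NA_real_
  hs_bar <- mean(hs); htp_bar <- mean(htp)
  denom <- (2 * htp_bar - hs_bar) * (1 - hs_bar)
  gpp <- if (denom > 0) 2 * (htp_bar - hs_bar) / denom else NA_real_
  list(fst = fst, gst_pp = gpp)
}
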