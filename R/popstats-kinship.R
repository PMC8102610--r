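#' Dosage-based kinship screening within populations
#'
#' Allele-sharing kinship in the Weir-Goudet style: for a pair of
#' individuals the per-locus probability that one random gene copy from
#' each matches, `M = (x y + (2 - x)(2 - y)) / 4`, is averaged over
#' shared loci and centred by the mean within-population sharing:
#' `beta = (M_pair - M_mean) / (1 - M_mean)`. Relative to an unrelated
#' baseline the expectations are ~0.25 for parent-offspring or full
#' sibs and ~0.5 for duplicates, on the kinship scale.
#'
#' Pairs above `threshold` are flagged; a `pruned_samples` list (greedy:
#' one member of each flagged pair removed, higher-missingness member
#' first) supports robustness re-analysis with close kin excluded.
#'
#' @param g a [genotype_matrix()].
#' @param map a population map; only within-population pairs are
#'   screened.
#' @param threshold kinship flag threshold (default 0.125, i.e. halfway
#'   between the second- and third-degree expectations).
#' @return list of class `kinship_result`: data.frame `pairs` (sample_1,
#'   sample_2, population, n_loci, kinship, flagged), the `threshold`,
#'   `flagged_pairs`, `pruned_samples` and `kept_samples`.
#' @export
kinship_screen <- function(g, map, threshold = 0.125) {
  map <- align_map(g, map)
  m <- unclass(g)
  out <- list()
  for (pk in unique(map$population)) {
    rows <- which(map$population == pk)
    if (length(rows) < 2) next
    sub <- m[rows, , drop = FALSE]
    called <- !is.na(sub)
    x0 <- sub; x0[!called] <- 0L
    y0 <- 2L - sub; y0[!called] <- 0L
    shared <- tcrossprod(called * 1L)
    match_sum <- (tcrossprod(x0) + tcrossprod(y0)) / 4
    M <- match_sum / shared
    off <- upper.tri(M)
    mbar <- mean(M[off])
    beta <- (M - mbar) / (1 - mbar)
    idx <- which(off, arr.ind = TRUE)
    out[[pk]] <- data.frame(
      sample_1 = rownames(sub)[idx[, 1]],
      sample_2 = rownames(sub)[idx[, 2]],
      population = pk,
      n_loci = shared[off],
      kinship = beta[off],
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs))
    pairs <- data.frame(sample_1 = character(), sample_2 = character(),
                        population = character(), n_loci = integer(),
                        kinship = numeric())
  rownames(pairs) <- NULL
  pairs$flagged <- pairs$kinship > threshold
  flagged <- pairs[pairs$flagged, , drop = FALSE]
  # greedy pruning: drop the higher-missingness member of each flagged pair
  miss <- rowMeans(is.na(m)); names(miss) <- rownames(m)
  pruned <- character(0)
  for (i in seq_len(nrow(flagged))) {
    s1 <- flagged$sample_1[i]; s2 <- flagged$sample_2[i]
    if (s1 %in% pruned || s2 %in% pruned) next
    pruned <- c(pruned, if (miss[s1] >= miss[s2]) s1 else s2)
  }
  structure(list(pairs = pairs, threshold = threshold,
                 flagged_pairs = flagged,
                 pruned_samples = pruned,
                 kept_samples = setdiff(rownames(m), pruned)),
            class = "kinship_result")
}

#' @export
print.kinship_result <- function(x, ...) {
  cat(sprintf("kinship screen: %d within-population pairs, %d flagged (> %g), %d samples pruned\n",
              nrow(x$pairs), nrow(x$flagged_pairs), x$threshold,
              length(x$pruned_samples)))
  invisible(x)
}
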