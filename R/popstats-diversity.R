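#' Per-population diversity statistics
#'
#' For each population with at least `min_n` individuals, per-locus
#' statistics are computed from genotyped samples only and averaged over
#' loci: number of alleles observed A; effective alleles
#' A_E = 1 / (p^2 + q^2); observed heterozygosity H_O; unbiased expected
#' heterozygosity H_E = (2n / (2n - 1)) 2pq (small-sample corrected, n =
#' genotyped individuals at the locus); polymorphic index P_E = 2pq; and
#' the inbreeding coefficient F_IS = 1 - H_O / H_E averaged over
#' polymorphic loci only (H_E > 0).
#'
#' @param g a [genotype_matrix()].
#' @param map a population map.
#' @param min_n minimum individuals for a population to be reported
#'   (default 6, the study's inclusion rule).
#' @return data.frame, one row per included population, with columns
#'   `population`, `n`, `A`, `A_E`, `H_O`, `H_E`, `F_IS`, `P_E`.
#' @export
diversity_table <- function(g, map, min_n = 6) {
  map <- align_map(g, map)
  pops <- unique(map$population)
  m <- unclass(g)
  rows <- lapply(pops, function(pk) {
    sel <- map$population == pk
    n_ind <- sum(sel)
    if (n_ind < min_n) {
      message("population ", pk, " has n = ", n_ind, " < ", min_n,
              ": excluded from diversity table")
      return(NULL)
    }
    sub <- m[sel, , drop = FALSE]
    n <- colSums(!is.na(sub))
    called <- n > 0
    sub <- sub[, called, drop = FALSE]; n <- n[called]
    p <- colSums(sub, na.rm = TRUE) / (2 * n)
    q <- 1 - p
    A <- 1 + (p > 0 & p < 1)
    AE <- 1 / (p^2 + q^2)
    HO <- colMeans(sub == 1L, na.rm = TRUE)
    HE <- (2 * n / (2 * n - 1)) * 2 * p * q
    PE <- 2 * p * q
    poly <- HE > 0
    fis <- if (any(poly)) mean(1 - HO[poly] / HE[poly]) else NA_real_
    data.frame(population = pk, n = n_ind, A = mean(A), A_E = mean(AE),
               H_O = mean(HO), H_E = mean(HE), F_IS = fis, P_E = mean(PE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no population meets the n >= ", min_n, " rule")
  rownames(out) <- NULL
  out
}
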