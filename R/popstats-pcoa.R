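#' Genetic distance matrices
#'
#' `nei_distance()` computes Nei's (1972) standard genetic distance
#' between populations from allele frequencies:
#' `D = -ln( Jxy / sqrt(Jx Jy) )` with `Jxy = mean_l sum_a p_a p'_a`
#' (loci with a frequency defined in both populations).
#' `prevosti_distance()` computes the individual-level Prevosti distance,
#' the mean over shared loci of `|x - y| / 2` on dosages.
#'
#' @param freqs an [allele_frequencies()] result (or a loci x populations
#'   frequency matrix).
#' @return a square symmetric distance matrix.
#' @export
nei_distance <- function(freqs) {
  p <- if (is.list(freqs)) freqs$p else freqs
  k <- ncol(p)
  d <- matrix(0, k, k, dimnames = list(colnames(p), colnames(p)))
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    ok <- !is.na(p[, a]) & !is.na(p[, b])
    pa <- p[ok, a]; pb <- p[ok, b]
    jxy <- mean(pa * pb + (1 - pa) * (1 - pb))
    jx <- mean(pa^2 + (1 - pa)^2)
    jy <- mean(pb^2 + (1 - pb)^2)
    d[a, b] <- d[b, a] <- -log(jxy / sqrt(jx * jy))
  }
  d
}

#' @rdname nei_distance
#' @param g a [genotype_matrix()].
#' @export
prevosti_distance <- function(g) {
  m <- unclass(g)
  n <- nrow(m)
  called <- !is.na(m)
  x0 <- m; x0[!called] <- 0L
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    ok <- called[a, ] & called[b, ]
    d[a, b] <- d[b, a] <- mean(abs(x0[a, ok] - x0[b, ok])) / 2
  }
  d
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling (double-centering and eigendecomposition, via
#' `stats::cmdscale`). Axes are ordered by eigenvalue; the percent
#' variance of an axis is its eigenvalue over the sum of positive
#' eigenvalues (negative eigenvalues, if any, are reported but excluded
#' from the denominator).
#'
#' @param d square symmetric non-negative distance matrix.
#' @param level label for what the rows are (`"population"` or
#'   `"individual"`).
#' @param k number of axes to return (default all positive).
#' @return list of class `ordination`: `coordinates` (entities x axes),
#'   `percent_variance`, `eigenvalues`, `level`, and `degenerate` (TRUE
#'   when all distances are ~0).
#' @export
pcoa <- function(d, level = c("population", "individual"), k = NULL) {
  level <- match.arg(level)
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), all(abs(d - t(d)) < 1e-8), all(d >= 0))
  degenerate <- all(d < 1e-12)
  if (degenerate) {
    warning("all distances are zero: degenerate ordination")
    coords <- matrix(0, nrow(d), 1, dimnames = list(rownames(d), "Axis1"))
    return(structure(list(coordinates = coords, percent_variance = NA_real_,
                          eigenvalues = rep(0, nrow(d) - 1), level = level,
                          degenerate = TRUE), class = "ordination"))
  }
  kmax <- nrow(d) - 1
  # cmdscale warns when fewer than k eigenvalues are positive; the
  # positive set is handled explicitly below
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = kmax,
                                          eig = TRUE))
  eig <- fit$eig[seq_len(kmax)]
  pos <- eig > sqrt(.Machine$double.eps) * max(abs(eig))
  if (any(eig < 0))
    message(sum(eig < 0), " negative eigenvalue(s) excluded from the variance denominator")
  if (is.null(k)) k <- max(1L, sum(pos))
  k <- min(k, sum(pos))
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(k))
  pv <- 100 * eig[seq_len(k)] / sum(eig[pos])
  structure(list(coordinates = coords, percent_variance = pv,
                 eigenvalues = eig, level = level, degenerate = FALSE),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("PCoA (%s level): %d entities", x$level, nrow(x$coordinates)))
  if (!x$degenerate)
    cat(sprintf("; axis 1-2 variance %%: %s",
                paste(round(utils::head(x$percent_variance, 2), 1), collapse = ", ")))
  cat("\n")
  invisible(x)
}
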