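# Independent brute-force oracles used to cross-check the package's
# implementations. These are written naively (scalar loops, direct
# enumeration) and never call the code paths they check.

# quick genotype_matrix builder: loci on one scaffold unless given
gm <- function(dosage, scaffold = NULL, position = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("s", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("L", seq_len(ncol(dosage)))
  if (is.null(scaffold)) scaffold <- rep("scaffold_1", ncol(dosage))
  if (is.null(position)) position <- seq_len(ncol(dosage)) * 10000L
  genotype_matrix(dosage, scaffold, position)
}

popmap_for <- function(g, population, region = NULL, lat = NULL, lon = NULL) {
  if (is.null(region)) region <- rep("regionA", length(population))
  data.frame(sample = rownames(g), population = population, region = region,
             lat = if (is.null(lat)) rep(0, nrow(g)) else lat,
             lon = if (is.null(lon)) rep(0, nrow(g)) else lon,
             stringsAsFactors = FALSE)
}

# locus-by-locus Nei-Chesser / Nei-1987 pairwise differentiation,
# written with explicit per-locus scalars
oracle_fst_pair <- function(m1, m2) {
  hs_sum <- 0; htp_sum <- 0; hs_all <- c(); htp_all <- c()
  for (l in seq_len(ncol(m1))) {
    x1 <- m1[, l][!is.na(m1[, l])]; x2 <- m2[, l][!is.na(m2[, l])]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(x1) / (2 * n1); p2 <- sum(x2) / (2 * n2)
    ho <- (mean(x1 == 1) + mean(x2 == 1)) / 2
    nh <- 2 / (1 / n1 + 1 / n2)
    hexp <- 1 - (p1^2 + (1 - p1)^2 + p2^2 + (1 - p2)^2) / 2
    hs <- nh / (nh - 1) * (hexp - ho / (2 * nh))
    pb <- (p1 + p2) / 2
    ht <- 1 - (pb^2 + (1 - pb)^2) + hs / (2 * 2 * nh / 2) - ho / (2 * 2 * nh)
    htp <- hs + 2 * (ht - hs)
    hs_sum <- hs_sum + hs; htp_sum <- htp_sum + htp
    hs_all <- c(hs_all, hs); htp_all <- c(htp_all, htp)
  }
  hsb <- mean(hs_all); htpb <- mean(htp_all)
  list(fst = 1 - hs_sum / htp_sum,
       gst_pp = 2 * (htpb - hsb) / ((2 * htpb - hsb) * (1 - hsb)))
}

# exhaustive rarefaction: mean distinct alleles over all choose(N, g)
# subsamples of the gene copies
oracle_rarefaction <- function(n_alt, n_ref, g) {
  copies <- c(rep(1L, n_alt), rep(0L, n_ref))
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# brute-force maximum coverage: best covered-element count over all
# subsets of the given size (presence = elements x groups logical matrix)
oracle_max_coverage <- function(pres, b) {
  best <- -1
  for (s in utils::combn(ncol(pres), b, simplify = FALSE)) {
    cov <- 0
    for (e in seq_len(nrow(pres))) if (any(pres[e, s])) cov <- cov + 1
    if (cov > best) best <- cov
  }
  best
}

# naive recount of the filter cascade fates, one stage at a time
oracle_filter_recount <- function(g, cfg) {
  m <- unclass(g)
  scaf <- attr(g, "scaffold"); pos <- attr(g, "position")
  removed <- integer(0)
  counts <- c()
  keep <- seq_len(ncol(m))
  # stage 1
  bad <- keep[sapply(keep, function(j) mean(!is.na(m[, j])) < cfg$min_locus_call_rate)]
  counts <- c(counts, length(bad)); keep <- setdiff(keep, bad)
  # stage 2
  bad <- keep[sapply(keep, function(j) {
    x <- m[, j][!is.na(m[, j])]
    min(sum(x), 2 * length(x) - sum(x)) < cfg$min_minor_allele_count
  })]
  counts <- c(counts, length(bad)); keep <- setdiff(keep, bad)
  # stage 3
  bad <- keep[sapply(keep, function(j) mean(m[, j][!is.na(m[, j])] == 1) > cfg$max_obs_het)]
  counts <- c(counts, length(bad)); keep <- setdiff(keep, bad)
  # stage 4: windowed LD pruning, same deterministic tie-break
  nmiss <- sapply(seq_len(ncol(m)), function(j) sum(is.na(m[, j])))
  alive <- keep[order(scaf[keep], pos[keep])]
  dead <- c()
  for (ii in seq_along(alive)) {
    i <- alive[ii]
    if (i %in% dead) next
    for (jj in seq_along(alive)) {
      if (jj <= ii) next
      j <- alive[jj]
      if (scaf[j] != scaf[i] || pos[j] - pos[i] >= cfg$ld_window_bp) break
      if (j %in% dead) next
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      if (sum(ok) < cfg$ld_min_shared) next
      r <- suppressWarnings(cor(m[ok, i], m[ok, j]))
      stat <- if (cfg$ld_stat == "r") abs(r) else r^2
      if (!is.na(stat) && stat > cfg$ld_threshold) {
        victim <- if (nmiss[j] >= nmiss[i]) j else i
        dead <- c(dead, victim)
        if (victim == i) break
      }
    }
  }
  counts <- c(counts, length(dead)); keep <- setdiff(keep, dead)
  # stage 5
  bad_s <- which(sapply(seq_len(nrow(m)), function(i) mean(is.na(m[i, keep])) > cfg$max_sample_missing))
  counts <- c(counts, length(bad_s))
  list(removed = counts, n_loci = length(keep),
       n_samples = nrow(m) - length(bad_s))
}

# Smouse-Peakall r from first principles for one distance class
oracle_autocorr_r <- function(gd2, pair_index) {
  n <- nrow(gd2)
  rm <- sapply(seq_len(n), function(i) mean(gd2[i, ]))
  gmn <- mean(gd2)
  cmat <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    cmat[i, j] <- -0.5 * (gd2[i, j] - rm[i] - rm[j] + gmn)
  num <- 0
  for (k in seq_len(nrow(pair_index)))
    num <- num + cmat[pair_index[k, 1], pair_index[k, 2]]
  inds <- unique(c(pair_index))
  num / sum(diag(cmat)[inds])
}
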