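test_that("diversity table matches hand-computed values on a printed fixture", {
  d <- cbind(L1 = c(0L, 0L, 1L, 1L, 2L),
             L2 = c(0L, 0L, 0L, 0L, 0L),
             L3 = c(1L, 1L, 1L, 1L, 1L),
             L4 = c(2L, 2L, 2L, 1L, 0L))
  rownames(d) <- paste0("s", 1:5)
  g <- gm(d)
  map <- popmap_for(g, rep("p1", 5))
  tab <- diversity_table(g, map, min_n = 5)
  # hand-computed: per-locus A, A_E, H_O, unbiased H_E, P_E, F_IS means
  expect_equal(tab$A, 1.75, tolerance = 1e-12)
  expect_equal(tab$A_E, mean(c(1 / 0.52, 1, 2, 1 / 0.58)), tolerance = 1e-12)
  expect_equal(tab$H_O, 0.4, tolerance = 1e-12)
  expect_equal(tab$H_E, mean(c(10 / 9 * 0.48, 0, 10 / 9 * 0.5, 10 / 9 * 0.42)),
               tolerance = 1e-12)
  expect_equal(tab$P_E, 0.35, tolerance = 1e-12)
  expect_equal(tab$F_IS,
               mean(c(1 - 0.4 / (10 / 9 * 0.48),
                      1 - 1 / (10 / 9 * 0.5),
                      1 - 0.2 / (10 / 9 * 0.42))), tolerance = 1e-12)
  # biallelic bounds
  expect_true(tab$A >= 1 && tab$A <= 2 && tab$A_E <= tab$A)
})

test_that("all-heterozygous and monomorphic loci hit the documented limits", {
  d <- cbind(L1 = rep(1L, 30), L2 = rep(0L, 30))
  rownames(d) <- paste0("s", 1:30)
  tab <- diversity_table(gm(d), popmap_for(gm(d), rep("p1", 30)))
  # L1: H_O = 1, F_IS ~ -1 (slightly below via the unbiased H_E);
  # L2 monomorphic: excluded from the F_IS mean, zero diversity
  expect_equal(tab$H_O, 0.5)           # mean over the two loci
  expect_lt(abs(tab$F_IS + 1), 0.05)
  expect_equal(tab$A, 1.5)
})

test_that("small populations are excluded by the n >= 6 rule", {
  d <- matrix(1L, 8, 3, dimnames = list(paste0("s", 1:8), paste0("L", 1:3)))
  g <- gm(d)
  map <- popmap_for(g, c(rep("big", 6), rep("tiny", 2)))
  expect_message(tab <- diversity_table(g, map), "tiny")
  expect_equal(tab$population, "big")
})

test_that("pairwise F_ST and G''_ST equal the locus-by-locus oracle and obey their limits", {
  set.seed(8)
  d <- matrix(sample(0:2, 12 * 3, TRUE), 12, 3,
              dimnames = list(paste0("s", 1:12), paste0("L", 1:3)))
  g <- gm(d)
  map <- popmap_for(g, rep(c("pA", "pB"), each = 6))
  res <- pairwise_fst(g, map, n_perm = 0)
  oracle <- oracle_fst_pair(d[1:6, ], d[7:12, ])
  expect_equal(res$fst["pA", "pB"], oracle$fst, tolerance = 1e-12)
  expect_equal(res$gst_pp["pA", "pB"], oracle$gst_pp, tolerance = 1e-12)
  expect_true(isSymmetric(res$fst) && all(diag(res$fst) == 0))

  # fixed differences: both statistics exactly 1
  dfix <- cbind(L1 = c(rep(0L, 6), rep(2L, 6)), L2 = c(rep(2L, 6), rep(0L, 6)))
  rownames(dfix) <- paste0("s", 1:12)
  rfix <- pairwise_fst(gm(dfix), map, n_perm = 0)
  expect_equal(rfix$fst["pA", "pB"], 1)
  expect_equal(rfix$gst_pp["pA", "pB"], 1)

  # identical source frequencies: near zero, possibly negative, not clamped
  sim <- simulate_dataset(sim_config(n_regions = 1, pops_per_region = 2,
                                     n_per_pop = 15, n_loci = 1500,
                                     f_region = 0, f_pop = 0,
                                     missing_rate = 0, seed = 6))
  rnull <- pairwise_fst(sim$genotypes, sim$popmap, n_perm = 0)
  expect_lt(abs(rnull$fst[1, 2]), 0.02)
})

test_that("standardisation inflates: G''_ST >= F_ST whenever H_S > 0", {
  for (s in 1:5) {
    sim <- simulate_dataset(sim_config(n_per_pop = 10, n_loci = 400,
                                       f_region = 0.3, f_pop = 0.05,
                                       missing_rate = 0.02, seed = s))
    res <- pairwise_fst(sim$genotypes, sim$popmap, n_perm = 0)
    ut <- upper.tri(res$fst)
    expect_true(all(res$gst_pp[ut] >= res$fst[ut] - 1e-9))
    expect_true(all(res$fst[ut] <= 1 & res$gst_pp[ut] <= 1))
  }
})

test_that("permutation test calls strong differentiation significant and null pairs not", {
  sim <- simulate_dataset(sim_config(n_regions = 2, pops_per_region = c(1, 1),
                                     n_per_pop = 12, n_loci = 500,
                                     f_region = 0.4, f_pop = 0,
                                     missing_rate = 0, seed = 17))
  set.seed(1)
  res <- pairwise_fst(sim$genotypes, sim$popmap, n_perm = 99)
  expect_equal(res$p_value[1, 2], 0.01)
  simnull <- simulate_dataset(sim_config(n_regions = 1, pops_per_region = 2,
                                         n_per_pop = 12, n_loci = 500,
                                         f_region = 0, f_pop = 0,
                                         missing_rate = 0, seed = 18))
  set.seed(2)
  rnull <- pairwise_fst(simnull$genotypes, simnull$popmap, n_perm = 99)
  expect_gt(rnull$p_value[1, 2], 0.05)
})

test_that("kinship: duplicates ~0.5, unrelated ~0, pruning removes one member per pair", {
  sim <- simulate_dataset(sim_config(n_regions = 1, pops_per_region = 1,
                                     n_per_pop = 14, n_loci = 4000,
                                     f_region = 0, f_pop = 0.05,
                                     missing_rate = 0, seed = 30))
  m <- unclass(sim$genotypes)
  m[14, ] <- m[1, ]   # plant a duplicate of sample 1
  rownames(m) <- paste0("s", 1:14)
  g <- gm(m)
  map <- popmap_for(g, rep("p1", 14))
  kin <- kinship_screen(g, map)
  dup <- kin$pairs[kin$pairs$sample_1 == "s1" & kin$pairs$sample_2 == "s14", ]
  expect_lt(abs(dup$kinship - 0.5), 0.05)
  expect_true(dup$flagged)
  unrel <- kin$pairs[!(kin$pairs$sample_1 %in% c("s1", "s14") |
                         kin$pairs$sample_2 %in% c("s1", "s14")), ]
  expect_lt(max(abs(unrel$kinship)), 0.05)
  expect_false(any(unrel$flagged))
  expect_equal(length(kin$pruned_samples), 1)
  expect_true(kin$pruned_samples %in% c("s1", "s14"))
})

test_that("removing flagged kin barely moves H_O on kin-free simulations", {
  sim <- simulate_dataset(sim_config(n_per_pop = 12, n_loci = 1500,
                                     missing_rate = 0, seed = 44))
  kin <- kinship_screen(sim$genotypes, sim$popmap)
  g2 <- sim$genotypes[rownames(sim$genotypes) %in% kin$kept_samples, ]
  t1 <- diversity_table(sim$genotypes, sim$popmap)
  t2 <- diversity_table(g2, sim$popmap, min_n = 2)
  shared <- intersect(t1$population, t2$population)
  expect_true(all(abs(t1$H_O[match(shared, t1$population)] -
                        t2$H_O[match(shared, t2$population)]) < 0.02))
})

test_that("Nei distance matches hand arithmetic and PCoA reproduces distances", {
  p <- cbind(pX = c(0.5, 0.2), pY = c(0.5, 0.8))
  rownames(p) <- c("L1", "L2")
  d <- nei_distance(p)
  expect_equal(d["pX", "pY"], -log(0.41 / 0.59), tolerance = 1e-12)

  # 4-population Euclidean-consistent distances round-trip through PCoA
  set.seed(3)
  pts <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("p", 1:4), NULL))
  dm <- as.matrix(dist(pts))
  ord <- pcoa(dm, "population")
  emb <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(emb), unname(dm), tolerance = 1e-9)
  expect_true(all(diff(ord$percent_variance) < 1e-9))
  expect_lte(sum(ord$percent_variance), 100 + 1e-9)
})

test_that("collinear populations load on one axis and identical ones degenerate", {
  p <- cbind(pA = rep(0.1, 50), pB = rep(0.3, 50), pC = rep(0.5, 50))
  d <- nei_distance(p)
  # distances are not perfectly additive on a line, but axis 1 dominates
  ord <- pcoa(d, "population")
  expect_gt(ord$percent_variance[1], 99)
  dz <- matrix(0, 3, 3, dimnames = list(colnames(p), colnames(p)))
  expect_warning(ordz <- pcoa(dz, "population"), "degenerate")
  expect_true(ordz$degenerate)
})

test_that("Prevosti distance averages per-locus dosage mismatch over shared loci", {
  d <- rbind(a = c(0L, 2L, 1L, NA), b = c(2L, 2L, 0L, 1L))
  colnames(d) <- paste0("L", 1:4)
  pd <- prevosti_distance(gm(d))
  expect_equal(pd["a", "b"], mean(c(2, 0, 1)) / 2, tolerance = 1e-12)
})
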