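test_that("closed-form rarefied AR matches binomial arithmetic and enumeration", {
  # counts (9,1), N = 10, g = 8: AR = 2 - C(9,8)/C(10,8) = 1.8
  expect_equal(conigen:::rarefaction_curve(1, 10, 8), 1.8, tolerance = 1e-12)
  expect_equal(oracle_rarefaction(1, 9, 8), 1.8, tolerance = 1e-12)
  # counts (7,1), N = 8, g = 8: every copy drawn
  expect_equal(conigen:::rarefaction_curve(1, 8, 8), 2, tolerance = 1e-12)
  # monomorphic: AR = 1 at any g
  expect_equal(conigen:::rarefaction_curve(0, 10, 4), 1, tolerance = 1e-12)
})

test_that("rarefied AR per group uses a shared locus panel and respects bounds", {
  sim <- simulate_dataset(sim_config(n_per_pop = c(8, 8, 8, 8), n_loci = 300,
                                     missing_rate = 0.05, seed = 10))
  rr <- rarefied_ar(sim$genotypes, sim$popmap)
  expect_true(all(rr$richness$mean_AR >= 1 & rr$richness$mean_AR <= 2))
  expect_equal(unique(rr$richness$n_loci), length(rr$loci_used))
  # merging via a group column
  map2 <- sim$popmap
  map2$group <- ifelse(map2$population %in% c("pop3", "pop4"),
                       "merged", map2$population)
  rr2 <- rarefied_ar(sim$genotypes, map2)
  expect_setequal(rr2$richness$group, c("pop1", "pop2", "merged"))
})

test_that("leave-one-out contributions: private alleles positive, duplicates ~0, depauperate can be negative", {
  # group B holds the only alternate copies at loci 1-3
  dA <- cbind(matrix(0L, 8, 3), matrix(1L, 8, 3))
  dB <- cbind(matrix(c(2L, rep(0L, 7)), 8, 3), matrix(1L, 8, 3))
  d <- rbind(dA, dB)
  rownames(d) <- paste0("s", 1:16); colnames(d) <- paste0("L", 1:6)
  g <- gm(d)
  map <- popmap_for(g, rep(c("A", "B"), each = 8))
  lc <- loo_contributions(g, map)
  cb <- lc$richness$contribution[lc$richness$group == "B"]
  expect_gt(cb, 0)

  # exact duplicate of a group contributes ~0
  sim <- simulate_dataset(sim_config(n_regions = 1, pops_per_region = 1,
                                     n_per_pop = 50, n_loci = 1000,
                                     f_pop = 0.1, missing_rate = 0,
                                     ancestral_maf_range = c(0.2, 0.5),
                                     seed = 3))
  m <- unclass(sim$genotypes)
  d2 <- rbind(m, m)
  rownames(d2) <- paste0("s", 1:100)
  g2 <- gm(d2)
  map2 <- popmap_for(g2, rep(c("orig", "copy"), each = 50))
  lc2 <- loo_contributions(g2, map2)
  expect_lt(max(abs(lc2$richness$contribution)), 0.01)

  # a monomorphic (depauperate) group can have negative contribution
  dpoly <- matrix(rep(c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 1L), 40), 8, 40)
  dmono <- matrix(0L, 8, 40)
  d3 <- rbind(dpoly, dmono)
  rownames(d3) <- paste0("s", 1:16); colnames(d3) <- paste0("L", 1:40)
  g3 <- gm(d3)
  map3 <- popmap_for(g3, rep(c("rich", "poor"), each = 8))
  lc3 <- loo_contributions(g3, map3)
  expect_lt(lc3$richness$contribution[lc3$richness$group == "poor"], 0)
  expect_error(loo_contributions(gm(matrix(0L, 8, 4,
                                           dimnames = list(paste0("s", 1:8),
                                                           paste0("L", 1:4))),
                                    ),
                                 popmap_for(gm(matrix(0L, 8, 4,
                                                      dimnames = list(paste0("s", 1:8),
                                                                      paste0("L", 1:4)))),
                                            rep(c("A", "B"), each = 4)),
                                 g_copies = 4),
               "monomorphic")
})

test_that("exact maximum coverage reproduces the worked nesting example", {
  # alleles a1..a3; A = {a1,a2,a3}, B = {a2,a3}, C = {a3} via private alleles
  # locus design: group A carries alt at L1 (private), A+B alt at L2, all at L3
  dA <- cbind(L1 = rep(1L, 4), L2 = rep(1L, 4), L3 = rep(1L, 4))
  dB <- cbind(L1 = rep(0L, 4), L2 = rep(1L, 4), L3 = rep(1L, 4))
  dC <- cbind(L1 = rep(0L, 4), L2 = rep(0L, 4), L3 = rep(1L, 4))
  d <- rbind(dA, dB, dC)
  rownames(d) <- paste0("s", 1:12)
  g <- gm(d)
  map <- popmap_for(g, rep(c("A", "B", "C"), each = 4))
  mc <- max_coverage(g, map, budgets = 1:3, n_iter = 5, n_per_pop = 4,
                     g_copies = 8, seed = 1)
  # budget 1: A covers all alleles present; deterministic since the
  # 4-individual subsample is the whole group
  expect_equal(unname(mc$selection_freq["budget_1", ]),
               c(1, 0, 0))
  expect_equal(mc$coverage$mean_coverage[1], 1)
  expect_equal(mc$coverage$mean_coverage, rep(1, 3))
  # coverage monotone in budget within iterations
  expect_true(all(diff(mc$coverage$min_coverage) >= -1e-12))
})

test_that("enumerated optimum equals the brute-force subset search on random matrices", {
  set.seed(5)
  for (rep in 1:10) {
    pres <- matrix(runif(40 * 5) < 0.3, 40, 5)
    for (b in 1:5) {
      best <- -1
      for (s in utils::combn(5, b, simplify = FALSE))
        best <- max(best, sum(rowSums(pres[, s, drop = FALSE]) > 0))
      expect_equal(best, oracle_max_coverage(pres, b))
    }
  }
})

test_that("full-budget selection always covers everything and runs are seed-deterministic", {
  sim <- simulate_dataset(sim_config(n_per_pop = 8, n_loci = 200,
                                     missing_rate = 0.02, seed = 14))
  mc1 <- max_coverage(sim$genotypes, sim$popmap, budgets = c(2, 4),
                      n_iter = 8, seed = 7)
  mc2 <- max_coverage(sim$genotypes, sim$popmap, budgets = c(2, 4),
                      n_iter = 8, seed = 7)
  expect_identical(mc1, mc2)
  expect_equal(mc1$coverage$mean_coverage[mc1$coverage$budget == 4], 1)
  expect_true(all(rowSums(mc1$selection_freq) ==
                    mc1$budgets))
  expect_warning(max_coverage(sim$genotypes, sim$popmap, budgets = 9,
                              n_iter = 2, seed = 1), "capped")
})
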