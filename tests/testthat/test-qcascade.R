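test_that("complete-case panel drops exactly the loci with missing calls", {
  d <- matrix(1L, 4, 6, dimnames = list(paste0("s", 1:4), paste0("L", 1:6)))
  g0 <- gm(d)
  expect_identical(unclass(suppressMessages(complete_case_panel(g0))),
                   unclass(g0))
  set.seed(2)
  d[matrix(runif(24) < 0.2, 4, 6)] <- NA
  g <- gm(d)
  cc <- suppressMessages(complete_case_panel(g))
  expect_identical(colnames(cc),
                   colnames(d)[sapply(seq_len(6), function(j) !anyNA(d[, j]))])
  dall <- d; dall[1, ] <- NA
  expect_error(suppressMessages(complete_case_panel(gm(dall))), "no complete-case")
})

test_that("rao_q matches its closed forms", {
  expect_equal(rao_q(0.5)$Q, 0.5)
  expect_equal(rao_q(0.5)$D, 2)
  expect_equal(rao_q(0)$Q, 0)
  expect_equal(rao_q(1)$D, 1)
  two <- rao_q(c(0.5, 0.1))
  expect_equal(two$Q, 1 - 1 / mean(c(2, 1 / 0.82)), tolerance = 1e-12)
  expect_equal(round(two$Q, 4), 0.3788)
  # allele-relabeling invariance: p and 1-p give the same Q
  expect_equal(rao_q(c(0.3, 0.8))$Q, rao_q(c(0.7, 0.2))$Q, tolerance = 1e-15)
})

test_that("identical populations collapse the cascade: delta = beta = 0", {
  d <- rbind(matrix(rep(c(0L, 1L, 2L, 1L), 4), 4, 4, byrow = TRUE),
             matrix(rep(c(0L, 1L, 2L, 1L), 4), 4, 4, byrow = TRUE),
             matrix(rep(c(0L, 1L, 2L, 1L), 4), 4, 4, byrow = TRUE),
             matrix(rep(c(0L, 1L, 2L, 1L), 4), 4, 4, byrow = TRUE))
  rownames(d) <- paste0("s", 1:16); colnames(d) <- paste0("L", 1:4)
  g <- gm(d)
  map <- popmap_for(g, rep(paste0("p", 1:4), each = 4),
                    region = rep(c("r1", "r2"), each = 8))
  cs <- cascade(g, map)
  expect_equal(cs$delta, 0, tolerance = 1e-12)
  expect_equal(unname(cs$beta), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(cs$sigma), rep(cs$gamma, 2), tolerance = 1e-12)
  expect_equal(unname(cs$alpha), rep(cs$gamma, 4), tolerance = 1e-12)
})

test_that("fixed inter-region differences give the closed-form cascade", {
  # two regions fixed for alternative alleles, no within-region variation
  d <- rbind(matrix(0L, 8, 10), matrix(2L, 8, 10))
  rownames(d) <- paste0("s", 1:16); colnames(d) <- paste0("L", 1:10)
  g <- gm(d)
  map <- popmap_for(g, rep(paste0("p", 1:4), each = 4),
                    region = rep(c("r1", "r2"), each = 8))
  cs <- cascade(g, map)
  expect_equal(unname(cs$alpha), rep(0, 4))
  expect_equal(unname(cs$sigma), rep(0, 2))
  expect_equal(cs$gamma, 0.5)  # pooled p = 0.5 at every locus
  expect_equal(cs$delta, 0.5)
})

test_that("partition identities hold to 1e-9 in both weighting modes", {
  for (w in c(TRUE, FALSE)) for (s in 1:3) {
    sim <- simulate_dataset(sim_config(n_per_pop = c(15, 10, 6, 11),
                                       n_loci = 400, missing_rate = 0.02,
                                       seed = s))
    cs <- cascade(sim$genotypes, sim$popmap, weighted = w)
    wmean <- function(x, n) if (w) sum(x * n) / sum(n) else mean(x)
    expect_equal(cs$D_GT, cs$D_AR * wmean(cs$D_WR, cs$n_region),
                 tolerance = 1e-9)
    for (rk in names(cs$D_WR)) {
      pk <- names(cs$alpha)[cs$table$region[match(names(cs$alpha),
                                                  cs$table$population)] == rk]
      expect_equal(cs$D_WR[[rk]],
                   cs$D_AP[[rk]] * wmean(cs$D_alpha[pk], cs$n_population[pk]),
                   tolerance = 1e-9)
    }
    expect_true(all(unlist(cs[c("gamma", "delta", "sigma", "alpha")]) >= 0))
    expect_true(all(unlist(cs[c("gamma", "delta", "sigma", "alpha")]) < 1))
  }
})

test_that("a single region collapses gracefully: gamma = sigma, delta = 0", {
  sim <- simulate_dataset(sim_config(n_regions = 1, pops_per_region = 2,
                                     n_per_pop = 8, n_loci = 200,
                                     missing_rate = 0, seed = 4))
  cs <- cascade(sim$genotypes, sim$popmap)
  expect_equal(cs$delta, 0, tolerance = 1e-12)
  expect_equal(unname(cs$sigma), cs$gamma, tolerance = 1e-12)
  expect_true(is.na(cs$bartlett_p))
  # and a region with one population has undefined beta
  simr <- simulate_dataset(sim_config(n_regions = 2, pops_per_region = c(2, 1),
                                      n_per_pop = 8, n_loci = 200,
                                      missing_rate = 0, seed = 5))
  csr <- cascade(simr$genotypes, simr$popmap)
  expect_true(is.na(csr$beta[["region2"]]))
  expect_false(is.na(csr$beta[["region1"]]))
})

test_that("strong between-lineage divergence dominates the cascade and Bartlett behaves", {
  sim <- simulate_dataset(sim_config(n_loci = 800, f_region = 0.5,
                                     f_pop = 0.05, missing_rate = 0,
                                     seed = 7))
  cs <- cascade(sim$genotypes, sim$popmap)
  expect_gt(cs$delta, mean(cs$beta, na.rm = TRUE))
  expect_gt(cs$delta, 0.1)
  expect_true(cs$bartlett_p >= 0 && cs$bartlett_p <= 1)
  set.seed(1)
  bp <- beta_permutation_test(sim$genotypes, sim$popmap, n_perm = 19)
  expect_true(all(bp > 0 & bp <= 1))
})
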