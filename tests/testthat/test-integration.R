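test_that("gene list intersection is exact and rejects duplicates", {
  expect_equal(intersect_genes(c("g1", "g2"), c("g3", "g4")), character())
  expect_setequal(
    intersect_genes(c("g1", "g2", "g3"), c("g2", "g3", "g4")),
    c("g2", "g3")
  )
  l <- c("a", "b", "c")
  expect_setequal(intersect_genes(l, l), l)
  expect_error(intersect_genes(c("a", "a"), l), "duplicate")
})

test_that("hypergeometric_oracle matches exhaustive subset enumeration", {
  o <- hypergeometric_oracle(4, 5, 10)
  expect_equal(o$mean, 2)
  expect_equal(o$sd, sqrt(2 / 3))
  e <- enum_overlap_moments(10, 4, 5)
  expect_equal(o$mean, e$mean, tolerance = 1e-12)
  expect_equal(o$sd, e$sd, tolerance = 1e-12)
  e2 <- enum_overlap_moments(12, 3, 7)
  o2 <- hypergeometric_oracle(3, 7, 12)
  expect_equal(o2$mean, e2$mean, tolerance = 1e-12)
  expect_equal(o2$sd, e2$sd, tolerance = 1e-12)
  # forced overlap: first list is the whole universe
  o3 <- hypergeometric_oracle(10, 6, 10)
  expect_equal(o3$mean, 6)
  expect_equal(o3$sd, 0)
  expect_error(hypergeometric_oracle(2, 3, 0), "> 0")
  expect_error(hypergeometric_oracle(11, 3, 10), "<=")
})

test_that("the closed form reproduces the published expectation scale", {
  # universe back-solved from the published simulation means
  o <- hypergeometric_oracle(2722, 1646, 18277)
  expect_equal(round(o$mean, 2), 245.14)
  expect_equal(round(o$sd, 2), 13.78)
})

test_that("jackknife_test is deterministic and respects its invariants", {
  r1 <- jackknife_test(40, 50, 1000, 10, n_sims = 5000, seed = 99)
  r2 <- jackknife_test(40, 50, 1000, 10, n_sims = 5000, seed = 99)
  expect_identical(r1, r2)
  expect_gte(r1$p_empirical, 1 / 5001)
  expect_lte(r1$p_empirical, 1)
  # n_a = N forces every simulated intersection to n_b
  rf <- jackknife_test(10, 6, 10, 6, n_sims = 200, seed = 1)
  expect_equal(rf$sim_mean, 6)
  expect_equal(rf$sim_sd, 0)
  expect_equal(rf$p_gauss, 1)
  expect_error(jackknife_test(20, 5, 10, 2), "universe")
  expect_error(jackknife_test(5, 5, 10, 6), "observed")
  # two-sided Gaussian tail against an independent erfc-based oracle
  r <- jackknife_test(40, 50, 1000, 8, n_sims = 20000, seed = 7)
  expect_equal(r$p_gauss, pracma::erfc(abs(r$z) / sqrt(2)),
    tolerance = 1e-12
  )
})

test_that("subset sampling and hypergeometric draws agree in distribution", {
  n_sub <- 3000L
  o <- hypergeometric_oracle(40, 50, 500)
  rs <- jackknife_test(40, 50, 500, 10,
    n_sims = n_sub, seed = 5,
    method = "subset"
  )
  rh <- jackknife_test(40, 50, 500, 10, n_sims = 100000L, seed = 5)
  se <- o$sd * sqrt(1 / n_sub + 1 / 100000)
  expect_lt(abs(rs$sim_mean - rh$sim_mean), 4 * se)
  expect_lt(abs(rs$sim_mean - o$mean), 4 * o$sd / sqrt(n_sub))
  expect_lt(abs(rs$sim_sd - o$sd) / o$sd, 0.1)
})

test_that("simulated moments converge to the closed form across seeds", {
  o <- hypergeometric_oracle(4, 5, 10)
  for (s in 1:5) {
    r <- jackknife_test(4, 5, 10, 2, n_sims = 100000L, seed = s)
    expect_lt(abs(r$sim_mean - o$mean), 4 * o$sd / sqrt(100000))
  }
})

test_that("directional_correlation labels pairings and flags plants", {
  set.seed(71)
  universe <- sprintf("g%04d", 1:1000)
  hypo <- universe[1:100]
  hyper <- universe[101:200]
  # plant: 60 hypo genes forced over-expressed, rest of "over" random
  over <- c(hypo[1:60], sample(universe[201:1000], 100))
  under <- sample(setdiff(universe, c(over, hypo, hyper)), 150)
  res <- directional_correlation(hyper, hypo, over, under,
    gene_universe(universe),
    n_sims = 20000, seed = 72
  )
  expect_equal(res$pairing, c("hyper_over", "hypo_under", "hyper_under", "hypo_over"))
  expect_equal(res$correlation, c("positive", "positive", "negative", "negative"))
  ho <- res[res$pairing == "hypo_over", ]
  expect_gt(ho$observed, ho$sim_mean + 3 * ho$sim_sd)
  expect_true(ho$enriched)
  expect_lt(ho$p_empirical, 1e-3)

  # depleted design: hypo/under overlap forced far below expectation
  hypo2 <- universe[1:150]
  hyper2 <- universe[151:250]
  under2 <- c(hypo2[1:12], sample(universe[301:1000], 188))
  res2 <- directional_correlation(hyper2, hypo2, character(), under2,
    gene_universe(universe),
    n_sims = 20000, seed = 73
  )
  hu <- res2[res2$pairing == "hypo_under", ]
  expect_lt(hu$observed, hu$sim_mean)
  expect_true(hu$depleted)

  expect_error(
    directional_correlation(hyper, c(hyper[1], hypo), over, under, 1000),
    "overlap"
  )
  expect_error(
    directional_correlation(hyper, hypo, over, c(over[1], under), 1000),
    "overlap"
  )
  expect_error(
    directional_correlation(c(hyper, "stranger"), hypo, over, under,
      gene_universe(universe)
    ),
    "outside the universe"
  )
})

test_that("null coupling shows no directional enrichment", {
  set.seed(74)
  universe <- sprintf("g%04d", 1:1000)
  hyper <- sample(universe, 100)
  hypo <- sample(setdiff(universe, hyper), 100)
  over <- sample(universe, 150)
  under <- sample(setdiff(universe, over), 150)
  res <- directional_correlation(hyper, hypo, over, under,
    gene_universe(universe),
    n_sims = 10000, seed = 75
  )
  expect_false(any(res$enriched))
  # observed overlaps sit within 3 simulated SDs of the simulated mean
  expect_true(all(abs(res$observed - res$sim_mean) <= 3 * res$sim_sd))
})

test_that("DEG direction split follows the sign convention per frame", {
  deg <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    logFC = c(2, -1.5, 0.5, -3),
    FDR = c(1e-5, 1e-6, 0.5, 1e-8)
  )
  ov <- split_deg_directions(deg, 1e-3, frame = "ovary")
  expect_equal(ov$over, "g1")
  expect_setequal(ov$under, c("g2", "g4"))
  hp <- split_deg_directions(deg, 1e-3, frame = "hypothalamus")
  expect_setequal(hp$over, c("g2", "g4"))
  expect_equal(hp$under, "g1")
})
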