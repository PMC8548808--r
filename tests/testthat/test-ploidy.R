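test_that("allele-balance extraction applies depth and minor-read filters", {
  ref <- matrix(c(5L, 10L, 3L), 3)
  alt <- matrix(c(5L, 0L, 2L), 3)
  ds <- makeDataset(ref, alt, ploidy = 2L)
  ab <- extractAlleleBalance(ds, 1, min_depth = 10, min_minor_reads = 3)
  expect_equal(ab$values, 0.5)          # AD=(5,5) retained at exactly 0.5
  expect_equal(ab$n_sites_retained, 1L) # (10,0) homozygous and (3,2) shallow drop
  expect_error(extractAlleleBalance(ds, "nope"), "unknown individual")
})

test_that("EM log-likelihood is non-decreasing and free nests fixed", {
  x <- simulateAlleleBalance(4, 1500, depth_mean = 30, seed = 37)
  for (k in 2:4) {
    ff <- fitFixedMixture(x, k)
    expect_true(all(diff(ff$logLik_trace) > -1e-8))
    fr <- fitFreeMixture(x, k - 1L)
    expect_true(all(diff(fr$logLik_trace) > -1e-8))
    expect_gte(fr$logLik, ff$logLik - 1e-6)
  }
})

test_that("degenerate unimodal data: single component takes all the weight", {
  set.seed(41)
  x <- pmin(pmax(rnorm(800, 0.5, 0.01), 0.01), 0.99)
  ff <- fitFixedMixture(x, 2)
  expect_lt(ff$noise_weight, 0.02)
  expect_gt(ff$weights[1], 0.95)
  fr <- fitFreeMixture(x, 3)
  # the free components collapse onto the single mode
  expect_lt(diff(range(fr$means)), 0.05)
  expect_lt(fr$noise_weight, 0.05)
  expect_identical(fitFreeMixture(x, 3)$means, fr$means)  # deterministic
})

test_that("known tetraploid mixture weights are recovered within 0.03", {
  set.seed(43)
  n <- 5000
  comp <- sample(1:3, n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  x <- rnorm(n, c(0.25, 0.5, 0.75)[comp], 0.05)
  x <- x[x > 0 & x < 1]
  ff <- fitFixedMixture(x, 4)
  expect_lt(max(abs(ff$weights - c(0.3, 0.4, 0.3))), 0.03)
  expect_lt(abs(sqrt(ff$variance) - 0.05), 0.01)
})

test_that("ploidy selection recovers simulated diploids and tetraploids", {
  for (k in c(2L, 4L)) {
    x <- simulateAlleleBalance(k, 2000, depth_mean = 30, seed = 47 + k)
    pc <- selectPloidy(x)
    expect_equal(pc$ploidy, k)
    expect_true(pc$confident)
    expect_equal(nrow(pc$stats), 3)       # a statistic for every candidate
    expect_true(all(is.finite(pc$stats$ratio)))
  }
})

test_that("uniform noise balances yield a low-confidence call", {
  set.seed(53)
  x <- runif(400, 0.02, 0.98)
  pc <- selectPloidy(x)
  expect_false(pc$confident)
})

test_that("per-sample ploidy table covers a mixed-ploidy dataset", {
  sp <- scenarioSpec("standing_variation", n_loci = 1200, n_per_pop = 2L,
                     prop_selected = 0, depth_mean = 30,
                     pop_ploidy = c(D1_high = 4L, D1_low = 2L, D2_high = 4L,
                                    D2_low = 2L, OUT = 4L), seed = 59)
  ds <- simulateScenario(sp)
  tab <- callPloidyAll(ds)
  expect_equal(nrow(tab), ncol(ds))
  truth <- sampleMeta(ds)$ploidy
  expect_gte(mean(tab$selected_k == truth), 0.9)
})
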