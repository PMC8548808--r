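test_that("frequency EM behaves at fixed and symmetric inputs", {
  # all individuals homozygous reference
  ds <- makeDataset(ref = matrix(30L, 1, 4), alt = matrix(0L, 1, 4))
  q <- estimateAlleleFreqs(ds, error_rate = 0.001)
  expect_lt(q[1, 1], 0.01)
  # two balanced tetraploids -> q ~ 0.5
  ds2 <- makeDataset(ref = matrix(20L, 1, 2), alt = matrix(20L, 1, 2))
  q2 <- estimateAlleleFreqs(ds2, error_rate = 0.001)
  expect_equal(unname(q2[1, 1]), 0.5, tolerance = 1e-3)
  # all-missing locus flagged NA
  ds3 <- makeDataset(ref = matrix(c(0L, 10L), 2, 1), alt = matrix(c(0L, 5L), 2, 1))
  q3 <- estimateAlleleFreqs(ds3)
  expect_true(is.na(q3[1, 1]) && !is.na(q3[2, 1]))
})

test_that("frequency EM recovers a simulated locus frequency", {
  set.seed(61)
  n <- 16; k <- 4; q <- 0.3
  g <- rbinom(n, k, q)
  dp <- rep(30L, n)
  a <- rbinom(n, dp, ecoploid:::doseReadFrac(g, k, 0.005))
  ds <- makeDataset(ref = matrix(dp - a, 1), alt = matrix(a, 1))
  qh <- estimateAlleleFreqs(ds, error_rate = 0.005)
  expect_lt(abs(qh[1, 1] - q), 0.08)
})

test_that("dosage posterior equals brute-force enumeration to 1e-10", {
  # independent oracle: enumerate the product formula directly
  oracle <- function(refd, altd, k, q, e) {
    n <- refd + altd
    un <- vapply(0:k, function(g) {
      f <- (g / k) * (1 - e) + (1 - g / k) * e
      choose(n, altd) * f^altd * (1 - f)^(n - altd) * choose(k, g) *
        q^g * (1 - q)^(k - g)
    }, 0)
    un / sum(un)
  }
  cases <- list(c(12, 8, 4, 0.5, 0.01), c(0, 30, 4, 0.5, 0.001),
                c(7, 3, 2, 0.2, 0.005), c(20, 20, 6, 0.8, 0.02))
  for (cs in cases) {
    got <- dosagePosterior(cs[1], cs[2], cs[3], cs[4], cs[5])
    expect_lt(max(abs(got - oracle(cs[1], cs[2], cs[3], cs[4], cs[5]))), 1e-10)
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("vectorized caller agrees with the cell-wise posterior and handles missing data", {
  set.seed(67)
  L <- 40; n <- 6; k <- 4
  q <- runif(L, 0.1, 0.9)
  g <- matrix(rbinom(L * n, k, rep(q, n)), L, n)
  dp <- matrix(rpois(L * n, 25), L, n)
  dp[1, 1] <- 0L
  a <- matrix(rbinom(L * n, dp, ecoploid:::doseReadFrac(as.vector(g), k, 0.01)), L, n)
  ds <- makeDataset(dp - a, a, ploidy = k)
  freqs <- matrix(q, L, 1, dimnames = list(rownames(refDepth(ds)), "P1"))
  gt <- callGenotypes(ds, freqs = freqs, error_rate = 0.01)
  expect_true(is.na(dosage(gt)[1, 1]))       # zero depth -> missing
  for (idx in list(c(2, 1), c(10, 3), c(40, 6))) {
    po <- dosagePosterior(dp[idx[1], idx[2]] - a[idx[1], idx[2]],
                          a[idx[1], idx[2]], k, q[idx[1]], 0.01)
    expect_equal(dosage(gt)[idx[1], idx[2]], which.max(po) - 1L)
    expect_equal(maxPosterior(gt)[idx[1], idx[2]], max(po), tolerance = 1e-9)
  }
  # overwhelming evidence: AD = (0, 30) at q = 0.5 -> dosage k
  ds5 <- makeDataset(ref = matrix(0L, 1, 1), alt = matrix(30L, 1, 1))
  f5 <- matrix(0.5, 1, 1, dimnames = list(rownames(refDepth(ds5)), "P1"))
  expect_equal(dosage(callGenotypes(ds5, f5, error_rate = 0.001))[1, 1], 4)
})

test_that("Hind/He closed form and exclusion rules", {
  ds <- makeDataset(ref = matrix(c(5L, 1L), 1, 2), alt = matrix(c(5L, 0L), 1, 2))
  hh <- hindHe(ds)
  # individual 2 has a single read and is excluded; AD=(5,5): 2*25/90
  expect_equal(hh$mean_hind, 50 / 90)
  expect_equal(hh$n_ind, 1L)
  # monomorphic locus undefined
  ds2 <- makeDataset(ref = matrix(10L, 1, 3), alt = matrix(0L, 1, 3))
  expect_false(hindHe(ds2)$defined)
})

test_that("Hind/He approaches (k-1)/k under Mendelian segregation", {
  for (k in c(2L, 4L)) {
    set.seed(70 + k)
    n <- 200; L <- 300
    q <- rep(0.5, L)
    g <- matrix(rbinom(L * n, k, 0.5), L, n)
    dp <- matrix(100L, L, n)
    a <- matrix(rbinom(L * n, dp, ecoploid:::doseReadFrac(as.vector(g), k, 0.001)), L, n)
    ds <- makeDataset(dp - a, a, ploidy = k)
    hh <- hindHe(ds)
    expect_lt(abs(mean(hh$hind_he, na.rm = TRUE) - (k - 1) / k), 0.03)
  }
})

test_that("Hind/He threshold simulation is monotone, deterministic and above HWE", {
  t90 <- simulateHindHeThreshold(30, 2L, n_sim_loci = 500, quantile_p = 0.90, seed = 73)
  t99 <- simulateHindHeThreshold(30, 2L, n_sim_loci = 500, quantile_p = 0.99, seed = 73)
  expect_gt(t99$threshold, t90$threshold)
  expect_gt(t90$threshold, 0.5)  # upper quantile exceeds the HWE expectation
  again <- simulateHindHeThreshold(30, 2L, n_sim_loci = 500, quantile_p = 0.90, seed = 73)
  expect_identical(t90$threshold, again$threshold)
  expect_error(simulateHindHeThreshold(30, 2L, depths = c(0, 0)), "degenerate")
})

test_that("ploidy-consistency partition uses inclusive thresholds and is exhaustive", {
  hh <- data.frame(locus = paste0("L", 1:6),
                   mean_hind = 0.3, he = 0.5,
                   hind_he = c(0.40, 0.52, 0.60, 0.65, 0.80, NA),
                   n_ind = 10, defined = c(rep(TRUE, 5), FALSE))
  part <- partitionLociByPloidy(hh, list(t_diploid = 0.52, t_tetraploid = 0.65))
  expect_setequal(part$diploid_set, c("L1", "L2"))
  expect_setequal(part$tetraploid_set, c("L3", "L4"))
  expect_setequal(part$discarded, c("L5", "L6"))
  expect_length(c(part$diploid_set, part$tetraploid_set, part$discarded), 6)
  expect_error(partitionLociByPloidy(hh, list(t_diploid = 0.7, t_tetraploid = 0.65)))
})

test_that("coverage filter boundaries", {
  ref <- rbind(c(20L, 20L, 0L, 0L),    # 50% genotyped -> fails strict >
               c(20L, 20L, 19L, 21L),  # mean 20 -> kept
               c(20L, 20L, 19L, 20L))  # mean 19.75 -> dropped
  ds <- makeDataset(ref, matrix(0L, 3, 4))
  cf <- coverageFilter(ds, min_prop_genotyped = 0.5, min_mean_depth = 20)
  expect_setequal(cf$retained, "L2")
  empty <- makeDataset(matrix(0L, 0, 2), matrix(0L, 0, 2))
  expect_length(coverageFilter(empty)$retained, 0)
})

test_that("tetraploid MAP calls are near-perfect at depth 200", {
  sp <- scenarioSpec("standing_variation", n_loci = 800, prop_selected = 0,
                     depth_mean = 200, depth_dispersion = 10,
                     error_rate = 0.001, n_per_pop = 4L, seed = 79)
  ds <- simulateScenario(sp)
  gt <- callGenotypes(ds, error_rate = 0.001)
  acc <- mean(dosage(gt) == trueDosage(ds), na.rm = TRUE)
  expect_gte(acc, 0.99)
  pm <- maxPosterior(gt)
  expect_true(all(pm[!is.na(pm)] <= 1 + 1e-9))
})
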