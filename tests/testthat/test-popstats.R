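test_that("gene diversity matches hand arithmetic", {
  expect_equal(geneDiversity(c(0.5, 0.5)), 0.5)
  expect_equal(geneDiversity(c(1, 0)), 0)
  expect_equal(geneDiversity(c(0.25, 0.75)), 0.375)
  expect_error(geneDiversity(c(0.5, 0.4)), "invalid")
})

test_that("F_ST, Jost's D and D_XY match hand oracles", {
  expect_equal(fstGst(c(0.3, 0.3)), 0)
  expect_equal(fstGst(c(0, 1)), 1)
  expect_equal(fstGst(c(0.2, 0.8)), 0.36)          # (0.5 - 0.32) / 0.5
  expect_true(is.na(fstGst(c(0, 0))))              # Ht = 0 undefined
  expect_error(fstGst(matrix(0.5, 2, 1)), ">= 2")

  expect_equal(jostD(c(0.4, 0.4)), 0)
  expect_equal(jostD(c(0, 1)), 1)
  expect_equal(jostD(c(0.2, 0.8)), (0.18 / 0.68) * 2)

  expect_equal(dxy(0.5, 0.5), 0.5)
  expect_equal(dxy(0, 1), 1)
  expect_equal(dxy(0.2, 0.8), 0.68)
  md <- meanDxy(c(0.2, NA, 0.5), c(0.8, 0.1, 0.5))
  expect_equal(md$n_used, 2)
  expect_equal(md$mean, mean(c(0.68, 0.5)))
})

test_that("differentiation statistics are invariant to allele-label swaps", {
  set.seed(83)
  p <- matrix(runif(300), 100, 3)
  expect_equal(fstGst(p), fstGst(1 - p))
  expect_equal(jostD(p), jostD(1 - p))
  expect_equal(dxy(p[, 1], p[, 2]), dxy(1 - p[, 1], 1 - p[, 2]))
})

test_that("mean Hs <= Ht so F_ST is non-negative (Jensen)", {
  set.seed(89)
  p <- matrix(runif(500), 100, 5)
  f <- fstGst(p)
  expect_true(all(f >= -1e-12, na.rm = TRUE))
  expect_true(all(f <= 1 + 1e-12, na.rm = TRUE))
})

test_that("MAF filter uses a strict threshold", {
  freq <- c(a = 0.05, b = 0.051, c = 0.5, d = 0.96, e = NA)
  mf <- mafFilter(freq, 0.05)
  expect_setequal(mf$retained, c("b", "c"))       # 0.05 dropped; 1-0.96 = 0.04 dropped
  mono <- mafFilter(c(x = 0, y = 1), 0.05)
  expect_length(mono$retained, 0)
  expect_equal(mono$report$discarded, 2)
})

test_that("locusStats assembles the per-locus table", {
  p <- matrix(c(0.2, 0.5, 0.8, 0.5), 2, 2,
              dimnames = list(c("L1", "L2"), c("A", "B")))
  tab <- locusStats(p)
  expect_equal(tab$fst[1], 0.36)
  expect_equal(tab$dxy_A.B, unname(dxy(p[, 1], p[, 2])))
  expect_equal(tab$ht[2], 0.5)
  expect_equal(tab$maf, unname(pmin(rowMeans(p), 1 - rowMeans(p))))
})

test_that("two-population G_ST recovers the simulated drift intensity", {
  set.seed(97)
  F <- 0.2
  p0 <- runif(6000, 0.05, 0.95)
  p <- cbind(ecoploid:::rdrift(p0, F), ecoploid:::rdrift(p0, F))
  est <- multilocusGst(p)
  expect_lt(abs(est$f_hat - F) / F, 0.15)
  # and the uncorrected two-deme G_ST sits near F/(2-F)
  expect_lt(abs(est$gst - F / (2 - F)) / (F / (2 - F)), 0.15)
})

test_that("posterior-mean frequencies track MAP frequencies and shrink at low depth", {
  sp <- scenarioSpec("standing_variation", n_loci = 400, prop_selected = 0,
                     depth_mean = 8, n_per_pop = 6L, seed = 211)
  ds <- simulateScenario(sp)
  gt <- callGenotypes(ds)
  f_map <- popFreqs(gt)$freq
  f_pm <- popFreqs(gt, posterior_mean = TRUE)$freq
  expect_equal(dim(f_pm), dim(f_map))
  expect_lt(mean(abs(f_pm - f_map), na.rm = TRUE), 0.05)
  expect_false(identical(f_pm, f_map))
})
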