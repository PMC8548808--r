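# Vectorized dosage-posterior machinery shared by the frequency EM and the
# genotype caller. For a group of individuals with common ploidy k, reads at
# each cell are Binomial(depth, f_g) with f_g = (g/k)(1-e) + (1-g/k)e, and the
# prior over dosages g = 0..k is Binomial(k, q) with q the population allele
# frequency at that locus. Likelihoods do not change across EM iterations, so
# they are computed once (normalized per cell to a max of 1 for numerical
# range) and the per-iteration work is a prior multiply + renormalize.
.doseLik <- function(alt, dp, k, e) {
  ll <- lapply(0:k, function(g) dbinom(alt, dp, doseReadFrac(g, k, e), log = TRUE))
  mx <- Reduce(pmax, ll)
  lapply(ll, function(x) exp(x - mx))
}

.dosePosterior <- function(lik, q, k) {
  # lik: list over g of normalized (L x n) likelihood matrices; q: length-L
  # frequency vector. Returns list over g of posterior matrices (cells with
  # zero depth carry the prior).
  L <- nrow(lik[[1]])
  post <- vector("list", k + 1)
  tot <- 0
  for (g in 0:k) {
    # prior vector recycles down columns (matrices are L x n, column-major)
    post[[g + 1]] <- lik[[g + 1]] * pmax(dbinom(g, k, q), 1e-300)
    tot <- tot + post[[g + 1]]
  }
  for (g in 0:k) post[[g + 1]] <- post[[g + 1]] / tot
  post
}

#' Estimate per-locus allele frequencies by EM over dosage posteriors
#'
#' Population-informed genotyping prior: iterates between a Binomial(k, q)
#' dosage prior and per-individual dosage posteriors, updating q as the
#' posterior-mean dosage divided by ploidy, averaged over genotyped
#' individuals, until the largest frequency change drops below \code{tol}.
#' Frequencies are estimated within groups defined by \code{by} (default: the
#' sample's population), which matches how structured populations are handled
#' by polyploid-aware callers.
#'
#' @param ds a \linkS4class{ReadDataset}.
#' @param error_rate per-read miscall probability assumed by the read model.
#' @param by grouping factor for frequency estimation, one value per sample
#'   (default \code{population}); use a constant to pool all samples.
#' @param max_iter,tol EM controls.
#' @param ploidy_override optional named vector of per-sample ploidies to use
#'   instead of the metadata (e.g. from [callPloidyAll()]).
#' @return a matrix (loci x groups) of alternate-allele frequencies; loci with
#'   no genotyped individual in a group are NA.
#' @export
estimateAlleleFreqs <- function(ds, error_rate = 0.005,
                                by = sampleMeta(ds)$population,
                                max_iter = 50, tol = 1e-6,
                                ploidy_override = NULL) {
  stopifnot(is(ds, "ReadDataset"))
  kvec <- ploidy(ds)
  if (!is.null(ploidy_override)) kvec[names(ploidy_override)] <- ploidy_override
  by <- as.character(by)
  groups <- unique(by)
  alt <- altDepth(ds); dp <- refDepth(ds) + alt
  L <- nrow(ds)
  out <- matrix(NA_real_, L, length(groups),
                dimnames = list(rownames(ds), groups))
  for (grp in groups) {
    js <- which(by == grp)
    ksub <- kvec[js]
    # per-locus totals accumulated across ploidy sub-groups
    q <- rep(0.5, L)
    covered <- rowSums(dp[, js, drop = FALSE] > 0) > 0
    ll_by_k <- lapply(unique(ksub), function(k) {
      sel <- js[ksub == k]
      list(k = k, idx = sel,
           ll = .doseLik(alt[, sel, drop = FALSE], dp[, sel, drop = FALSE], k,
                         error_rate),
           has = dp[, sel, drop = FALSE] > 0)
    })
    for (it in seq_len(max_iter)) {
      num <- rep(0, L); den <- rep(0, L)
      for (blk in ll_by_k) {
        k <- blk$k
        wsum <- blk$ll[[1]] * pmax(dbinom(0, k, q), 1e-300)
        gsum <- 0
        for (g in seq_len(k)) {
          w <- blk$ll[[g + 1]] * pmax(dbinom(g, k, q), 1e-300)
          wsum <- wsum + w
          gsum <- gsum + g * w
        }
        num <- num + rowSums((gsum / wsum) * blk$has)
        den <- den + k * rowSums(blk$has)
      }
      qn <- ifelse(den > 0, num / pmax(den, 1), q)
      delta <- max(abs(qn - q))
      q <- qn
      if (delta < tol) break
    }
    q[!covered] <- NA_real_
    out[, grp] <- q
  }
  out
}

#' Call MAP dosage genotypes under per-individual ploidy
#'
#' Posterior P(g | reads) proportional to Binomial(alt | depth, f_g) x
#' Binomial(g | k, q), with f_g = (g/k)(1-e) + (1-g/k)e and q the
#' population allele frequency (estimated by [estimateAlleleFreqs()] when not
#' supplied). Cells with zero depth are missing.
#'
#' @param ds a \linkS4class{ReadDataset}.
#' @param freqs optional loci x groups frequency matrix; estimated when NULL.
#' @param error_rate per-read miscall probability.
#' @param by grouping factor matching \code{freqs} columns.
#' @param ploidy_override optional named per-sample ploidy vector.
#' @return a \linkS4class{GenotypeCalls}; assays include the MAP dosage, its
#'   posterior probability, the posterior-mean dosage, and depth.
#' @export
callGenotypes <- function(ds, freqs = NULL, error_rate = 0.005,
                          by = sampleMeta(ds)$population,
                          ploidy_override = NULL) {
  stopifnot(is(ds, "ReadDataset"))
  kvec <- ploidy(ds)
  if (!is.null(ploidy_override)) kvec[names(ploidy_override)] <- ploidy_override
  by <- as.character(by)
  if (is.null(freqs))
    freqs <- estimateAlleleFreqs(ds, error_rate, by, ploidy_override = ploidy_override)
  alt <- altDepth(ds); dp <- refDepth(ds) + alt
  L <- nrow(ds); N <- ncol(ds)
  dose <- post_max <- mean_dose <- matrix(NA_real_, L, N,
                                          dimnames = dimnames(alt))
  for (grp in unique(by)) {
    q <- freqs[, grp]
    q[is.na(q)] <- 0.5
    for (k in unique(kvec[by == grp])) {
      js <- which(by == grp & kvec == k)
      ll <- .doseLik(alt[, js, drop = FALSE], dp[, js, drop = FALSE], k,
                     error_rate)
      post <- .dosePosterior(ll, q, k)
      best <- matrix(0L, L, length(js)); bp <- post[[1]]
      eg <- 0
      for (g in seq_len(k)) {
        better <- post[[g + 1]] > bp
        best[better] <- g
        bp[better] <- post[[g + 1]][better]
        eg <- eg + g * post[[g + 1]]
      }
      dose[, js] <- best
      post_max[, js] <- bp
      mean_dose[, js] <- eg
    }
  }
  miss <- dp == 0
  dose[miss] <- NA
  post_max[miss] <- NA
  mean_dose[miss] <- NA
  se <- SummarizedExperiment(
    assays = list(dosage = dose, maxPosterior = post_max,
                  meanDosage = mean_dose, depth = dp),
    colData = DataFrame(sampleMeta(ds), ploidy_used = kvec[colnames(ds)],
                        row.names = colnames(ds)))
  colData(se)$ploidy <- kvec[colnames(ds)]
  metadata(se) <- list(popFreq = freqs, error_rate = error_rate)
  new("GenotypeCalls", se)
}

#' Dosage posterior for a single cell (reference enumeration form)
#'
#' Direct enumeration of the unnormalized Binomial-product posterior for one
#' individual at one locus; exposed mainly for validation and inspection.
#'
#' @param ref,alt read depths.
#' @param k ploidy.
#' @param q population allele frequency.
#' @param error_rate per-read miscall probability.
#' @return numeric vector of length k+1 summing to 1 (dosages 0..k).
#' @export
dosagePosterior <- function(ref, alt, k, q, error_rate = 0.005) {
  n <- ref + alt
  if (n == 0) return(rep(NA_real_, k + 1))
  lik <- dbinom(alt, n, doseReadFrac(0:k, k, error_rate))
  prior <- dbinom(0:k, k, q)
  un <- lik * prior
  un / sum(un)
}

#' Per-locus Hind/He statistic
#'
#' Hind is the probability that two reads drawn without replacement from one
#' individual carry different alleles: 2 r a / (n (n-1)) with r, a the ref and
#' alt read counts and n = r + a (individuals with n < 2 are excluded). He is
#' the population gene diversity 1 - sum p_i^2 computed from pooled read
#' proportions across individuals (avoiding circularity with the genotype
#' caller). The locus value is mean(Hind) / He; under Mendelian segregation
#' its expectation is (k-1)/k, and markers exceeding a simulated upper bound
#' betray collapsed paralogs or contamination.
#'
#' @param ds a \linkS4class{ReadDataset}.
#' @param loci optional locus subset (names or indices).
#' @return a data.frame of class \code{"HindHeTable"}: locus, mean_hind, he,
#'   hind_he, n_ind (contributing individuals), defined flag.
#' @export
hindHe <- function(ds, loci = NULL) {
  stopifnot(is(ds, "ReadDataset"))
  r <- refDepth(ds); a <- altDepth(ds)
  if (!is.null(loci)) { r <- r[loci, , drop = FALSE]; a <- a[loci, , drop = FALSE] }
  n <- r + a
  ok <- n >= 2
  hind <- matrix(NA_real_, nrow(r), ncol(r))
  hind[ok] <- 2 * r[ok] * a[ok] / (n[ok] * (n[ok] - 1))
  mean_hind <- rowSums(hind, na.rm = TRUE) / pmax(rowSums(ok), 1)
  p_pool <- rowSums(a) / pmax(rowSums(n), 1)
  he <- 2 * p_pool * (1 - p_pool)
  defined <- rowSums(ok) >= 2 & he > 0
  out <- data.frame(locus = rownames(r), mean_hind = mean_hind, he = he,
                    hind_he = ifelse(defined, mean_hind / he, NA_real_),
                    n_ind = rowSums(ok), defined = defined,
                    stringsAsFactors = FALSE)
  class(out) <- c("HindHeTable", "data.frame")
  out
}

#' Simulate the null distribution of Hind/He and return a threshold
#'
#' Simulates well-behaved Mendelian loci (frequency ~ Uniform(0.05, 0.95),
#' dosages Binomial(k, q), negative-binomial depths, binomial reads with
#' error), computes the per-locus Hind/He, and returns the requested upper
#' quantile. Loci above this threshold in real data are statistically
#' inconsistent with ploidy-k Mendelian behaviour.
#'
#' @param n_ind number of individuals per simulated locus.
#' @param k ploidy.
#' @param depth_mean,depth_dispersion negative-binomial depth model (or supply
#'   \code{depths}, an empirical depth pool sampled with replacement).
#' @param depths optional empirical depths.
#' @param error_rate per-read miscall probability.
#' @param n_sim_loci simulated loci.
#' @param quantile_p upper-quantile defining the threshold.
#' @param seed integer seed.
#' @return a list: \code{threshold}, \code{values} (simulated per-locus
#'   Hind/He), and the simulation metadata.
#' @export
simulateHindHeThreshold <- function(n_ind, k, depth_mean = 25,
                                    depth_dispersion = 5, depths = NULL,
                                    error_rate = 0.005, n_sim_loci = 2000,
                                    quantile_p = 0.95, seed = 1L) {
  if (!is.null(depths) && (!length(depths) || all(depths <= 0)))
    stop("degenerate empirical depth model")
  set.seed(seed)
  q <- runif(n_sim_loci, 0.05, 0.95)
  g <- matrix(rbinom(n_sim_loci * n_ind, k, rep(q, n_ind)), n_sim_loci, n_ind)
  dp <- if (is.null(depths))
    matrix(rnbinom(n_sim_loci * n_ind, size = depth_dispersion, mu = depth_mean),
           n_sim_loci, n_ind)
  else matrix(sample(depths, n_sim_loci * n_ind, replace = TRUE),
              n_sim_loci, n_ind)
  a <- matrix(rbinom(length(g), as.vector(dp),
                     doseReadFrac(as.vector(g), k, error_rate)),
              n_sim_loci, n_ind)
  r <- dp - a
  n <- dp
  ok <- n >= 2
  hind <- matrix(NA_real_, n_sim_loci, n_ind)
  hind[ok] <- 2 * r[ok] * a[ok] / (n[ok] * (n[ok] - 1))
  mean_hind <- rowSums(hind, na.rm = TRUE) / pmax(rowSums(ok), 1)
  p_pool <- rowSums(a) / pmax(rowSums(n), 1)
  he <- 2 * p_pool * (1 - p_pool)
  vals <- (mean_hind / he)[he > 0 & rowSums(ok) >= 2]
  list(threshold = as.numeric(quantile(vals, quantile_p)),
       values = vals, n_ind = n_ind, k = k, n_sim_loci = n_sim_loci,
       quantile_p = quantile_p, seed = seed)
}

#' Simulate the diploid/tetraploid Hind/He threshold pair
#'
#' @inheritParams simulateHindHeThreshold
#' @return a list of class \code{"ThresholdPair"} with \code{t_diploid},
#'   \code{t_tetraploid} and the simulation metadata.
#' @export
hindHeThresholdPair <- function(n_ind, depth_mean = 25, depth_dispersion = 5,
                                depths = NULL, error_rate = 0.005,
                                n_sim_loci = 2000, quantile_p = 0.95,
                                seed = 1L) {
  t2 <- simulateHindHeThreshold(n_ind, 2L, depth_mean, depth_dispersion,
                                depths, error_rate, n_sim_loci, quantile_p,
                                seed = childSeed(seed, 11L))
  t4 <- simulateHindHeThreshold(n_ind, 4L, depth_mean, depth_dispersion,
                                depths, error_rate, n_sim_loci, quantile_p,
                                seed = childSeed(seed, 12L))
  structure(list(t_diploid = t2$threshold, t_tetraploid = t4$threshold,
                 meta = list(n_ind = n_ind, n_sim_loci = n_sim_loci,
                             quantile_p = quantile_p, seed = seed)),
            class = "ThresholdPair")
}

#' Partition loci by ploidy consistency of Hind/He
#'
#' Loci with Hind/He at or below the diploid threshold are statistically
#' consistent with diploid Mendelian behaviour; loci between the two
#' thresholds with tetraploid behaviour; loci above the tetraploid threshold
#' (or with undefined Hind/He) are discarded as likely collapsed paralogs.
#' Thresholds are inclusive upper bounds.
#'
#' @param hh a \code{HindHeTable} from [hindHe()].
#' @param thresholds a \code{ThresholdPair} (or list with \code{t_diploid},
#'   \code{t_tetraploid}).
#' @return a list: \code{diploid_set}, \code{tetraploid_set},
#'   \code{discarded} (locus names), and \code{report} (a data.frame of
#'   counts).
#' @export
partitionLociByPloidy <- function(hh, thresholds) {
  t2 <- thresholds$t_diploid; t4 <- thresholds$t_tetraploid
  if (!(t2 > 0 && t2 < t4)) stop("need 0 < t_diploid < t_tetraploid")
  v <- hh$hind_he
  undef <- !hh$defined | is.na(v)
  dip <- !undef & v <= t2
  tet <- !undef & !dip & v <= t4
  disc <- undef | (!dip & !tet)
  report <- data.frame(
    rule = c("diploid_consistent", "tetraploid_consistent", "discarded_high",
             "discarded_undefined"),
    kept = c(sum(dip), sum(tet), 0L, 0L),
    discarded = c(0L, 0L, sum(!undef & !dip & !tet), sum(undef)))
  list(diploid_set = hh$locus[dip], tetraploid_set = hh$locus[tet],
       discarded = hh$locus[disc], report = report,
       thresholds = c(t_diploid = t2, t_tetraploid = t4))
}

#' Coverage and genotyping-rate filter
#'
#' Retains loci genotyped (depth > 0) in more than \code{min_prop_genotyped}
#' of individuals and with mean per-individual depth (over genotyped
#' individuals) of at least \code{min_mean_depth}.
#'
#' @param ds a \linkS4class{ReadDataset}.
#' @param min_prop_genotyped minimum genotyped proportion (strict >).
#' @param min_mean_depth minimum mean depth among genotyped individuals
#'   (inclusive >=).
#' @return a list: \code{retained} locus names and a \code{report} data.frame
#'   (kept/discarded counts per rule).
#' @export
coverageFilter <- function(ds, min_prop_genotyped = 0.5, min_mean_depth = 20) {
  stopifnot(is(ds, "ReadDataset"))
  dp <- refDepth(ds) + altDepth(ds)
  if (nrow(dp) == 0)
    return(list(retained = character(0),
                report = data.frame(rule = c("prop_genotyped", "mean_depth"),
                                    kept = c(0L, 0L), discarded = c(0L, 0L))))
  geno <- dp > 0
  prop <- rowMeans(geno)
  mean_dp <- rowSums(dp) / pmax(rowSums(geno), 1)
  pass_prop <- prop > min_prop_genotyped
  pass_depth <- mean_dp >= min_mean_depth
  keep <- pass_prop & pass_depth
  report <- data.frame(
    rule = c("prop_genotyped", "mean_depth"),
    kept = c(sum(pass_prop), sum(pass_depth)),
    discarded = c(sum(!pass_prop), sum(!pass_depth)))
  list(retained = rownames(dp)[keep], report = report)
}
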