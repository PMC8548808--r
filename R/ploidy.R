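#' Extract allele-balance values for one individual
#'
#' Returns alternate-read fractions alt/(ref+alt) at putatively heterozygous
#' bi-allelic sites: total depth >= \code{min_depth} and both alleles
#' supported by >= \code{min_minor_reads} reads. The multimodality of these
#' values is what reveals ploidy (one mode at 1/2 for diploids; modes near
#' 1/4, 1/2, 3/4 for autotetraploids).
#'
#' @param ds a \linkS4class{ReadDataset}.
#' @param individual sample id (column name) or index.
#' @param min_depth minimum total depth for a site to be considered.
#' @param min_minor_reads minimum reads supporting each allele.
#' @return a list of class \code{"AlleleBalanceSet"}: \code{individual},
#'   \code{values} (fractions strictly in (0,1)), \code{n_sites_total},
#'   \code{n_sites_retained}, \code{empty} flag.
#' @export
extractAlleleBalance <- function(ds, individual, min_depth = 10, min_minor_reads = 3) {
  stopifnot(is(ds, "ReadDataset"))
  if (is.character(individual) && !individual %in% colnames(ds))
    stop("unknown individual: ", individual)
  r <- refDepth(ds)[, individual]
  a <- altDepth(ds)[, individual]
  n <- r + a
  keep <- n >= min_depth & r >= min_minor_reads & a >= min_minor_reads
  vals <- (a / n)[keep]
  structure(list(individual = if (is.character(individual)) individual
                   else colnames(ds)[individual],
                 values = as.numeric(vals),
                 n_sites_total = length(n),
                 n_sites_retained = sum(keep),
                 empty = sum(keep) == 0L),
            class = "AlleleBalanceSet")
}

#' @export
print.AlleleBalanceSet <- function(x, ...) {
  cat(sprintf("AlleleBalanceSet '%s': %d/%d sites retained\n",
              x$individual, x$n_sites_retained, x$n_sites_total))
  invisible(x)
}

# Core EM for a Gaussian mixture on (0,1) with one uniform noise component.
# means: fixed vector (fixed model) or NULL (free: initialized from quantiles,
# then re-estimated). Shared variance across components, floored at var_floor.
.balanceEM <- function(x, means, n_components = length(means),
                       free_means = is.null(means),
                       max_iter = 500, tol = 1e-6, var_floor = 1e-4) {
  stopifnot(length(x) > 0, all(is.finite(x)))
  m <- n_components
  if (free_means) means <- as.numeric(quantile(x, (seq_len(m) - 0.5) / m, names = FALSE))
  w <- rep(0.95 / m, m)
  w0 <- 0.05              # uniform(0,1) de-noising component
  v <- 0.01
  n <- length(x)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    dens <- vapply(seq_len(m), function(j) w[j] * dnorm(x, means[j], sqrt(v)),
                   numeric(n))
    if (m == 1L) dens <- matrix(dens, ncol = 1L)
    tot <- rowSums(dens) + w0
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    ll_old <- ll
    resp <- dens / tot
    r0 <- w0 / tot
    Nj <- colSums(resp)
    w <- Nj / n
    w0 <- sum(r0) / n
    if (free_means) {
      mu_new <- colSums(resp * x) / Nj
      means <- ifelse(Nj > 1e-12, mu_new, means)
    }
    sq <- vapply(seq_len(m), function(j) sum(resp[, j] * (x - means[j])^2),
                 numeric(1))
    v <- max(sum(sq) / max(sum(Nj), 1e-12), var_floor)
  }
  structure(list(model = if (free_means) sprintf("free-%d", m)
                   else sprintf("fixed-%d", length(means) + 1L),
                 means = means, weights = w, variance = v, noise_weight = w0,
                 logLik = ll_trace[length(ll_trace)], logLik_trace = ll_trace,
                 iterations = iter, converged = converged,
                 n = n, free_means = free_means),
            class = "MixtureFit")
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat(sprintf("MixtureFit %s: logL = %.3f (%d obs, %d iter%s)\n", x$model,
              x$logLik, x$n, x$iterations,
              if (x$converged) ", converged" else ""))
  cat("  means:  ", paste(sprintf("%.3f", x$means), collapse = " "), "\n")
  cat("  weights:", paste(sprintf("%.3f", x$weights), collapse = " "),
      sprintf("| noise %.3f, sd %.4f\n", x$noise_weight, sqrt(x$variance)))
  invisible(x)
}

#' Fit the fixed-ploidy allele-balance mixture
#'
#' EM over component weights and a shared variance, with component means fixed
#' at i/k (i = 1..k-1) for ploidy k, plus a uniform(0,1) de-noising component.
#' Initialization is deterministic (equal weights, variance 0.01, noise weight
#' 0.05); convergence when the log-likelihood change drops below 1e-6 or 500
#' iterations.
#'
#' @param balances an \code{AlleleBalanceSet} (or numeric vector of balances).
#' @param k candidate ploidy (component means at i/k).
#' @return a \code{"MixtureFit"}.
#' @export
fitFixedMixture <- function(balances, k) {
  x <- if (inherits(balances, "AlleleBalanceSet")) balances$values else balances
  if (length(x) == 0) stop("empty allele-balance input")
  if (!is_count(k) || k < 2) stop("k must be an integer >= 2")
  fit <- .balanceEM(x, means = seq_len(k - 1) / k)
  fit$k <- as.integer(k)
  fit$low_confidence_n <- length(x) < 50
  fit
}

#' Fit the free-means allele-balance mixture
#'
#' As [fitFixedMixture()] but component means are free parameters,
#' deterministically initialized at the (j-1/2)/m quantiles of the data.
#' The free model nests every fixed model with the same component count, so
#' its log-likelihood is the normalizing reference for ploidy selection.
#'
#' @param balances an \code{AlleleBalanceSet} or numeric vector.
#' @param n_components number of Gaussian components.
#' @return a \code{"MixtureFit"}.
#' @export
fitFreeMixture <- function(balances, n_components) {
  x <- if (inherits(balances, "AlleleBalanceSet")) balances$values else balances
  if (length(x) == 0) stop("empty allele-balance input")
  if (!is_count(n_components)) stop("n_components must be a positive count")
  .balanceEM(x, means = NULL, n_components = n_components)
}

#' Select the best-supported ploidy for an individual
#'
#' Fits the fixed mixture (means i/k) for each candidate ploidy k and one
#' common free-means reference mixture with max(candidates) - 1 components.
#' The selection statistic is the fixed-model log-likelihood normalized
#' against the free reference (delta = logL_fixed - logL_free; the
#' printed-form ratio logL_fixed/logL_free is reported for every candidate).
#' Because the fixed models are nested across even ploidies (the diploid
#' component set is a subset of the tetraploid one, so the raw likelihood can
#' never favour the smaller model), candidates are compared on a
#' BIC-penalized score, logL_fixed - (k+1)/2 log(n), which resolves the
#' degeneracy by parsimony while leaving genuinely multimodal signals
#' untouched.
#'
#' The call is flagged low-confidence when the top two penalized scores are
#' separated by fewer than 2 units, fewer than 50 balance values were
#' available, or the winning fit explains the data mostly through its uniform
#' noise component (noise weight > 0.5, e.g. on uniform random balances).
#'
#' @param balances an \code{AlleleBalanceSet} or numeric vector.
#' @param candidates candidate ploidies.
#' @return a list of class \code{"PloidyCall"}: \code{ploidy} (selected k),
#'   \code{stats} (data.frame with logL_fixed, logL_free, delta, ratio and
#'   bic_score per candidate), \code{confident} flag, \code{n_sites}.
#' @export
selectPloidy <- function(balances, candidates = c(2L, 3L, 4L)) {
  x <- if (inherits(balances, "AlleleBalanceSet")) balances$values else balances
  if (length(x) == 0) stop("empty allele-balance input")
  ref <- fitFreeMixture(x, max(candidates) - 1L)
  n <- length(x)
  fits <- lapply(candidates, function(k) fitFixedMixture(x, k))
  stats <- do.call(rbind, lapply(seq_along(candidates), function(i) {
    k <- candidates[i]; ff <- fits[[i]]
    data.frame(k = k, logL_fixed = ff$logLik, logL_free = ref$logLik,
               delta = ff$logLik - ref$logLik,
               ratio = ff$logLik / ref$logLik,
               bic_score = ff$logLik - 0.5 * (k + 1) * log(n))
  }))
  ord <- order(stats$bic_score, decreasing = TRUE)
  best_i <- ord[1]
  gap <- if (nrow(stats) > 1) stats$bic_score[ord[1]] - stats$bic_score[ord[2]]
         else Inf
  structure(list(ploidy = as.integer(stats$k[best_i]), stats = stats,
                 confident = gap >= 2 && n >= 50 &&
                   fits[[best_i]]$noise_weight <= 0.5,
                 n_sites = n,
                 individual = if (inherits(balances, "AlleleBalanceSet"))
                   balances$individual else NA_character_),
            class = "PloidyCall")
}

#' @export
print.PloidyCall <- function(x, ...) {
  cat(sprintf("PloidyCall: k = %d (%s; %d sites)\n", x$ploidy,
              if (x$confident) "confident" else "low confidence", x$n_sites))
  print(x$stats, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Call ploidy for every individual in a dataset
#'
#' @param ds a \linkS4class{ReadDataset}.
#' @param candidates candidate ploidies.
#' @param min_depth,min_minor_reads site filters passed to
#'   [extractAlleleBalance()].
#' @return a data.frame with one row per sample: n_sites, one
#'   \code{delta_k<k>} column per candidate, selected_k, confident.
#' @export
callPloidyAll <- function(ds, candidates = c(2L, 3L, 4L), min_depth = 10,
                          min_minor_reads = 3) {
  rows <- lapply(colnames(ds), function(s) {
    ab <- extractAlleleBalance(ds, s, min_depth, min_minor_reads)
    if (ab$empty) {
      out <- data.frame(sample = s, n_sites = 0L)
      for (k in candidates) out[[paste0("delta_k", k)]] <- NA_real_
      out$selected_k <- NA_integer_
      out$confident <- FALSE
      return(out)
    }
    pc <- selectPloidy(ab, candidates)
    out <- data.frame(sample = s, n_sites = ab$n_sites_retained)
    for (i in seq_along(candidates))
      out[[paste0("delta_k", candidates[i])]] <- pc$stats$delta[i]
    out$selected_k <- pc$ploidy
    out$confident <- pc$confident
    out
  })
  do.call(rbind, rows)
}

#' Simulate allele-balance values for heterozygous sites of known ploidy
#'
#' Utility for calibrating and testing ploidy selection: site frequencies are
#' Uniform(0.05, 0.95), dosages Binomial(k, q) conditioned on heterozygosity,
#' depths negative-binomial, and alternate reads binomial with symmetric read
#' error; the standard extraction filters are then applied.
#'
#' @param k true ploidy.
#' @param n_sites heterozygous sites to simulate (before filtering).
#' @param depth_mean,depth_dispersion negative-binomial depth parameters.
#' @param error_rate per-read miscall probability.
#' @param min_depth,min_minor_reads retention filters.
#' @param seed integer seed.
#' @return numeric vector of allele-balance values.
#' @export
simulateAlleleBalance <- function(k, n_sites = 2000, depth_mean = 30,
                                  depth_dispersion = 5, error_rate = 0.005,
                                  min_depth = 10, min_minor_reads = 3,
                                  seed = 1L) {
  set.seed(seed)
  q <- runif(n_sites, 0.05, 0.95)
  # dosage from Binomial(k, q) conditioned on 1 <= g <= k-1
  g <- vapply(q, function(qi) {
    pr <- dbinom(seq_len(k - 1), k, qi)
    sample(seq_len(k - 1), 1L, prob = pr)
  }, 0L)
  dp <- rnbinom(n_sites, size = depth_dispersion, mu = depth_mean)
  a <- rbinom(n_sites, dp, doseReadFrac(g, k, error_rate))
  r <- dp - a
  keep <- dp >= min_depth & a >= min_minor_reads & r >= min_minor_reads
  (a / dp)[keep]
}
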