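#' @import methods
#' @importFrom stats rbeta rbinom rnbinom runif dbinom dnorm quantile var setNames as.dist
#' @importFrom utils head read.table write.table
#' @importFrom S4Vectors metadata "metadata<-"
#' @importFrom SummarizedExperiment "rowData<-" "colData<-"
NULL

# Balding-Nichols drift pulse: child frequency given parent frequency p and
# drift intensity F, distributed Beta with mean p and variance F*p*(1-p).
# Loci already fixed (p = 0 or 1) stay fixed.
rdrift <- function(p, F) {
  stopifnot(F > 0, F < 1)
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  out <- p
  seg <- p > 0 & p < 1
  out[seg] <- rbeta(sum(seg), a[seg], b[seg])
  out
}

# clamp frequencies away from 0/1 so loci remain informative at small n
clampFreq <- function(p, lo = 0.001, hi = 0.999) {
  pmin(pmax(p, lo), hi)
}

# expected alternate read fraction for dosage g under ploidy k and
# symmetric per-read error e
doseReadFrac <- function(g, k, e) {
  f <- g / k
  f * (1 - e) + (1 - f) * e
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

is_frac <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

# deterministic child seed streams derived from one integer seed; kept
# below 2^31 so they remain valid R integers
childSeed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(idx)) %% 2147483399) + 1L
}
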