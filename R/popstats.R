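#' Gene diversity Hs = 1 - sum(p_i^2)
#'
#' Frequency-based ('expected heterozygosity' in diploids, but ploidy-free as
#' a gene diversity) for one locus given a full allele-frequency vector.
#'
#' @param p allele frequency vector summing to 1 (for bi-allelic data,
#'   \code{c(p, 1-p)}).
#' @return Hs.
#' @export
geneDiversity <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("invalid allele frequency vector")
  1 - sum(p^2)
}

# bi-allelic gene diversity from the alt frequency, vectorized
.hsBi <- function(p) 2 * p * (1 - p)

#' Population allele frequencies from genotype calls
#'
#' Alternate-allele frequency per locus and population: sum of called dosages
#' divided by the summed ploidy of genotyped individuals. The default uses
#' MAP dosages (deterministic); \code{posterior_mean = TRUE} instead sums the
#' posterior-mean dosages stored by [callGenotypes()], which shrinks calls at
#' low depth toward the population prior.
#'
#' @param gt a \linkS4class{GenotypeCalls}.
#' @param by grouping (default population).
#' @param posterior_mean use posterior-mean rather than MAP dosages.
#' @return list with \code{freq} (loci x groups), \code{n_chrom}
#'   (chromosomes sampled per locus/group).
#' @export
popFreqs <- function(gt, by = sampleMeta(gt)$population,
                     posterior_mean = FALSE) {
  stopifnot(is(gt, "GenotypeCalls"))
  d <- if (posterior_mean) assay(gt, "meanDosage") else dosage(gt)
  k <- colData(gt)$ploidy
  by <- as.character(by)
  groups <- unique(by)
  freq <- nch <- matrix(NA_real_, nrow(d), length(groups),
                        dimnames = list(rownames(d), groups))
  for (grp in groups) {
    js <- which(by == grp)
    called <- !is.na(d[, js, drop = FALSE])
    nchrom <- called %*% k[js]
    tot <- rowSums(d[, js, drop = FALSE] * called, na.rm = TRUE)
    freq[, grp] <- ifelse(nchrom > 0, tot / nchrom, NA_real_)
    nch[, grp] <- nchrom
  }
  list(freq = freq, n_chrom = nch)
}

#' Per-locus F_ST (Nei G_ST form)
#'
#' F_ST = (Ht - mean Hs) / Ht with Ht the gene diversity of the mean allele
#' frequency. Depends only on allele frequencies, hence valid across (and
#' between) ploidies. Undefined (NA) where Ht = 0.
#'
#' @param p matrix (loci x populations) or vector of per-population alternate
#'   allele frequencies at one locus.
#' @return vector of per-locus F_ST.
#' @export
fstGst <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (ncol(p) < 2) stop("need >= 2 populations")
  pbar <- rowMeans(p)
  ht <- .hsBi(pbar)
  hs <- rowMeans(.hsBi(p))
  ifelse(ht > 0, (ht - hs) / ht, NA_real_)
}

#' Per-locus Jost's D
#'
#' D = [(Ht - mean Hs) / (1 - mean Hs)] * n/(n-1) for n populations.
#'
#' @param p matrix (loci x populations) or vector at one locus.
#' @return vector of per-locus D.
#' @export
jostD <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  n <- ncol(p)
  if (n < 2) stop("need >= 2 populations")
  pbar <- rowMeans(p)
  ht <- .hsBi(pbar)
  hs <- rowMeans(.hsBi(p))
  ifelse(hs < 1, (ht - hs) / (1 - hs) * n / (n - 1), NA_real_)
}

#' Per-SNP absolute divergence D_XY
#'
#' D_XY = p1 (1 - p2) + (1 - p1) p2: the probability that alleles drawn from
#' the two populations differ. Genome-wide values are arithmetic means over
#' loci (see [meanDxy()]).
#'
#' @param p1,p2 alternate-allele frequencies (vectors over loci).
#' @return per-locus D_XY.
#' @export
dxy <- function(p1, p2) {
  p1 * (1 - p2) + (1 - p1) * p2
}

#' Mean D_XY across loci, skipping missing frequencies
#'
#' @param p1,p2 frequency vectors.
#' @return list: \code{mean}, \code{n_used}, \code{n_skipped}.
#' @export
meanDxy <- function(p1, p2) {
  d <- dxy(p1, p2)
  ok <- is.finite(d)
  list(mean = mean(d[ok]), n_used = sum(ok), n_skipped = sum(!ok))
}

#' Minor-allele-frequency filter
#'
#' Keeps loci whose global minor allele frequency strictly exceeds the
#' threshold.
#'
#' @param freq global alternate-allele frequency per locus (e.g. pooled over
#'   all samples), optionally named.
#' @param threshold MAF threshold (strict >).
#' @return list: \code{retained} (names or indices), \code{report}.
#' @export
mafFilter <- function(freq, threshold = 0.05) {
  maf <- pmin(freq, 1 - freq)
  keep <- !is.na(maf) & maf > threshold
  ids <- if (!is.null(names(freq))) names(freq) else seq_along(freq)
  list(retained = ids[keep],
       report = data.frame(rule = "maf", kept = sum(keep),
                           discarded = sum(!keep)))
}

#' Per-locus differentiation statistics table
#'
#' Assembles the per-locus statistics for a set of populations: per-population
#' Hs, mean Hs, Ht, F_ST (G_ST form), Jost's D, pairwise D_XY, and global MAF.
#'
#' @param freq matrix (loci x populations) of alternate-allele frequencies.
#' @param pairs optional list of length-2 character vectors naming population
#'   pairs for D_XY columns (default: all pairs).
#' @return a data.frame of class \code{"LocusStatsTable"}, one row per locus.
#' @export
locusStats <- function(freq, pairs = NULL) {
  pops <- colnames(freq)
  if (is.null(pairs))
    pairs <- utils::combn(pops, 2, simplify = FALSE)
  pbar <- rowMeans(freq)
  out <- data.frame(locus = rownames(freq), stringsAsFactors = FALSE)
  for (pop in pops) out[[paste0("hs_", pop)]] <- .hsBi(freq[, pop])
  out$mean_hs <- rowMeans(.hsBi(freq))
  out$ht <- .hsBi(pbar)
  out$fst <- fstGst(freq)
  out$jost_d <- jostD(freq)
  for (pr in pairs)
    out[[paste0("dxy_", pr[1], ".", pr[2])]] <- dxy(freq[, pr[1]], freq[, pr[2]])
  out$maf <- pmin(pbar, 1 - pbar)
  class(out) <- c("LocusStatsTable", "data.frame")
  out
}

#' Multilocus G_ST and the two-deme drift estimate
#'
#' Multilocus G_ST as the ratio of summed (Ht - mean Hs) to summed Ht. For two
#' populations that each drifted from a common ancestor with intensity F,
#' E[G_ST] converges to F/(2-F) (Nei's finite-deme effect), so the drift
#' intensity is estimated by inverting that mapping: F_hat = 2 G / (1 + G).
#'
#' @param freq loci x populations frequency matrix.
#' @return list: \code{gst} (multilocus ratio-of-sums), \code{f_hat}
#'   (two-deme drift estimate).
#' @export
multilocusGst <- function(freq) {
  pbar <- rowMeans(freq)
  ht <- .hsBi(pbar)
  hs <- rowMeans(.hsBi(freq))
  ok <- is.finite(ht) & is.finite(hs)
  g <- sum(ht[ok] - hs[ok]) / sum(ht[ok])
  list(gst = g, f_hat = 2 * g / (1 + g))
}
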