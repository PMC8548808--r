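#' Block-jackknife standard error for a ratio-of-sums statistic
#'
#' Delete-one-block jackknife over contiguous locus blocks for statistics of
#' the form sum(num)/sum(den) (Patterson's D, f4 means, f4 ratios). Loci are
#' assumed unlinked, so contiguous index blocks stand in for genomic blocks.
#'
#' @param num,den per-locus numerator and denominator terms.
#' @param n_blocks number of blocks (>= 2; must not exceed the locus count).
#' @return list: \code{estimate}, \code{se}, \code{z}, \code{n_blocks},
#'   \code{n_loci}.
#' @export
blockJackknife <- function(num, den = rep(1, length(num)), n_blocks = 50) {
  n <- length(num)
  if (n_blocks > n) stop("n_blocks exceeds the number of loci")
  if (n_blocks < 2) stop("need at least 2 blocks")
  ok <- is.finite(num) & is.finite(den)
  num <- num[ok]; den <- den[ok]; n <- length(num)
  if (n < n_blocks) stop("too few informative loci for the requested blocks")
  blk <- ceiling(seq_along(num) / (n / n_blocks))
  blk[blk > n_blocks] <- n_blocks
  sn <- sum(num); sd_ <- sum(den)
  est <- sn / sd_
  bn <- tapply(num, blk, sum); bd <- tapply(den, blk, sum)
  loo <- (sn - bn) / (sd_ - bd)
  B <- length(loo)
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  list(estimate = est, se = se,
       z = if (se > 0) est / se else ifelse(est == 0, 0, sign(est) * Inf),
       n_blocks = B, n_loci = n)
}

#' Four-taxon Patterson's D from population allele frequencies
#'
#' With p1..p4 the alternate-allele frequencies of P1, P2, P3 and the outgroup
#' under the assumed topology (((P1,P2),P3),P4):
#' ABBA = (1-p1) p2 p3 (1-p4), BABA = p1 (1-p2) p3 (1-p4), and
#' D = sum(ABBA-BABA) / sum(ABBA+BABA). Positive D marks excess derived-allele
#' sharing between P2 and P3. Uncertainty by contiguous block jackknife.
#'
#' @param freq loci x populations frequency matrix.
#' @param quartet character vector (P1, P2, P3, Outgroup); population names
#'   must match \code{colnames(freq)}.
#' @param n_blocks jackknife blocks.
#' @return a list of class \code{"DResult"}: \code{D}, \code{se}, \code{z},
#'   \code{n_loci}, \code{n_blocks}, \code{quartet}, and the per-locus
#'   \code{abba}/\code{baba} terms.
#' @export
pattersonD <- function(freq, quartet, n_blocks = 50) {
  stopifnot(length(quartet) == 4, !anyDuplicated(quartet))
  if (!all(quartet %in% colnames(freq)))
    stop("quartet populations missing from frequency matrix: ",
         paste(setdiff(quartet, colnames(freq)), collapse = ", "))
  p <- freq[, quartet, drop = FALSE]
  ok <- rowSums(is.na(p)) == 0
  p <- p[ok, , drop = FALSE]
  abba <- (1 - p[, 1]) * p[, 2] * p[, 3] * (1 - p[, 4])
  baba <- p[, 1] * (1 - p[, 2]) * p[, 3] * (1 - p[, 4])
  if (sum(abba + baba) == 0)
    return(structure(list(D = NA_real_, se = NA_real_, z = NA_real_,
                          n_loci = nrow(p), n_blocks = 0, quartet = quartet,
                          abba = abba, baba = baba, defined = FALSE),
                     class = "DResult"))
  nb <- min(n_blocks, nrow(p))
  if (nb >= 2) {
    jk <- blockJackknife(abba - baba, abba + baba, n_blocks = nb)
  } else {
    warning("too few loci for a jackknife; D reported without SE")
    jk <- list(estimate = sum(abba - baba) / sum(abba + baba), se = NA_real_,
               z = NA_real_, n_loci = nrow(p), n_blocks = 1L)
  }
  structure(list(D = jk$estimate, se = jk$se, z = jk$z, n_loci = jk$n_loci,
                 n_blocks = jk$n_blocks, quartet = quartet,
                 abba = abba, baba = baba, defined = TRUE),
            class = "DResult")
}

#' @export
print.DResult <- function(x, ...) {
  cat(sprintf("Patterson's D [%s]: D = %.4f, Z = %.2f (SE %.4f, %d loci, %d blocks)\n",
              paste(x$quartet, collapse = ","), x$D, x$z, x$se, x$n_loci,
              x$n_blocks))
  invisible(x)
}

#' f4 statistic
#'
#' f4(A,B;C,D) = mean over loci of (pA - pB)(pC - pD).
#'
#' @param freq loci x populations frequency matrix.
#' @param quartet character vector (A, B, C, D).
#' @return list: \code{f4}, per-locus \code{terms}, \code{n_loci}.
#' @export
f4stat <- function(freq, quartet) {
  stopifnot(length(quartet) == 4)
  if (!all(quartet %in% colnames(freq)))
    stop("quartet populations missing from frequency matrix")
  p <- freq[, quartet, drop = FALSE]
  ok <- rowSums(is.na(p)) == 0
  p <- p[ok, , drop = FALSE]
  terms <- (p[, 1] - p[, 2]) * (p[, 3] - p[, 4])
  list(f4 = mean(terms), terms = terms, n_loci = nrow(p))
}

#' f4-ratio admixture fraction
#'
#' Ratio of two f4 statistics; with a suitably chosen numerator/denominator
#' pair this estimates the admixture fraction contributed by the donor
#' lineage. Uncertainty by joint block jackknife over the shared loci.
#'
#' @param freq loci x populations frequency matrix.
#' @param num_quartet,den_quartet (A,B;C,D) quartets for numerator and
#'   denominator f4.
#' @param n_blocks jackknife blocks.
#' @return list: \code{ratio}, \code{se}, \code{z}, \code{f4_num},
#'   \code{f4_den}, \code{n_loci}.
#' @export
f4Ratio <- function(freq, num_quartet, den_quartet, n_blocks = 50) {
  fn <- f4stat(freq, num_quartet)
  fd <- f4stat(freq, den_quartet)
  if (fn$n_loci != fd$n_loci)
    stop("numerator and denominator use different locus sets")
  if (fd$f4 == 0) stop("zero denominator f4")
  jk <- blockJackknife(fn$terms, fd$terms,
                       n_blocks = min(n_blocks, fn$n_loci))
  list(ratio = jk$estimate, se = jk$se, z = jk$z,
       f4_num = fn$f4, f4_den = fd$f4, n_loci = fn$n_loci)
}
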