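#' Assemble the evidence needed to classify a divergence scenario
#'
#' Computes, from population allele frequencies and a layout, every input of
#' the scenario decision matrix:
#' \itemize{
#'   \item per-drainage F_ST-bin partitions (within-drainage highland/lowland
#'     pair) with a neighbor-joining tree and topology call per occupied bin;
#'   \item the D_XY-ratio partition and per-partition trees/topology calls;
#'   \item genome-wide Patterson's D/Z for the heterospecific quartet
#'     (lowland_X, highland_X; highland_Y, outgroup) per drainage ordering
#'     (descriptive), D/Z per F_ST bin, and the genome-wide admixture f4
#'     test f4(lowland_X, highland_X; lowland_Y, outgroup), whose
#'     block-jackknife |Z| (\code{z_contact}, maximized over orderings) is
#'     the classifier's introgression significance: f4 is exactly zero under
#'     any drainage-first tree, selection included, but departs from zero
#'     genome-wide when contact-era gene flow has mixed a highland population
#'     with its local lowland;
#'   \item per-drainage outlier locus sets (top F_ST bin, >= 0.75) and their
#'     Jaccard overlap across drainages;
#'   \item the homogenization ratio: mean multilocus G_ST of the
#'     within-drainage heterospecific pairs over that of the among-drainage
#'     conspecific-highland pairs (near zero when contact-era gene flow has
#'     homogenized ecotype pairs genome-wide);
#'   \item the outlier D_XY-ratio: mean conspecific-highland D_XY over mean
#'     within-drainage heterospecific D_XY at the pooled outlier loci (small
#'     when ecotypes share ancestry at selected loci).
#' }
#'
#' @param freq loci x populations alternate-allele frequency matrix.
#' @param layout layout data.frame (population, drainage, ecotype), including
#'   an \code{ecotype == "outgroup"} row for four-taxon tests.
#' @param min_bin_loci minimum loci for a bin to receive a topology call.
#' @param n_blocks jackknife blocks for D.
#' @return a list of class \code{"ScenarioEvidence"}.
#' @export
scenarioEvidence <- function(freq, layout, min_bin_loci = 20, n_blocks = 50) {
  lay <- layout[layout$ecotype %in% c("highland", "lowland"), ]
  drainages <- unique(lay$drainage)
  if (length(drainages) < 2) stop("need >= 2 drainages")
  og <- layout$population[layout$ecotype == "outgroup"]
  ingroup <- lay$population
  highs <- vapply(drainages, function(d)
    lay$population[lay$drainage == d & lay$ecotype == "highland"], "")
  lows <- vapply(drainages, function(d)
    lay$population[lay$drainage == d & lay$ecotype == "lowland"], "")

  # drainage-pair focal quartets: with >2 drainages, use the first as X and
  # each other in turn as Y; calls are aggregated over pairs
  pair_ids <- utils::combn(seq_along(drainages), 2, simplify = FALSE)

  bins <- list(); bin_calls <- list(); outliers <- list(); d_bins <- list()
  for (i in seq_along(drainages)) {
    d <- drainages[i]
    fb <- fstBinPartition(freq, c(highs[i], lows[i]))
    bins[[d]] <- fb
    outliers[[d]] <- names(fb$bin)[fb$bin == 4L]
    # topology per occupied bin, judged against the first other drainage
    j <- if (i == 1) 2L else 1L
    focal <- c(HX = unname(highs[i]), LX = unname(lows[i]),
               HY = unname(highs[j]), LY = unname(lows[j]))
    calls <- rep(NA_character_, 4)
    dz <- rep(NA_real_, 4)
    for (b in 1:4) {
      loci_b <- names(fb$bin)[fb$bin == b]
      if (length(loci_b) < min_bin_loci) next
      tr <- njPopTree(popDistanceMatrix(freq, loci_b, ingroup))
      calls[b] <- classifyTopology(tr, focal)$call
      if (length(og) == 1 && length(loci_b) >= 2) {
        dr_b <- tryCatch(pattersonD(freq, c(focal[["LX"]], focal[["HX"]],
                                            focal[["HY"]], og),
                                    n_blocks = min(n_blocks, length(loci_b))),
                         error = function(e) NULL)
        if (!is.null(dr_b)) dz[b] <- dr_b$z
      }
    }
    bin_calls[[d]] <- calls
    d_bins[[d]] <- dz
  }

  # D_XY-ratio partition and its trees
  drt <- dxyRatioTable(freq, layout)
  drt_calls <- list()
  focal1 <- c(HX = unname(highs[1]), LX = unname(lows[1]),
              HY = unname(highs[2]), LY = unname(lows[2]))
  for (lab in c("both_gt1", "other")) {
    loci_l <- drt$locus[drt$label == lab]
    drt_calls[[lab]] <- if (length(loci_l) >= min_bin_loci)
      classifyTopology(njPopTree(popDistanceMatrix(freq, loci_l, ingroup)),
                       focal1)$call
    else NA_character_
  }

  # genome-wide D for each drainage-ordering of the heterospecific quartet
  # (descriptive), plus the f4 admixture test of within-drainage treeness:
  # f4(L_d, H_d; L_d', OUT) is zero for any drainage-first tree but non-zero
  # genome-wide when the highland pool is admixed with its local lowland
  # (contact-era homogenization), so its |Z| is the classifier's genome-wide
  # introgression significance.
  d_genome <- list(); f4_contact <- list()
  if (length(og) == 1) {
    for (pr in pair_ids) {
      i <- pr[1]; j <- pr[2]
      for (ord in list(c(i, j), c(j, i))) {
        qt <- c(lows[ord[1]], highs[ord[1]], highs[ord[2]], og)
        key <- paste(qt[1:3], collapse = ",")
        d_genome[[key]] <- pattersonD(freq, qt, n_blocks = n_blocks)
        f4q <- c(lows[ord[1]], highs[ord[1]], lows[ord[2]], og)
        fkey <- paste(f4q[1:3], collapse = ",")
        ft <- f4stat(freq, f4q)
        f4_contact[[fkey]] <- c(f4 = ft$f4,
          z = blockJackknife(ft$terms,
                             n_blocks = min(n_blocks, ft$n_loci))$z)
      }
    }
  }
  z_max <- if (length(d_genome))
    max(abs(vapply(d_genome, function(x) x$z, 0)), na.rm = TRUE) else NA_real_
  z_contact <- if (length(f4_contact))
    max(abs(vapply(f4_contact, function(x) x[["z"]], 0)), na.rm = TRUE) else NA_real_

  # homogenization ratio
  gst_het <- mean(vapply(seq_along(drainages), function(i)
    multilocusGst(freq[, c(highs[i], lows[i])])$gst, 0))
  gst_consp <- mean(vapply(pair_ids, function(pr)
    multilocusGst(freq[, c(highs[pr[1]], highs[pr[2]])])$gst, 0))
  hom_ratio <- if (is.finite(gst_consp) && gst_consp > 1e-6)
    gst_het / gst_consp else NA_real_

  # shared-ancestry-at-outliers evidence
  out_union <- unique(unlist(outliers))
  dxy_out_ratio <- NA_real_
  if (length(out_union) >= 5) {
    consp <- mean(vapply(pair_ids, function(pr)
      meanDxy(freq[out_union, highs[pr[1]]], freq[out_union, highs[pr[2]]])$mean, 0))
    het <- mean(vapply(seq_along(drainages), function(i)
      meanDxy(freq[out_union, highs[i]], freq[out_union, lows[i]])$mean, 0))
    if (is.finite(het) && het > 1e-6) dxy_out_ratio <- consp / het
  }
  jac <- NA_real_
  if (length(drainages) >= 2) {
    jacs <- vapply(pair_ids, function(pr) {
      a <- outliers[[drainages[pr[1]]]]; b <- outliers[[drainages[pr[2]]]]
      u <- length(union(a, b))
      if (u == 0) NA_real_ else length(intersect(a, b)) / u
    }, 0)
    jac <- mean(jacs, na.rm = TRUE)
  }

  structure(list(
    drainages = drainages, bins = bins, bin_calls = bin_calls,
    d_bins = d_bins, dxy_ratio_table = drt, dxy_ratio_calls = drt_calls,
    d_genome = d_genome, z_max = z_max,
    f4_contact = f4_contact, z_contact = z_contact, outliers = outliers,
    outlier_jaccard = jac, hom_ratio = hom_ratio,
    dxy_out_ratio = dxy_out_ratio, min_bin_loci = min_bin_loci
  ), class = "ScenarioEvidence")
}

#' Classify the divergence/introgression scenario of replicated ecotype pairs
#'
#' Applies an ordered decision matrix to [scenarioEvidence()]:
#' \enumerate{
#'   \item \strong{secondary_contact}: the highest occupied F_ST bin is
#'     species-grouped in at least one drainage, the lowest occupied bin is
#'     drainage-grouped, and the genome-wide admixture f4 |Z| is significant
#'     (>= \code{z_crit}); ancestries are correlated with and shared among
#'     ecotypes at selected loci while the rest of the genome is homogenized.
#'   \item \strong{de_novo_emergence}: low-divergence loci group by drainage,
#'     the per-drainage outlier sets are disjoint (Jaccard <
#'     \code{jaccard_max}), and ancestries at outliers are independent:
#'     either every bin topology is drainage-grouped, or conspecific
#'     highlands are no closer at outlier loci than ecotype pairs are
#'     (outlier D_XY ratio >= \code{dxy_ratio_max}). The latter clause is
#'     needed because conditioning on extreme F_ST of one pair distorts
#'     absolute-D_XY tree distances for that pair's bin.
#'   \item \strong{standing_or_adaptive_introgression}: the highest occupied
#'     bin is species-grouped in at least one drainage, the genome-wide
#'     admixture f4 is non-significant, and conspecific highland populations
#'     share ancestry at the outlier loci (outlier D_XY ratio <
#'     \code{dxy_ratio_max}; standing variation and adaptive introgression
#'     are acknowledged as confounded at unlinked-SNP resolution and share
#'     this label).
#'   \item \strong{inconclusive} otherwise, or when an evidence component is
#'     missing.
#' }
#'
#' @param evidence a \code{ScenarioEvidence} (or the frequency matrix, in
#'   which case \code{layout} must also be given and evidence is computed).
#' @param layout optional layout when \code{evidence} is a matrix.
#' @param z_crit genome-wide admixture-f4 |Z| significance threshold.
#' @param jaccard_max outlier-overlap threshold for disjointness.
#' @param dxy_ratio_max outlier conspecific/heterospecific D_XY threshold.
#' @return a list of class \code{"ScenarioCall"}: \code{label},
#'   \code{reasons} (character), and \code{evidence}.
#' @export
classifyScenario <- function(evidence, layout = NULL, z_crit = 3,
                             jaccard_max = 0.1, dxy_ratio_max = 0.75) {
  if (is.matrix(evidence)) {
    if (is.null(layout)) stop("layout required when passing a frequency matrix")
    evidence <- scenarioEvidence(evidence, layout)
  }
  ev <- evidence
  reasons <- character()

  top_call <- function(calls) {
    occ <- which(!is.na(calls))
    if (!length(occ)) NA_character_ else calls[max(occ)]
  }
  low_call <- function(calls) {
    occ <- which(!is.na(calls))
    if (!length(occ)) NA_character_ else calls[min(occ)]
  }
  tops <- vapply(ev$bin_calls, top_call, "")
  lows <- vapply(ev$bin_calls, low_call, "")
  any_top_species <- any(tops == "species_grouped", na.rm = TRUE)
  all_low_drainage <- all(lows == "drainage_grouped", na.rm = TRUE) &&
    any(!is.na(lows))
  all_calls <- unlist(ev$bin_calls)
  all_drainage <- all(all_calls[!is.na(all_calls)] == "drainage_grouped") &&
    any(!is.na(all_calls))

  missing_ev <- c(
    if (all(is.na(tops))) "no occupied F_ST bins",
    if (is.na(ev$z_contact)) "no genome-wide admixture test (missing outgroup?)")
  label <- "inconclusive"

  if (length(missing_ev)) {
    reasons <- c(reasons, missing_ev)
  } else if (any_top_species && all_low_drainage && ev$z_contact >= z_crit) {
    label <- "secondary_contact"
    reasons <- c(reasons,
      "high-F_ST loci group by species while low-F_ST loci group by drainage",
      sprintf("genome-wide admixture f4 |Z| = %.1f >= %g (ecotype pairs homogenized by gene flow)",
              ev$z_contact, z_crit))
  } else if (all_low_drainage && !is.na(ev$outlier_jaccard) &&
             ev$outlier_jaccard < jaccard_max &&
             (all_drainage || (!is.na(ev$dxy_out_ratio) &&
                               ev$dxy_out_ratio >= dxy_ratio_max))) {
    label <- "de_novo_emergence"
    reasons <- c(reasons,
      "low-divergence loci group by drainage",
      sprintf("per-drainage outlier sets disjoint (Jaccard %.3f)",
              ev$outlier_jaccard),
      if (all_drainage) "all locus partitions group by drainage"
      else sprintf("no shared conspecific-highland ancestry at outliers (D_XY ratio %.2f >= %g)",
                   ev$dxy_out_ratio, dxy_ratio_max))
  } else if (any_top_species && ev$z_contact < z_crit &&
             !is.na(ev$dxy_out_ratio) && ev$dxy_out_ratio < dxy_ratio_max) {
    label <- "standing_or_adaptive_introgression"
    reasons <- c(reasons,
      "high-F_ST loci group by species without genome-wide admixture",
      sprintf("conspecific highlands share ancestry at outliers (D_XY ratio %.2f < %g)",
              ev$dxy_out_ratio, dxy_ratio_max))
  } else {
    reasons <- c(reasons, "no decision rule satisfied")
  }

  structure(list(label = label, reasons = reasons,
                 summary = list(top_calls = tops, low_calls = lows,
                                z_max = ev$z_max, z_contact = ev$z_contact,
                                hom_ratio = ev$hom_ratio,
                                outlier_jaccard = ev$outlier_jaccard,
                                dxy_out_ratio = ev$dxy_out_ratio),
                 evidence = ev),
            class = "ScenarioCall")
}

#' @export
print.ScenarioCall <- function(x, ...) {
  cat("ScenarioCall:", x$label, "\n")
  for (r in x$reasons) cat("  -", r, "\n")
  s <- x$summary
  cat(sprintf("  [Zcontact %.2f | Zmax %.2f | hom %.2f | jaccard %s | dxy-out %s]\n",
              s$z_contact, s$z_max, s$hom_ratio,
              ifelse(is.na(s$outlier_jaccard), "NA", sprintf("%.2f", s$outlier_jaccard)),
              ifelse(is.na(s$dxy_out_ratio), "NA", sprintf("%.2f", s$dxy_out_ratio))))
  invisible(x)
}
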