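#' Layout helper: focal populations of a drainage pair
#'
#' @param layout data.frame with population, drainage, ecotype.
#' @param drainages length-2 character vector (defaults to the first two
#'   non-outgroup drainages).
#' @return named character vector HX, LX, HY, LY (highland/lowland of each).
#' @export
focalQuartet <- function(layout, drainages = NULL) {
  lay <- layout[layout$ecotype %in% c("highland", "lowland"), ]
  if (is.null(drainages)) drainages <- unique(lay$drainage)[1:2]
  pick <- function(d, eco) {
    p <- lay$population[lay$drainage == d & lay$ecotype == eco]
    if (length(p) != 1) stop("layout lacks a unique ", eco, " population in ", d)
    p
  }
  c(HX = pick(drainages[1], "highland"), LX = pick(drainages[1], "lowland"),
    HY = pick(drainages[2], "highland"), LY = pick(drainages[2], "lowland"))
}

#' Per-locus D_XY-ratio records
#'
#' For each drainage, the ratio of heterospecific-within-drainage divergence
#' to conspecific-among-drainage divergence:
#' ratio_X = D_XY(highland_X, lowland_X) / D_XY(highland_X, highland_Y).
#' Ratios above 1 mark loci where ecotype pairs stay more diverged than
#' conspecific highland populations -- candidate targets of divergent
#' selection whose ancestry survives homogenization. Loci whose conspecific
#' denominator falls below \code{eps} are excluded (near-zero distances make
#' the ratio unstable).
#'
#' @param freq loci x populations frequency matrix.
#' @param layout layout data.frame (population, drainage, ecotype).
#' @param eps denominator floor.
#' @return data.frame of class \code{"DxyRatioTable"}: locus, per-drainage
#'   numerators, the conspecific denominator per drainage, per-drainage
#'   ratios, and a label in \{both_gt1, other, excluded_zero_denominator\}.
#' @export
dxyRatioTable <- function(freq, layout, eps = 1e-6) {
  lay <- layout[layout$ecotype %in% c("highland", "lowland"), ]
  drainages <- unique(lay$drainage)
  if (length(drainages) < 2) stop("need >= 2 drainages")
  highs <- vapply(drainages, function(d)
    lay$population[lay$drainage == d & lay$ecotype == "highland"], "")
  lows <- vapply(drainages, function(d)
    lay$population[lay$drainage == d & lay$ecotype == "lowland"], "")
  out <- data.frame(locus = rownames(freq), stringsAsFactors = FALSE)
  ratios <- matrix(NA_real_, nrow(freq), length(drainages))
  excl <- rep(FALSE, nrow(freq))
  for (i in seq_along(drainages)) {
    others <- highs[-i]
    # conspecific-highland divergence, averaged over the other drainages
    den <- rowMeans(matrix(vapply(others, function(h)
      dxy(freq[, highs[i]], freq[, h]), numeric(nrow(freq))),
      nrow = nrow(freq)))
    num <- dxy(freq[, highs[i]], freq[, lows[i]])
    out[[paste0("num_", drainages[i])]] <- num
    out[[paste0("den_", drainages[i])]] <- den
    bad <- !is.finite(den) | den < eps
    ratios[, i] <- ifelse(bad, NA_real_, num / den)
    excl <- excl | bad
    out[[paste0("ratio_", drainages[i])]] <- ratios[, i]
  }
  out$label <- ifelse(excl, "excluded_zero_denominator",
                      ifelse(rowSums(ratios > 1) == length(drainages),
                             "both_gt1", "other"))
  class(out) <- c("DxyRatioTable", "data.frame")
  out
}

#' Partition loci into F_ST bins for one population pair
#'
#' Bins locus-wise F_ST of the named pair into [0,0.25), [0.25,0.50),
#' [0.50,0.75), [0.75,1.0] (half-open with a closed top bin). Loci with
#' undefined F_ST are omitted and counted.
#'
#' @param freq loci x populations frequency matrix.
#' @param pair length-2 character vector of population names.
#' @param edges bin edges.
#' @return list of class \code{"FstBinPartition"}: \code{bin} (named integer
#'   per retained locus), \code{fst} (the per-locus values), \code{pair},
#'   \code{n_omitted}.
#' @export
fstBinPartition <- function(freq, pair,
                            edges = c(0, 0.25, 0.50, 0.75, 1.0)) {
  stopifnot(length(pair) == 2, all(pair %in% colnames(freq)))
  fst <- fstGst(freq[, pair, drop = FALSE])
  names(fst) <- rownames(freq)
  ok <- is.finite(fst)
  b <- findInterval(fst[ok], edges, rightmost.closed = TRUE)
  b[b < 1] <- 1L; b[b > length(edges) - 1] <- length(edges) - 1L
  structure(list(bin = setNames(as.integer(b), names(fst)[ok]),
                 fst = fst, pair = pair, edges = edges,
                 n_omitted = sum(!ok)),
            class = "FstBinPartition")
}

#' Pairwise mean-D_XY population distance matrix
#'
#' Mean per-SNP D_XY over a locus subset for every population pair. Note this
#' is an absolute distance: identical populations yield 2p(1-p), not zero, so
#' only contrasts between entries are meaningful (the constant within-
#' population diversity cancels in tree estimation only approximately; for
#' topology questions the raw matrix is used as-is).
#'
#' @param freq loci x populations frequency matrix.
#' @param loci locus subset (names or indices); default all.
#' @param populations subset of populations; default all.
#' @return symmetric matrix with zero diagonal.
#' @export
popDistanceMatrix <- function(freq, loci = NULL, populations = colnames(freq)) {
  sub <- freq[if (is.null(loci)) seq_len(nrow(freq)) else loci,
              populations, drop = FALSE]
  if (nrow(sub) == 0) stop("empty locus subset")
  np <- ncol(sub)
  D <- matrix(0, np, np, dimnames = list(populations, populations))
  for (i in seq_len(np - 1)) for (j in (i + 1):np) {
    d <- dxy(sub[, i], sub[, j])
    D[i, j] <- D[j, i] <- mean(d, na.rm = TRUE)
  }
  D
}

#' Neighbor-joining population tree
#'
#' Standard neighbor-joining (via \pkg{ape}) on a symmetric distance matrix;
#' negative branch lengths are clamped to zero and flagged.
#'
#' @param D symmetric non-negative distance matrix with labelled rows.
#' @return a list of class \code{"PopTree"}: \code{tree} (an \pkg{ape}
#'   \code{phylo}), \code{clamped} (were negative branch lengths clamped),
#'   \code{n_loci} attribute is left to the caller.
#' @export
njPopTree <- function(D) {
  if (!isSymmetric(unname(as.matrix(D)), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (nrow(D) < 3) stop("need >= 3 taxa")
  tr <- ape::nj(as.dist(D))
  clamped <- any(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  structure(list(tree = tr, clamped = clamped), class = "PopTree")
}

#' @export
print.PopTree <- function(x, ...) {
  cat("PopTree (unrooted NJ", if (x$clamped) ", clamped branch lengths" else "",
      "):\n", sep = "")
  cat(" ", ape::write.tree(x$tree), "\n")
  invisible(x)
}

#' Classify the induced four-population topology
#'
#' Restricts the tree to the focal quartet \{highland_X, lowland_X,
#' highland_Y, lowland_Y\} and reads off its unrooted split:
#' (HX,LX)|(HY,LY) is drainage-grouped, (HX,HY)|(LX,LY) species-grouped
#' (ecotype clades, i.e. consistent with species-level taxonomy), and the
#' remaining split is 'other'.
#'
#' @param ptree a \code{PopTree} (or \code{phylo}) containing the four focal
#'   populations.
#' @param focal named vector as from [focalQuartet()].
#' @return a list of class \code{"TopologyCall"}: \code{call} in
#'   \{drainage_grouped, species_grouped, other\}, and \code{sisters} (the
#'   tip pair forming one side of the induced split).
#' @export
classifyTopology <- function(ptree, focal) {
  tr <- if (inherits(ptree, "PopTree")) ptree$tree else ptree
  if (!all(focal %in% tr$tip.label))
    stop("tree lacks focal population(s): ",
         paste(setdiff(focal, tr$tip.label), collapse = ", "))
  t4 <- ape::unroot(ape::keep.tip(tr, unname(focal)))
  # unrooted binary 4-taxon tree: find the cherry containing focal["HX"]
  hx <- focal[["HX"]]
  pair_of <- function(tip) {
    tipn <- which(t4$tip.label == tip)
    par <- t4$edge[t4$edge[, 2] == tipn, 1]
    sibs <- t4$edge[t4$edge[, 1] == par, 2]
    sibs <- sibs[sibs <= length(t4$tip.label) & sibs != tipn]
    if (length(sibs)) t4$tip.label[sibs[1]] else NA_character_
  }
  sib <- pair_of(hx)
  if (is.na(sib)) {
    # HX attaches to the internal node alone (star-like); infer from another tip
    sib_ly <- pair_of(focal[["LY"]])
    sib <- if (!is.na(sib_ly) && sib_ly == focal[["HY"]]) focal[["LX"]] else NA
  }
  call <- if (is.na(sib)) "other"
    else if (sib == focal[["LX"]]) "drainage_grouped"
    else if (sib == focal[["HY"]]) "species_grouped"
    else "other"
  structure(list(call = call, sisters = c(hx, sib)), class = "TopologyCall")
}

#' @export
print.TopologyCall <- function(x, ...) {
  cat("TopologyCall:", x$call, sprintf("(sisters: %s)\n",
      paste(x$sisters, collapse = " + ")))
  invisible(x)
}
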