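# Small in-code fixtures shared across test files.

# A hand-built ReadDataset: `depths` is a list of 2-column (ref, alt) matrices,
# one per individual, all with the same locus count.
makeDataset <- function(ref, alt, ploidy = 4L, population = "P1",
                        drainage = "D1", ecotype = "highland") {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  n <- ncol(ref)
  meta <- data.frame(
    population = rep_len(population, n),
    drainage = rep_len(drainage, n),
    ecotype = rep_len(ecotype, n),
    ploidy = rep_len(as.integer(ploidy), n))
  ReadDataset(ref, alt, meta)
}

# layout of a two-drainage, two-ecotype design plus outgroup
twoDrainageLayout <- function() {
  data.frame(
    population = c("D1_high", "D1_low", "D2_high", "D2_low", "OUT"),
    drainage = c("D1", "D1", "D2", "D2", "OUT"),
    ecotype = c("highland", "lowland", "highland", "lowland", "outgroup"),
    stringsAsFactors = FALSE)
}

# additive distance matrix from a 4-taxon unrooted tree with internal branch
# x0 and terminal branches b (named A,B,C,D), split AB|CD
additive4 <- function(b, x0) {
  D <- matrix(0, 4, 4, dimnames = list(names(b), names(b)))
  D["A", "B"] <- b["A"] + b["B"]
  D["C", "D"] <- b["C"] + b["D"]
  for (i in c("A", "B")) for (j in c("C", "D"))
    D[i, j] <- b[i] + b[j] + x0
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

# exhaustive ordinary-least-squares fit of a 4-taxon additive tree for each of
# the three unrooted topologies; returns the split of the best fit and its
# fitted branch lengths (independent oracle for nj)
bruteForceLS4 <- function(D) {
  taxa <- rownames(D)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  best <- NULL
  for (s in splits) {
    pair1 <- taxa[s]
    pair2 <- setdiff(taxa, pair1)
    # design: distances as sums of 4 terminal branches + internal branch
    pairs <- utils::combn(taxa, 2, simplify = FALSE)
    X <- t(vapply(pairs, function(pr) {
      row <- setNames(numeric(5), c(taxa, "x0"))
      row[pr] <- 1
      same <- (all(pr %in% pair1)) || (all(pr %in% pair2))
      row["x0"] <- if (same) 0 else 1
      row
    }, numeric(5)))
    y <- vapply(pairs, function(pr) D[pr[1], pr[2]], 0)
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(split = sort(pair1), rss = rss, branches = fit$coefficients)
  }
  best
}

# split of a 4-taxon unrooted phylo: the sorted cherry containing taxon 1
treeSplit4 <- function(tr) {
  tr <- ape::unroot(tr)
  first <- tr$tip.label[1]
  tipn <- which(tr$tip.label == first)
  par <- tr$edge[tr$edge[, 2] == tipn, 1]
  sibs <- tr$edge[tr$edge[, 1] == par, 2]
  sibs <- sibs[sibs <= length(tr$tip.label)]
  sort(tr$tip.label[sibs])
}
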