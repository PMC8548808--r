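#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' ReadDataset: per-individual, per-locus allele read depths with sample metadata
#'
#' The common currency of the pipeline: a \linkS4class{SummarizedExperiment}
#' whose rows are bi-allelic SNP loci and whose columns are individuals.
#' Assays \code{refDepth} and \code{altDepth} hold non-negative integer read
#' depths; simulated data additionally carry a \code{trueDosage} assay.
#' \code{colData} must provide \code{population}, \code{drainage},
#' \code{ecotype} and \code{ploidy} for every sample.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @seealso [simulateReads()], [readDataset()], [writeDataset()]
#' @export
setClass("ReadDataset", contains = "SummarizedExperiment")

.validReadDataset <- function(object) {
  msg <- character()
  need <- c("refDepth", "altDepth")
  if (!all(need %in% assayNames(object)))
    msg <- c(msg, "assays 'refDepth' and 'altDepth' are required")
  meta_cols <- c("population", "drainage", "ecotype", "ploidy")
  miss <- setdiff(meta_cols, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  if (all(need %in% assayNames(object))) {
    if (any(assay(object, "refDepth") < 0, na.rm = TRUE) ||
        any(assay(object, "altDepth") < 0, na.rm = TRUE))
      msg <- c(msg, "read depths must be non-negative")
  }
  if ("ploidy" %in% colnames(colData(object))) {
    k <- colData(object)$ploidy
    if (any(!is.finite(k)) || any(k < 1) || any(k != round(k)))
      msg <- c(msg, "ploidy must be positive integers")
    if ("trueDosage" %in% assayNames(object)) {
      td <- assay(object, "trueDosage")
      bad <- sweep(td, 2, k, FUN = ">")
      if (any(bad, na.rm = TRUE))
        msg <- c(msg, "trueDosage exceeds sample ploidy")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("ReadDataset", .validReadDataset)

#' Construct a ReadDataset
#'
#' @param refDepth,altDepth integer matrices (loci x individuals) of reference
#'   and alternate allele read depths.
#' @param sampleMeta a data.frame with one row per individual and columns
#'   \code{population}, \code{drainage}, \code{ecotype}, \code{ploidy}.
#' @param trueDosage optional matrix of simulated true allele dosages.
#' @param rowData optional per-locus annotation (e.g. selected-locus flags).
#' @param metadata optional list stored in the object metadata.
#' @return a \linkS4class{ReadDataset}.
#' @export
ReadDataset <- function(refDepth, altDepth, sampleMeta, trueDosage = NULL,
                        rowData = NULL, metadata = list()) {
  refDepth <- as.matrix(refDepth)
  altDepth <- as.matrix(altDepth)
  if (!identical(dim(refDepth), dim(altDepth)))
    stop("refDepth and altDepth dimensions differ")
  if (nrow(sampleMeta) != ncol(refDepth))
    stop("sampleMeta rows must match the number of individuals")
  if (is.null(rownames(refDepth)) && nrow(refDepth) > 0)
    rownames(refDepth) <- rownames(altDepth) <- paste0("L", seq_len(nrow(refDepth)))
  if (is.null(colnames(refDepth))) {
    ids <- rownames(sampleMeta)
    if (is.null(ids) || identical(ids, as.character(seq_len(nrow(sampleMeta)))))
      ids <- sprintf("S%03d", seq_len(ncol(refDepth)))
    colnames(refDepth) <- colnames(altDepth) <- ids
  }
  assays <- list(refDepth = refDepth, altDepth = altDepth)
  if (!is.null(trueDosage)) {
    trueDosage <- as.matrix(trueDosage)
    dimnames(trueDosage) <- dimnames(refDepth)
    assays$trueDosage <- trueDosage
  }
  cd <- DataFrame(sampleMeta, row.names = colnames(refDepth))
  se <- SummarizedExperiment(assays = assays, colData = cd)
  if (!is.null(rowData)) rowData(se) <- DataFrame(rowData, row.names = rownames(refDepth))
  metadata(se) <- metadata
  new("ReadDataset", se)
}

#' GenotypeCalls: MAP dosage genotypes with posterior support
#'
#' Rows are loci, columns individuals. Assays: \code{dosage} (MAP alternate
#' allele dosage, 0..ploidy, NA where depth is zero), \code{maxPosterior}
#' (posterior probability of the MAP dosage), \code{meanDosage} (posterior
#' mean) and \code{depth} (total reads).
#' \code{colData} carries the per-individual ploidy used for calling;
#' \code{metadata(x)$popFreq} holds the per-population allele frequencies used
#' as genotype priors.
#'
#' @seealso [callGenotypes()]
#' @export
setClass("GenotypeCalls", contains = "SummarizedExperiment")

.validGenotypeCalls <- function(object) {
  msg <- character()
  if (!all(c("dosage", "maxPosterior") %in% assayNames(object)))
    msg <- c(msg, "assays 'dosage' and 'maxPosterior' are required")
  if (!"ploidy" %in% colnames(colData(object)))
    msg <- c(msg, "colData lacks 'ploidy'")
  if (all(c("dosage") %in% assayNames(object)) &&
      "ploidy" %in% colnames(colData(object))) {
    d <- assay(object, "dosage")
    k <- colData(object)$ploidy
    if (any(sweep(d, 2, k, FUN = ">"), na.rm = TRUE) || any(d < 0, na.rm = TRUE))
      msg <- c(msg, "dosage outside 0..ploidy")
  }
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeCalls", .validGenotypeCalls)

#' @describeIn ReadDataset reference allele depth matrix (loci x individuals)
#' @param x a ReadDataset
#' @export
refDepth <- function(x) assay(x, "refDepth")

#' @describeIn ReadDataset alternate allele depth matrix
#' @export
altDepth <- function(x) assay(x, "altDepth")

#' @describeIn ReadDataset simulated true dosage matrix, or NULL
#' @export
trueDosage <- function(x) {
  if ("trueDosage" %in% assayNames(x)) assay(x, "trueDosage") else NULL
}

#' @describeIn ReadDataset sample metadata as a data.frame
#' @export
sampleMeta <- function(x) as.data.frame(colData(x))

#' @describeIn ReadDataset per-individual ploidy vector (named by sample)
#' @export
ploidy <- function(x) setNames(colData(x)$ploidy, colnames(x))

#' @describeIn GenotypeCalls MAP dosage matrix
#' @param x a GenotypeCalls
#' @export
dosage <- function(x) assay(x, "dosage")

#' @describeIn GenotypeCalls posterior probability of the MAP dosage
#' @export
maxPosterior <- function(x) assay(x, "maxPosterior")

setMethod("show", "ReadDataset", function(object) {
  cat("ReadDataset:", nrow(object), "loci x", ncol(object), "individuals\n")
  tb <- table(colData(object)$ploidy)
  cat("  ploidy:", paste(sprintf("%sx(n=%d)", names(tb), as.integer(tb)),
      collapse = ", "), "\n")
  cat("  populations:", paste(unique(colData(object)$population), collapse = ", "), "\n")
  dp <- assay(object, "refDepth") + assay(object, "altDepth")
  cat(sprintf("  mean depth: %.1f\n", mean(dp)))
  invisible(NULL)
})

setMethod("show", "GenotypeCalls", function(object) {
  d <- assay(object, "dosage")
  cat("GenotypeCalls:", nrow(object), "loci x", ncol(object), "individuals\n")
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(d))))
  invisible(NULL)
})
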