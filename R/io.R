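#' Write a ReadDataset as VCF v4.2 plus a population map
#'
#' Produces a plain-text VCF with FORMAT fields GT and AD. The GT string
#' carries as many alleles as the individual's ploidy (e.g. a tetraploid with
#' alternate dosage 1 is written \code{0/0/0/1}; a diploid heterozygote
#' \code{0/1}). When no true dosage is available GT is emitted as missing
#' (\code{./.} per ploidy). The popmap is a TSV with header
#' \code{sample population drainage ecotype ploidy}.
#'
#' @param ds a \linkS4class{ReadDataset}.
#' @param vcf_path,popmap_path output file paths.
#' @return invisibly, the two paths.
#' @export
writeDataset <- function(ds, vcf_path, popmap_path) {
  stopifnot(is(ds, "ReadDataset"))
  meta <- sampleMeta(ds)
  ref <- refDepth(ds); alt <- altDepth(ds); td <- trueDosage(ds)
  L <- nrow(ds); N <- ncol(ds)

  gt_cell <- function(g, k) {
    if (is.na(g)) return(paste(rep(".", k), collapse = "/"))
    paste(c(rep("0", k - g), rep("1", g)), collapse = "/")
  }
  cols <- vapply(seq_len(N), function(j) {
    k <- meta$ploidy[j]
    gt <- if (is.null(td)) rep(paste(rep(".", k), collapse = "/"), L)
          else vapply(td[, j], gt_cell, "", k = k)
    paste0(gt, ":", ref[, j], ",", alt[, j])
  }, character(L))
  if (L == 1L) cols <- matrix(cols, nrow = 1L)

  hdr <- c("##fileformat=VCFv4.2",
           "##source=ecoploid",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths (ref,alt)\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", colnames(ds)), collapse = "\t"))
  body <- paste(paste0("locus", seq_len(L)), seq_len(L), rownames(ds),
                "A", "T", ".", "PASS", ".", "GT:AD",
                apply(cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), vcf_path)

  pm <- data.frame(sample = rownames(meta), meta, row.names = NULL,
                   check.names = FALSE)
  write.table(pm, popmap_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf = vcf_path, popmap = popmap_path))
}

#' Read a VCF (FORMAT/AD) and popmap into a ReadDataset
#'
#' Parses per-sample ref/alt allele depths from the AD FORMAT field of a
#' bi-allelic VCF (via \pkg{vcfR}) and joins the popmap metadata. Samples
#' present in the VCF but absent from the popmap (or vice versa) are an error.
#'
#' @param vcf_path path to a VCF v4.2 file with AD depths.
#' @param popmap_path path to a TSV with columns
#'   \code{sample population drainage ecotype ploidy}.
#' @return a \linkS4class{ReadDataset}.
#' @export
readDataset <- function(vcf_path, popmap_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) stop("VCF lacks a FORMAT/AD field")
  pm <- read.table(popmap_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("sample", "population", "drainage", "ecotype", "ploidy")
  if (!all(need %in% colnames(pm)))
    stop("popmap must have columns: ", paste(need, collapse = ", "))
  vcf_samples <- colnames(ad)
  missing_pm <- setdiff(vcf_samples, pm$sample)
  if (length(missing_pm))
    stop("popmap is missing VCF sample(s): ", paste(missing_pm, collapse = ", "))
  extra_pm <- setdiff(pm$sample, vcf_samples)
  if (length(extra_pm))
    stop("popmap sample(s) absent from VCF: ", paste(extra_pm, collapse = ", "))
  pm <- pm[match(vcf_samples, pm$sample), ]

  split_ad <- function(x, idx) {
    out <- suppressWarnings(as.integer(vapply(strsplit(x, ","), function(p) {
      if (length(p) < 2) NA_character_ else p[idx]
    }, "")))
    out[is.na(out)] <- 0L
    out
  }
  ref <- apply(ad, 2, split_ad, idx = 1L)
  alt <- apply(ad, 2, split_ad, idx = 2L)
  ids <- vcfR::getID(v)
  if (anyDuplicated(ids) || any(is.na(ids))) ids <- paste0("L", seq_len(nrow(ad)))
  rownames(ref) <- rownames(alt) <- ids

  gt <- vcfR::extract.gt(v, element = "GT")
  td <- NULL
  if (!is.null(gt) && !all(is.na(gt)) && !any(grepl("\\.", gt))) {
    td <- matrix(vapply(gt, function(g) {
      sum(strsplit(g, "[/|]")[[1]] == "1")
    }, 0L), nrow(gt), ncol(gt))
    rownames(td) <- ids
  }
  meta <- data.frame(population = pm$population, drainage = pm$drainage,
                     ecotype = pm$ecotype, ploidy = as.integer(pm$ploidy),
                     row.names = pm$sample, stringsAsFactors = FALSE)
  ReadDataset(ref, alt, meta, trueDosage = td)
}
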