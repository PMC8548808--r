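#' Validate a pipeline configuration
#'
#' A configuration (R list, or path to a YAML file with the same shape) must
#' contain exactly one input source: \code{scenario} (arguments for
#' [scenarioSpec()]) or \code{vcf} + \code{popmap} paths. Optional blocks:
#' \code{out_dir}, \code{seed}, \code{stages} (logical toggles: ploidy,
#' hindhe, dstat, partition), \code{ploidy_table} (path or data.frame of
#' sample/selected_k to use instead of the ploidy stage), \code{genotype}
#' (error_rate), \code{filters} (min_prop_genotyped, min_mean_depth, maf,
#' hindhe_quantile), \code{classify} (z_crit, hom_max, jaccard_max,
#' dxy_ratio_max).
#'
#' @param config list or YAML path.
#' @return a list: \code{ok} flag, \code{errors} (character), and the
#'   normalized \code{config}; schema problems are aggregated, not thrown.
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  errs <- character()
  if (!is.list(config)) return(list(ok = FALSE, errors = "config must be a list",
                                    config = NULL))
  has_sim <- !is.null(config$scenario)
  has_files <- !is.null(config$vcf) || !is.null(config$popmap)
  if (has_sim && has_files)
    errs <- c(errs, "give either a scenario block or vcf+popmap paths, not both")
  if (!has_sim && !has_files)
    errs <- c(errs, "one of scenario or vcf+popmap is required")
  if (has_files && (is.null(config$vcf) || is.null(config$popmap)))
    errs <- c(errs, "vcf and popmap must both be given")
  if (has_sim) {
    sp <- tryCatch(do.call(scenarioSpec, config$scenario), error = function(e) e)
    if (inherits(sp, "error")) errs <- c(errs, paste("scenario:", conditionMessage(sp)))
  }
  if (!is.null(config$seed) && !is_count(abs(config$seed) + 1))
    errs <- c(errs, "seed must be an integer")
  f <- config$filters
  if (!is.null(f$maf) && !is_frac(f$maf)) errs <- c(errs, "filters$maf must be in [0,1]")
  if (!is.null(f$min_prop_genotyped) && !is_frac(f$min_prop_genotyped))
    errs <- c(errs, "filters$min_prop_genotyped must be in [0,1]")
  if (!is.null(f$min_mean_depth) && f$min_mean_depth < 0)
    errs <- c(errs, "filters$min_mean_depth must be >= 0")
  list(ok = length(errs) == 0, errors = errs, config = config)
}

.cfgGet <- function(config, path, default) {
  x <- config
  for (p in path) {
    x <- x[[p]]
    if (is.null(x)) return(default)
  }
  x
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> coverage filter -> ploidy calling -> Hind/He
#' partitioning -> dosage genotyping -> differentiation statistics -> D
#' statistics -> locus-partitioned trees and scenario classification, writing
#' every stage artifact as a plain file under \code{out_dir}. Identical
#' config + seed gives identical outputs.
#'
#' @param config list or YAML path (see [validatePipelineConfig()]).
#' @return invisibly, a run report list (also written as run_report.json);
#'   elements include per-stage locus counts and the scenario call when a
#'   layout with >= 2 drainages and an outgroup is available.
#' @export
runPipeline <- function(config) {
  val <- validatePipelineConfig(config)
  if (!val$ok) stop("invalid pipeline config:\n  ",
                    paste(val$errors, collapse = "\n  "))
  config <- val$config
  out_dir <- .cfgGet(config, "out_dir", "ecoploid_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(.cfgGet(config, "seed", 1L))
  report <- list(seed = seed, stages = list())
  stage <- function(.name, ...) {
    report$stages[[.name]] <<- list(...)
  }

  # --- input ------------------------------------------------------------
  if (!is.null(config$scenario)) {
    sp_args <- config$scenario
    if (is.null(sp_args$seed)) sp_args$seed <- seed
    spec <- do.call(scenarioSpec, sp_args)
    ds <- simulateScenario(spec)
    writeDataset(ds, file.path(out_dir, "simulated.vcf"),
                 file.path(out_dir, "popmap.tsv"))
    stage("input", source = "simulated", scenario = spec$scenario,
          n_loci = nrow(ds), n_samples = ncol(ds))
  } else {
    ds <- readDataset(config$vcf, config$popmap)
    stage("input", source = "files", vcf = config$vcf,
          n_loci = nrow(ds), n_samples = ncol(ds))
  }

  # --- coverage filter --------------------------------------------------
  cf <- coverageFilter(ds,
    min_prop_genotyped = .cfgGet(config, c("filters", "min_prop_genotyped"), 0.5),
    min_mean_depth = .cfgGet(config, c("filters", "min_mean_depth"), 0))
  ds <- ds[cf$retained, ]
  stage("coverage_filter", retained = length(cf$retained))

  # --- ploidy -----------------------------------------------------------
  ploidy_override <- NULL
  do_ploidy <- isTRUE(.cfgGet(config, c("stages", "ploidy"), TRUE))
  if (!is.null(config$ploidy_table)) {
    pt <- config$ploidy_table
    if (is.character(pt)) pt <- read.table(pt, header = TRUE, sep = "\t",
                                           stringsAsFactors = FALSE)
    ploidy_override <- setNames(as.integer(pt$selected_k), pt$sample)
    stage("ploidy", source = "supplied", n_supplied = length(ploidy_override))
  } else if (do_ploidy) {
    ptab <- callPloidyAll(ds)
    write.table(ptab, file.path(out_dir, "ploidy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ok <- !is.na(ptab$selected_k)
    ploidy_override <- setNames(ptab$selected_k[ok], ptab$sample[ok])
    stage("ploidy", source = "called",
          agreement = mean(ptab$selected_k == ploidy(ds)[ptab$sample], na.rm = TRUE))
  } else {
    stage("ploidy", source = "metadata")
  }

  # --- Hind/He partition ------------------------------------------------
  if (isTRUE(.cfgGet(config, c("stages", "hindhe"), TRUE))) {
    hh <- hindHe(ds)
    dp <- refDepth(ds) + altDepth(ds)
    thr <- hindHeThresholdPair(
      n_ind = ncol(ds), depths = as.vector(dp[dp > 0]),
      error_rate = .cfgGet(config, c("genotype", "error_rate"), 0.005),
      quantile_p = .cfgGet(config, c("filters", "hindhe_quantile"), 0.95),
      seed = childSeed(seed, 3L))
    part <- partitionLociByPloidy(hh, thr)
    keep <- c(part$diploid_set, part$tetraploid_set)
    write.table(hh, file.path(out_dir, "hind_he.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ds <- ds[rownames(ds) %in% keep, ]
    stage("hindhe", t_diploid = thr$t_diploid, t_tetraploid = thr$t_tetraploid,
          diploid_consistent = length(part$diploid_set),
          tetraploid_consistent = length(part$tetraploid_set),
          discarded = length(part$discarded))
  }

  # --- genotyping -------------------------------------------------------
  err <- .cfgGet(config, c("genotype", "error_rate"), 0.005)
  gt <- callGenotypes(ds, error_rate = err, ploidy_override = ploidy_override)
  pf <- popFreqs(gt)
  glob <- rowSums(dosage(gt), na.rm = TRUE) /
    pmax(rowSums(t(t(!is.na(dosage(gt))) * as.numeric(colData(gt)$ploidy))), 1)
  mf <- mafFilter(setNames(glob, rownames(gt)),
                  .cfgGet(config, c("filters", "maf"), 0.05))
  freq <- pf$freq[mf$retained, , drop = FALSE]
  stage("genotype", n_loci = nrow(gt), maf_retained = length(mf$retained),
        missing_rate = mean(is.na(dosage(gt))))

  # --- statistics -------------------------------------------------------
  ls_tab <- locusStats(freq)
  write.table(ls_tab, file.path(out_dir, "locus_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stage("stats", n_loci = nrow(ls_tab))

  # --- layout-dependent stages -----------------------------------------
  meta <- sampleMeta(ds)
  layout <- unique(meta[, c("population", "drainage", "ecotype")])
  n_drain <- length(unique(layout$drainage[layout$ecotype != "outgroup"]))
  has_og <- any(layout$ecotype == "outgroup")
  call <- NULL
  if (n_drain >= 2 && isTRUE(.cfgGet(config, c("stages", "partition"), TRUE))) {
    ev <- scenarioEvidence(freq, layout)
    drt <- ev$dxy_ratio_table
    write.table(drt, file.path(out_dir, "dxy_partition.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (d in names(ev$bins)) {
      fb <- ev$bins[[d]]
      for (b in 1:4) {
        loci_b <- names(fb$bin)[fb$bin == b]
        if (length(loci_b) >= ev$min_bin_loci) {
          tr <- njPopTree(popDistanceMatrix(freq, loci_b,
                                            layout$population[layout$ecotype != "outgroup"]))
          ape::write.tree(tr$tree,
                          file.path(out_dir, sprintf("tree_%s_bin%d.nwk", d, b)))
        }
      }
    }
    if (has_og) {
      dtab <- do.call(rbind, lapply(names(ev$d_genome), function(k) {
        x <- ev$d_genome[[k]]
        data.frame(quartet = k, D = x$D, se = x$se, z = x$z,
                   n_loci = x$n_loci)
      }))
      write.table(dtab, file.path(out_dir, "dstats.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    cl_args <- config$classify
    call <- do.call(classifyScenario, c(list(evidence = ev), cl_args))
    jsonlite::write_json(
      list(label = call$label, reasons = call$reasons,
           summary = call$summary[c("z_contact", "z_max", "hom_ratio",
                                    "outlier_jaccard", "dxy_out_ratio")]),
      file.path(out_dir, "scenario_call.json"), auto_unbox = TRUE, digits = NA)
    stage("classify", label = call$label)
  }

  report$scenario_call <- if (!is.null(call)) call$label else NA_character_
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(report, list(call = call, freq = freq, genotypes = gt)))
}
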