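#' Specify a simulation scenario for replicated ecotype pairs
#'
#' Defines the study design emulated by the simulator: highland/lowland
#' ecotype pairs replicated across river drainages, with an optional basal
#' outgroup, under one of four divergence/introgression scenarios:
#' \describe{
#'   \item{standing_variation}{drainages split first; one shared locus set is
#'     driven to \code{sel_shift} in the highland population of every drainage
#'     (parallel selection on the same standing alleles).}
#'   \item{de_novo_mutation}{drainages split first; each drainage has its own
#'     disjoint selected locus set, driven only in that drainage's highland
#'     population (independent mutational origins).}
#'   \item{secondary_contact}{ecotypes split first (highland vs lowland
#'     lineages), drainages split within ecotypes; upon contact the highland
#'     population of each drainage receives a gene-flow pulse
#'     \code{p' = (1-m) p_highland + m p_lowland} at neutral loci only, while
#'     selected loci retain the pre-contact ecotype divergence (divergent
#'     selection blocks introgression there).}
#'   \item{adaptive_introgression}{drainages split first; the selected set is
#'     driven to \code{sel_shift} in the donor (first) drainage's highland
#'     population and introgresses into the other highland populations as
#'     \code{p' = (1-m) p_self + m p_donor}.}
#' }
#'
#' Drift along each branch is a Balding-Nichols pulse: the child frequency is
#' Beta-distributed with mean equal to the parent frequency and variance
#' \code{F p (1-p)}. The outgroup receives a single basal pulse with
#' \code{F = 2 * F_eco}.
#'
#' @param scenario one of \code{"standing_variation"}, \code{"de_novo_mutation"},
#'   \code{"secondary_contact"}, \code{"adaptive_introgression"}.
#' @param n_drainages number of replicated drainages (>= 2 for partition
#'   analyses).
#' @param n_loci number of unlinked bi-allelic SNP loci.
#' @param prop_selected fraction of loci under divergent selection.
#' @param F_eco,F_drainage,F_terminal drift intensities (each in (0,1)) for
#'   the ecotype-level, drainage-level and terminal branches.
#' @param m admixture fraction in [0,1] for contact-era gene flow
#'   (secondary_contact) or adaptive introgression.
#' @param sel_shift frequency to which the selected allele is driven in
#'   selected highland populations.
#' @param n_per_pop individuals per population.
#' @param pop_ploidy even ploidy (2 or 4) for every ingroup/outgroup
#'   population; either a single value or a named vector by population.
#' @param depth_mean,depth_dispersion negative-binomial read depth parameters
#'   (mean and size).
#' @param error_rate per-read miscall probability.
#' @param include_outgroup simulate a basal outgroup population (needed for
#'   four-taxon tests).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return a list of class \code{"ScenarioSpec"}.
#' @examples
#' sp <- scenarioSpec("secondary_contact", n_loci = 200, seed = 1)
#' @export
scenarioSpec <- function(scenario = c("standing_variation", "de_novo_mutation",
                                      "secondary_contact", "adaptive_introgression"),
                         n_drainages = 2L, n_loci = 5000L, prop_selected = 0.05,
                         F_eco = 0.1, F_drainage = 0.15, F_terminal = 0.05,
                         m = 0.5, sel_shift = 0.95, n_per_pop = 8L,
                         pop_ploidy = 4L, depth_mean = 25, depth_dispersion = 5,
                         error_rate = 0.005, include_outgroup = TRUE, seed = 1L) {
  scenario <- match.arg(scenario)
  if (!is_count(n_drainages) || n_drainages < 1) stop("n_drainages must be a positive count")
  if (!is_count(n_loci)) stop("n_loci must be a positive count")
  if (!is_frac(prop_selected)) stop("prop_selected must be in [0,1]")
  for (F in c(F_eco, F_drainage, F_terminal))
    if (!(is.numeric(F) && F > 0 && F < 1)) stop("drift intensities must lie in (0,1)")
  if (!is_frac(m)) stop("m must be in [0,1]")
  if (!is_frac(sel_shift)) stop("sel_shift must be in [0,1]")
  if (!is_count(n_per_pop)) stop("n_per_pop must be a positive count")
  if (any(pop_ploidy %% 2 != 0) || any(pop_ploidy < 2))
    stop("pop_ploidy must be even and >= 2")
  if (!(depth_mean > 0)) stop("depth_mean must be positive")
  if (!(depth_dispersion > 0)) stop("depth_dispersion must be positive")
  if (!is_frac(error_rate) || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")

  drainages <- paste0("D", seq_len(n_drainages))
  pops <- as.vector(t(outer(drainages, c("high", "low"), paste, sep = "_")))
  layout <- data.frame(
    population = pops,
    drainage = rep(drainages, each = 2),
    ecotype = rep(c("highland", "lowland"), n_drainages),
    stringsAsFactors = FALSE
  )
  if (include_outgroup)
    layout <- rbind(layout, data.frame(population = "OUT", drainage = "OUT",
                                       ecotype = "outgroup"))
  if (length(pop_ploidy) == 1L) {
    layout$ploidy <- as.integer(pop_ploidy)
  } else {
    if (is.null(names(pop_ploidy)) || !all(layout$population %in% names(pop_ploidy)))
      stop("named pop_ploidy must cover every population")
    layout$ploidy <- as.integer(pop_ploidy[layout$population])
  }

  structure(list(
    scenario = scenario, n_drainages = as.integer(n_drainages),
    n_loci = as.integer(n_loci), prop_selected = prop_selected,
    F_eco = F_eco, F_drainage = F_drainage, F_terminal = F_terminal,
    m = m, sel_shift = sel_shift, n_per_pop = as.integer(n_per_pop),
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    error_rate = error_rate, include_outgroup = include_outgroup,
    layout = layout, seed = as.integer(seed)
  ), class = "ScenarioSpec")
}

#' @export
print.ScenarioSpec <- function(x, ...) {
  cat("ScenarioSpec:", x$scenario, "\n")
  cat(sprintf("  %d drainages x 2 ecotypes%s; %d ind/pop; %d loci (%.0f%% selected)\n",
              x$n_drainages, if (x$include_outgroup) " + outgroup" else "",
              x$n_per_pop, x$n_loci, 100 * x$prop_selected))
  cat(sprintf("  F(eco/drainage/terminal) = %.3g/%.3g/%.3g; m = %.2f; sel_shift = %.2f\n",
              x$F_eco, x$F_drainage, x$F_terminal, x$m, x$sel_shift))
  cat(sprintf("  depth ~ NegBin(mean=%.3g, size=%.3g); error = %.3g; seed = %d\n",
              x$depth_mean, x$depth_dispersion, x$error_rate, x$seed))
  invisible(x)
}

#' Simulate per-population allele frequencies under a scenario
#'
#' Realizes the hierarchical Balding-Nichols drift process described in
#' [scenarioSpec()] and applies the scenario's selection and gene-flow rules.
#' Ancestral frequencies are drawn from Uniform(0.05, 0.95).
#'
#' @param spec a \code{ScenarioSpec}.
#' @return a list of class \code{"FreqTable"} with elements \code{freq}
#'   (loci x populations matrix of alternate-allele frequencies),
#'   \code{selected} (logical per locus), \code{causal_drainage} (which
#'   drainage's selected set a locus belongs to; NA for neutral or shared
#'   sets), \code{layout} and \code{spec}.
#' @export
simulateFrequencies <- function(spec) {
  stopifnot(inherits(spec, "ScenarioSpec"))
  set.seed(childSeed(spec$seed, 1L))
  L <- spec$n_loci
  dr <- paste0("D", seq_len(spec$n_drainages))
  p0 <- runif(L, 0.05, 0.95)

  n_sel <- round(spec$prop_selected * L)
  selected <- rep(FALSE, L)
  causal <- rep(NA_character_, L)
  sel_sets <- list()
  if (n_sel > 0) {
    if (spec$scenario == "de_novo_mutation") {
      pool <- sample.int(L, n_sel * spec$n_drainages)
      sel_sets <- split(pool, rep(dr, each = n_sel))[dr]
      selected[pool] <- TRUE
      for (d in dr) causal[sel_sets[[d]]] <- d
    } else {
      S <- sample.int(L, n_sel)
      sel_sets <- setNames(rep(list(S), spec$n_drainages), dr)
      selected[S] <- TRUE
    }
  }

  freq <- matrix(NA_real_, L, nrow(spec$layout),
                 dimnames = list(paste0("L", seq_len(L)), spec$layout$population))

  if (spec$scenario == "secondary_contact") {
    # ecotypes split first, then drainages within ecotypes
    pH <- rdrift(p0, spec$F_eco)
    pL <- rdrift(p0, spec$F_eco)
    if (n_sel > 0) pH[sel_sets[[1L]]] <- spec$sel_shift  # pre-contact divergent selection
    for (d in dr) {
      h <- rdrift(rdrift(pH, spec$F_drainage), spec$F_terminal)
      l <- rdrift(rdrift(pL, spec$F_drainage), spec$F_terminal)
      if (n_sel > 0) h[sel_sets[[d]]] <- spec$sel_shift  # selection maintains the allele
      # contact: gene flow into the highland ecotype at neutral loci only
      mix <- (1 - spec$m) * h + spec$m * l
      keep <- selected
      h2 <- ifelse(keep, h, mix)
      freq[, paste0(d, "_high")] <- h2
      freq[, paste0(d, "_low")] <- l
    }
  } else {
    # drainages split first, then ecotypes within drainages
    donorH <- NULL
    for (d in dr) {
      pd <- rdrift(p0, spec$F_drainage)
      h <- rdrift(rdrift(pd, spec$F_eco), spec$F_terminal)
      l <- rdrift(rdrift(pd, spec$F_eco), spec$F_terminal)
      if (n_sel > 0) {
        if (spec$scenario == "standing_variation") {
          h[sel_sets[[d]]] <- spec$sel_shift
        } else if (spec$scenario == "de_novo_mutation") {
          h[sel_sets[[d]]] <- spec$sel_shift
        } else if (spec$scenario == "adaptive_introgression") {
          if (d == dr[1L]) {
            h[sel_sets[[d]]] <- spec$sel_shift
            donorH <- h
          } else {
            S <- sel_sets[[d]]
            h[S] <- (1 - spec$m) * h[S] + spec$m * donorH[S]
          }
        }
      }
      freq[, paste0(d, "_high")] <- h
      freq[, paste0(d, "_low")] <- l
    }
  }
  if (spec$include_outgroup)
    freq[, "OUT"] <- rdrift(p0, min(2 * spec$F_eco, 0.999))

  structure(list(freq = freq, selected = selected, causal_drainage = causal,
                 ancestral = p0, layout = spec$layout, spec = spec),
            class = "FreqTable")
}

#' Simulate read depths and dosages from population frequencies
#'
#' For each individual and locus: dosage ~ Binomial(k, p) (autopolyploid HWE),
#' total depth ~ NegBin(depth_mean, depth_dispersion), and alternate reads ~
#' Binomial(depth, f(1-e) + (1-f)e) with f = dosage/k. Frequencies are clamped
#' to [0.001, 0.999] before sampling.
#'
#' @param freqs a \code{FreqTable} from [simulateFrequencies()].
#' @param spec the matching \code{ScenarioSpec} (defaults to the one stored in
#'   \code{freqs}).
#' @return a \linkS4class{ReadDataset}; rowData records the selected flag and
#'   causal drainage of each locus, and true population frequencies are kept
#'   in \code{metadata()$trueFreq}.
#' @export
simulateReads <- function(freqs, spec = freqs$spec) {
  stopifnot(inherits(freqs, "FreqTable"))
  if (!identical(colnames(freqs$freq), spec$layout$population))
    stop("FreqTable populations do not match the scenario layout")
  set.seed(childSeed(spec$seed, 2L))
  L <- nrow(freqs$freq)
  lay <- spec$layout
  n <- spec$n_per_pop
  N <- n * nrow(lay)

  meta <- data.frame(
    population = rep(lay$population, each = n),
    drainage = rep(lay$drainage, each = n),
    ecotype = rep(lay$ecotype, each = n),
    ploidy = rep(lay$ploidy, each = n),
    stringsAsFactors = FALSE
  )
  rownames(meta) <- sprintf("S%03d", seq_len(N))

  ref <- alt <- dose <- matrix(0L, L, N,
    dimnames = list(rownames(freqs$freq), rownames(meta)))
  e <- spec$error_rate
  for (j in seq_len(N)) {
    p <- clampFreq(freqs$freq[, meta$population[j]])
    k <- meta$ploidy[j]
    g <- rbinom(L, k, p)
    dp <- rnbinom(L, size = spec$depth_dispersion, mu = spec$depth_mean)
    a <- rbinom(L, dp, doseReadFrac(g, k, e))
    dose[, j] <- as.integer(g)
    ref[, j] <- as.integer(dp - a)
    alt[, j] <- as.integer(a)
  }
  ReadDataset(ref, alt, meta, trueDosage = dose,
              rowData = data.frame(selected = freqs$selected,
                                   causal_drainage = freqs$causal_drainage),
              metadata = list(trueFreq = freqs$freq, scenario = spec$scenario,
                              spec = spec))
}

#' Simulate a full dataset from a scenario in one call
#'
#' @param spec a \code{ScenarioSpec}.
#' @return a \linkS4class{ReadDataset}.
#' @export
simulateScenario <- function(spec) {
  simulateReads(simulateFrequencies(spec), spec)
}
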