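#' Simulation configuration for the synthetic methylome generator
#'
#' Bundles every knob of the synthetic cohort: genome layout, cohort sizes,
#' SEV injection rate, an optional clustered imprinting defect, chip-batch
#' structure, detection-p reliability and the latent-factor effects on SEV
#' burden.  Defaults emulate a cord-blood case/control study of 23 cases and
#' 41 controls typed on a small array.
#'
#' @param seed master seed; every downstream draw is derived from it.
#' @param n_probes number of CpG probes on the synthetic array.
#' @param n_chromosomes number of chromosomes probes are spread over.
#' @param n_genes number of genes; each spans at least 5 consecutive probes.
#' @param n_imprinted_dmrs number of imprinted DMRs; each spans at least 8
#'   consecutive probes so a clustered defect is enrichable.
#' @param n_reference number of reference (control) subjects.
#' @param n_cases number of case subjects.
#' @param sev_rate expected number of injected outlier epimutations per
#'   subject (Poisson mean before latent-factor modulation).
#' @param defect_subject optional sample id receiving a clustered imprinting
#'   defect, or `NULL`.
#' @param defect_dmr optional DMR id carrying the defect; defaults to the
#'   first DMR when a defect subject is set.
#' @param batch_count number of chip batches samples are split over.
#' @param batch_shift_sd standard deviation (beta scale) of the per-batch,
#'   per-probe additive shift.
#' @param unreliable_fraction fraction of detection-p entries at or above the
#'   0.05 reliability threshold.
#' @param phenotype_effect named numeric vector mapping latent factors
#'   (`"factor1"` .. `"factor4"`) to slopes on the log SEV count; `NULL` for
#'   no effect.
#' @param beta_precision precision `nu` of the Beta(mean*nu, (1-mean)*nu)
#'   subject-level noise around each probe mean.
#' @param snp_fraction,sex_fraction,rare_fraction fractions of probes flagged
#'   as SNP-overlapping, sex-chromosomal, or rare-variant-overlapping.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_probes = 10000L,
                       n_chromosomes = 4L,
                       n_genes = 150L,
                       n_imprinted_dmrs = 8L,
                       n_reference = 41L,
                       n_cases = 23L,
                       sev_rate = 20,
                       defect_subject = NULL,
                       defect_dmr = NULL,
                       batch_count = 2L,
                       batch_shift_sd = 0.01,
                       unreliable_fraction = 0.001,
                       phenotype_effect = NULL,
                       beta_precision = 100,
                       snp_fraction = 0.02,
                       sex_fraction = 0.02,
                       rare_fraction = 0.01) {
  cfg <- list(seed = as.integer(seed), n_probes = as.integer(n_probes),
              n_chromosomes = as.integer(n_chromosomes),
              n_genes = as.integer(n_genes),
              n_imprinted_dmrs = as.integer(n_imprinted_dmrs),
              n_reference = as.integer(n_reference),
              n_cases = as.integer(n_cases),
              sev_rate = sev_rate, defect_subject = defect_subject,
              defect_dmr = defect_dmr, batch_count = as.integer(batch_count),
              batch_shift_sd = batch_shift_sd,
              unreliable_fraction = unreliable_fraction,
              phenotype_effect = phenotype_effect,
              beta_precision = beta_precision,
              snp_fraction = snp_fraction, sex_fraction = sex_fraction,
              rare_fraction = rare_fraction)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_probes", "n_chromosomes", "n_genes", "n_imprinted_dmrs",
              "n_reference", "n_cases", "batch_count")
  for (nm in counts) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop("sim_config: '", nm, "' must be a count >= 1", call. = FALSE)
  }
  if (cfg$sev_rate < 0)
    stop("sim_config: 'sev_rate' must be >= 0", call. = FALSE)
  if (cfg$unreliable_fraction < 0 || cfg$unreliable_fraction > 1)
    stop("sim_config: 'unreliable_fraction' must lie in [0,1]", call. = FALSE)
  if (cfg$beta_precision <= 0)
    stop("sim_config: 'beta_precision' must be > 0", call. = FALSE)
  if (cfg$batch_shift_sd < 0)
    stop("sim_config: 'batch_shift_sd' must be >= 0", call. = FALSE)
  for (nm in c("snp_fraction", "sex_fraction", "rare_fraction")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("sim_config: '", nm, "' must lie in [0,1]", call. = FALSE)
  }
  if (!is.null(cfg$phenotype_effect)) {
    pe <- cfg$phenotype_effect
    if (is.null(names(pe)) || !all(names(pe) %in% paste0("factor", 1:4)))
      stop("sim_config: 'phenotype_effect' must be named factor1..factor4",
           call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sevscan simulation config\n")
  cat(sprintf("  probes: %d on %d chromosome(s); genes: %d; imprinted DMRs: %d\n",
              x$n_probes, x$n_chromosomes, x$n_genes, x$n_imprinted_dmrs))
  cat(sprintf("  cohort: %d reference + %d cases; sev_rate %.3g; batches %d\n",
              x$n_reference, x$n_cases, x$sev_rate, x$batch_count))
  if (!is.null(x$defect_subject))
    cat(sprintf("  imprinting defect: subject %s in DMR %s\n",
                x$defect_subject, x$defect_dmr %||% "<first>"))
  invisible(x)
}

#' Sample identifiers implied by a simulation config
#'
#' Reference (control) subjects precede cases; ids are stable and zero padded.
#'
#' @param config a [sim_config()].
#' @return list with `reference`, `cases` and `all` character vectors.
#' @export
sim_sample_ids <- function(config) {
  ref <- sprintf("ctrl_%02d", seq_len(config$n_reference))
  cas <- sprintf("case_%02d", seq_len(config$n_cases))
  list(reference = ref, cases = cas, all = c(ref, cas))
}
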