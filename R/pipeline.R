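#' Build a pipeline run configuration
#'
#' Collects every stage parameter with its standard default: fence
#' multiplier 3, sliding window 5000/2500 bp, alpha 0.05, 10 retained
#' dimensions, genome-wide threshold 1e-7, detection-p threshold 0.05.
#' Accepts a YAML file path or a list; missing entries fall back to
#' defaults.  The resolved config is serialized into the output directory on
#' every run.
#'
#' @param config `NULL`, a YAML file path, or a list with any of the
#'   elements `seed`, `out_dir`, `simulation` (arguments to [sim_config()]),
#'   `stages` (logical toggles: `qc`, `call`, `enrich`, `famd`,
#'   `associate`), `params` (stage parameters, see defaults in the source).
#' @return a validated `run_config` list.
#' @export
run_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  defaults <- list(
    seed = 1L, out_dir = tempfile("sevscan_run_"),
    simulation = list(),
    stages = list(qc = TRUE, call = TRUE, enrich = TRUE, famd = TRUE,
                  associate = TRUE),
    params = list(fence_multiplier = 3, window = 5000L, step = 2500L,
                  alpha = 0.05, n_dims = 10L, gw_threshold = 1e-7,
                  detp_threshold = 0.05, max_unreliable = 0,
                  internal_mode = "pooled", quantile_method = "hinges",
                  min_n = 10L, external_n = 50L, wholeblood_shift = 0.5,
                  run_window_enrichment = FALSE))
  out <- utils::modifyList(defaults, config)
  out$stages <- utils::modifyList(defaults$stages, out$stages %||% list())
  out$params <- utils::modifyList(defaults$params, out$params %||% list())
  class(out) <- "run_config"
  out
}

#' Run the full SEV analysis pipeline
#'
#' Executes simulate, QC (probe filtering + greedy detection-p pruning), SEV
#' calling against three reference populations (internal pooled controls,
#' external same-tissue, external shifted-tissue), imprinted-DMR and
#' (optionally) sliding-window enrichment, FAMD phenotype reduction with the
#' dimension screens, and the log(SEV) association stage with Fisher
#' combination.  Every stage writes plain TSV/BED/JSON outputs into
#' `out_dir`; a machine-readable manifest (parameters, seeds, record counts,
#' file checksums) permits an exact re-run.  Any stage failure halts with a
#' stage-named error.
#'
#' @param config a [run_config()], a list, or a YAML path.
#' @return invisibly, a list with the in-memory stage results (`annotation`,
#'   `cohort`, `phenotypes`, `qc`, `profile`, `enrichment`, `famd`,
#'   `association`, `ewas`) and the `manifest`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, params = cfg$params,
                   stages = list(), started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  res <- list()
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    out
  }

  # ---- simulate -------------------------------------------------------
  res$sim_config <- do.call(sim_config,
                            utils::modifyList(list(seed = cfg$seed),
                                              cfg$simulation))
  scfg <- res$sim_config
  res$annotation <- stage("simulate_annotation",
                          function() generate_annotation(scfg))
  res$cohort <- stage("simulate_cohort",
                      function() generate_cohort(scfg, res$annotation))
  res$phenotypes <- stage("simulate_phenotypes",
                          function() generate_phenotypes(scfg,
                                                         res$cohort$truth))
  write_beta_tsv(res$cohort$beta, file.path(cfg$out_dir, "beta.tsv"))
  write_beta_tsv(res$cohort$detp, file.path(cfg$out_dir, "detp.tsv"))
  write_annotation_tsv(res$annotation,
                       file.path(cfg$out_dir, "annotation.tsv"))
  write_bed(res$annotation$genes, file.path(cfg$out_dir, "genes.bed"))
  write_bed(res$annotation$dmrs, file.path(cfg$out_dir, "dmrs.bed"))
  write_phenotypes(res$phenotypes, file.path(cfg$out_dir, "phenotypes.tsv"))
  write_ground_truth(res$cohort$truth,
                     file.path(cfg$out_dir, "ground_truth.json"))

  ids <- sim_sample_ids(scfg)
  beta <- res$cohort$beta

  # ---- qc -------------------------------------------------------------
  if (cfg$stages$qc) {
    res$qc <- stage("qc", function() {
      flt <- filter_probes(beta, res$annotation)
      gc <- greedycut(res$cohort$detp[flt$report$kept_probes, ,
                                      drop = FALSE],
                      threshold = cfg$params$detp_threshold,
                      max_unreliable = cfg$params$max_unreliable)
      list(filter = flt$report, greedycut = gc,
           beta = flt$matrix[gc$kept_probes, gc$kept_samples,
                             drop = FALSE])
    })
    beta <- res$qc$beta
    utils::write.table(
      data.frame(metric = c("n_snp_overlap", "n_sex_chromosome",
                            "n_rare_variant", "n_removed_flags",
                            "n_removed_greedycut_probes",
                            "n_removed_greedycut_samples",
                            "n_probes_kept", "n_samples_kept"),
                 value = c(res$qc$filter$n_snp_overlap,
                           res$qc$filter$n_sex_chromosome,
                           res$qc$filter$n_rare_variant,
                           res$qc$filter$n_removed,
                           sum(res$qc$greedycut$trace$what == "probe"),
                           sum(res$qc$greedycut$trace$what == "sample"),
                           nrow(beta), ncol(beta))),
      file.path(cfg$out_dir, "qc_report.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }

  ann_qc <- res$annotation$probes[
    res$annotation$probes$probe_id %in% rownames(beta), , drop = FALSE]

  # ---- call -----------------------------------------------------------
  if (cfg$stages$call) {
    res$references <- stage("references", function() list(
      internal_pooled = beta[, intersect(ids$reference, colnames(beta)),
                             drop = FALSE],
      external_cord = generate_reference(scfg, res$annotation,
                                         n_samples = cfg$params$external_n,
                                         label = "extcord")[rownames(beta), ,
                                                            drop = FALSE],
      external_wholeblood = generate_reference(
        scfg, res$annotation, n_samples = cfg$params$external_n,
        label = "extwb",
        mean_shift_sd = cfg$params$wholeblood_shift)[rownames(beta), ,
                                                     drop = FALSE]))
    res$profile <- stage("call", function()
      sev_profile(beta, res$references,
                  internal_mode = cfg$params$internal_mode,
                  min_n = cfg$params$min_n,
                  quantile_method = cfg$params$quantile_method,
                  multiplier = cfg$params$fence_multiplier))
    utils::write.table(res$profile$summary,
                       file.path(cfg$out_dir, "sev_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$profile$calls,
                       file.path(cfg$out_dir, "sev_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # ---- enrich ---------------------------------------------------------
  if (cfg$stages$enrich && cfg$stages$call) {
    res$enrichment <- stage("enrich", function() {
      dmr_index <- probe_region_index(ann_qc, res$annotation$dmrs)
      calls_int <- res$profile$calls[
        res$profile$calls$mode == "internal_pooled", , drop = FALSE]
      dmr_reports <- lapply(colnames(beta), function(sid)
        region_enrichment(unique(calls_int$probe_id[calls_int$sample_id == sid]),
                          dmr_index, ann_qc, alpha = cfg$params$alpha,
                          sample_id = sid, kind = "imprinted_dmr"))
      dmr_long <- do.call(rbind, dmr_reports)
      win_counts <- NULL
      if (isTRUE(cfg$params$run_window_enrichment)) {
        win_reports <- lapply(colnames(beta), function(sid)
          window_enrichment(unique(calls_int$probe_id[calls_int$sample_id == sid]),
                            ann_qc, window = cfg$params$window,
                            step = cfg$params$step,
                            alpha = cfg$params$alpha, sample_id = sid))
        win_counts <- enriched_region_counts(win_reports,
                                             modes = rep("internal_pooled",
                                                         ncol(beta)))
      }
      list(dmr = dmr_long, window_counts = win_counts)
    })
    utils::write.table(res$enrichment$dmr,
                       file.path(cfg$out_dir, "dmr_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # ---- famd -----------------------------------------------------------
  if (cfg$stages$famd) {
    res$famd <- stage("famd", function() {
      tab <- res$phenotypes[colnames(beta), , drop = FALSE]
      tab$case_control <- NULL   # group label is the outcome, not a trait
      model <- famd_fit(tab, n_dims = cfg$params$n_dims)
      list(model = model,
           correlations = dim_trait_correlations(model, tab),
           group_screen = dims_vs_group(
             model, res$phenotypes[colnames(beta), "case_control"]))
    })
    utils::write.table(
      data.frame(sample_id = rownames(res$famd$model$dimension_scores),
                 res$famd$model$dimension_scores, check.names = FALSE),
      file.path(cfg$out_dir, "famd_scores.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    utils::write.table(res$famd$correlations,
                       file.path(cfg$out_dir, "famd_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # ---- associate ------------------------------------------------------
  if (cfg$stages$associate && cfg$stages$call && cfg$stages$famd) {
    res$association <- stage("associate", function()
      sev_dim_regression(res$profile$summary, res$famd$model,
                         batch = res$cohort$truth$batch))
    utils::write.table(res$association,
                       file.path(cfg$out_dir, "sev_associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$ewas <- stage("ewas", function() {
      flagged <- res$famd$group_screen$dimension[res$famd$group_screen$flagged]
      covs <- cbind(res$famd$model$dimension_scores[, flagged,
                                                    drop = FALSE],
                    batch = as.integer(res$cohort$truth$batch[colnames(beta)]))
      ewas_lite(beta, res$phenotypes[colnames(beta), "case_control"],
                covariates = covs,
                gw_threshold = cfg$params$gw_threshold)
    })
    utils::write.table(res$ewas$results,
                       file.path(cfg$out_dir, "ewas.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # ---- manifest -------------------------------------------------------
  cfg_plain <- unclass(cfg)
  yaml::write_yaml(cfg_plain, file.path(cfg$out_dir, "run_config.yaml"))
  files <- list.files(cfg$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) list(md5 = unname(tools::md5sum(f)),
                                            bytes = file.size(f)))
  manifest$counts <- list(
    n_probes_simulated = scfg$n_probes,
    n_samples = scfg$n_reference + scfg$n_cases,
    n_probes_post_qc = nrow(beta), n_samples_post_qc = ncol(beta))
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

# per-probe annotation as TSV (id/chrom/pos/strand/gene/island/flags)
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(as_probe_table(annotation), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(injected_sevs = lapply(truth$injected_sevs, function(d)
           as.list(d)),
         defect_probes = truth$defect_probes,
         latent_factors = as.data.frame(truth$latent_factors),
         true_sev_slopes = as.list(truth$true_sev_slopes),
         batch = as.list(stats::setNames(as.integer(truth$batch),
                                         names(truth$batch)))),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}
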