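#' Generate a synthetic methylation cohort with ground truth
#'
#' Draws a probes x samples beta-value matrix emulating normalized array
#' data: per-probe baseline means from a bimodal distribution
#' (hypomethylated mode near 0.1, hypermethylated near 0.9, minor
#' intermediate mass), subject-level Beta(mean*nu, (1-mean)*nu) noise,
#' additive per-batch/per-probe shifts, then injected stochastic
#' epimutations.  Per subject, a Poisson number of probes (mean `sev_rate`,
#' modulated by any `phenotype_effect` on the latent factors) is perturbed to
#' the midpoint between the cohort's own 3xIQR fence and the nearer of
#' \{0, 1\}, guaranteeing a call irrespective of quantile convention.  An
#' optional defect subject receives mid-range aberrant values at every probe
#' of one imprinted DMR, emulating a clustered imprinting defect.
#'
#' Baseline values that would fall beyond the clean cohort's own fences are
#' winsorised to just inside the fence before injection, so the injected
#' epimutations are the only outliers and the recorded ground truth is exact.
#' The detection-p matrix is mostly well below 0.05 with
#' `unreliable_fraction` entries at or above it.
#'
#' @param config a [sim_config()].
#' @param annotation the matching [generate_annotation()] result.
#' @return an object of class `sev_cohort`: list with
#'   \describe{
#'     \item{beta}{probes x samples matrix with injected SEVs and defect.}
#'     \item{beta_clean}{the uncontaminated matrix (no injection, no defect).}
#'     \item{detp}{detection-p matrix of the same shape.}
#'     \item{truth}{`sev_ground_truth`: `injected_sevs` (per-subject
#'       data.frames of `probe_id`, `direction`), `defect_probes`,
#'       `latent_factors` (subjects x 4 matrix), `true_sev_slopes`,
#'       `fences` (clean-reference fence table), `batch` (named factor).}
#'   }
#' @export
generate_cohort <- function(config, annotation) {
  validate_sim_config(config)
  probes <- annotation$probes
  if (nrow(probes) != config$n_probes)
    stop("annotation does not match config: probe counts differ",
         call. = FALSE)
  ids <- sim_sample_ids(config)
  n_sub <- length(ids$all)
  np <- config$n_probes

  # -- baseline betas (probe means, then subject draws in-stream) -------
  mu <- probe_means(config)
  nu <- config$beta_precision
  beta <- matrix(stats::rbeta(np * n_sub, mu * nu, (1 - mu) * nu),
                 nrow = np, ncol = n_sub,
                 dimnames = list(probes$probe_id, ids$all))

  # -- chip batches -----------------------------------------------------
  set.seed(component_seed(config$seed, "batch"))
  batch <- factor(sample(rep_len(seq_len(config$batch_count), n_sub)),
                  levels = seq_len(config$batch_count))
  names(batch) <- ids$all
  if (config$batch_shift_sd > 0) {
    shift <- matrix(stats::rnorm(np * config$batch_count,
                                 sd = config$batch_shift_sd),
                    nrow = np)
    beta <- beta + shift[, as.integer(batch), drop = FALSE]
  }
  beta <- pmin(pmax(beta, 0), 1)

  # -- winsorise natural tails at the cohort's own fences ---------------
  ref_cols <- ids$reference
  min_n <- min(10L, config$n_reference)
  fences <- compute_fences(beta[, ref_cols, drop = FALSE], min_n = min_n)
  # clipped tails land well inside the fence (not borderline under
  # replicate-scale measurement noise) while leaving the hinges untouched
  margin <- pmin(0.02, fences$iqr / 2)
  lo_lim <- fences$lower + margin
  hi_lim <- fences$upper - margin
  beta <- pmin(pmax(beta, lo_lim), hi_lim)
  beta <- pmin(pmax(beta, 0), 1)
  beta_clean <- beta

  # -- latent phenotype factors & SEV injection -------------------------
  set.seed(component_seed(config$seed, "factors"))
  latent <- matrix(stats::rnorm(n_sub * 4L), nrow = n_sub,
                   dimnames = list(ids$all, paste0("factor", 1:4)))
  slopes <- stats::setNames(numeric(4L), paste0("factor", 1:4))
  if (!is.null(config$phenotype_effect))
    slopes[names(config$phenotype_effect)] <- config$phenotype_effect

  set.seed(component_seed(config$seed, "sevs"))
  feasible_low <- fences$usable & fences$lower > 0
  feasible_high <- fences$usable & fences$upper < 1
  eligible <- which(feasible_low | feasible_high)
  rate <- config$sev_rate * exp(drop(latent %*% slopes))
  injected <- vector("list", n_sub)
  names(injected) <- ids$all
  for (s in seq_len(n_sub)) {
    k <- stats::rpois(1L, rate[s])
    k <- min(k, length(eligible))
    if (k == 0L) {
      injected[[s]] <- data.frame(probe_id = character(),
                                  direction = character(),
                                  stringsAsFactors = FALSE)
      next
    }
    pr <- sample(eligible, k)
    dir <- character(k)
    for (j in seq_len(k)) {
      sides <- c("low", "high")[c(feasible_low[pr[j]], feasible_high[pr[j]])]
      dir[j] <- if (length(sides) == 1L) sides else sample(sides, 1L)
    }
    val <- ifelse(dir == "low", fences$lower[pr] / 2,
                  (fences$upper[pr] + 1) / 2)
    beta[cbind(pr, s)] <- val
    injected[[s]] <- data.frame(probe_id = probes$probe_id[pr],
                                direction = dir, stringsAsFactors = FALSE)
  }

  # -- clustered imprinting defect --------------------------------------
  defect_probes <- character()
  if (!is.null(config$defect_subject)) {
    if (!config$defect_subject %in% ids$all)
      stop("defect_subject '", config$defect_subject,
           "' is not a cohort sample id", call. = FALSE)
    dmr_id <- config$defect_dmr %||% annotation$dmrs$region_id[1L]
    in_dmr <- which(!is.na(probes$dmr) & probes$dmr == dmr_id)
    if (length(in_dmr) == 0L)
      stop("defect_dmr '", dmr_id, "' has no probes", call. = FALSE)
    set.seed(component_seed(config$seed, "defect"))
    s <- match(config$defect_subject, ids$all)
    target <- ifelse(mu[in_dmr] < 0.5, 0.6, 0.4) +
      stats::rnorm(length(in_dmr), sd = 0.02)
    beta[cbind(in_dmr, s)] <- pmin(pmax(target, 0.05), 0.95)
    defect_probes <- probes$probe_id[in_dmr]
  }

  # -- detection p-values ----------------------------------------------
  set.seed(component_seed(config$seed, "detp"))
  detp <- matrix(stats::runif(np * n_sub, 0, 0.01), nrow = np,
                 dimnames = dimnames(beta))
  n_bad <- round(config$unreliable_fraction * length(detp))
  if (n_bad > 0)
    detp[sample.int(length(detp), n_bad)] <- stats::runif(n_bad, 0.05, 1)

  truth <- list(injected_sevs = injected, defect_probes = defect_probes,
                latent_factors = latent, true_sev_slopes = slopes,
                fences = fences, batch = batch)
  class(truth) <- "sev_ground_truth"
  out <- list(beta = beta, beta_clean = beta_clean, detp = detp,
              truth = truth)
  class(out) <- "sev_cohort"
  out
}

#' Per-probe baseline methylation means of a simulated genome
#'
#' The bimodal baseline (hypomethylated mode near 0.1, hypermethylated near
#' 0.9, minor intermediate mass) is a deterministic function of the master
#' seed, shared by the study cohort and any external reference generated
#' from the same config.  Seeds the `betas` stream; subject draws continue
#' in that stream.
#'
#' @param config a [sim_config()].
#' @return numeric vector of length `n_probes`, means in `(0, 1)`.
#' @export
probe_means <- function(config) {
  set.seed(component_seed(config$seed, "betas"))
  np <- config$n_probes
  mode <- sample(c("hypo", "hyper", "mid"), np, replace = TRUE,
                 prob = c(0.45, 0.45, 0.10))
  mu <- numeric(np)
  mu[mode == "hypo"] <- stats::rbeta(sum(mode == "hypo"), 5, 45)
  mu[mode == "hyper"] <- stats::rbeta(sum(mode == "hyper"), 45, 5)
  mu[mode == "mid"] <- stats::rbeta(sum(mode == "mid"), 30, 30)
  pmin(pmax(mu, 0.02), 0.98)
}

#' Generate an external reference beta matrix
#'
#' Draws a clean reference cohort sharing the study genome's per-probe
#' baseline means (same master seed) but with independent subjects, an
#' optional systematic per-probe mean shift on the logit scale (emulating a
#' tissue or platform difference, e.g. whole blood versus cord blood), and
#' its own winsorisation at its own fences.  No epimutations are injected:
#' a reference population defines fences, it is not screened.
#'
#' @param config the study [sim_config()].
#' @param annotation the matching annotation.
#' @param n_samples number of reference subjects.
#' @param label prefix for sample ids (also seeds the subject draws, so two
#'   references with different labels are independent).
#' @param mean_shift_sd standard deviation of the per-probe logit-scale mean
#'   shift (0 = same tissue).
#' @return probes x samples beta matrix.
#' @export
generate_reference <- function(config, annotation, n_samples = 50L,
                               label = "ext", mean_shift_sd = 0) {
  mu <- probe_means(config)
  np <- config$n_probes
  seed <- component_seed(config$seed, "external") +
    sum(utf8ToInt(label)) %% 1000L
  set.seed(seed)
  if (mean_shift_sd > 0)
    mu <- stats::plogis(stats::qlogis(mu) +
                          stats::rnorm(np, sd = mean_shift_sd))
  mu <- pmin(pmax(mu, 0.02), 0.98)
  nu <- config$beta_precision
  beta <- matrix(stats::rbeta(np * n_samples, mu * nu, (1 - mu) * nu),
                 nrow = np,
                 dimnames = list(annotation$probes$probe_id,
                                 sprintf("%s_%02d", label,
                                         seq_len(n_samples))))
  fences <- compute_fences(beta, min_n = min(10L, n_samples))
  margin <- pmin(0.02, fences$iqr / 2)
  beta <- pmin(pmax(beta, fences$lower + margin), fences$upper - margin)
  pmin(pmax(beta, 0), 1)
}

#' @export
print.sev_cohort <- function(x, ...) {
  cat(sprintf("sev_cohort: %d probes x %d samples; %d injected SEVs; %d defect probes\n",
              nrow(x$beta), ncol(x$beta),
              sum(vapply(x$truth$injected_sevs, nrow, 1L)),
              length(x$truth$defect_probes)))
  invisible(x)
}
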