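#' Per-CpG extreme-outlier fences from a reference population
#'
#' For every probe, computes the quartiles of the reference beta values and
#' the extreme-outlier fences \eqn{Q_1 - m \cdot IQR} and
#' \eqn{Q_3 + m \cdot IQR} with multiplier `m = 3` (box-and-whiskers extreme
#' outliers, not the conventional 1.5).  Fences are deliberately not clipped
#' to `[0, 1]`: a fence below 0 or above 1 simply cannot produce calls on
#' that side.
#'
#' @param reference numeric matrix, probes x samples, beta values in `[0,1]`
#'   with missing values allowed; rownames are probe ids.
#' @param min_n minimum number of non-missing reference values a probe needs
#'   to receive usable fences; probes below it are marked unusable and are
#'   skipped (and tallied) during calling.
#' @param quantile_method `"hinges"` (default; Tukey hinges, the quartile
#'   convention of R's boxplot statistics) or `"linear"`
#'   (linear-interpolation quantiles, [stats::quantile()] type 7).
#' @param multiplier IQR multiplier of the fences (default 3).
#' @return a `fence_table` data.frame with columns `probe_id`, `q1`, `q3`,
#'   `iqr`, `lower`, `upper`, `n_reference`, `usable`.
#' @export
compute_fences <- function(reference, min_n = 10L,
                           quantile_method = c("hinges", "linear"),
                           multiplier = 3) {
  quantile_method <- match.arg(quantile_method)
  if (is.null(dim(reference)))
    reference <- matrix(reference, nrow = 1L)
  if (ncol(reference) < min_n)
    stop(sprintf("reference has %d samples but min_n = %d non-missing values per probe are required",
                 ncol(reference), min_n), call. = FALSE)
  if (is.null(rownames(reference)))
    rownames(reference) <- sprintf("probe_%d", seq_len(nrow(reference)))

  n_ok <- rowSums(!is.na(reference))
  qs <- row_quartiles(reference, quantile_method)
  iqr <- qs$q3 - qs$q1
  out <- data.frame(probe_id = rownames(reference),
                    q1 = qs$q1, q3 = qs$q3, iqr = iqr,
                    lower = qs$q1 - multiplier * iqr,
                    upper = qs$q3 + multiplier * iqr,
                    n_reference = n_ok,
                    usable = n_ok >= min_n,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$q1[!out$usable] <- NA_real_
  out$q3[!out$usable] <- NA_real_
  out$iqr[!out$usable] <- NA_real_
  out$lower[!out$usable] <- NA_real_
  out$upper[!out$usable] <- NA_real_
  class(out) <- c("fence_table", "data.frame")
  out
}

# Q1/Q3 for every row of a matrix.  Fast path: no missing values (rows share
# n, sort all rows at once); otherwise per-row.
row_quartiles <- function(x, method) {
  if (!anyNA(x)) {
    n <- ncol(x)
    s <- apply(x, 1L, sort.int, method = "quick")   # n x n_probes
    if (method == "hinges") {
      d <- floor((n + 3) / 2) / 2
      lo <- (s[floor(d), , drop = TRUE] + s[ceiling(d), , drop = TRUE]) / 2
      hi <- (s[n + 1 - floor(d), , drop = TRUE] +
             s[n + 1 - ceiling(d), , drop = TRUE]) / 2
    } else {
      lo <- interp_quantile_sorted(s, n, 0.25)
      hi <- interp_quantile_sorted(s, n, 0.75)
    }
    return(list(q1 = unname(lo), q3 = unname(hi)))
  }
  q1 <- q3 <- rep(NA_real_, nrow(x))
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    v <- v[!is.na(v)]
    if (length(v) == 0L) next
    if (method == "hinges") {
      fn <- stats::fivenum(v)
      q1[i] <- fn[2L]; q3[i] <- fn[4L]
    } else {
      qq <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
      q1[i] <- qq[1L]; q3[i] <- qq[2L]
    }
  }
  list(q1 = q1, q3 = q3)
}

# type-7 quantile on pre-sorted columns of s (n rows)
interp_quantile_sorted <- function(s, n, p) {
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo, , drop = TRUE] + (h - lo) * (s[hi, , drop = TRUE] - s[lo, , drop = TRUE])
}

#' Call stochastic epigenetic variations for one subject
#'
#' Flags every probe whose beta value lies strictly beyond the reference
#' fences: direction `"low"` iff `value < lower`, `"high"` iff
#' `value > upper`.  Ties at a fence are not outliers.  Missing values are
#' never flagged; probes without usable fences are skipped and tallied.
#'
#' @param values named numeric vector of the subject's beta values (names are
#'   probe ids).
#' @param fences a [compute_fences()] table.
#' @param sample_id subject identifier recorded in the result.
#' @param reference_mode label of the reference population used (e.g.
#'   `"internal_pooled"`, `"external_cord"`, `"external_wholeblood"`).
#' @return an object of class `sev_callset`: list with `sample_id`,
#'   `reference_mode`, `calls` (data.frame `probe_id`, `direction`, `value`,
#'   `lower`, `upper`), `n_sev`, `log_sev` (natural log; `log(n_sev + 1)`
#'   with `zero_adjusted = TRUE` when `n_sev = 0`), `n_skipped` (probes
#'   without usable fences), `n_zero_iqr` (calls at zero-IQR probes).
#' @export
call_sevs <- function(values, fences, sample_id = "subject",
                      reference_mode = "internal_pooled") {
  if (is.null(names(values)))
    stop("'values' must be named by probe id", call. = FALSE)
  idx <- match(names(values), fences$probe_id)
  unknown <- is.na(idx)
  usable <- !unknown & fences$usable[idx]
  n_skipped <- sum(!usable)

  lower <- fences$lower[idx]; upper <- fences$upper[idx]
  iqr <- fences$iqr[idx]
  low <- usable & !is.na(values) & values < lower
  high <- usable & !is.na(values) & values > upper
  hit <- low | high
  calls <- data.frame(probe_id = names(values)[hit],
                      direction = ifelse(low[hit], "low", "high"),
                      value = unname(values[hit]),
                      lower = lower[hit], upper = upper[hit],
                      row.names = NULL, stringsAsFactors = FALSE)
  n_sev <- nrow(calls)
  out <- list(sample_id = sample_id, reference_mode = reference_mode,
              calls = calls, n_sev = n_sev,
              log_sev = if (n_sev >= 1L) log(n_sev) else log1p(n_sev),
              zero_adjusted = n_sev == 0L,
              n_skipped = n_skipped,
              n_zero_iqr = sum(hit & !is.na(iqr) & iqr == 0))
  class(out) <- "sev_callset"
  out
}

#' @export
print.sev_callset <- function(x, ...) {
  cat(sprintf("sev_callset: %s [%s] n_sev = %d (log %0.3f%s), skipped %d, zero-IQR calls %d\n",
              x$sample_id, x$reference_mode, x$n_sev, x$log_sev,
              if (x$zero_adjusted) ", zero-adjusted" else "",
              x$n_skipped, x$n_zero_iqr))
  invisible(x)
}

#' SEV profile of a cohort against one or more reference populations
#'
#' For each reference mode, computes per-CpG fences from that reference and
#' calls SEVs for every cohort sample.  Samples that are members of a
#' reference (matched by sample id) are, under `internal_mode = "pooled"`,
#' called against fences computed from the whole reference including
#' themselves; under `"loo"` each member is called against fences from the
#' reference minus itself.  Non-members are always called against the full
#' reference.  The probe universe is the intersection of the cohort's and all
#' references' probes.
#'
#' @param cohort probes x samples beta matrix of the study subjects.
#' @param references named list of reference beta matrices; names become the
#'   `reference_mode` labels.
#' @param internal_mode `"pooled"` (default) or `"loo"`.
#' @param min_n,quantile_method,multiplier passed to [compute_fences()].
#' @return an object of class `sev_profile`: list with `summary` (one row per
#'   sample x mode: `sample_id`, `mode`, `n_sev`, `log_sev`, `zero_adjusted`,
#'   `n_skipped`, `n_zero_iqr`), `calls` (long data.frame of all flagged
#'   probes) and `n_common_probes`.
#' @export
sev_profile <- function(cohort, references,
                        internal_mode = c("pooled", "loo"),
                        min_n = 10L, quantile_method = c("hinges", "linear"),
                        multiplier = 3) {
  internal_mode <- match.arg(internal_mode)
  quantile_method <- match.arg(quantile_method)
  if (is.null(names(references)) || any(!nzchar(names(references))))
    stop("'references' must be a named list of beta matrices", call. = FALSE)
  universe <- Reduce(intersect,
                     c(list(rownames(cohort)), lapply(references, rownames)))
  if (length(universe) == 0L)
    stop("empty probe intersection between cohort and references",
         call. = FALSE)
  cohort <- cohort[universe, , drop = FALSE]

  summaries <- list(); all_calls <- list()
  for (mode in names(references)) {
    ref <- references[[mode]][universe, , drop = FALSE]
    fences_full <- compute_fences(ref, min_n = min_n,
                                  quantile_method = quantile_method,
                                  multiplier = multiplier)
    members <- intersect(colnames(ref), colnames(cohort))
    for (sid in colnames(cohort)) {
      fences <- fences_full
      if (internal_mode == "loo" && sid %in% members && ncol(ref) > min_n) {
        fences <- compute_fences(ref[, setdiff(colnames(ref), sid),
                                     drop = FALSE],
                                 min_n = min_n,
                                 quantile_method = quantile_method,
                                 multiplier = multiplier)
      }
      cs <- call_sevs(cohort[, sid], fences, sample_id = sid,
                      reference_mode = mode)
      summaries[[length(summaries) + 1L]] <- data.frame(
        sample_id = sid, mode = mode, n_sev = cs$n_sev,
        log_sev = cs$log_sev, zero_adjusted = cs$zero_adjusted,
        n_skipped = cs$n_skipped, n_zero_iqr = cs$n_zero_iqr,
        stringsAsFactors = FALSE)
      if (cs$n_sev > 0L)
        all_calls[[length(all_calls) + 1L]] <-
          cbind(sample_id = sid, mode = mode, cs$calls,
                stringsAsFactors = FALSE)
    }
  }
  out <- list(summary = do.call(rbind, summaries),
              calls = if (length(all_calls)) do.call(rbind, all_calls)
                      else data.frame(sample_id = character(),
                                      mode = character(),
                                      probe_id = character(),
                                      direction = character(),
                                      value = numeric(), lower = numeric(),
                                      upper = numeric()),
              n_common_probes = length(universe))
  class(out) <- "sev_profile"
  out
}

#' @export
print.sev_profile <- function(x, ...) {
  cat(sprintf("sev_profile: %d sample x mode rows over %d common probes\n",
              nrow(x$summary), x$n_common_probes))
  print(utils::head(x$summary, 8L))
  invisible(x)
}
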