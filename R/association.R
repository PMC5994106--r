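#' Fisher's combined probability test
#'
#' Combines k independent p-values via \eqn{-2 \sum \ln p_i}, referred to a
#' chi-square distribution with 2k degrees of freedom.  With k = 1 the
#' combination is the identity.  A p-value of exactly 0 is rejected (its log
#' is undefined); callers should floor p-values first (the package uses a
#' documented floor of 1e-300).
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @return list with `statistic`, `df` (= 2k) and `p_combined`.
#' @export
fisher_combine <- function(pvalues) {
  if (length(pvalues) == 0L)
    stop("fisher_combine: no p-values supplied", call. = FALSE)
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("fisher_combine: p-values must lie in (0, 1]; floor exact zeros at 1e-300 first",
         call. = FALSE)
  stat <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(statistic = stat, df = df,
       p_combined = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Regress log SEV burden on phenotype dimensions, combined across modes
#'
#' For each reference mode, fits one ordinary-least-squares model of the log
#' SEV count on all retained dimension scores plus chip-batch indicators,
#' takes the per-dimension t-test p-values, combines each dimension's
#' p-values across modes with [fisher_combine()] (exact zeros floored at
#' 1e-300), and Bonferroni-corrects the combined p over the number of tested
#' dimensions.
#'
#' @param log_sev data.frame with columns `sample_id`, `mode`, `log_sev`
#'   (e.g. the `summary` of [sev_profile()]).
#' @param model a [famd_fit()] result whose scores cover the samples.
#' @param batch named factor of chip batches per sample, or `NULL` to omit
#'   the batch covariate.
#' @return data.frame with one row per dimension: per-mode p-values
#'   (`p_<mode>`), per-mode coefficients (`coef_<mode>`), `fisher_statistic`,
#'   `fisher_df`, `p_combined`, `p_adj`, `significant`.
#' @export
sev_dim_regression <- function(log_sev, model, batch = NULL) {
  needed <- c("sample_id", "mode", "log_sev")
  if (!all(needed %in% names(log_sev)))
    stop("'log_sev' needs columns sample_id, mode, log_sev", call. = FALSE)
  scores <- model$dimension_scores
  modes <- unique(log_sev$mode)
  dims <- colnames(scores)

  pmat <- matrix(NA_real_, length(dims), length(modes),
                 dimnames = list(dims, modes))
  cmat <- pmat
  for (m in modes) {
    sub <- log_sev[log_sev$mode == m, , drop = FALSE]
    idx <- match(sub$sample_id, rownames(scores))
    if (anyNA(idx))
      stop("samples in log_sev missing from the factor model: ",
           paste(utils::head(sub$sample_id[is.na(idx)], 3L), collapse = ", "),
           call. = FALSE)
    X <- scores[idx, , drop = FALSE]
    df <- data.frame(log_sev = sub$log_sev, X, check.names = FALSE)
    form <- stats::as.formula(paste("log_sev ~",
                                    paste(sprintf("`%s`", dims),
                                          collapse = " + ")))
    if (!is.null(batch)) {
      b <- droplevels(as.factor(batch[sub$sample_id]))
      if (nlevels(b) > 1L) {
        df$chip_batch <- b
        form <- stats::update(form, . ~ . + chip_batch)
      }
    }
    fit <- stats::lm(form, data = df)
    aliased <- is.na(stats::coef(fit))
    if (any(aliased))
      stop("rank-deficient design; collinear columns: ",
           paste(names(aliased)[aliased], collapse = ", "), call. = FALSE)
    co <- summary(fit)$coefficients
    rn <- gsub("`", "", rownames(co))
    pmat[, m] <- co[match(dims, rn), "Pr(>|t|)"]
    cmat[, m] <- co[match(dims, rn), "Estimate"]
  }

  comb <- t(vapply(dims, function(d) {
    fc <- fisher_combine(pmax(pmat[d, ], 1e-300))
    c(fc$statistic, fc$df, fc$p_combined)
  }, numeric(3)))
  out <- data.frame(dimension = dims,
                    stringsAsFactors = FALSE)
  for (m in modes) out[[paste0("p_", m)]] <- pmat[, m]
  for (m in modes) out[[paste0("coef_", m)]] <- cmat[, m]
  out$fisher_statistic <- comb[, 1L]
  out$fisher_df <- comb[, 2L]
  out$p_combined <- comb[, 3L]
  out$p_adj <- pmin(1, out$p_combined * length(dims))
  out$significant <- out$p_adj < 0.05
  rownames(out) <- NULL
  out
}

#' Per-site linear-model scan with genomic inflation diagnostic
#'
#' Ordinary least squares of each probe's beta values on the group label
#' plus covariates, with a t-test on the group coefficient, a genome-wide
#' significance flag and the genomic inflation factor of the scan.  The
#' model uses classical (non-moderated) standard errors; it exists as a
#' covariate-adjustment and inflation diagnostic, not as a full differential
#' methylation engine.
#'
#' @param beta probes x samples matrix.
#' @param group binary labels (factor or coercible) per sample.
#' @param covariates optional numeric matrix / data.frame of per-sample
#'   covariates (e.g. dimension scores, batch indicators).
#' @param gw_threshold genome-wide significance threshold (default 1e-7).
#' @return list with `results` (data.frame `probe_id`, `estimate`, `se`,
#'   `t`, `p`, `genomewide`) and `lambda`.
#' @export
ewas_lite <- function(beta, group, covariates = NULL,
                      gw_threshold = 1e-7) {
  g <- droplevels(as.factor(group))
  if (nlevels(g) != 2L)
    stop("'group' must be binary", call. = FALSE)
  y <- as.numeric(g == levels(g)[2L])
  X <- cbind(intercept = 1, group = y)
  if (!is.null(covariates)) {
    cov <- as.matrix(as.data.frame(covariates))
    storage.mode(cov) <- "double"
    X <- cbind(X, cov)
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 2L)
    stop("need n_samples > n_covariates + 2", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[setdiff(seq_len(p), keep)], collapse = ", "),
         call. = FALSE)
  }
  XtXinv <- chol2inv(qr.R(qrX))
  B <- beta %*% X %*% XtXinv                       # probes x p
  resid <- beta - B %*% t(X)
  dfree <- n - p
  sigma2 <- rowSums(resid^2) / dfree
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  tstat <- B[, 2L] / se
  pval <- 2 * stats::pt(-abs(tstat), df = dfree)
  res <- data.frame(probe_id = rownames(beta) %||%
                      sprintf("probe_%d", seq_len(nrow(beta))),
                    estimate = B[, 2L], se = se, t = tstat, p = pval,
                    genomewide = pval < gw_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(results = res, lambda = genomic_lambda(pval))
}

#' Genomic inflation factor
#'
#' Converts p-values to 1-df chi-square quantiles and divides their median
#' by the null median \eqn{\chi^2_{1, 0.5} \approx 0.4549364}.  A
#' well-calibrated scan gives lambda near 1; residual confounding inflates
#' it.
#'
#' @param pvalues p-values in `(0, 1]`.
#' @return lambda (positive scalar).
#' @export
genomic_lambda <- function(pvalues) {
  if (length(pvalues) == 0L)
    stop("genomic_lambda: empty p-value list", call. = FALSE)
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("genomic_lambda: p-values must lie in (0, 1]", call. = FALSE)
  chisq <- stats::qchisq(pvalues, df = 1L, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1L, lower.tail = FALSE)
}

#' Two-group sample size under the normal approximation
#'
#' Per-group n for detecting a mean methylation difference `delta` (beta
#' units) with per-group standard deviation `sd`, two-sided level `alpha`
#' and the requested power:
#' \eqn{n = \lceil 2 (z_{1-\alpha/2} + z_{power})^2 sd^2 / delta^2 \rceil},
#' floored at 1.
#'
#' @param delta smallest group difference worth detecting (> 0).
#' @param sd per-group standard deviation (> 0).
#' @param alpha two-sided type-I error (default 1e-7, an epigenome-wide
#'   threshold).
#' @param power target power (default 0.95).
#' @return integer sample size per group.
#' @export
sample_size_two_group <- function(delta, sd, alpha = 1e-7, power = 0.95) {
  if (delta <= 0 || sd <= 0)
    stop("'delta' and 'sd' must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= alpha || power >= 1)
    stop("need 0 < alpha < power < 1", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  max(1L, as.integer(ceiling(2 * z^2 * sd^2 / delta^2)))
}
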