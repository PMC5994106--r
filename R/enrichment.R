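#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `k` marked elements when drawing `n`
#' elements without replacement from a universe of `N` elements of which `K`
#' are marked: \eqn{P(X \ge k)} for \eqn{X \sim Hypergeom(N, K, n)}.
#' Evaluated through the stable log-space tail of the hypergeometric
#' distribution.
#'
#' @param N universe size (e.g. probes genome-wide after QC).
#' @param K marked elements in the universe (probes in the region).
#' @param n drawn elements (the subject's genome-wide SEV count).
#' @param k observed marked draws (the subject's SEVs inside the region).
#' @return the upper-tail probability, in `(0, 1]`.
#' @export
hypergeom_upper <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || anyNA(c(N, K, n, k)))
    stop("hypergeom_upper: counts must be non-negative", call. = FALSE)
  if (K > N || n > N)
    stop("hypergeom_upper: need K <= N and n <= N", call. = FALSE)
  if (k > min(K, n))
    stop("hypergeom_upper: need k <= min(K, n)", call. = FALSE)
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Sliding-window SEV enrichment for one subject
#'
#' Slides fixed-width windows along every chromosome and tests each window
#' containing at least one probe for over-representation of the subject's
#' SEVs with [hypergeom_upper()], Bonferroni-corrected over the number of
#' tested windows for that subject.  Call direction is ignored.
#'
#' @param calls a `sev_callset` (from [call_sevs()]) or a character vector of
#'   SEV probe ids.
#' @param annotation post-QC probe annotation (or `sev_annotation`); its
#'   probes define the universe `N`.
#' @param window window width in bp (default 5000).
#' @param step slide step in bp (default 2500, i.e. 50% overlap).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param sample_id label for the report (taken from the callset if given).
#' @return data.frame with one row per tested window: `sample_id`,
#'   `region_id`, `region_kind`, `K`, `k`, `N`, `n`, `p`, `p_adj`,
#'   `enriched`; attribute `n_enriched` carries the subject's enriched-window
#'   count.
#' @export
window_enrichment <- function(calls, annotation, window = 5000L,
                              step = 2500L, alpha = 0.05,
                              sample_id = NULL) {
  if (window <= 0 || step <= 0 || window < step)
    stop("need window >= step > 0", call. = FALSE)
  probes <- as_probe_table(annotation)
  sev <- sev_probe_ids(calls)
  sample_id <- sample_id %||% sev_sample_id(calls)

  windows <- do.call(rbind, lapply(split(probes, probes$chrom), function(p) {
    extent <- max(p$pos)
    starts <- seq(0L, max(0L, extent - 1L), by = step)
    data.frame(region_id = sprintf("%s_win_%06d", p$chrom[1L],
                                   seq_along(starts)),
               chrom = p$chrom[1L], start = starts,
               end = starts + window, kind = "window",
               stringsAsFactors = FALSE)
  }))
  region_enrichment(sev, windows, probes, alpha = alpha,
                    sample_id = sample_id, kind = "window")
}

#' Region-set SEV enrichment for one subject
#'
#' Applies the hypergeometric over-representation test to an arbitrary
#' region set (genes, promoters, imprinted DMRs, tiling), Bonferroni
#' correcting over the tested (non-empty) regions of that set.  Regions
#' without probes are skipped.
#'
#' @param calls `sev_callset` or character vector of SEV probe ids.
#' @param regions region data.frame (`region_id`, `chrom`, `start`, `end`,
#'   optionally `kind`) *or* a precomputed probe index (data.frame with
#'   `region_id`, `probe_id`).
#' @param annotation post-QC probe annotation; defines the universe.
#' @param alpha significance level on the adjusted p.
#' @param sample_id,kind labels for the report.
#' @return as [window_enrichment()].
#' @export
region_enrichment <- function(calls, regions, annotation, alpha = 0.05,
                              sample_id = NULL, kind = NULL) {
  probes <- as_probe_table(annotation)
  sev <- sev_probe_ids(calls)
  sample_id <- sample_id %||% sev_sample_id(calls)
  sev <- intersect(sev, probes$probe_id)
  N <- nrow(probes)
  n <- length(sev)

  index <- if (all(c("region_id", "probe_id") %in% names(regions)) &&
               !"start" %in% names(regions)) regions
           else probe_region_index(probes, regions)
  index <- index[index$probe_id %in% probes$probe_id, , drop = FALSE]
  if (nrow(index) == 0L)
    return(empty_enrichment(sample_id))

  K_tab <- table(index$region_id)
  k_tab <- table(factor(index$region_id[index$probe_id %in% sev],
                        levels = names(K_tab)))
  kinds <- index$kind[match(names(K_tab), index$region_id)]
  K <- as.integer(K_tab); k <- as.integer(k_tab)
  p <- vapply(seq_along(K), function(i) hypergeom_upper(N, K[i], n, k[i]),
              numeric(1))
  n_tested <- length(K)
  out <- data.frame(sample_id = sample_id %||% "subject",
                    region_id = names(K_tab),
                    region_kind = kinds %||% kind %||% NA_character_,
                    K = K, k = k, N = N, n = n, p = p,
                    p_adj = pmin(1, p * n_tested),
                    stringsAsFactors = FALSE)
  out$enriched <- out$p_adj < alpha
  rownames(out) <- NULL
  attr(out, "n_enriched") <- sum(out$enriched)
  out
}

empty_enrichment <- function(sample_id) {
  out <- data.frame(sample_id = character(), region_id = character(),
                    region_kind = character(), K = integer(), k = integer(),
                    N = integer(), n = integer(), p = numeric(),
                    p_adj = numeric(), enriched = logical())
  attr(out, "n_enriched") <- 0L
  out
}

sev_probe_ids <- function(calls) {
  if (inherits(calls, "sev_callset")) unique(calls$calls$probe_id)
  else if (is.character(calls)) unique(calls)
  else stop("'calls' must be a sev_callset or character probe ids",
            call. = FALSE)
}

sev_sample_id <- function(calls) {
  if (inherits(calls, "sev_callset")) calls$sample_id else "subject"
}

#' Enriched-region counts per subject and reference mode
#'
#' Summarizes a set of per-subject enrichment reports into counts of
#' enriched regions, on the natural-log scale used for SEV burden
#' (`log(count)`, or `log(count + 1)` flagged when the count is 0).
#'
#' @param reports list of enrichment report data.frames (each carrying
#'   `sample_id`, `enriched`), or one long data.frame with a `mode` column.
#' @param modes optional character vector of mode labels parallel to
#'   `reports`.
#' @return data.frame `sample_id`, `mode`, `n_enriched`, `log_enriched`,
#'   `zero_adjusted`.
#' @export
enriched_region_counts <- function(reports, modes = NULL) {
  if (is.data.frame(reports)) reports <- list(reports)
  rows <- lapply(seq_along(reports), function(i) {
    rep_i <- reports[[i]]
    mode <- if (!is.null(modes)) modes[i]
            else if ("mode" %in% names(rep_i) && nrow(rep_i)) rep_i$mode[1L]
            else "default"
    if (nrow(rep_i) == 0L)
      return(data.frame(sample_id = character(), mode = character(),
                        n_enriched = integer(), log_enriched = numeric(),
                        zero_adjusted = logical()))
    agg <- stats::aggregate(list(n_enriched = rep_i$enriched),
                            by = list(sample_id = rep_i$sample_id), FUN = sum)
    data.frame(sample_id = agg$sample_id, mode = mode,
               n_enriched = agg$n_enriched,
               log_enriched = ifelse(agg$n_enriched >= 1L,
                                     log(agg$n_enriched),
                                     log1p(agg$n_enriched)),
               zero_adjusted = agg$n_enriched == 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
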