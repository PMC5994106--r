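# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# Tukey hinges by explicit median-of-halves on a sorted vector
oracle_hinges <- function(v) {
  v <- sort(v[!is.na(v)])
  n <- length(v)
  med_of <- function(x) {
    x <- unname(x)
    m <- length(x)
    if (m %% 2 == 1) x[(m + 1) / 2] else (x[m / 2] + x[m / 2 + 1]) / 2
  }
  half <- ceiling(n / 2)
  c(lower = med_of(v[1:half]), upper = med_of(v[(n - half + 1):n]))
}

oracle_fences <- function(v, multiplier = 3) {
  h <- oracle_hinges(v)
  iqr <- h[["upper"]] - h[["lower"]]
  c(lower = h[["lower"]] - multiplier * iqr,
    upper = h[["upper"]] + multiplier * iqr)
}

# brute-force SEV calling: per probe, fence from reference rows, strict compare
oracle_call_matrix <- function(reference, subject_values, multiplier = 3) {
  out <- character(0)
  for (p in rownames(reference)) {
    f <- oracle_fences(reference[p, ], multiplier)
    v <- subject_values[[p]]
    if (!is.na(v) && (v < f[["lower"]] || v > f[["upper"]]))
      out <- c(out, p)
  }
  out
}

# exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
oracle_hyper_enum <- function(N, K, n, k) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# hypergeometric upper tail by direct PMF summation with log-binomials
oracle_hyper_pmfsum <- function(N, K, n, k) {
  if (k == 0) return(1)
  kk <- k:min(K, n)
  terms <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
  sum(exp(terms))
}

oracle_hyper_pmf <- function(N, K, n) {
  kk <- max(0, n - (N - K)):min(K, n)
  exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n))
}

# exhaustive greedy removal on a logical unreliability matrix, recomputing
# fractions after each removal; ties probe-before-sample then lexicographic
oracle_greedy <- function(bad, max_unreliable) {
  trace <- list()
  repeat {
    rf <- rowMeans(bad); cf <- colMeans(bad)
    worst <- max(rf, cf)
    if (worst <= max_unreliable) break
    rows <- sort(names(rf)[rf == worst])
    cols <- sort(names(cf)[cf == worst])
    if (length(rows) > 0) {
      trace[[length(trace) + 1]] <- c("probe", rows[1])
      bad <- bad[setdiff(rownames(bad), rows[1]), , drop = FALSE]
    } else {
      trace[[length(trace) + 1]] <- c("sample", cols[1])
      bad <- bad[, setdiff(colnames(bad), cols[1]), drop = FALSE]
    }
  }
  list(kept_probes = rownames(bad), kept_samples = colnames(bad),
       removals = trace)
}

# small labelled random beta matrix
random_beta_matrix <- function(n_probes, n_samples) {
  matrix(runif(n_probes * n_samples), n_probes, n_samples,
         dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# tiny annotation for toy genomes: probes every 500 bp on one chromosome
toy_annotation <- function(n_probes, chrom = "chr1", spacing = 500L) {
  data.frame(probe_id = sprintf("p%03d", seq_len(n_probes)),
             chrom = chrom, pos = spacing * seq_len(n_probes),
             strand = "+", gene = NA_character_, island = NA_character_,
             dmr = NA_character_, snp_overlap = FALSE,
             sex_chromosome = FALSE, rare_variant_overlap = FALSE,
             stringsAsFactors = FALSE)
}
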