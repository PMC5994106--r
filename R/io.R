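#' Write / read a beta-value (or detection-p) matrix as TSV
#'
#' Probe ids form the first column (`probe_id`), sample ids the header.
#' Values are written with 12 significant digits so a write/read round trip
#' reproduces them.
#'
#' @param x numeric matrix with rownames (probes) and colnames (samples).
#' @param path file path.
#' @export
write_beta_tsv <- function(x, path) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("matrix must carry probe rownames and sample colnames",
         call. = FALSE)
  header <- paste(c("probe_id", colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], formatC(x[i, ], format = "g", digits = 12)),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_beta_tsv
#' @param range permissible closed value range; entries outside it raise a
#'   parse error naming the offending line.  Use `c(0, 1)` for betas and
#'   detection p-values, or `NULL` to skip the check.
#' @return `read_beta_tsv`: the numeric matrix.
#' @export
read_beta_tsv <- function(path, range = c(0, 1)) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expect <- length(fields[[1L]])
  samples <- fields[[1L]][-1L]
  n <- length(lines) - 1L
  out <- matrix(NA_real_, nrow = n, ncol = ncol_expect - 1L,
                dimnames = list(NULL, samples))
  probe_ids <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i + 1L]]
    if (length(f) != ncol_expect)
      stop(sprintf("%s: line %d has %d fields, expected %d", path, i + 1L,
                   length(f), ncol_expect), call. = FALSE)
    probe_ids[i] <- f[1L]
    v <- suppressWarnings(as.numeric(f[-1L]))
    bad <- is.na(v) & !(f[-1L] %in% c("NA", "nan", ""))
    if (any(bad))
      stop(sprintf("%s: line %d: non-numeric value '%s'", path, i + 1L,
                   f[-1L][bad][1L]), call. = FALSE)
    if (!is.null(range)) {
      oob <- !is.na(v) & (v < range[1L] | v > range[2L])
      if (any(oob))
        stop(sprintf("%s: line %d: value %s outside [%g, %g]", path, i + 1L,
                     formatC(v[oob][1L]), range[1L], range[2L]),
             call. = FALSE)
    }
    out[i, ] <- v
  }
  rownames(out) <- probe_ids
  out
}

#' Write / read genomic regions as 6-column BED
#'
#' BED coordinates are 0-based, half-open.  The name field carries the
#' region id; the score field carries 0; strand is `.` when absent.
#'
#' @param regions data.frame with columns `region_id`, `chrom`, `start`,
#'   `end` and optionally `strand`, `kind`.
#' @param path file path.
#' @export
write_bed <- function(regions, path) {
  strand <- if ("strand" %in% names(regions)) regions$strand else "."
  strand[is.na(strand)] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", regions$chrom,
                   as.integer(regions$start), as.integer(regions$end),
                   regions$region_id, strand)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bed
#' @param kind region kind recorded on every row read (e.g. `"gene"`,
#'   `"imprinted_dmr"`).
#' @return `read_bed`: region data.frame (`region_id`, `chrom`, `start`,
#'   `end`, `strand`, `kind`).
#' @export
read_bed <- function(path, kind = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[ \t]+")
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop(sprintf("%s: line %d: BED needs at least 3 fields", path, i),
           call. = FALSE)
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end) || start >= end)
      stop(sprintf("%s: line %d: invalid interval [%s, %s)", path, i,
                   f[2L], f[3L]), call. = FALSE)
    data.frame(region_id = if (length(f) >= 4L) f[4L] else sprintf("region_%d", i),
               chrom = f[1L], start = start, end = end,
               strand = if (length(f) >= 6L) f[6L] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$kind <- kind
  out
}

#' Read a mixed phenotype table from TSV
#'
#' First column is the sample id (becomes rownames); character columns are
#' converted to factors, everything else stays numeric.
#'
#' @param path file path.
#' @return data.frame with sample-id rownames.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  rownames(df) <- df[[1L]]
  df <- df[, -1L, drop = FALSE]
  for (j in seq_along(df))
    if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  df
}

#' Write a phenotype table as TSV
#' @param pheno data.frame with sample-id rownames.
#' @param path file path.
#' @export
write_phenotypes <- function(pheno, path) {
  out <- cbind(sample_id = rownames(pheno), pheno)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
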