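#' Remove flagged probes from a beta matrix
#'
#' Drops probes flagged as SNP-overlapping, on a sex chromosome, or
#' overlapping rare genetic variants.  A probe flagged on several criteria is
#' removed once and attributed to the first criterion in the fixed order
#' SNP, sex chromosome, rare variant.
#'
#' @param matrix probes x samples beta matrix (rownames = probe ids).
#' @param annotation per-probe annotation data.frame (a `sev_annotation` is
#'   also accepted) with logical columns `snp_overlap`, `sex_chromosome`,
#'   `rare_variant_overlap`.
#' @return list with `matrix` (filtered copy; input untouched) and `report`
#'   (removal counts per criterion, total, and surviving probe ids).
#' @export
filter_probes <- function(matrix, annotation) {
  ann <- as_probe_table(annotation)
  idx <- match(rownames(matrix), ann$probe_id)
  if (anyNA(idx))
    stop("probe(s) missing from annotation: ",
         paste(utils::head(rownames(matrix)[is.na(idx)], 5L),
               collapse = ", "), call. = FALSE)
  snp <- ann$snp_overlap[idx]
  sexc <- !snp & ann$sex_chromosome[idx]
  rare <- !snp & !ann$sex_chromosome[idx] & ann$rare_variant_overlap[idx]
  drop <- snp | sexc | rare
  report <- list(n_snp_overlap = sum(snp), n_sex_chromosome = sum(sexc),
                 n_rare_variant = sum(rare), n_removed = sum(drop),
                 kept_probes = rownames(matrix)[!drop])
  list(matrix = matrix[!drop, , drop = FALSE], report = report)
}

as_probe_table <- function(annotation) {
  if (inherits(annotation, "sev_annotation")) annotation$probes
  else annotation
}

#' Greedy removal of unreliable probes and samples
#'
#' An entry is unreliable iff its detection p-value is not below the
#' threshold (`p >= threshold`).  Iteratively removes the single row (probe)
#' or column (sample) with the highest fraction of unreliable entries — ties
#' resolved probe before sample, then lexicographically by id — until every
#' row and column has an unreliable fraction at most `max_unreliable`.
#'
#' @param detp detection-p matrix (probes x samples, dimnames required).
#' @param threshold reliability threshold (default 0.05).
#' @param max_unreliable largest tolerated unreliable fraction per row or
#'   column after removal; default 0 removes until fully reliable.
#' @return list with `kept_probes`, `kept_samples`, and `trace` (data.frame
#'   of each removal: `step`, `what`, `id`, `fraction`).
#' @export
greedycut <- function(detp, threshold = 0.05, max_unreliable = 0) {
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie in (0,1)", call. = FALSE)
  if (max_unreliable < 0 || max_unreliable >= 1)
    stop("'max_unreliable' must lie in [0,1)", call. = FALSE)
  if (is.null(rownames(detp)) || is.null(colnames(detp)))
    stop("'detp' must carry probe rownames and sample colnames",
         call. = FALSE)
  bad <- detp >= threshold
  trace <- list()
  repeat {
    if (nrow(bad) == 0L || ncol(bad) == 0L)
      stop("greedycut: all data removed", call. = FALSE)
    rf <- rowMeans(bad); cf <- colMeans(bad)
    worst <- max(max(rf), max(cf))
    if (worst <= max_unreliable) break
    cand_r <- names(rf)[rf == worst]
    cand_c <- names(cf)[cf == worst]
    if (length(cand_r) > 0L) {
      id <- sort(cand_r)[1L]
      trace[[length(trace) + 1L]] <- data.frame(
        step = length(trace) + 1L, what = "probe", id = id,
        fraction = worst, stringsAsFactors = FALSE)
      bad <- bad[setdiff(rownames(bad), id), , drop = FALSE]
    } else {
      id <- sort(cand_c)[1L]
      trace[[length(trace) + 1L]] <- data.frame(
        step = length(trace) + 1L, what = "sample", id = id,
        fraction = worst, stringsAsFactors = FALSE)
      bad <- bad[, setdiff(colnames(bad), id), drop = FALSE]
    }
  }
  list(kept_probes = rownames(bad), kept_samples = colnames(bad),
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(step = integer(), what = character(),
                               id = character(), fraction = numeric()))
}

#' Derive promoter and tiling region sets and a probe-to-region index
#'
#' Promoters span 1500 bases upstream and 500 bases downstream of each
#' gene's transcription start site, oriented by strand; tiling regions are
#' non-overlapping fixed-width windows laid over each chromosome from
#' coordinate 0.  All regions are 0-based half-open; probe positions
#' (1-based) are converted explicitly for the containment test.
#'
#' @param annotation per-probe annotation (or `sev_annotation`).
#' @param genes gene region data.frame (`region_id`, `chrom`, `start`,
#'   `end`, `strand`); every gene must carry a strand.
#' @param tiling_width tiling window width in bp (default 5000).
#' @return list with region data.frames `promoters`, `tiling`, and `index`
#'   (data.frame `region_id`, `kind`, `probe_id` of all containments).
#' @export
build_regions <- function(annotation, genes, tiling_width = 5000L) {
  probes <- as_probe_table(annotation)
  if (any(is.na(genes$strand)) || any(!genes$strand %in% c("+", "-")))
    stop("every gene needs a strand ('+' or '-') to orient its promoter",
         call. = FALSE)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  prom_start <- ifelse(genes$strand == "+", tss - 1500L, tss - 500L)
  prom_end <- ifelse(genes$strand == "+", tss + 500L, tss + 1500L)
  promoters <- data.frame(region_id = paste0(genes$region_id, "_prom"),
                          chrom = genes$chrom,
                          start = pmax(prom_start, 0L), end = prom_end,
                          strand = genes$strand, kind = "promoter",
                          stringsAsFactors = FALSE)

  tiling <- do.call(rbind, lapply(split(probes, probes$chrom), function(p) {
    extent <- max(p$pos)
    starts <- seq(0L, extent - 1L, by = tiling_width)
    data.frame(region_id = sprintf("%s_tile_%05d", p$chrom[1L],
                                   seq_along(starts)),
               chrom = p$chrom[1L], start = starts,
               end = pmin(starts + tiling_width, extent),
               strand = NA_character_, kind = "tiling",
               stringsAsFactors = FALSE)
  }))
  rownames(tiling) <- NULL

  index <- rbind(probe_region_index(probes, promoters),
                 probe_region_index(probes, tiling))
  list(promoters = promoters, tiling = tiling, index = index)
}

#' Map probes into regions by position containment
#'
#' @param probes probe annotation data.frame (`probe_id`, `chrom`, `pos`).
#' @param regions region data.frame (`region_id`, `chrom`, `start`, `end`
#'   0-based half-open, `kind`).
#' @return data.frame `region_id`, `kind`, `probe_id`.
#' @export
probe_region_index <- function(probes, regions) {
  probes <- as_probe_table(probes)
  p0 <- probes$pos - 1L   # 1-based position -> 0-based coordinate
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    hit <- probes$chrom == regions$chrom[i] &
      p0 >= regions$start[i] & p0 < regions$end[i]
    if (!any(hit)) return(NULL)
    data.frame(region_id = regions$region_id[i],
               kind = regions$kind[i] %||% NA_character_,
               probe_id = probes$probe_id[hit], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region_id = character(), kind = character(),
                      probe_id = character())
  rownames(out) <- NULL
  out
}
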