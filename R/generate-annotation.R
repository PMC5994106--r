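#' Generate a synthetic probe annotation
#'
#' Lays out `n_probes` CpG probes over `n_chromosomes` chromosomes with
#' 1-based, strictly increasing positions (minimum spacing 100 bp, the
#' manifest convention), carves out non-overlapping gene bodies (>= 5
#' consecutive probes each) and imprinted DMRs (>= 8 consecutive probes, so a
#' clustered imprinting defect is enrichable), assigns a fraction of probes to
#' CpG islands, and flags configurable fractions of probes as SNP-overlapping,
#' sex-chromosomal or rare-variant-overlapping.
#'
#' @param config a [sim_config()].
#' @return an object of class `sev_annotation`: a list with
#'   \describe{
#'     \item{probes}{data.frame with columns `probe_id`, `chrom`, `pos`
#'       (1-based), `strand`, `gene`, `island`, `dmr` (NA when outside),
#'       `snp_overlap`, `sex_chromosome`, `rare_variant_overlap`.}
#'     \item{genes}{region data.frame (`region_id`, `chrom`, `start`, `end`
#'       0-based half-open, `strand`, `kind = "gene"`).}
#'     \item{dmrs}{region data.frame, `kind = "imprinted_dmr"`.}
#'   }
#' @export
generate_annotation <- function(config) {
  validate_sim_config(config)
  min_gene <- 5L; min_dmr <- 8L
  need <- config$n_genes * min_gene + config$n_imprinted_dmrs * min_dmr
  if (need > config$n_probes)
    stop(sprintf(paste0("annotation sizing: n_probes = %d cannot host %d genes",
                        " (>= %d probes each) plus %d imprinted DMRs (>= %d",
                        " probes each); need at least %d probes"),
                 config$n_probes, config$n_genes, min_gene,
                 config$n_imprinted_dmrs, min_dmr, need), call. = FALSE)

  set.seed(component_seed(config$seed, "annotation"))
  n <- config$n_probes
  # probes per chromosome (as even as possible)
  per_chr <- rep(n %/% config$n_chromosomes, config$n_chromosomes)
  if (n %% config$n_chromosomes > 0)
    per_chr[seq_len(n %% config$n_chromosomes)] <-
      per_chr[seq_len(n %% config$n_chromosomes)] + 1L
  chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)), per_chr)
  pos <- unlist(lapply(per_chr, function(m)
    cumsum(sample(100:1000, m, replace = TRUE))), use.names = FALSE)

  probes <- data.frame(
    probe_id = sprintf("cg%07d", seq_len(n)),
    chrom = chrom, pos = pos,
    strand = sample(c("+", "-"), n, replace = TRUE),
    gene = NA_character_, island = NA_character_, dmr = NA_character_,
    stringsAsFactors = FALSE)

  # distribute gene / DMR blocks over chromosomes proportionally to size
  gene_sizes <- sample(min_gene:12L, config$n_genes, replace = TRUE)
  dmr_sizes <- sample(min_dmr:12L, config$n_imprinted_dmrs, replace = TRUE)
  blocks <- data.frame(
    id = c(sprintf("gene_%03d", seq_along(gene_sizes)),
           sprintf("dmr_%02d", seq_along(dmr_sizes))),
    kind = rep(c("gene", "imprinted_dmr"),
               c(length(gene_sizes), length(dmr_sizes))),
    size = c(gene_sizes, dmr_sizes), stringsAsFactors = FALSE)
  blocks <- blocks[sample.int(nrow(blocks)), , drop = FALSE]
  blocks$chr_idx <- assign_blocks_to_chromosomes(blocks$size, per_chr)
  if (anyNA(blocks$chr_idx)) {
    # fall back to minimum block sizes if random sizes overflow chromosomes
    blocks$size <- ifelse(blocks$kind == "gene", min_gene, min_dmr)
    blocks$chr_idx <- assign_blocks_to_chromosomes(blocks$size, per_chr)
    if (anyNA(blocks$chr_idx))
      stop("annotation sizing: chromosomes too small for requested regions",
           call. = FALSE)
  }

  chr_offset <- c(0L, cumsum(per_chr))
  for (ci in seq_len(config$n_chromosomes)) {
    b <- blocks[blocks$chr_idx == ci, , drop = FALSE]
    if (nrow(b) == 0L) next
    starts <- place_blocks(b$size, per_chr[ci])
    for (j in seq_len(nrow(b))) {
      idx <- chr_offset[ci] + seq(starts[j], length.out = b$size[j])
      if (b$kind[j] == "gene") probes$gene[idx] <- b$id[j]
      else probes$dmr[idx] <- b$id[j]
    }
  }

  # CpG islands: short blocks covering ~15% of probes
  n_isl <- max(1L, floor(0.15 * n / 4))
  isl_start <- sort(sample.int(n, n_isl))
  for (k in seq_len(n_isl)) {
    len <- sample(3:6, 1L)
    idx <- isl_start[k]:min(n, isl_start[k] + len - 1L)
    idx <- idx[chrom[idx] == chrom[isl_start[k]]]
    probes$island[idx] <- sprintf("island_%04d", k)
  }

  probes$snp_overlap <- flag_fraction(n, config$snp_fraction)
  probes$sex_chromosome <- flag_fraction(n, config$sex_fraction)
  probes$rare_variant_overlap <- flag_fraction(n, config$rare_fraction)

  genes <- region_table(probes, "gene", blocks[blocks$kind == "gene", "id"])
  dmrs <- region_table(probes, "dmr",
                       blocks[blocks$kind == "imprinted_dmr", "id"])
  genes$kind <- "gene"; dmrs$kind <- "imprinted_dmr"

  out <- list(probes = probes, genes = genes, dmrs = dmrs)
  class(out) <- "sev_annotation"
  out
}

# random flag vector with an exact count, deterministic under the caller's seed
flag_fraction <- function(n, fraction) {
  flags <- logical(n)
  k <- round(fraction * n)
  if (k > 0) flags[sample.int(n, k)] <- TRUE
  flags
}

# greedy proportional assignment of blocks to chromosomes; NA if impossible
assign_blocks_to_chromosomes <- function(sizes, capacity) {
  free <- capacity
  out <- rep(NA_integer_, length(sizes))
  for (i in order(sizes, decreasing = TRUE)) {
    ci <- which.max(free)
    if (free[ci] < sizes[i]) return(rep(NA_integer_, length(sizes)))
    out[i] <- ci
    free[ci] <- free[ci] - sizes[i]
  }
  out
}

# non-overlapping 1-based start offsets for blocks within m probe slots,
# random gaps distributed before/between blocks
place_blocks <- function(sizes, m) {
  slack <- m - sum(sizes)
  nb <- length(sizes)
  gaps <- if (slack > 0) as.vector(stats::rmultinom(1, slack, rep(1, nb + 1L)))
          else rep(0L, nb + 1L)
  starts <- integer(nb)
  cursor <- 1L
  for (j in seq_len(nb)) {
    cursor <- cursor + gaps[j]
    starts[j] <- cursor
    cursor <- cursor + sizes[j]
  }
  starts
}

# region table (0-based half-open) from the probe spans of each block
region_table <- function(probes, column, ids) {
  rows <- lapply(ids, function(id) {
    p <- probes[!is.na(probes[[column]]) & probes[[column]] == id, ,
                drop = FALSE]
    data.frame(region_id = id, chrom = p$chrom[1L],
               start = min(p$pos) - 1L, end = max(p$pos),
               strand = p$strand[1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$region_id), , drop = FALSE]
}

#' @export
print.sev_annotation <- function(x, ...) {
  cat(sprintf("sev_annotation: %d probes, %d genes, %d imprinted DMRs, %d chromosome(s)\n",
              nrow(x$probes), nrow(x$genes), nrow(x$dmrs),
              length(unique(x$probes$chrom))))
  invisible(x)
}
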