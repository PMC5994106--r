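test_that("beta TSV round trip reproduces ids and values", {
  set.seed(1)
  m <- random_beta_matrix(7, 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_beta_tsv(m, f)
  m2 <- read_beta_tsv(f)
  expect_identical(rownames(m2), rownames(m))
  expect_identical(colnames(m2), colnames(m))
  expect_equal(m2, m, tolerance = 1e-12)
})

test_that("beta TSV parse errors carry the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "p1\t0.5\t0.6", "p2\t1.2\t0.1"), f)
  expect_error(read_beta_tsv(f), "line 3.*outside")
  writeLines(c("probe_id\ts1\ts2", "p1\t0.5\t0.6", "p2\tabc\t0.1"), f)
  expect_error(read_beta_tsv(f), "line 3.*non-numeric")
  writeLines(c("probe_id\ts1\ts2", "p1\t0.5"), f)
  expect_error(read_beta_tsv(f), "line 2.*fields")
})

test_that("BED I/O preserves 0-based half-open coordinates", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tdmr1", f)
  r <- read_bed(f, kind = "imprinted_dmr")
  expect_equal(r$start, 100L)
  expect_equal(r$end, 200L)
  expect_equal(r$region_id, "dmr1")
  # round trip
  regions <- data.frame(region_id = c("a", "b"), chrom = "chr2",
                        start = c(0L, 5000L), end = c(5000L, 7000L),
                        strand = c("+", "-"))
  write_bed(regions, f)
  r2 <- read_bed(f)
  expect_equal(r2$start, regions$start)
  expect_equal(r2$end, regions$end)
  expect_equal(r2$strand, regions$strand)
})

test_that("phenotype TSV round trip preserves types", {
  ph <- data.frame(x = c(1.5, 2.5), g = factor(c("a", "b")),
                   row.names = c("s1", "s2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(ph, f)
  ph2 <- read_phenotypes(f)
  expect_equal(rownames(ph2), c("s1", "s2"))
  expect_true(is.numeric(ph2$x) && is.factor(ph2$g))
})

test_that("filter_probes removes flagged probes with fixed attribution", {
  m <- random_beta_matrix(20, 4)
  ann <- toy_annotation(20)
  # identity when nothing is flagged
  out <- filter_probes(m, ann)
  expect_identical(out$matrix, m)
  expect_equal(out$report$n_removed, 0)

  ann$snp_overlap[1:10] <- TRUE
  out <- filter_probes(m, ann)
  expect_equal(out$report$n_snp_overlap, 10)
  expect_equal(nrow(out$matrix), 10)
  expect_identical(rownames(out$matrix), ann$probe_id[11:20])

  # doubly flagged probe attributed to the first criterion (SNP, sex, rare)
  ann2 <- toy_annotation(6)
  ann2$snp_overlap[2] <- TRUE
  ann2$sex_chromosome[c(2, 3)] <- TRUE
  ann2$rare_variant_overlap[c(3, 4)] <- TRUE
  out2 <- filter_probes(random_beta_matrix(6, 3), ann2)
  expect_equal(out2$report$n_snp_overlap, 1)
  expect_equal(out2$report$n_sex_chromosome, 1)
  expect_equal(out2$report$n_rare_variant, 1)
  expect_equal(out2$report$n_removed,
               length(unique(c(2, 3, 4))))
  # idempotence
  again <- filter_probes(out2$matrix, ann2)
  expect_identical(again$matrix, out2$matrix)
  expect_equal(again$report$n_removed, 0)
})

test_that("filter_probes errors on unannotated probes", {
  m <- random_beta_matrix(3, 2)
  rownames(m)[2] <- "mystery"
  expect_error(filter_probes(m, toy_annotation(3)), "mystery")
})

test_that("greedycut leaves clean data alone and removes a single offender", {
  d <- matrix(0.001, 8, 5,
              dimnames = list(sprintf("p%d", 1:8), sprintf("s%d", 1:5)))
  out <- greedycut(d, max_unreliable = 0.1)
  expect_equal(nrow(out$trace), 0)
  expect_length(out$kept_probes, 8)

  d[1:5, "s3"] <- 0.5   # 62.5% unreliable entries in one sample
  out <- greedycut(d, max_unreliable = 0.3)
  expect_equal(out$trace$what, "sample")
  expect_equal(out$trace$id, "s3")
  expect_setequal(out$kept_samples, c("s1", "s2", "s4", "s5"))
})

test_that("threshold is closed: p exactly 0.05 is unreliable", {
  d <- matrix(0.001, 4, 12,
              dimnames = list(sprintf("p%d", 1:4), sprintf("s%02d", 1:12)))
  d["p2", ] <- 0.05
  out <- greedycut(d, max_unreliable = 0)
  expect_equal(out$trace$id, "p2")
})

test_that("greedycut matches the exhaustive greedy oracle on mixed toys", {
  for (s in 1:5) {
    set.seed(s)
    d <- matrix(sample(c(0.001, 0.5), 36, replace = TRUE,
                       prob = c(0.7, 0.3)), 6, 6,
                dimnames = list(sprintf("p%d", 1:6), sprintf("s%d", 1:6)))
    out <- greedycut(d, max_unreliable = 0.2)
    orc <- oracle_greedy(d >= 0.05, max_unreliable = 0.2)
    expect_identical(out$kept_probes, orc$kept_probes)
    expect_identical(out$kept_samples, orc$kept_samples)
    expect_equal(nrow(out$trace), length(orc$removals))
    if (nrow(out$trace) > 0) {
      expect_identical(out$trace$what,
                       vapply(orc$removals, `[`, character(1), 1))
      expect_identical(out$trace$id,
                       vapply(orc$removals, `[`, character(1), 2))
    }
  }
})

test_that("promoters orient by strand and tiling partitions coordinates", {
  ann <- toy_annotation(24)
  genes <- data.frame(region_id = c("gplus", "gminus"), chrom = "chr1",
                      start = c(10000L, 8000L), end = c(11000L, 10000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  reg <- build_regions(ann, genes, tiling_width = 5000L)
  plus <- reg$promoters[reg$promoters$region_id == "gplus_prom", ]
  expect_equal(c(plus$start, plus$end), c(8500L, 10500L))
  minus <- reg$promoters[reg$promoters$region_id == "gminus_prom", ]
  expect_equal(c(minus$start, minus$end), c(9500L, 11500L))

  # 24 probes at 500 bp spacing: extent 12000 -> [0,5000),[5000,10000),[10000,12000)
  expect_equal(reg$tiling$start, c(0L, 5000L, 10000L))
  expect_equal(reg$tiling$end, c(5000L, 10000L, 12000L))
  # every probe maps into exactly one tiling window
  tile_idx <- reg$index[reg$index$kind == "tiling", ]
  expect_equal(sort(tile_idx$probe_id), sort(ann$probe_id))
  expect_false(anyDuplicated(tile_idx$probe_id) > 0)
})

test_that("genes without strand are rejected", {
  genes <- data.frame(region_id = "g", chrom = "chr1", start = 1000L,
                      end = 2000L, strand = NA_character_)
  expect_error(build_regions(toy_annotation(5), genes), "strand")
})
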