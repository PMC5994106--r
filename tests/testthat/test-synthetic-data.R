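small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 11L, n_probes = 600L, n_chromosomes = 2L, n_genes = 12L,
         n_imprinted_dmrs = 2L, n_reference = 15L, n_cases = 6L,
         sev_rate = 5, batch_count = 2L),
    list(...))
  do.call(sim_config, args)
}

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_probes = 0), "n_probes")
  expect_error(sim_config(sev_rate = -1), "sev_rate")
  expect_error(sim_config(unreliable_fraction = 1.5), "unreliable_fraction")
  expect_error(sim_config(phenotype_effect = c(bogus = 1)), "factor1")
})

test_that("annotation is deterministic, well-formed, and sized correctly", {
  cfg <- small_cfg()
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)

  p <- a1$probes
  expect_equal(nrow(p), cfg$n_probes)
  expect_false(anyDuplicated(p$probe_id) > 0)
  for (ch in unique(p$chrom)) {
    pos <- p$pos[p$chrom == ch]
    expect_true(all(diff(pos) >= 100))
    expect_true(all(pos >= 1))
  }
  gene_sizes <- table(p$gene)
  expect_equal(length(gene_sizes), cfg$n_genes)
  expect_true(all(gene_sizes >= 5))
  dmr_sizes <- table(p$dmr)
  expect_equal(length(dmr_sizes), cfg$n_imprinted_dmrs)
  expect_true(all(dmr_sizes >= 8))
  # DMR probes are contiguous within the probe order of their chromosome
  for (d in names(dmr_sizes)) {
    idx <- which(!is.na(p$dmr) & p$dmr == d)
    expect_equal(idx, seq(min(idx), max(idx)))
  }
})

test_that("flag fractions are honoured, including the zero case", {
  a0 <- generate_annotation(small_cfg(snp_fraction = 0, sex_fraction = 0,
                                      rare_fraction = 0))
  expect_false(any(a0$probes$snp_overlap | a0$probes$sex_chromosome |
                     a0$probes$rare_variant_overlap))
  a <- generate_annotation(small_cfg(snp_fraction = 0.1))
  expect_equal(sum(a$probes$snp_overlap), round(0.1 * 600))
})

test_that("infeasible gene demand raises a sizing error", {
  expect_error(generate_annotation(small_cfg(n_probes = 50L, n_genes = 20L,
                                             n_imprinted_dmrs = 1L)),
               "cannot host")
})

test_that("cohort respects ranges, determinism, and the null-signal case", {
  cfg <- small_cfg(sev_rate = 0, batch_shift_sd = 0)
  ann <- generate_annotation(cfg)
  c1 <- generate_cohort(cfg, ann)
  c2 <- generate_cohort(cfg, ann)
  expect_identical(c1$beta, c2$beta)
  expect_identical(c1$detp, c2$detp)
  expect_true(all(c1$beta >= 0 & c1$beta <= 1))
  expect_true(all(c1$detp >= 0 & c1$detp <= 1))
  expect_true(all(vapply(c1$truth$injected_sevs, nrow, 1L) == 0L))
  expect_identical(c1$beta, c1$beta_clean)
})

test_that("changing sev_rate leaves baseline betas untouched", {
  cfg_a <- small_cfg(sev_rate = 0)
  cfg_b <- small_cfg(sev_rate = 10)
  ann <- generate_annotation(cfg_a)
  expect_identical(generate_cohort(cfg_a, ann)$beta_clean,
                   generate_cohort(cfg_b, ann)$beta_clean)
})

test_that("defect subject receives every probe of the defect DMR", {
  cfg <- small_cfg(defect_subject = "case_01")
  ann <- generate_annotation(cfg)
  coh <- generate_cohort(cfg, ann)
  dmr1 <- ann$dmrs$region_id[1]
  expect_setequal(coh$truth$defect_probes,
                  ann$probes$probe_id[!is.na(ann$probes$dmr) &
                                        ann$probes$dmr == dmr1])
  expect_gt(length(coh$truth$defect_probes), 7)
})

test_that("injected SEV count matches the Poisson mean over subjects", {
  counts <- unlist(lapply(1:4, function(s) {
    cfg <- small_cfg(seed = 100L + s, n_probes = 2000L, n_reference = 10L,
                     n_cases = 10L, n_genes = 10L, sev_rate = 20)
    ann <- generate_annotation(cfg)
    vapply(generate_cohort(cfg, ann)$truth$injected_sevs, nrow, 1L)
  }))
  se <- sqrt(20 / length(counts))
  expect_lt(abs(mean(counts) - 20), 3 * se)
})

test_that("injected SEVs lie strictly outside the clean-reference fences", {
  for (s in c(3L, 4L)) {
    cfg <- small_cfg(seed = s, sev_rate = 10)
    ann <- generate_annotation(cfg)
    coh <- generate_cohort(cfg, ann)
    ids <- sim_sample_ids(cfg)
    fen <- compute_fences(coh$beta_clean[, ids$reference],
                          min_n = cfg$n_reference)
    for (sid in ids$all) {
      inj <- coh$truth$injected_sevs[[sid]]
      if (nrow(inj) == 0) next
      i <- match(inj$probe_id, fen$probe_id)
      v <- coh$beta[inj$probe_id, sid]
      outside <- ifelse(inj$direction == "low", v < fen$lower[i],
                        v > fen$upper[i])
      expect_true(all(outside))
    }
  }
})

test_that("phenotypes: ranges, determinism, and factor-driven structure", {
  cfg <- small_cfg(n_reference = 41L, n_cases = 23L)
  ann <- generate_annotation(cfg)
  coh <- generate_cohort(cfg, ann)
  p1 <- generate_phenotypes(cfg, coh$truth)
  p2 <- generate_phenotypes(cfg, coh$truth)
  expect_identical(p1, p2)
  props <- as.matrix(p1[, grep("^prop_", names(p1))])
  expect_true(all(props >= 0))
  expect_true(all(rowSums(props) <= 1))
  expect_equal(levels(p1$case_control), c("control", "case"))
  expect_equal(sum(p1$case_control == "case"), 23)
  # traits actually track their dominant factor
  f <- coh$truth$latent_factors
  expect_gt(cor(p1$gestational_age, f[, 1]), 0.5)
  expect_gt(cor(p1$gestational_weight_gain, f[, 2]), 0.5)
})

test_that("zero loadings give a null trait correlation structure", {
  cfg <- small_cfg(n_reference = 41L, n_cases = 23L)
  ann <- generate_annotation(cfg)
  coh <- generate_cohort(cfg, ann)
  ph <- generate_phenotypes(cfg, coh$truth, loading_scale = 0)
  cont <- c("birth_weight", "birthweight_centile", "gestational_age",
            "mother_age", "mother_bmi", "father_bmi",
            "pregestational_weight", "gestational_weight_gain")
  cm <- cor(as.matrix(ph[, cont]))
  off <- abs(cm[upper.tri(cm)])
  expect_lt(mean(off), 0.15)
})

test_that("noise-free season is deterministic in its latent factor", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg)
  coh <- generate_cohort(cfg, ann)
  ph <- generate_phenotypes(cfg, coh$truth, trait_noise_scale = 0)
  z <- coh$truth$latent_factors[, 3]
  expected <- cut(z, breaks = c(-Inf, -0.6745, 0, 0.6745, Inf),
                  labels = c("winter", "spring", "summer", "autumn"))
  expect_identical(as.character(ph$season), as.character(expected))
})
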