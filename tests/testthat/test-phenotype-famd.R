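toy_mixed_table <- function() {
  data.frame(x = c(1.0, 2.0, 4.0, 3.0, 5.0, 2.5),
             y = c(0.2, 0.5, 0.1, 0.9, 0.4, 0.3),
             g = factor(c("a", "b", "c", "a", "b", "c")),
             row.names = sprintf("s%d", 1:6))
}

test_that("all-continuous FAMD equals standardized PCA up to sign", {
  set.seed(1)
  tab <- as.data.frame(matrix(rnorm(40 * 5), 40, 5))
  rownames(tab) <- sprintf("s%02d", 1:40)
  m <- famd_fit(tab, n_dims = 5)

  # independent eigen-decomposition oracle on the population-standardized data
  Z <- scale(as.matrix(tab))
  Z <- sweep(Z, 2, apply(Z, 2, function(v) sqrt(mean(v^2))), "/")
  eg <- eigen(crossprod(Z) / nrow(Z), symmetric = TRUE)
  expect_equal(m$eigenvalues[1:5], eg$values[1:5], tolerance = 1e-10)
  pca_scores <- Z %*% eg$vectors
  for (j in 1:5) {
    r <- cor(m$dimension_scores[, j], pca_scores[, j])
    expect_equal(abs(r), 1, tolerance = 1e-8)
    expect_equal(abs(m$dimension_scores[, j]), abs(pca_scores[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("one binary categorical alone has exactly one nonzero eigenvalue", {
  tab <- data.frame(g = factor(rep(c("a", "b"), c(7, 5))))
  m <- famd_fit(tab, n_dims = 1)
  expect_equal(sum(m$eigenvalues > 1e-10), 1L)
  expect_equal(m$total_inertia, 1)
})

test_that("mixed toy table: inertia and eigen oracle", {
  tab <- toy_mixed_table()
  m <- famd_fit(tab, n_dims = 4)
  expect_equal(m$total_inertia, 2 + 2)   # 2 continuous + (3 levels - 1)
  expect_equal(sum(m$eigenvalues), 4, tolerance = 1e-10)

  # independent oracle: explicit weighted indicator coding + eigen
  n <- 6
  std <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  ind <- sapply(levels(tab$g), function(l) as.numeric(tab$g == l))
  pk <- colMeans(ind)
  W <- sweep(ind, 2, sqrt(pk), "/")
  W <- sweep(W, 2, colMeans(W), "-")
  Z <- cbind(std(tab$x), std(tab$y), W)
  eg <- eigen(crossprod(Z) / n, symmetric = TRUE)
  expect_equal(m$eigenvalues[1:4], eg$values[1:4], tolerance = 1e-10)
})

test_that("eigenvalues non-increasing, scores centered, reconstruction exact", {
  tab <- toy_mixed_table()
  m <- famd_fit(tab, n_dims = 5)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_equal(colMeans(m$dimension_scores), rep(0, ncol(m$dimension_scores)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # with all dimensions retained the SVD reconstructs the weighted matrix
  Z <- sevscan:::famd_preprocess(tab)$Z
  recon <- m$dimension_scores %*% t(m$variable_loadings)
  expect_equal(recon, Z, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("scale invariance and level-label invariance", {
  tab <- toy_mixed_table()
  m1 <- famd_fit(tab, n_dims = 3)
  tab2 <- tab; tab2$x <- tab2$x * 1000
  m2 <- famd_fit(tab2, n_dims = 3)
  expect_equal(m1$dimension_scores, m2$dimension_scores, tolerance = 1e-10)
  tab3 <- tab; levels(tab3$g) <- c("zebra", "yak", "xerus")
  m3 <- famd_fit(tab3, n_dims = 3)
  expect_equal(m1$eigenvalues, m3$eigenvalues, tolerance = 1e-12)
})

test_that("degenerate columns are rejected by name", {
  tab <- toy_mixed_table()
  tab$flat <- 1
  expect_error(famd_fit(tab, n_dims = 2), "flat")
  tab$flat <- NULL
  tab$solo <- factor(rep("only", 6))
  expect_error(famd_fit(tab, n_dims = 2), "solo")
})

test_that("dimension-trait correlations: identity, oracle, and null", {
  set.seed(2)
  tab <- as.data.frame(matrix(rnorm(64 * 4), 64, 4))
  rownames(tab) <- sprintf("s%02d", 1:64)
  m <- famd_fit(tab, n_dims = 3)
  # a trait that IS a dimension plus tiny noise correlates near 1
  tab$echo <- m$dimension_scores[, 1] + rnorm(64, sd = 0.01)
  ct <- dim_trait_correlations(m, tab)
  r_echo <- ct$rho[ct$dimension == "Dim1" & ct$trait == "echo"]
  expect_gt(r_echo, 0.99)
  expect_true(ct$flagged[ct$dimension == "Dim1" & ct$trait == "echo"])

  # textbook Pearson on a 5-row toy
  s5 <- c(1, 2, 3, 4, 5); t5 <- c(2, 1, 4, 3, 6)
  r_hand <- sum((s5 - 3) * (t5 - mean(t5))) /
    sqrt(sum((s5 - 3)^2) * sum((t5 - mean(t5))^2))
  mdl <- list(dimension_scores = matrix(s5, 5, 1,
                                        dimnames = list(NULL, "Dim1")))
  class(mdl) <- "famd_model"
  ct5 <- dim_trait_correlations(mdl, data.frame(t = t5))
  expect_equal(ct5$rho, r_hand, tolerance = 1e-12)

  # independent random traits rarely cross the 0.5 flag threshold
  set.seed(3)
  n_cross <- 0L
  for (i in 1:100) {
    tab$noise <- rnorm(64)
    ctn <- dim_trait_correlations(m, tab["noise"])
    n_cross <- n_cross + as.integer(any(abs(ctn$rho) > 0.5))
  }
  expect_lte(n_cross, 2L)
})

test_that("correlation ratio handles multi-level traits", {
  set.seed(4)
  g <- factor(rep(c("a", "b", "c"), each = 12))
  s <- c(rnorm(12, -2, 0.2), rnorm(12, 0, 0.2), rnorm(12, 2, 0.2))
  mdl <- list(dimension_scores = matrix(s, 36, 1,
                                        dimnames = list(NULL, "Dim1")))
  class(mdl) <- "famd_model"
  ct <- dim_trait_correlations(mdl, data.frame(g = g))
  expect_equal(ct$type, "multilevel")
  expect_gt(ct$rho, 0.95)
  expect_lt(ct$p, 0.01)
})

test_that("logistic dimension screen: planted signal, null rate, separation", {
  set.seed(5)
  tab <- as.data.frame(matrix(rnorm(60 * 4), 60, 4))
  rownames(tab) <- sprintf("s%02d", 1:60)
  m <- famd_fit(tab, n_dims = 4)
  # group = thresholded Dim1 with noise -> Dim1 flagged
  g <- ifelse(m$dimension_scores[, 1] + rnorm(60, sd = 0.3) >
                median(m$dimension_scores[, 1]), "case", "control")
  scr <- dims_vs_group(m, g)
  expect_true(scr$flagged[scr$dimension == "Dim1"])

  # random labels: type-I rate near the nominal level over replicates
  set.seed(6)
  n_tests <- 0L; n_sig <- 0L
  for (i in 1:50) {
    gr <- sample(c("a", "b"), 60, replace = TRUE)
    if (length(unique(gr)) < 2) next
    scr_i <- dims_vs_group(m, gr)
    n_tests <- n_tests + nrow(scr_i)
    n_sig <- n_sig + sum(scr_i$flagged)
  }
  rate <- n_sig / n_tests
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_tests))

  # group fully determined by a dimension -> separation reported, no crash
  g_det <- ifelse(m$dimension_scores[, 2] > median(m$dimension_scores[, 2]),
                  "case", "control")
  scr_d <- dims_vs_group(m, g_det)
  expect_true(scr_d$separation[scr_d$dimension == "Dim2"])
  expect_gte(scr_d$p[scr_d$dimension == "Dim2"], 1e-12)
})

test_that("latent factor recovery through FAMD on generated phenotypes", {
  cfg <- sim_config(seed = 31L, n_probes = 600L, n_chromosomes = 2L,
                    n_genes = 10L, n_imprinted_dmrs = 1L,
                    n_reference = 41L, n_cases = 23L, sev_rate = 5)
  ann <- generate_annotation(cfg)
  coh <- generate_cohort(cfg, ann)
  ph <- generate_phenotypes(cfg, coh$truth)
  m <- famd_fit(ph[, setdiff(names(ph), "case_control")], n_dims = 10)
  r <- abs(cor(m$dimension_scores[, "Dim1"],
               coh$truth$latent_factors[, "factor1"]))
  expect_gt(r, 0.9)
})
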