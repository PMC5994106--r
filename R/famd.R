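#' Factor analysis of mixed data
#'
#' Dimension reduction for tables mixing continuous and categorical
#' variables.  Continuous columns are standardized to zero mean and unit
#' (population) variance; each categorical is expanded to indicator columns,
#' each indicator divided by the square root of its level frequency and
#' centered.  The singular value decomposition of the combined matrix yields
#' sample scores and variable loadings; with this weighting the total
#' inertia equals the number of continuous variables plus
#' \eqn{\sum (levels - 1)} over categoricals, and an all-continuous table
#' reduces to standardized PCA.
#'
#' Each dimension is oriented so that its largest-magnitude loading is
#' positive, making the sign deterministic across runs.
#'
#' @param table data.frame of phenotypes: numeric columns are continuous,
#'   factor/character columns categorical.  Constant columns and
#'   single-level categoricals are rejected; missing values are not allowed.
#' @param n_dims number of dimensions to retain (default 10).
#' @return an object of class `famd_model`: list with `dimension_scores`
#'   (samples x dims, zero column means), `variable_loadings` (weighted
#'   right singular vectors), `eigenvalues` (all, non-increasing),
#'   `variance_explained` and `cumulative_variance` (fractions over the
#'   retained dims), `total_inertia`, `column_info`, and the preprocessing
#'   parameters needed for reconstruction.
#' @export
famd_fit <- function(table, n_dims = 10L) {
  if (anyNA(table))
    stop("famd_fit: missing values are not allowed", call. = FALSE)
  n <- nrow(table)
  if (n <= n_dims)
    stop("famd_fit: need more samples than retained dimensions",
         call. = FALSE)
  prep <- famd_preprocess(table)
  Z <- prep$Z
  sv <- svd(Z)
  eig <- sv$d^2 / n
  keep <- seq_len(min(n_dims, sum(sv$d > 1e-12 * sv$d[1L])))

  # deterministic orientation: largest-|loading| positive
  V <- sv$v; U <- sv$u
  for (j in seq_along(sv$d)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- U[, keep, drop = FALSE] %*% diag(sv$d[keep], nrow = length(keep))
  dimnames(scores) <- list(rownames(table), paste0("Dim", keep))
  loadings <- V[, keep, drop = FALSE]
  dimnames(loadings) <- list(colnames(Z), paste0("Dim", keep))

  total <- prep$total_inertia
  out <- list(dimension_scores = scores, variable_loadings = loadings,
              eigenvalues = eig,
              variance_explained = eig[keep] / total,
              cumulative_variance = cumsum(eig[keep] / total),
              total_inertia = total, column_info = prep$info,
              center = prep$center, scale = prep$scale,
              singular_values = sv$d, n_samples = n)
  class(out) <- "famd_model"
  out
}

famd_preprocess <- function(table) {
  n <- nrow(table)
  blocks <- list(); info <- list()
  center <- numeric(); scl <- numeric()
  for (nm in names(table)) {
    x <- table[[nm]]
    if (is.numeric(x)) {
      s <- stats::sd(x) * sqrt((n - 1) / n)   # population sd
      if (s < 1e-12)
        stop("famd_fit: column '", nm, "' is constant", call. = FALSE)
      m <- mean(x)
      blocks[[nm]] <- matrix((x - m) / s, ncol = 1L,
                             dimnames = list(NULL, nm))
      center <- c(center, stats::setNames(m, nm))
      scl <- c(scl, stats::setNames(s, nm))
      info[[nm]] <- list(type = "continuous")
    } else {
      f <- droplevels(as.factor(x))
      if (nlevels(f) < 2L)
        stop("famd_fit: categorical column '", nm,
             "' has a single level", call. = FALSE)
      ind <- stats::model.matrix(~ f - 1)
      colnames(ind) <- paste(nm, levels(f), sep = ".")
      pk <- colMeans(ind)
      W <- sweep(ind, 2L, sqrt(pk), "/")
      W <- sweep(W, 2L, colMeans(W), "-")
      blocks[[nm]] <- W
      info[[nm]] <- list(type = "categorical", levels = levels(f),
                         frequencies = pk)
    }
  }
  Z <- do.call(cbind, blocks)
  n_cont <- sum(vapply(info, function(i) i$type == "continuous", TRUE))
  n_cat_inertia <- sum(vapply(info, function(i)
    if (i$type == "categorical") length(i$levels) - 1L else 0L, numeric(1)))
  list(Z = Z, info = info, center = center, scale = scl,
       total_inertia = n_cont + n_cat_inertia)
}

#' @export
print.famd_model <- function(x, ...) {
  k <- ncol(x$dimension_scores)
  cat(sprintf("famd_model: %d samples, %d retained dimensions, total inertia %.3f\n",
              x$n_samples, k, x$total_inertia))
  cat(sprintf("  variance explained (cumulative over %d dims): %.1f%%\n",
              k, 100 * x$cumulative_variance[k]))
  invisible(x)
}

#' Correlations between FAMD dimensions and phenotype traits
#'
#' Continuous traits: Pearson correlation with the dimension scores; binary
#' categoricals: point-biserial correlation; categoricals with more than two
#' levels: the correlation ratio (square root of the between-level fraction
#' of the score variance), with a p-value from the one-way ANOVA of scores
#' on levels.  Pairs with `|rho| > 0.5` and `p < 0.01` are flagged.
#'
#' @param model a [famd_fit()] result.
#' @param table the phenotype table the model was fitted on.
#' @param rho_threshold,p_threshold flagging thresholds (defaults 0.5, 0.01).
#' @return data.frame `dimension`, `trait`, `type`, `rho`, `p`, `flagged`.
#' @export
dim_trait_correlations <- function(model, table, rho_threshold = 0.5,
                                   p_threshold = 0.01) {
  scores <- model$dimension_scores
  rows <- list()
  for (d in colnames(scores)) {
    s <- scores[, d]
    for (nm in names(table)) {
      x <- table[[nm]]
      if (is.numeric(x)) {
        ct <- stats::cor.test(s, x)
        rows[[length(rows) + 1L]] <- data.frame(
          dimension = d, trait = nm, type = "continuous",
          rho = unname(ct$estimate), p = ct$p.value,
          stringsAsFactors = FALSE)
      } else {
        f <- droplevels(as.factor(x))
        if (nlevels(f) == 2L) {
          ct <- stats::cor.test(s, as.numeric(f == levels(f)[2L]))
          rows[[length(rows) + 1L]] <- data.frame(
            dimension = d, trait = nm, type = "binary",
            rho = unname(ct$estimate), p = ct$p.value,
            stringsAsFactors = FALSE)
        } else {
          fit <- stats::aov(s ~ f)
          an <- summary(fit)[[1L]]
          ss <- an[["Sum Sq"]]
          eta <- sqrt(ss[1L] / sum(ss))
          rows[[length(rows) + 1L]] <- data.frame(
            dimension = d, trait = nm, type = "multilevel",
            rho = eta, p = an[["Pr(>F)"]][1L], stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$flagged <- abs(out$rho) > rho_threshold & out$p < p_threshold
  out
}

#' Logistic screen of FAMD dimensions against a binary group
#'
#' Fits one logistic regression per retained dimension (group on scores) and
#' reports the likelihood-ratio p-value.  Perfect separation is detected
#' (fitted probabilities collapsing to 0/1) and reported with a floored p
#' rather than a failure; flagged dimensions are candidate confounder
#' covariates for downstream differential analyses.
#'
#' @param model a [famd_fit()] result.
#' @param group binary labels (factor or coercible), aligned with the
#'   model's samples.
#' @param alpha flagging level (default 0.05).
#' @param p_floor smallest reported p under separation (default 1e-12).
#' @return data.frame `dimension`, `coefficient`, `p`, `separation`,
#'   `flagged`.
#' @export
dims_vs_group <- function(model, group, alpha = 0.05, p_floor = 1e-12) {
  g <- droplevels(as.factor(group))
  if (nlevels(g) != 2L || any(table(g) == 0L))
    stop("'group' must have two non-empty levels", call. = FALSE)
  y <- as.numeric(g == levels(g)[2L])
  scores <- model$dimension_scores
  rows <- lapply(colnames(scores), function(d) {
    s <- scores[, d]
    fit <- suppressWarnings(stats::glm(y ~ s, family = stats::binomial()))
    mu <- stats::fitted(fit)
    sep <- any(mu < 1e-8 | mu > 1 - 1e-8) || !fit$converged
    p <- if (sep) {
      lrt <- fit$null.deviance - fit$deviance
      max(stats::pchisq(lrt, df = 1L, lower.tail = FALSE), p_floor)
    } else {
      summary(fit)$coefficients["s", "Pr(>|z|)"]
    }
    data.frame(dimension = d, coefficient = unname(stats::coef(fit)["s"]),
               p = p, separation = sep, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$p < alpha
  out
}
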