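#' Generate a mixed phenotype table driven by latent factors
#'
#' Builds the trait panel of a perinatal cohort — birth weight and centile,
#' gestational age, maternal/paternal anthropometry, six cord-blood cell
#' proportions, and categorical traits (sex, smoking, cesarean section,
#' folate supplementation, season of birth, case/control status) — as noisy
#' functions of at most four latent subject factors, so that downstream
#' dimension reduction has a recoverable structure.  Factor 1 dominates
#' birth centiles, gestational age, cesarean delivery, parental BMI and the
#' adaptive cell fractions; factor 2 the weight variables; factor 3 smoking,
#' NK cells and season of birth; factor 4 folate supplementation and
#' cesarean.  Cell proportions are non-negative and sum to at most 1 by
#' construction (closed composition scaled to 0.97).
#'
#' @param config a [sim_config()].
#' @param truth the `sev_ground_truth` of the matching [generate_cohort()]
#'   run (provides `latent_factors` for every subject).
#' @param loading_scale multiplier on all factor loadings; `0` yields traits
#'   that are pure noise (null structure).
#' @param trait_noise_scale multiplier on the trait-level noise standard
#'   deviations; `0` makes continuous traits and season deterministic
#'   functions of the latent factors.
#' @return data.frame (rownames = sample ids) with numeric columns for
#'   continuous traits and factor columns for categorical traits.
#' @export
generate_phenotypes <- function(config, truth, loading_scale = 1,
                                trait_noise_scale = 1) {
  f <- truth$latent_factors
  if (is.null(f) || nrow(f) < 1L)
    stop("'truth' must contain latent_factors for every subject",
         call. = FALSE)
  n <- nrow(f)
  ids <- rownames(f)
  set.seed(component_seed(config$seed, "phenotypes"))
  ls <- loading_scale
  rn <- function(sd) stats::rnorm(n, sd = sd * trait_noise_scale)

  # standardized latent trait scores (loadings * factors + noise)
  centile_z <- ls * (0.9 * f[, 1] + 0.4 * f[, 4]) + rn(0.4)
  gestage_z <- ls * 0.9 * f[, 1] + rn(0.5)
  bw_z      <- ls * (0.6 * f[, 2] + 0.4 * f[, 1]) + rn(0.5)
  mbmi_z    <- ls * (0.7 * f[, 1] + 0.4 * f[, 2]) + rn(0.5)
  fbmi_z    <- ls * 0.7 * f[, 1] + rn(0.6)
  mwt_z     <- ls * (0.6 * f[, 1] + 0.5 * f[, 2]) + rn(0.5)
  gain_z    <- ls * 0.8 * f[, 2] + rn(0.5)
  mage_z    <- ls * 0.5 * f[, 2] + rn(0.8)

  pheno <- data.frame(
    birth_weight = 3300 + 450 * bw_z,
    birthweight_centile = pmin(pmax(50 + 28 * centile_z, 0.1), 99.9),
    gestational_age = 39 + 1.4 * gestage_z,
    mother_age = 32 + 4.5 * mage_z,
    mother_bmi = 24 + 3.5 * mbmi_z,
    father_bmi = 25.5 + 3.5 * fbmi_z,
    pregestational_weight = 63 + 9 * mwt_z,
    gestational_weight_gain = 12.5 + 4 * gain_z,
    row.names = ids)

  # cord-blood cell composition: closed composition from log-linear weights
  base <- c(cd8t = 0.08, cd4t = 0.15, nk = 0.05, bcell = 0.10,
            mono = 0.07, gran = 0.55)
  load <- rbind(cd8t = c(0.8, 0, 0, 0), cd4t = c(0.7, 0, 0, 0),
                nk = c(0, 0, 0.8, 0), bcell = c(0.7, 0, 0, 0),
                mono = c(0, 0, 0, 0), gran = c(0, 0, 0, 0))
  logw <- matrix(log(base), n, 6L, byrow = TRUE) +
    ls * f %*% t(load) + matrix(stats::rnorm(n * 6L, sd = 0.25 * trait_noise_scale), n)
  w <- exp(logw)
  props <- 0.97 * w / rowSums(w)
  colnames(props) <- paste0("prop_", names(base))
  pheno <- cbind(pheno, as.data.frame(props))

  # categorical traits
  bern <- function(lin) factor(ifelse(stats::runif(n) < stats::plogis(lin),
                                      "yes", "no"), levels = c("no", "yes"))
  pheno$sex <- factor(sample(c("female", "male"), n, replace = TRUE))
  pheno$smoking <- bern(-1 + ls * 1.6 * f[, 3])
  pheno$cesarean <- bern(-0.4 + ls * (1.2 * f[, 1] + 0.7 * f[, 4]))
  pheno$folate <- bern(0.3 + ls * 1.4 * f[, 4])
  season_z <- ls * f[, 3] + rn(if (ls > 0) 0.4 else 1)
  pheno$season <- cut(season_z, breaks = c(-Inf, -0.6745, 0, 0.6745, Inf),
                      labels = c("winter", "spring", "summer", "autumn"))
  grp <- sim_sample_ids(config)
  pheno$case_control <- factor(ifelse(ids %in% grp$cases, "case", "control"),
                               levels = c("control", "case"))
  pheno
}
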