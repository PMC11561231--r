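#' Configuration for the synthetic cis-region generator
#'
#' Defines the study conditions emulated by the generator: a cis-region
#' with block LD, three exposure cohorts of the study's sizes measuring a
#' standardised protein exposure, outcome GWAS with a known causal effect,
#' and a biobank-like individual-level cohort.
#'
#' Defaults: 60 variants in 6 LD blocks of 10 with within-block signed
#' correlation decaying as `rho^|i-j|` (`rho = 0.6`), minor-allele
#' frequencies uniform on [0.05, 0.45], exposure cohort sizes 3,301 /
#' 35,559 / 10,708, two causal variants with direct effects of -0.04 and
#' -0.07 SD per allele (study-scale instrument effects), no between-cohort
#' heterogeneity, causal effect `true_theta = 0.3` per SD increase of the
#' exposure, quantitative outcome GWAS of 400,000.
#'
#' @param n_variants number of variants in the region.
#' @param block_sizes integer vector of LD block sizes (must sum to
#'   `n_variants`).
#' @param within_block_rho signed base correlation within a block.
#' @param maf_range range of minor-allele frequencies.
#' @param cohort_ns exposure cohort sample sizes.
#' @param causal_idx indices of causal variants for the exposure.
#' @param causal_effects direct per-allele effects (SD units) at
#'   `causal_idx`.
#' @param causal_mafs effect-allele frequencies pinned at `causal_idx`
#'   (default 0.33 and 0.09, the study-scale instrument frequencies, so
#'   that instrument strength at the default sample sizes matches the
#'   published F-statistics of 30-40); `NULL` leaves them random.
#' @param heterogeneity_tau SD of the per-cohort marginal-effect
#'   perturbation (0 = homogeneous cohorts).
#' @param true_theta causal effect of the exposure on the outcome, per 1
#'   SD increase in exposure.
#' @param outcome_type `"quantitative"` or `"binary"` outcome GWAS.
#' @param outcome_n outcome GWAS sample size.
#' @param case_fraction case fraction for binary outcome GWAS.
#' @param n_subjects size of the individual-level cohort.
#' @param chromosome,gene_start,gene_end synthetic gene region coordinates.
#' @param spacing_bp distance between adjacent variants.
#' @param seed mandatory integer seed; all generator outputs are
#'   deterministic functions of the config.
#' @return A `sim_config` list, with derived fields `maf` (per-variant
#'   frequencies), `positions`, `variant_ids`, `effects` (length
#'   `n_variants` direct-effect vector).
#' @export
sim_config <- function(n_variants = 60L, block_sizes = rep(10L, 6L),
                       within_block_rho = 0.6, maf_range = c(0.05, 0.45),
                       cohort_ns = c(3301L, 35559L, 10708L),
                       causal_idx = c(15L, 35L),
                       causal_effects = c(-0.04, -0.07),
                       causal_mafs = c(0.33, 0.09),
                       heterogeneity_tau = 0, true_theta = 0.3,
                       outcome_type = c("quantitative", "binary"),
                       outcome_n = 400000L, case_fraction = 0.1,
                       n_subjects = 10000L,
                       chromosome = "17", gene_start = 43753738L,
                       gene_end = 43758791L, spacing_bp = 2000L,
                       seed) {
  outcome_type <- match.arg(outcome_type)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(sum(block_sizes) == n_variants, abs(within_block_rho) < 1,
            length(causal_idx) == length(causal_effects),
            all(causal_idx >= 1L), all(causal_idx <= n_variants),
            maf_range[1] > 0, maf_range[2] <= 0.5)
  maf <- .with_seed(seed, stats::runif(n_variants, maf_range[1], maf_range[2]))
  if (!is.null(causal_mafs)) {
    stopifnot(length(causal_mafs) == length(causal_idx))
    maf[causal_idx] <- causal_mafs
  }
  effects <- numeric(n_variants)
  effects[causal_idx] <- causal_effects
  structure(list(n_variants = as.integer(n_variants),
                 block_sizes = as.integer(block_sizes),
                 within_block_rho = within_block_rho,
                 maf_range = maf_range, maf = maf,
                 cohort_ns = cohort_ns,
                 causal_idx = as.integer(causal_idx),
                 causal_effects = causal_effects, effects = effects,
                 heterogeneity_tau = heterogeneity_tau,
                 true_theta = true_theta, outcome_type = outcome_type,
                 outcome_n = outcome_n, case_fraction = case_fraction,
                 n_subjects = as.integer(n_subjects),
                 chromosome = chromosome,
                 gene_start = as.integer(gene_start),
                 gene_end = as.integer(gene_end),
                 variant_ids = sprintf("rs%07d", 1000000L + seq_len(n_variants)),
                 positions = as.integer(gene_start - 50000L +
                                          spacing_bp * (seq_len(n_variants) - 1L)),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a block-diagonal signed LD matrix
#'
#' Within each block the correlation between variants `i` and `j` is
#' `rho^|i-j|` (AR(1) decay, positive definite by construction); between
#' blocks it is zero.
#'
#' @param config a [sim_config].
#' @return An [ld_matrix] over the config's variants.
#' @export
simulate_region_ld <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  blocks <- lapply(config$block_sizes, function(m) {
    config$within_block_rho^abs(outer(seq_len(m), seq_len(m), `-`))
  })
  r <- matrix(0, config$n_variants, config$n_variants)
  at <- 0L
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    r[idx, idx] <- b
    at <- at + nrow(b)
  }
  ld_matrix(r, variant_ids = config$variant_ids)
}

# Draw one MVN(0, D R D) vector using a pre-computed Cholesky factor of R.
.mvn_noise <- function(chol_r, sd) {
  sd * drop(crossprod(chol_r, stats::rnorm(ncol(chol_r))))
}

.gwas_se <- function(n, maf) 1 / sqrt(n * 2 * maf * (1 - maf))

.sumstats_frame <- function(config, beta, se) {
  data.frame(variant_id = config$variant_ids, chromosome = config$chromosome,
             position = config$positions, effect_allele = "A",
             other_allele = "G", eaf = config$maf, beta = beta, se = se,
             p_value = 2 * stats::pnorm(-abs(beta / se)),
             n = NA_real_, stringsAsFactors = FALSE)
}

#' Simulate one exposure cohort's regional summary statistics
#'
#' Marginal effects are `ld %*% effects` plus a per-cohort heterogeneity
#' perturbation (`N(0, heterogeneity_tau^2)` per variant) plus sampling
#' noise drawn jointly with covariance `se_i se_j rho_ij`, where
#' `se_i = 1/sqrt(n * 2 * maf_i (1 - maf_i))` is the standard error of a
#' standardised-trait GWAS. P-values are two-sided normal.
#'
#' @param config a [sim_config].
#' @param ld the region's [ld_matrix] (from [simulate_region_ld()]).
#' @param cohort_index which cohort (1-based; sets the sample size and the
#'   seed offset).
#' @param se_scale multiplier on the sampling-noise standard errors
#'   (used to probe the noise-free limit; default 1).
#' @param rep_index replicate index mixed into the seed, so repeated
#'   draws over the same region can be generated for calibration
#'   experiments.
#' @return A [sumstats] object for the cohort.
#' @export
simulate_cohort_sumstats <- function(config, ld, cohort_index, se_scale = 1,
                                     rep_index = 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(ld, "ld_matrix"),
            cohort_index >= 1L, cohort_index <= length(config$cohort_ns))
  n <- config$cohort_ns[cohort_index]
  r <- unclass(ld)
  se <- .gwas_se(n, config$maf) * se_scale
  .with_seed(config$seed * 13L + 7919L * (rep_index - 1L) + cohort_index, {
    het <- if (config$heterogeneity_tau > 0) {
      stats::rnorm(config$n_variants, 0, config$heterogeneity_tau)
    } else 0
    beta <- drop(r %*% config$effects) + het + .mvn_noise(chol(r), se)
    out <- .sumstats_frame(config, beta, se)
    out$n <- n
    sumstats(out, trait = "exposure_protein", effect_scale = "sd",
             provenance = sprintf("synthetic cohort %d (n = %d)", cohort_index, n))
  })
}

#' Simulate outcome GWAS summary statistics with a known causal effect
#'
#' Outcome marginal effects are `true_theta` times the exposure's true
#' marginal effects (`ld %*% effects`), plus correlated sampling noise at
#' the outcome GWAS scale. Binary outcomes are emitted on the log-odds
#' scale with standard errors reflecting the effective case-control sample
#' size.
#'
#' @inheritParams simulate_cohort_sumstats
#' @param rep_index replicate index mixed into the seed, so independent
#'   outcome draws can be generated for calibration experiments.
#' @return A [sumstats] object for the outcome trait.
#' @export
simulate_outcome_sumstats <- function(config, ld, rep_index = 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(ld, "ld_matrix"))
  r <- unclass(ld)
  n_eff <- if (config$outcome_type == "binary") {
    config$outcome_n * config$case_fraction * (1 - config$case_fraction)
  } else config$outcome_n
  se <- .gwas_se(n_eff, config$maf)
  .with_seed(config$seed * 31L + 1000L + rep_index, {
    beta <- config$true_theta * drop(r %*% config$effects) +
      .mvn_noise(chol(r), se)
    out <- .sumstats_frame(config, beta, se)
    out$n <- config$outcome_n
    sumstats(out, trait = "outcome",
             effect_scale = if (config$outcome_type == "binary") "log_or" else "sd",
             provenance = sprintf("synthetic outcome GWAS (n = %d)", config$outcome_n))
  })
}

# Bivariate standard normal CDF P(X < h, Y < k) with correlation rho,
# by 1-D quadrature over the conditional distribution.
.pbvnorm <- function(h, k, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(h) * stats::pnorm(k))
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) stats::dnorm(x) * stats::pnorm((k - rho * x) / s),
                   -Inf, h, rel.tol = 1e-9)$value
}

# Correlation between Bernoulli(p1), Bernoulli(p2) indicators thresholded
# from a standard bivariate normal with latent correlation rho.
.threshold_corr <- function(rho, p1, p2) {
  p11 <- .pbvnorm(stats::qnorm(p1), stats::qnorm(p2), rho)
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# Latent correlation delivering a target correlation between thresholded
# indicators (inverse tetrachoric); NA when the target is unattainable.
.latent_rho <- function(target, p1, p2) {
  if (abs(target) < 1e-10) return(0)
  f <- function(r) .threshold_corr(r, p1, p2) - target
  lo <- -1 + 1e-6
  hi <- 1 - 1e-6
  if (f(hi) < 0 || f(lo) > 0) return(NA_real_)
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' Simulate an individual-level biobank-like cohort
#'
#' Dosages are generated from two haplotype draws of a Gaussian copula
#' thresholded at each variant's allele frequency (Hardy-Weinberg
#' genotypes). The latent correlation is adjusted per pair (inverse
#' tetrachoric) so that the *dosage* correlation matches the target LD;
#' pairs whose target is unattainable after thresholding retain the
#' maximal attainable correlation. Covariates are sex (Bernoulli 0.5), age
#' (uniform 40-69, the biobank recruitment range), genotyping batch (3
#' levels) and 10 genetic PCs (standard normal). The continuous outcome is
#' `true_theta * exposure + covariate effects + noise` where the exposure
#' is the per-subject genetic score plus non-genetic variation
#' (standardised); the binary outcome applies a logistic link with
#' intercept set by `case_fraction`; the survival outcome uses an
#' exponential hazard scaled by the linear predictor, time measured since
#' birth, with administrative censoring at the end of follow-up.
#'
#' @param config a [sim_config].
#' @param ld the region's [ld_matrix].
#' @return A [cohort_table] with dosage columns named by variant id,
#'   covariates, and outcomes `y_cont`, `y_bin`, `time`, `event`,
#'   `enrol_age`.
#' @export
simulate_individual_cohort <- function(config, ld) {
  stopifnot(inherits(config, "sim_config"), inherits(ld, "ld_matrix"))
  m <- config$n_variants
  n <- config$n_subjects
  maf <- config$maf
  target <- unclass(ld)
  latent <- diag(m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (target[i, j] != 0) {
        r <- .latent_rho(target[i, j], maf[i], maf[j])
        if (is.na(r)) r <- sign(target[i, j]) * (1 - 1e-6)
        latent[i, j] <- latent[j, i] <- r
      }
    }
  }
  es <- eigen((latent + t(latent)) / 2, symmetric = TRUE)
  ev <- pmax(es$values, 1e-8)
  latent <- es$vectors %*% (ev * t(es$vectors))
  d <- sqrt(diag(latent))
  latent <- latent / (d %o% d)
  cl <- chol(latent)
  thr <- stats::qnorm(maf)
  .with_seed(config$seed * 7L + 5000L, {
    hap <- function() {
      z <- matrix(stats::rnorm(n * m), n, m) %*% cl
      sweep(z, 2L, thr, `<`) * 1L
    }
    dosage <- hap() + hap()
    colnames(dosage) <- config$variant_ids
    sex <- stats::rbinom(n, 1L, 0.5)
    age <- stats::runif(n, 40, 69)
    batch <- factor(sample(paste0("b", 1:3), n, replace = TRUE))
    pcs <- matrix(stats::rnorm(n * 10L), n, 10L,
                  dimnames = list(NULL, paste0("pc", 1:10)))
    g <- drop(dosage %*% config$effects)
    exposure <- g + stats::rnorm(n, 0, sqrt(max(1e-8, 1 - stats::var(g))))
    covar_lp <- 0.1 * sex + 0.01 * (age - 55) + 0.05 * pcs[, 1]
    y_cont <- config$true_theta * exposure + covar_lp + stats::rnorm(n)
    lp_bin <- stats::qlogis(config$case_fraction) +
      config$true_theta * exposure + covar_lp
    y_bin <- stats::rbinom(n, 1L, stats::plogis(lp_bin))
    # exponential event times since birth; baseline rate set so that a
    # 40-69-year-old has had roughly a case_fraction chance of an event
    base_rate <- config$case_fraction / 55
    t_event <- stats::rexp(n, base_rate * exp(config$true_theta * exposure + covar_lp))
    censor_age <- age + 12  # ~12 years of follow-up after enrolment
    event <- as.integer(t_event <= censor_age)
    time <- pmin(t_event, censor_age)
    cohort_table(data.frame(subject_id = sprintf("S%06d", seq_len(n)),
                            dosage, sex = sex, age = age, batch = batch, pcs,
                            y_cont = y_cont, y_bin = y_bin,
                            time = time, event = event, enrol_age = age,
                            stringsAsFactors = FALSE,
                            check.names = FALSE),
                 variant_ids = config$variant_ids)
  })
}
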