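#' Cochran's Q, I-squared and Q p-value for a set of cohort effects
#'
#' Heterogeneity of per-cohort effects under inverse-variance weights
#' `w_i = 1/se_i^2`: `Q = sum w_i (beta_i - beta_pooled)^2`,
#' `I2 = max(0, (Q - (k-1))/Q)` (a fraction), and the Q p-value is the
#' upper tail of a chi-square with `k - 1` degrees of freedom. With fewer
#' than two cohorts `Q = 0`, `I2 = 0`, `p = 1`.
#'
#' @param beta per-cohort effect sizes.
#' @param se per-cohort standard errors (> 0).
#' @return A list with `Q`, `I2`, `q_p_value`, `df`.
#' @export
heterogeneity <- function(beta, se) {
  stopifnot(length(beta) == length(se), all(se > 0))
  k <- length(beta)
  if (k < 2L) return(list(Q = 0, I2 = 0, q_p_value = 1, df = 0L))
  w <- 1 / se^2
  bp <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - bp)^2)
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  list(Q = Q, I2 = I2,
       q_p_value = stats::pchisq(Q, df = k - 1, lower.tail = FALSE),
       df = k - 1L)
}

#' Heterogeneity statistics derived from a printed Q
#'
#' Inverts the identities used by [heterogeneity()] when only Cochran's Q
#' and the number of cohorts are available (as in a published table):
#' `I2 = max(0, (Q - (k-1))/Q)` and the upper-tail chi-square p-value.
#'
#' @param Q Cochran's Q statistic.
#' @param k number of cohorts.
#' @return A list with `I2` and `q_p_value`.
#' @export
heterogeneity_from_q <- function(Q, k) {
  stopifnot(Q >= 0, k >= 2)
  list(I2 = if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0,
       q_p_value = stats::pchisq(Q, df = k - 1, lower.tail = FALSE))
}

.meta_result <- function(beta, se, het, tau2, n_total, k, method) {
  z <- beta / se
  structure(list(beta = beta, se = se,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 ci_low = beta - stats::qnorm(0.975) * se,
                 ci_high = beta + stats::qnorm(0.975) * se,
                 n_total = n_total, k = k,
                 Q = het$Q, I2 = het$I2, tau2 = tau2,
                 q_p_value = het$q_p_value, method = method),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s-effects meta-analysis of %d cohort(s)\n",
              if (x$method == "fixed") "Fixed" else "Random", x$k))
  cat(sprintf("  beta = %.4g (SE %.4g), 95%% CI [%.4g, %.4g], p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  Q = %.3g (p = %.3g), I2 = %.2f, tau2 = %.3g\n",
              x$Q, x$q_p_value, x$I2, x$tau2))
  invisible(x)
}

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Pools per-cohort effects with weights `w_i = 1/se_i^2`:
#' `beta = sum(w b)/sum(w)`, `se = 1/sqrt(sum w)`; the two-sided p-value is
#' normal. Heterogeneity fields (Q, I2, Q p-value) come from
#' [heterogeneity()].
#'
#' @inheritParams heterogeneity
#' @param n per-cohort sample sizes (optional, summed into `n_total`).
#' @return A `meta_result`: pooled `beta`, `se`, `p_value`, 95% CI,
#'   heterogeneity statistics and `method`.
#' @export
fixed_effects_meta <- function(beta, se, n = NULL) {
  stopifnot(length(beta) >= 1L, length(beta) == length(se), all(is.finite(se)),
            all(se > 0))
  w <- 1 / se^2
  bp <- sum(w * beta) / sum(w)
  sp <- sqrt(1 / sum(w))
  het <- heterogeneity(beta, se)
  .meta_result(bp, sp, het, tau2 = 0,
               n_total = if (is.null(n)) NA_real_ else sum(n),
               k = length(beta), method = "fixed")
}

#' Random-effects (DerSimonian-Laird) meta-analysis
#'
#' Estimates the between-cohort variance by the DerSimonian-Laird moment
#' estimator `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))` with
#' fixed-effects weights `w_i = 1/se_i^2`, then pools with
#' `w*_i = 1/(se_i^2 + tau2)`. When `Q <= k - 1` the result equals
#' [fixed_effects_meta()] exactly.
#'
#' @inheritParams fixed_effects_meta
#' @return A `meta_result` with `method = "random"` and the estimated `tau2`.
#' @export
random_effects_meta <- function(beta, se, n = NULL) {
  stopifnot(length(beta) >= 2L, length(beta) == length(se), all(se > 0))
  w <- 1 / se^2
  het <- heterogeneity(beta, se)
  k <- length(beta)
  tau2 <- max(0, (het$Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  bp <- sum(ws * beta) / sum(ws)
  sp <- sqrt(1 / sum(ws))
  .meta_result(bp, sp, het, tau2 = tau2,
               n_total = if (is.null(n)) NA_real_ else sum(n),
               k = k, method = "random")
}

#' Genomic inflation factor
#'
#' `lambda = median(chisq(p)) / qchisq(0.5, 1)` where `chisq(p)` is the
#' 1-df chi-square quantile at `1 - p`. The reference null median
#' `qchisq(0.5, 1) = 0.4549364` (7 significant digits). Values near 1
#' indicate no systematic inflation of the test statistics.
#'
#' @param p_values p-values in [0, 1]; zeros (numerical underflow of very
#'   strong associations) map to an infinite chi-square, to which the
#'   median is robust.
#' @return `lambda_gc`, a positive scalar.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0L) stop("no p-values supplied", call. = FALSE)
  stopifnot(all(p_values >= 0), all(p_values <= 1))
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Per-variant meta-analysis of several cohorts' summary statistics
#'
#' Standardises every cohort to the allele orientation of the first cohort
#' carrying each variant, then pools each variant's effect across the
#' cohorts that carry it ([fixed_effects_meta()] or
#' [random_effects_meta()]; variants present in a single cohort pass
#' through unchanged under either method, with `Q = 0`). Returns pooled
#' summary statistics carrying per-variant heterogeneity columns, plus the
#' genomic inflation factor of the pooled p-values.
#'
#' @param cohorts list of [sumstats] objects (same trait, same build).
#' @param method `"fixed"` or `"random"`.
#' @return A list with `stats` (pooled [sumstats] whose data frame also
#'   carries `Q`, `I2`, `tau2`, `q_p_value`, `k` columns) and `lambda_gc`.
#' @export
meta_analyse <- function(cohorts, method = c("fixed", "random")) {
  method <- match.arg(method)
  stopifnot(length(cohorts) >= 1L)
  lapply(cohorts, function(s) stopifnot(inherits(s, "sumstats")))
  dfs <- lapply(cohorts, as.data.frame)
  all_ids <- unique(unlist(lapply(dfs, `[[`, "variant_id")))
  # reference orientation: first cohort that carries the variant
  reference <- list()
  for (d in dfs) {
    new <- setdiff(d$variant_id, names(reference))
    idx <- match(new, d$variant_id)
    ref_new <- Map(function(e, o) c(e, o), d$effect_allele[idx], d$other_allele[idx])
    names(ref_new) <- new
    reference <- c(reference, ref_new)
  }
  aligned <- lapply(cohorts, function(s) standardise_alleles(s, reference)$stats)
  adfs <- lapply(aligned, as.data.frame)
  nc <- length(adfs)
  m_ids <- length(all_ids)
  grab <- function(col) {
    vapply(adfs, function(d) d[[col]][match(all_ids, d$variant_id)], numeric(m_ids))
  }
  B <- matrix(grab("beta"), nrow = m_ids)
  SE <- matrix(grab("se"), nrow = m_ids)
  EAF <- matrix(grab("eaf"), nrow = m_ids)
  N <- matrix(grab("n"), nrow = m_ids)
  present <- !is.na(B) & !is.na(SE)
  k <- rowSums(present)
  W <- ifelse(present, 1 / SE^2, 0)
  B0 <- ifelse(present, B, 0)
  sumw <- rowSums(W)
  bp_fixed <- rowSums(W * B0) / sumw
  Q <- rowSums(W * (B0 - bp_fixed)^2 * present)
  I2 <- ifelse(Q > 0 & k >= 2, pmax(0, (Q - (k - 1)) / Q), 0)
  q_p <- ifelse(k >= 2, stats::pchisq(Q, df = pmax(k - 1, 1), lower.tail = FALSE), 1)
  if (method == "random") {
    denom <- sumw - rowSums(W^2) / sumw
    tau2 <- ifelse(k >= 2 & denom > 0, pmax(0, (Q - (k - 1)) / denom), 0)
    WS <- ifelse(present, 1 / (SE^2 + tau2), 0)
    beta_pooled <- rowSums(WS * B0) / rowSums(WS)
    se_pooled <- sqrt(1 / rowSums(WS))
  } else {
    tau2 <- rep(0, m_ids)
    beta_pooled <- bp_fixed
    se_pooled <- sqrt(1 / sumw)
  }
  N0 <- ifelse(present, N, 0)
  n_total <- rowSums(N0)
  eaf_pooled <- rowSums(ifelse(present, EAF, 0) * N0) / n_total
  first_idx <- apply(present, 1L, which.max)
  pick <- function(col) {
    mat <- vapply(adfs, function(d) d[[col]][match(all_ids, d$variant_id)],
                  vector(typeof(adfs[[1]][[col]]), m_ids))
    mat <- matrix(mat, nrow = m_ids)
    mat[cbind(seq_len(m_ids), first_idx)]
  }
  pooled <- data.frame(
    variant_id = all_ids,
    chromosome = pick("chromosome"),
    position = pick("position"),
    effect_allele = pick("effect_allele"),
    other_allele = pick("other_allele"),
    eaf = eaf_pooled, beta = beta_pooled, se = se_pooled,
    p_value = 2 * stats::pnorm(-abs(beta_pooled / se_pooled)),
    n = n_total, Q = Q, I2 = I2, tau2 = tau2, q_p_value = q_p, k = k,
    stringsAsFactors = FALSE)
  stats <- sumstats(pooled, trait = attr(cohorts[[1]], "trait"),
                    effect_scale = attr(cohorts[[1]], "effect_scale"),
                    provenance = sprintf("%s-effects meta-analysis of %d cohort(s)",
                                         method, length(cohorts)))
  extra <- pooled[c("Q", "I2", "tau2", "q_p_value", "k")]
  stats <- cbind(stats, extra)
  class(stats) <- c("sumstats", "data.frame")
  attr(stats, "trait") <- attr(cohorts[[1]], "trait")
  attr(stats, "effect_scale") <- attr(cohorts[[1]], "effect_scale")
  attr(stats, "provenance") <- sprintf("%s-effects meta-analysis of %d cohort(s)",
                                       method, length(cohorts))
  list(stats = stats, lambda_gc = genomic_inflation(pooled$p_value),
       method = method)
}
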