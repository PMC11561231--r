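#' Per-variant approximate Bayes factor (Wakefield)
#'
#' For an association with estimate `beta`, standard error `se` and
#' effect-size prior standard deviation `prior_sd` (`W = prior_sd^2`,
#' `V = se^2`, `z = beta/se`, shrinkage `r = W/(V+W)`), the natural-log
#' approximate Bayes factor against the null is
#' `log ABF = 0.5*log(1 - r) + 0.5*r*z^2`. Defaults follow the published
#' conventions for the method: `prior_sd = 0.20` for quantitative traits
#' (SD units), `0.15` for case-control traits (log-odds).
#'
#' @param beta effect size(s).
#' @param se standard error(s), > 0.
#' @param trait_type `"quantitative"` or `"case_control"`; sets the default
#'   `prior_sd`.
#' @param prior_sd optional explicit prior standard deviation.
#' @return Natural-log approximate Bayes factor(s).
#' @export
abf <- function(beta, se, trait_type = c("quantitative", "case_control"),
                prior_sd = NULL) {
  trait_type <- match.arg(trait_type)
  if (any(se <= 0)) stop("standard errors must be positive", call. = FALSE)
  if (is.null(prior_sd)) {
    prior_sd <- if (trait_type == "quantitative") 0.20 else 0.15
  }
  W <- prior_sd^2
  V <- se^2
  r <- W / (V + W)
  0.5 * log(1 - r) + 0.5 * r * (beta / se)^2
}

#' Colocalization priors
#'
#' Per-variant prior probabilities: `p1` (associated with trait 1 only),
#' `p2` (trait 2 only), `p12` (shared causal variant). The defaults are the
#' standard published values `1e-4`, `1e-4`, `1e-5`. A warning is issued
#' when `n * (p1 + p2 + p12)` approaches 1 for the region size `n`.
#'
#' @param p1,p2,p12 per-variant priors; `0 < p12 <= min(p1, p2)` required.
#' @return A `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p1 > 0, p2 > 0, p12 > 0, p12 <= min(p1, p2),
            p1 < 1, p2 < 1)
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

# log(sum(exp(x))) without overflow; -Inf for empty input
.logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Two-trait Bayesian colocalization over a cis-region
#'
#' Enumerates the five causal configurations under a single causal variant
#' per trait: H0 (no association), H1/H2 (association with one trait only),
#' H3 (both traits, distinct variants), H4 (shared variant). With
#' per-variant log approximate Bayes factors `L1`, `L2` from [abf()], the
#' unnormalised hypothesis weights are `1`, `p1*S1`, `p2*S2`,
#' `p1*p2*(S1*S2 - S12)`, `p12*S12`, where `S1 = sum(exp(L1))`,
#' `S2 = sum(exp(L2))`, `S12 = sum(exp(L1 + L2))`; posteriors are the
#' normalised weights, computed in log space with log-sum-exp for
#' numerical safety.
#'
#' @param beta1,se1 harmonised effects of trait 1 over the region.
#' @param beta2,se2 harmonised effects of trait 2, same variants and order.
#' @param priors a [coloc_priors] object.
#' @param trait_types length-2 character: `"quantitative"` or
#'   `"case_control"` per trait.
#' @param prior_sd optional length-2 numeric overriding the per-trait
#'   effect-size prior SD.
#' @param variant_ids optional ids (for reporting).
#' @return A `coloc_result`: list with `n_snps` and `pp`, the posterior
#'   probabilities `PP(H0)`..`PP(H4)` (summing to 1 within 1e-10).
#' @export
colocalise <- function(beta1, se1, beta2, se2, priors = coloc_priors(),
                       trait_types = c("quantitative", "quantitative"),
                       prior_sd = c(NA_real_, NA_real_),
                       variant_ids = NULL) {
  n <- length(beta1)
  if (!(length(se1) == n && length(beta2) == n && length(se2) == n)) {
    stop("trait vectors must cover identical variants in identical order",
         call. = FALSE)
  }
  stopifnot(n >= 1L, inherits(priors, "coloc_priors"))
  if (n * (priors$p1 + priors$p2 + priors$p12) >= 1) {
    warning("priors sum to >= 1 over the region; posteriors unreliable")
  }
  sd1 <- if (is.na(prior_sd[1])) NULL else prior_sd[1]
  sd2 <- if (is.na(prior_sd[2])) NULL else prior_sd[2]
  l1 <- abf(beta1, se1, trait_types[1], prior_sd = sd1)
  l2 <- abf(beta2, se2, trait_types[2], prior_sd = sd2)
  ls1 <- .logsumexp(l1)
  ls2 <- .logsumexp(l2)
  ls12 <- .logsumexp(l1 + l2)
  # log(S1*S2 - S12), stable; the cross term is 0 for n = 1
  lcross <- if (n == 1L) -Inf else {
    diffexp <- ls12 - (ls1 + ls2)
    ls1 + ls2 + log1p(-exp(diffexp))
  }
  lw <- c(h0 = 0,
          h1 = log(priors$p1) + ls1,
          h2 = log(priors$p2) + ls2,
          h3 = log(priors$p1) + log(priors$p2) + lcross,
          h4 = log(priors$p12) + ls12)
  pp <- exp(lw - .logsumexp(lw))
  names(pp) <- c("PP.H0", "PP.H1", "PP.H2", "PP.H3", "PP.H4")
  structure(list(n_snps = n, pp = pp, priors = priors,
                 variant_ids = variant_ids),
            class = "coloc_result")
}

#' Colocalise two harmonised summary-statistics objects
#'
#' Convenience wrapper around [colocalise()] taking two [sumstats] objects
#' restricted to the same region, intersecting on variant id (both traits
#' must already be on a common allele orientation, e.g. via
#' [standardise_alleles()]).
#'
#' @param trait1,trait2 [sumstats] objects.
#' @inheritParams colocalise
#' @return A `coloc_result`.
#' @export
colocalise_sumstats <- function(trait1, trait2, priors = coloc_priors(),
                                trait_types = c("quantitative", "quantitative"),
                                prior_sd = c(NA_real_, NA_real_)) {
  d1 <- as.data.frame(trait1)
  d2 <- as.data.frame(trait2)
  common <- intersect(d1$variant_id, d2$variant_id)
  if (length(common) == 0L) stop("no shared variants between traits", call. = FALSE)
  i1 <- match(common, d1$variant_id)
  i2 <- match(common, d2$variant_id)
  colocalise(d1$beta[i1], d1$se[i1], d2$beta[i2], d2$se[i2],
             priors = priors, trait_types = trait_types, prior_sd = prior_sd,
             variant_ids = common)
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d variant(s) (p1 = %g, p2 = %g, p12 = %g)\n",
              x$n_snps, x$priors$p1, x$priors$p2, x$priors$p12))
  out <- sprintf("%.2f%%", 100 * x$pp)
  names(out) <- names(x$pp)
  print(noquote(out))
  best <- which.max(x$pp)
  if (best == 5L && x$pp[5] > 0.8) {
    cat("  substantial evidence of colocalization (PP(H4) > 80%)\n")
  }
  invisible(x)
}
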