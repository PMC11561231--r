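#' Fit a cis-Mendelian-randomisation causal-effect model
#'
#' Estimates the causal effect of the exposure on the outcome from
#' harmonised per-variant effects, honouring the LD correlation between
#' instruments, and reports it per 1 SD *decrease* in the exposure by
#' default (mimicking pharmacological inhibition of the target protein).
#'
#' Methods:
#' \describe{
#'   \item{`wald`}{single-instrument Wald ratio `beta_Y / beta_X`, with the
#'     first-order delta-method standard error `se_Y / |beta_X|`.}
#'   \item{`givw`}{generalised inverse-variance weighting. With
#'     `Omega_ij = se_Yi * se_Yj * rho_ij`, the estimate is the generalised
#'     least-squares solution
#'     `theta = (bX' Omega^-1 bX)^-1 bX' Omega^-1 bY` with standard error
#'     `(bX' Omega^-1 bX)^-1/2` (fixed-effect residual scaling; with
#'     identity LD this reduces to textbook IVW, and with one instrument to
#'     the Wald ratio). Requires *signed* correlations: an LD matrix of
#'     squared values cannot recover the sign structure and is refused
#'     upstream by [ld_matrix()] validation of the input.}
#'   \item{`pca`}{projects `beta_X`, `beta_Y` and `Omega` onto the retained
#'     principal components of a [pca_basis] and runs generalised IVW in
#'     component space; with all components retained it equals `givw`.}
#' }
#'
#' Confidence intervals are normal-theory at 95%; the p-value is two-sided
#' normal. For binary/survival outcomes (`log_or`/`log_hr` scales) the
#' estimate exponentiates to an odds/hazard ratio per 1 SD decrease.
#'
#' @param h a `harmonised_set` (see [harmonise_pairs()] /
#'   [harmonised_set()]).
#' @param ld an [ld_matrix] over `h$variant_ids` in the same order;
#'   defaults to identity (uncorrelated instruments). Ignored for `wald`.
#' @param method `"givw"` (default), `"wald"`, or `"pca"`.
#' @param per_sd report per 1 SD `"decrease"` (default) or `"increase"` in
#'   the exposure.
#' @param basis a [pca_basis] for `method = "pca"`; built from
#'   `variance_threshold` when omitted.
#' @param variance_threshold cumulative variance retained when building the
#'   PCA basis (default 0.999).
#' @return An object of class `mr_fit` with components `theta`, `se`,
#'   `ci_low`, `ci_high`, `p_value`, `ratio_estimate` (exp(theta) for
#'   ratio-scale outcomes, else `NA`), `method`, `per_sd`,
#'   `n_instruments`, `outcome_scale`, traits and `variant_ids`.
#' @seealso [coef.mr_fit()], [confint.mr_fit()], [summary.mr_fit()]
#' @export
mr_fit <- function(h, ld = NULL, method = c("givw", "wald", "pca"),
                   per_sd = c("decrease", "increase"), basis = NULL,
                   variance_threshold = 0.999) {
  method <- match.arg(method)
  per_sd <- match.arg(per_sd)
  stopifnot(inherits(h, "harmonised_set"))
  k <- length(h$variant_ids)
  if (is.null(ld)) {
    ld <- ld_matrix(diag(k), variant_ids = h$variant_ids)
  }
  stopifnot(inherits(ld, "ld_matrix"), nrow(ld) == k)
  if (!identical(rownames(ld), h$variant_ids)) {
    stop("LD matrix order does not match the harmonised set", call. = FALSE)
  }
  fit <- switch(method,
    wald = {
      if (k != 1L) stop("Wald ratio requires exactly one instrument", call. = FALSE)
      if (h$beta_x == 0) stop("null instrument: beta_x = 0", call. = FALSE)
      list(theta = h$beta_y / h$beta_x, se = h$se_y / abs(h$beta_x))
    },
    givw = .givw(h$beta_x, h$beta_y, h$se_y, unclass(ld)),
    pca = {
      if (is.null(basis)) {
        basis <- pca_basis(h$beta_x, h$se_y, ld, variance_threshold)
      }
      stopifnot(inherits(basis, "pca_basis"), nrow(basis$loadings) == k)
      W <- basis$loadings
      omega <- (h$se_y %o% h$se_y) * unclass(ld)
      .givw_raw(drop(crossprod(W, h$beta_x)), drop(crossprod(W, h$beta_y)),
                crossprod(W, omega %*% W))
    })
  z975 <- stats::qnorm(0.975)
  out <- structure(list(theta = fit$theta, se = fit$se,
                        ci_low = fit$theta - z975 * fit$se,
                        ci_high = fit$theta + z975 * fit$se,
                        p_value = 2 * stats::pnorm(-abs(fit$theta / fit$se)),
                        ratio_estimate = NA_real_,
                        method = method, per_sd = "increase",
                        n_instruments = k,
                        outcome_scale = h$outcome_scale,
                        exposure_trait = h$exposure_trait,
                        outcome_trait = h$outcome_trait,
                        variant_ids = h$variant_ids),
                   class = "mr_fit")
  out <- .set_ratio(out)
  if (per_sd == "decrease") out <- rescale_per_sd_decrease(out) else out
}

# GLS core on outcome covariance Omega = D R D (D = diag(se_y)).
.givw <- function(beta_x, beta_y, se_y, rho) {
  .givw_raw(beta_x, beta_y, (se_y %o% se_y) * rho)
}

.givw_raw <- function(beta_x, beta_y, omega) {
  kappa <- tryCatch(kappa(omega, exact = TRUE), error = function(e) Inf)
  oi <- tryCatch(solve(omega), error = function(e) {
    stop(sprintf("singular outcome covariance (condition number %g)", kappa),
         call. = FALSE)
  })
  xox <- drop(crossprod(beta_x, oi %*% beta_x))
  if (xox <= 0) stop("degenerate instrument set: beta_x' Omega^-1 beta_x <= 0",
                     call. = FALSE)
  list(theta = drop(crossprod(beta_x, oi %*% beta_y)) / xox,
       se = 1 / sqrt(xox))
}

.set_ratio <- function(x) {
  x$ratio_estimate <- if (x$outcome_scale %in% c("log_or", "log_hr")) {
    exp(x$theta)
  } else NA_real_
  x
}

#' Re-express an MR estimate per 1 SD decrease (or back)
#'
#' Negates the causal estimate, negates and swaps the confidence-interval
#' endpoints, and recomputes the ratio estimate; the standard error and
#' p-value are unchanged. Applying it twice recovers the original fit.
#'
#' @param x an `mr_fit`.
#' @return The rescaled `mr_fit`.
#' @export
rescale_per_sd_decrease <- function(x) {
  stopifnot(inherits(x, "mr_fit"))
  x$theta <- -x$theta
  ci <- c(-x$ci_high, -x$ci_low)
  x$ci_low <- ci[1]
  x$ci_high <- ci[2]
  x$per_sd <- if (x$per_sd == "increase") "decrease" else "increase"
  .set_ratio(x)
}

#' @export
print.mr_fit <- function(x, ...) {
  scale_lab <- switch(x$outcome_scale,
                      log_or = "log-OR", log_hr = "log-HR",
                      sd = "SD change", unit = "unit change")
  cat(sprintf("MR estimate (%s, %d instrument(s)): %s on %s\n",
              x$method, x$n_instruments, x$exposure_trait, x$outcome_trait))
  cat(sprintf("  %s per 1 SD %s in exposure: %.4g (95%% CI %.4g, %.4g), p = %.3g\n",
              scale_lab, x$per_sd, x$theta, x$ci_low, x$ci_high, x$p_value))
  if (!is.na(x$ratio_estimate)) {
    cat(sprintf("  %s ratio: %.4g (95%% CI %.4g, %.4g)\n",
                if (x$outcome_scale == "log_or") "odds" else "hazard",
                x$ratio_estimate, exp(x$ci_low), exp(x$ci_high)))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$theta, sprintf("theta_per_sd_%s", object$per_sd))
}

#' @export
vcov.mr_fit <- function(object, ...) {
  matrix(object$se^2, 1, 1,
         dimnames = rep(list(sprintf("theta_per_sd_%s", object$per_sd)), 2))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$theta - z * object$se, object$theta + z * object$se), 1, 2)
  dimnames(m) <- list(sprintf("theta_per_sd_%s", object$per_sd),
                      sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2)))
  m
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(object, class = c("summary.mr_fit", "mr_fit"))
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print.mr_fit(x)
  cat("  instruments:", paste(x$variant_ids, collapse = ", "), "\n")
  cat("  significance at p < 0.05:", if (x$p_value < 0.05) "yes" else "no", "\n")
  invisible(x)
}

#' Collect MR fits into a forest-plot-ready table
#'
#' One row per fit: outcome, method, number of instruments, estimate with
#' 95% CI and p-value on the reporting scale, plus the ratio-scale columns
#' where applicable.
#'
#' @param fits list of `mr_fit` objects.
#' @return A data frame.
#' @export
mr_table <- function(fits) {
  stopifnot(length(fits) >= 1L)
  rows <- lapply(fits, function(f) {
    data.frame(outcome = f$outcome_trait, method = f$method,
               n_instruments = f$n_instruments, per_sd = f$per_sd,
               scale = paste0(switch(f$outcome_scale,
                                     log_or = "odds ratio", log_hr = "hazard ratio",
                                     sd = "SD change", unit = "unit change"),
                              " per 1 SD ", f$per_sd),
               theta = f$theta, se = f$se, ci_low = f$ci_low,
               ci_high = f$ci_high, p_value = f$p_value,
               ratio = f$ratio_estimate, ratio_low = exp(f$ci_low),
               ratio_high = exp(f$ci_high),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ratio_low[is.na(out$ratio)] <- NA_real_
  out$ratio_high[is.na(out$ratio)] <- NA_real_
  rownames(out) <- NULL
  out
}
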