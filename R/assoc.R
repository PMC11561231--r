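#' Individual-level cohort table
#'
#' A `cohort_table` is a data frame with one row per subject carrying
#' `subject_id`, per-variant dosage columns (0-2, named by variant id),
#' covariates (`sex` 0/1, `age` in years, `batch` categorical, `pc1`-`pc10`)
#' and outcomes: continuous (`y_cont`, standardised before association),
#' binary (`y_bin`), and survival (`time` since birth in years, `event`
#' 0/1, `enrol_age` age at enrolment).
#'
#' @param x data frame with the columns above.
#' @param variant_ids character vector naming the dosage columns.
#' @return A `cohort_table`.
#' @export
cohort_table <- function(x, variant_ids) {
  x <- as.data.frame(x)
  missing <- setdiff(variant_ids, names(x))
  if (length(missing) > 0L) {
    stop("dosage column(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (v in variant_ids) {
    if (any(is.na(x[[v]])) || any(x[[v]] < 0 | x[[v]] > 2)) {
      stop("dosages for ", v, " must be in [0, 2] with no missing values",
           call. = FALSE)
    }
  }
  structure(x, variant_ids = variant_ids,
            class = c("cohort_table", "data.frame"))
}

.rhs <- function(variant_id, covariates) {
  paste(c(variant_id, covariates), collapse = " + ")
}

.default_covariates <- function(cohort) {
  covs <- c("sex", "age", "batch", paste0("pc", 1:10))
  covs[covs %in% names(cohort)]
}

.assoc_result <- function(variant_id, beta, se, n, outcome_name, model,
                          flag = NA_character_) {
  data.frame(variant_id = variant_id, beta = beta, se = se,
             p_value = 2 * stats::pnorm(-abs(beta / se)), n = n,
             outcome_name = outcome_name, model = model, flag = flag,
             stringsAsFactors = FALSE)
}

.check_design <- function(df, variant_id, covariates) {
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", .rhs(variant_id, covariates))), data = df)
  qr_d <- qr(mm)
  if (qr_d$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_d$pivot[(qr_d$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  invisible(mm)
}

#' Per-variant linear association
#'
#' Ordinary least squares of a standardised continuous outcome on the
#' variant dosage plus covariates (sex, age, genotyping batch and the first
#' 10 genetic principal components when present). The outcome is
#' standardised to mean 0, SD 1 before fitting, so `beta` is the SD change
#' per dosage unit of the effect allele.
#'
#' @param cohort a [cohort_table].
#' @param variant_id dosage column to test.
#' @param outcome name of the continuous outcome column (default
#'   `"y_cont"`).
#' @param covariates covariate column names; default sex, age, batch,
#'   pc1-pc10 (those present).
#' @return A one-row data frame: `variant_id`, `beta`, `se`, `p_value`,
#'   `n`, `outcome_name`, `model`, `flag`.
#' @export
linear_assoc <- function(cohort, variant_id, outcome = "y_cont",
                         covariates = .default_covariates(cohort)) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- as.data.frame(cohort)
  df <- df[stats::complete.cases(df[c(variant_id, outcome, covariates)]), ]
  y <- df[[outcome]]
  df$.y_std <- (y - mean(y)) / stats::sd(y)
  .check_design(df, variant_id, covariates)
  fml <- stats::as.formula(paste(".y_std ~", .rhs(variant_id, covariates)))
  fit <- stats::lm(fml, data = df)
  cf <- summary(fit)$coefficients[variant_id, ]
  .assoc_result(variant_id, cf[["Estimate"]], cf[["Std. Error"]],
                nrow(df), outcome, "linear")
}

#' Per-variant logistic association
#'
#' Maximum-likelihood logistic regression (IRLS, convergence tolerance
#' `1e-8`, up to 50 iterations) of a binary outcome on dosage plus
#' covariates; `beta` is the log-odds per dosage unit. Apparent separation
#' (|log-OR| > 20 or non-convergence) sets the `flag` column to
#' `"separation"` rather than failing.
#'
#' @inheritParams linear_assoc
#' @param outcome name of the 0/1 outcome column (default `"y_bin"`).
#' @return A one-row association data frame as in [linear_assoc()].
#' @export
logistic_assoc <- function(cohort, variant_id, outcome = "y_bin",
                           covariates = .default_covariates(cohort)) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- as.data.frame(cohort)
  df <- df[stats::complete.cases(df[c(variant_id, outcome, covariates)]), ]
  y <- df[[outcome]]
  if (length(unique(y)) < 2L) stop("binary outcome needs both classes", call. = FALSE)
  .check_design(df, variant_id, covariates)
  fml <- stats::as.formula(paste(outcome, "~", .rhs(variant_id, covariates)))
  fit <- stats::glm(fml, family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 50L))
  cf <- summary(fit)$coefficients[variant_id, ]
  flag <- if (!fit$converged || abs(cf[["Estimate"]]) > 20) "separation" else NA_character_
  .assoc_result(variant_id, cf[["Estimate"]], cf[["Std. Error"]],
                nrow(df), outcome, "logistic", flag = flag)
}

#' Per-variant Cox proportional-hazards association
#'
#' Cox partial-likelihood fit (Breslow tie handling by default) of time to
#' event on dosage plus covariates; `beta` is the log-hazard per dosage
#' unit. The time origin is either birth (`time` used as is) or enrolment
#' (`time - enrol_age`); with `origin = "enrolment"` and
#' `exclude_prevalent = TRUE`, subjects whose event precedes enrolment are
#' removed and counted, approximating an incident-disease cohort. Subjects
#' with missing event time are excluded and counted.
#'
#' @inheritParams linear_assoc
#' @param time,event,enrol_age column names for the survival outcome.
#' @param origin time origin: `"birth"` (default) or `"enrolment"`.
#' @param exclude_prevalent drop subjects with events before enrolment
#'   (only with `origin = "enrolment"`).
#' @param ties tie handling passed to [survival::coxph()] (default
#'   `"breslow"`; `"efron"` available).
#' @return A one-row association data frame as in [linear_assoc()], with
#'   attribute `n_excluded` (prevalent + missing-date exclusions).
#' @export
cox_assoc <- function(cohort, variant_id, time = "time", event = "event",
                      enrol_age = "enrol_age",
                      origin = c("birth", "enrolment"),
                      exclude_prevalent = FALSE,
                      covariates = .default_covariates(cohort),
                      ties = c("breslow", "efron")) {
  origin <- match.arg(origin)
  ties <- match.arg(ties)
  stopifnot(inherits(cohort, "cohort_table"))
  df <- as.data.frame(cohort)
  n_missing <- sum(df[[event]] == 1 & is.na(df[[time]]))
  df <- df[!(df[[event]] == 1 & is.na(df[[time]])), ]
  n_prevalent <- 0L
  if (origin == "enrolment") {
    df$.t <- df[[time]] - df[[enrol_age]]
    if (exclude_prevalent) {
      prev <- df[[event]] == 1 & df$.t <= 0
      n_prevalent <- sum(prev)
      df <- df[!prev, ]
    }
    df <- df[df$.t > 0, ]
  } else {
    df$.t <- df[[time]]
  }
  df <- df[stats::complete.cases(df[c(variant_id, ".t", event, covariates)]), ]
  if (sum(df[[event]]) == 0L) stop("zero events after exclusions", call. = FALSE)
  if (stats::var(df[[variant_id]]) == 0) {
    stop("rank-deficient design; collinear column(s): ", variant_id, call. = FALSE)
  }
  fml <- stats::as.formula(paste0("survival::Surv(.t, ", event, ") ~ ",
                                  .rhs(variant_id, covariates)))
  fit <- survival::coxph(fml, data = df, ties = ties)
  cf <- summary(fit)$coefficients[variant_id, ]
  out <- .assoc_result(variant_id, cf[["coef"]], cf[["se(coef)"]],
                       nrow(df), paste0(event, " (", origin, " origin)"), "cox")
  attr(out, "n_excluded") <- c(missing_date = n_missing, prevalent = n_prevalent)
  out
}

#' Association results as summary statistics
#'
#' Converts per-variant association rows into a [sumstats] object
#' consumable by the MR engine, attaching variant metadata (alleles,
#' position, frequency) from a reference table.
#'
#' @param assoc data frame of rows from [linear_assoc()] /
#'   [logistic_assoc()] / [cox_assoc()].
#' @param variant_info data frame with `variant_id`, `chromosome`,
#'   `position`, `effect_allele`, `other_allele`, `eaf`.
#' @param trait trait name.
#' @param effect_scale `"sd"`, `"log_or"` or `"log_hr"` depending on the
#'   model.
#' @return A [sumstats] object.
#' @export
assoc_to_sumstats <- function(assoc, variant_info, trait,
                              effect_scale = c("sd", "unit", "log_or", "log_hr")) {
  effect_scale <- match.arg(effect_scale)
  idx <- match(assoc$variant_id, variant_info$variant_id)
  if (anyNA(idx)) stop("variant metadata missing for some associations", call. = FALSE)
  sumstats(data.frame(variant_id = assoc$variant_id,
                      chromosome = variant_info$chromosome[idx],
                      position = variant_info$position[idx],
                      effect_allele = variant_info$effect_allele[idx],
                      other_allele = variant_info$other_allele[idx],
                      eaf = variant_info$eaf[idx],
                      beta = assoc$beta, se = assoc$se, p_value = assoc$p_value,
                      n = assoc$n, stringsAsFactors = FALSE),
           trait = trait, effect_scale = effect_scale,
           provenance = "individual-level association")
}
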