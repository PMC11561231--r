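# Small deterministic cohort for exact checks (no simulation machinery).
make_micro_cohort <- function(n = 200, seed = 101, beta_g = 0.5,
                              confounded = FALSE) {
  set.seed(seed)
  g <- rbinom(n, 2, 0.3)
  sex <- rbinom(n, 1, 0.5)
  age <- runif(n, 40, 69)
  batch <- factor(sample(c("b1", "b2"), n, replace = TRUE))
  u <- rnorm(n)
  dosage <- if (confounded) pmin(2, pmax(0, g + 0.3 * u)) else g
  y <- beta_g * dosage + 0.2 * sex + 0.01 * age +
    (if (confounded) 0.8 * u else 0) + rnorm(n)
  cohort_table(data.frame(subject_id = paste0("s", 1:n), v1 = dosage,
                          sex = sex, age = age, batch = batch, u = u,
                          y_cont = y, stringsAsFactors = FALSE),
               variant_ids = "v1")
}

test_that("noise-free linear association recovers the exact slope", {
  n <- 50
  g <- rep(0:2, length.out = n)
  co <- cohort_table(data.frame(subject_id = paste0("s", 1:n), v1 = g,
                                y_cont = 2 * g), variant_ids = "v1")
  res <- suppressWarnings(linear_assoc(co, "v1", covariates = character(0)))
  # outcome is standardised first, so the slope is 2 / sd(y)
  expect_equal(res$beta, 2 / sd(2 * g), tolerance = 1e-10)
  expect_lt(res$se, 1e-10)
})

test_that("linear association matches the normal-equations oracle to 1e-10", {
  co <- make_micro_cohort()
  res <- linear_assoc(co, "v1")
  df <- as.data.frame(co)
  y <- scale(df$y_cont)[, 1]
  X <- model.matrix(~ v1 + sex + age + batch, df)
  beta_hat <- solve(crossprod(X), crossprod(X, y))
  resid <- y - X %*% beta_hat
  sigma2 <- sum(resid^2) / (nrow(X) - ncol(X))
  se_hat <- sqrt(diag(sigma2 * solve(crossprod(X))))
  expect_equal(res$beta, unname(beta_hat["v1", 1]), tolerance = 1e-10)
  expect_equal(res$se, unname(se_hat["v1"]), tolerance = 1e-10)
  expect_equal(res$n, 200)
  expect_equal(res$model, "linear")
})

test_that("covariate adjustment removes confounding within 2 SE", {
  co <- make_micro_cohort(n = 2000, seed = 7, beta_g = 0.4, confounded = TRUE)
  df <- as.data.frame(co)
  truth <- 0.4 / sd(df$y_cont)   # direct effect on the standardised scale
  crude <- linear_assoc(co, "v1", covariates = c("sex", "age"))
  adj <- linear_assoc(co, "v1", covariates = c("sex", "age", "u"))
  expect_lt(abs(adj$beta - truth), 2 * adj$se)
  expect_gt(abs(crude$beta - truth), abs(adj$beta - truth))
})

test_that("linear beta is invariant to affine covariate rescaling", {
  co <- make_micro_cohort()
  base <- linear_assoc(co, "v1")
  df <- as.data.frame(co)
  df$age <- (df$age - 50) / 10
  co2 <- cohort_table(df, variant_ids = "v1")
  rescaled <- linear_assoc(co2, "v1")
  expect_equal(rescaled$beta, base$beta, tolerance = 1e-10)
  expect_equal(rescaled$se, base$se, tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear column", {
  co <- make_micro_cohort()
  df <- as.data.frame(co)
  df$age2 <- df$age * 2
  co2 <- cohort_table(df, variant_ids = "v1")
  expect_error(linear_assoc(co2, "v1", covariates = c("sex", "age", "age2")),
               "age2")
})

test_that("logistic association agrees with a Newton-Raphson oracle to 1e-6", {
  set.seed(55)
  n <- 500
  g <- rbinom(n, 2, 0.3)
  sex <- rbinom(n, 1, 0.5)
  age <- runif(n, 40, 69)
  y <- rbinom(n, 1, plogis(-1 + 0.4 * g + 0.3 * sex + 0.01 * (age - 55)))
  co <- cohort_table(data.frame(subject_id = paste0("s", 1:n), v1 = g,
                                sex = sex, age = age, y_bin = y),
                     variant_ids = "v1")
  res <- logistic_assoc(co, "v1")
  X <- model.matrix(~ v1 + sex + age, as.data.frame(co))
  o <- logit_oracle(X, y)
  expect_equal(res$beta, o$beta[2], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(res$se, o$se[2], tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(is.na(res$flag))
  expect_error(logistic_assoc(
    cohort_table(data.frame(subject_id = "s", v1 = 1, y_bin = 0),
                 variant_ids = "v1"), "v1"), "both classes")
})

test_that("a simulated OR of 1.5 is recovered within 2 SE at n = 20000", {
  set.seed(77)
  n <- 20000
  g <- rbinom(n, 2, 0.3)
  sex <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-2 + log(1.5) * g + 0.2 * sex))
  co <- cohort_table(data.frame(subject_id = paste0("s", 1:n), v1 = g,
                                sex = sex, y_bin = y), variant_ids = "v1")
  res <- logistic_assoc(co, "v1", covariates = "sex")
  expect_lt(abs(res$beta - log(1.5)), 2 * res$se)
})

test_that("separation is flagged, not fatal", {
  n <- 60
  g <- rep(0:2, each = 20)
  y <- as.integer(g >= 1)
  co <- cohort_table(data.frame(subject_id = paste0("s", 1:n), v1 = g,
                                y_bin = y), variant_ids = "v1")
  res <- suppressWarnings(logistic_assoc(co, "v1", covariates = character(0)))
  expect_equal(res$flag, "separation")
})

test_that("under a permuted outcome, association p-values are uniform", {
  set.seed(99)
  n <- 300
  g <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, 0.3)
  ps <- replicate(200, {
    co <- cohort_table(data.frame(subject_id = paste0("s", 1:n), v1 = g,
                                  y_bin = sample(y)), variant_ids = "v1")
    logistic_assoc(co, "v1", covariates = character(0))$p_value
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Cox association maximises the hand-enumerated partial likelihood", {
  time <- c(1, 2, 3, 4, 5)
  event <- c(1, 1, 0, 1, 0)
  x <- c(2, 0, 1, 1, 0)
  co <- cohort_table(data.frame(subject_id = paste0("s", 1:5), v1 = x,
                                time = time, event = event,
                                enrol_age = rep(0, 5)), variant_ids = "v1")
  res <- cox_assoc(co, "v1", covariates = character(0))
  # independent 1-d maximisation of the explicit partial likelihood
  opt <- optimize(function(b) -cox_partial_loglik(b, time, event, x),
                  c(-5, 5), tol = 1e-10)
  expect_equal(res$beta, opt$minimum, tolerance = 1e-5)
  # and the score at the estimate is ~ 0
  eps <- 1e-5
  score <- (cox_partial_loglik(res$beta + eps, time, event, x) -
            cox_partial_loglik(res$beta - eps, time, event, x)) / (2 * eps)
  expect_lt(abs(score), 1e-4)
})

test_that("a true hazard ratio of 2 is recovered within 2 SE", {
  set.seed(21)
  n <- 5000
  g <- rbinom(n, 1, 0.5)
  t_event <- rexp(n, 0.05 * exp(log(2) * g))
  co <- cohort_table(data.frame(subject_id = paste0("s", 1:n), v1 = g,
                                time = t_event, event = 1L,
                                enrol_age = rep(0, n)), variant_ids = "v1")
  res <- cox_assoc(co, "v1", covariates = character(0))
  expect_lt(abs(res$beta - log(2)), 2 * res$se)
})

test_that("constant dosage in a Cox model is a rank error; exclusions are counted", {
  n <- 100
  set.seed(4)
  co <- cohort_table(data.frame(subject_id = paste0("s", 1:n), v1 = rep(1, n),
                                time = rexp(n, 0.1), event = 1L,
                                enrol_age = rep(0, n)), variant_ids = "v1")
  expect_error(cox_assoc(co, "v1", covariates = character(0)), "v1")
  # enrolment origin with prevalent exclusion
  g <- rbinom(n, 2, 0.3)
  enrol <- runif(n, 40, 69)
  time <- enrol + runif(n, -10, 20)   # some events precede enrolment
  co2 <- cohort_table(data.frame(subject_id = paste0("s", 1:n), v1 = g,
                                 time = time, event = 1L, enrol_age = enrol),
                      variant_ids = "v1")
  res <- cox_assoc(co2, "v1", origin = "enrolment", exclude_prevalent = TRUE,
                   covariates = character(0))
  excl <- attr(res, "n_excluded")
  expect_equal(unname(excl["prevalent"]), sum(time <= enrol))
  expect_equal(res$n, n - sum(time <= enrol))
})

test_that("for rare outcomes over short follow-up, log-OR and log-HR nearly agree", {
  cfg <- sim_config(seed = 33, n_subjects = 8000L, true_theta = 0.4,
                    case_fraction = 0.05)
  ld <- simulate_region_ld(cfg)
  co <- simulate_individual_cohort(cfg, ld)
  v <- cfg$variant_ids[cfg$causal_idx[2]]
  # "ever had the event" as the categorical outcome vs time-to-event Cox:
  # for a rare outcome the log-OR and log-HR coincide closely
  lg <- logistic_assoc(co, v, outcome = "event")
  cx <- cox_assoc(co, v)
  expect_lt(abs(lg$beta - cx$beta), 0.5 * lg$se)
})

test_that("association rows convert to MR-consumable summary statistics", {
  co <- make_micro_cohort()
  res <- linear_assoc(co, "v1")
  res$variant_id <- "rs7220711"   # dosage column name -> rsID for reporting
  info <- data.frame(variant_id = "rs7220711", chromosome = "17",
                     position = 43712597L, effect_allele = "G",
                     other_allele = "A", eaf = 0.3, stringsAsFactors = FALSE)
  s <- assoc_to_sumstats(res, info, trait = "biomarker", effect_scale = "sd")
  expect_s3_class(s, "sumstats")
  expect_equal(s$beta, res$beta)
  expect_equal(s$se, res$se)
  expect_equal(attr(s, "effect_scale"), "sd")
  expect_equal(unname(qc_filter(s)$report[["n_kept"]]), 1L)
  expect_error(assoc_to_sumstats(res, info[0, ], "t"), "metadata")
})
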