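#' Published sclerostin instrument effects
#'
#' The two cis-instruments for circulating sclerostin selected from the
#' fixed-effects meta-analysis of the INTERVAL, deCODE and Fenland GWAS
#' (49,568 Europeans), as published: effect sizes in SD units of
#' sclerostin per effect allele, with the printed heterogeneity statistics
#' and F-statistics. Positions are GRCh38.
#'
#' @return A data frame with one row per instrument: `variant_id`,
#'   `chromosome`, `position`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `p_value`, `n`, `I2`, `Q`, `q_p_value`, `f_stat`.
#' @export
sclerostin_instruments <- function() {
  data.frame(
    variant_id = c("rs7220711", "rs66838809"),
    chromosome = "17",
    position = c(43712597L, 43721253L),
    effect_allele = c("G", "A"),
    other_allele = c("A", "G"),
    eaf = c(0.33, 0.09),
    beta = c(-0.04, -0.07),
    se = c(0.01, 0.01),
    p_value = c(1.11e-9, 7.76e-9),
    n = c(49372L, 49372L),
    I2 = c(0.64, 0.74),
    Q = c(5.56, 7.61),
    q_p_value = c(0.06, 0.02),
    f_stat = c(37.18, 33.38),
    stringsAsFactors = FALSE)
}

#' Published per-SNP effects of the sclerostin instruments on the outcomes
#'
#' Effects of the two sclerostin instruments on every outcome, as
#' published: GWAS-sourced positive controls (heel bone mineral density,
#' hip fracture), GWAS cardiovascular events, risk factors and biomarkers,
#' and the UK Biobank individual-level analyses (linear / logistic / Cox).
#' All estimates are reported with respect to the effect allele; `type`
#' distinguishes `Beta` (linear scale) from `OR`/`HR` (ratio scale, as
#' printed; use `log(estimate)` for the additive scale).
#'
#' @return A data frame with columns `outcome`, `source`, `variant_id`,
#'   `n`, `effect_allele`, `eaf`, `type`, `estimate`, `se`, `p_value`.
#' @export
sclerostin_outcomes <- function() {
  txt <- "
outcome|source|variant_id|n|effect_allele|eaf|type|estimate|se|p_value
Heel bone mineral density|GWAS|rs7220711|426824|G|0.39|Beta|0.039|0.002|3.90e-70
Heel bone mineral density|GWAS|rs66838809|426824|A|0.08|Beta|0.073|0.003|1.00e-85
Hip fracture|GWAS|rs7220711|735354|G|0.42|OR|0.932|0.015|2.35e-06
Hip fracture|GWAS|rs66838809|735354|A|0.09|OR|0.866|0.031|2.59e-06
LDL cholesterol|GWAS|rs7220711|1226841|G|0.39|Beta|0.001|0.001|4.52e-01
LDL cholesterol|GWAS|rs66838809|1228508|A|0.08|Beta|0.001|0.003|8.39e-01
HDL cholesterol|GWAS|rs7220711|1244439|G|0.39|Beta|-0.007|0.001|9.63e-07
HDL cholesterol|GWAS|rs66838809|1241791|A|0.08|Beta|-0.007|0.003|5.00e-03
Fasting glucose|GWAS|rs7220711|177305|G|0.42|Beta|0|0.002|7.42e-01
Fasting glucose|GWAS|rs66838809|178455|A|0.08|Beta|0.006|0.004|7.27e-02
HbA1c|GWAS|rs7220711|132400|G|0.42|Beta|0.001|0.001|4.70e-01
HbA1c|GWAS|rs66838809|132400|A|0.08|Beta|0.001|0.003|9.81e-01
Coronary artery disease|GWAS|rs7220711|1143140|G|0.39|OR|1.011|0.005|3.38e-02
Coronary artery disease|GWAS|rs66838809|1152860|A|0.08|OR|1.011|0.009|2.62e-01
Myocardial infarction|GWAS|rs7220711|638717|G|0.4|OR|1.01|0.008|1.74e-01
Myocardial infarction|GWAS|rs66838809|638717|A|0.08|OR|1.028|0.015|6.70e-02
Ischaemic stroke|GWAS|rs7220711|1847683|G|0.41|OR|1.012|0.007|1.02e-01
Ischaemic stroke|GWAS|rs66838809|1847683|A|0.08|OR|0.996|0.014|7.78e-01
Hypertension|GWAS|rs7220711|462933|G|0.39|OR|1.001|0.001|5.40e-01
Hypertension|GWAS|rs66838809|462933|A|0.08|OR|1.003|0.002|7.50e-02
Type 2 diabetes mellitus|GWAS|rs7220711|933970|G|0.39|OR|1.019|0.007|4.58e-03
Type 2 diabetes mellitus|GWAS|rs66838809|933970|A|0.08|OR|1.017|0.012|1.46e-01
Cholesterol|UK Biobank|rs7220711|256586|G|0.38|Beta|0.002|0.003|5.45e-01
Cholesterol|UK Biobank|rs66838809|256167|A|0.08|Beta|0.004|0.005|5.00e-01
LDL cholesterol|UK Biobank|rs7220711|256105|G|0.38|Beta|0.002|0.003|4.14e-01
LDL cholesterol|UK Biobank|rs66838809|255690|A|0.08|Beta|0.005|0.005|3.77e-01
HDL cholesterol|UK Biobank|rs7220711|234948|G|0.38|Beta|-0.006|0.003|2.66e-02
HDL cholesterol|UK Biobank|rs66838809|234554|A|0.08|Beta|-0.007|0.005|1.69e-01
Triglycerides|UK Biobank|rs7220711|256375|G|0.38|Beta|0.012|0.003|3.00e-05
Triglycerides|UK Biobank|rs66838809|255955|A|0.08|Beta|0.016|0.005|2.31e-03
Apolipoprotein-A|UK Biobank|rs7220711|233627|G|0.38|Beta|-0.004|0.003|1.98e-01
Apolipoprotein-A|UK Biobank|rs66838809|233244|A|0.08|Beta|-0.004|0.005|4.40e-01
Apolipoprotein-B|UK Biobank|rs7220711|255322|G|0.38|Beta|0.004|0.003|1.36e-01
Apolipoprotein-B|UK Biobank|rs66838809|254901|A|0.08|Beta|0.01|0.005|6.20e-02
C-Reactive protein|UK Biobank|rs7220711|256040|G|0.38|Beta|0|0.003|1.00e+00
C-Reactive protein|UK Biobank|rs66838809|255625|A|0.08|Beta|0.004|0.005|4.77e-01
Lipoprotein (a)|UK Biobank|rs7220711|203995|G|0.38|Beta|-0.001|0.003|8.41e-01
Lipoprotein (a)|UK Biobank|rs66838809|203682|A|0.08|Beta|-0.004|0.006|4.55e-01
Glucose|UK Biobank|rs7220711|234795|G|0.38|Beta|0.003|0.003|2.94e-01
Glucose|UK Biobank|rs66838809|234409|A|0.08|Beta|0.008|0.005|1.43e-01
HbA1c|UK Biobank|rs7220711|256419|G|0.38|Beta|-0.001|0.003|7.50e-01
HbA1c|UK Biobank|rs66838809|255984|A|0.08|Beta|0.003|0.005|5.42e-01
Coronary artery disease|UK Biobank (categorical outcome)|rs7220711|269168|G|0.38|OR|1.027|0.012|2.79e-02
Coronary artery disease|UK Biobank (categorical outcome)|rs66838809|268712|A|0.08|OR|1.039|0.022|8.68e-02
Myocardial infarction|UK Biobank (categorical outcome)|rs7220711|269168|G|0.38|OR|1.028|0.015|5.71e-02
Myocardial infarction|UK Biobank (categorical outcome)|rs66838809|268712|A|0.08|OR|0.983|0.027|5.34e-01
Ischaemic stroke|UK Biobank (categorical outcome)|rs7220711|269168|G|0.38|OR|1.003|0.024|9.11e-01
Ischaemic stroke|UK Biobank (categorical outcome)|rs66838809|268712|A|0.08|OR|1.036|0.044|4.18e-01
Hypertension|UK Biobank (categorical outcome)|rs7220711|269168|G|0.38|OR|1.004|0.006|4.84e-01
Hypertension|UK Biobank (categorical outcome)|rs66838809|268712|A|0.08|OR|1.018|0.011|1.18e-01
Type 2 diabetes|UK Biobank (categorical outcome)|rs7220711|269168|G|0.38|OR|1.018|0.011|8.82e-02
Type 2 diabetes|UK Biobank (categorical outcome)|rs66838809|268712|A|0.08|OR|1.038|0.019|5.14e-02
Coronary artery disease|UK Biobank (survival outcome)|rs7220711|269168|G|0.38|HR|1.025|0.012|3.16e-02
Coronary artery disease|UK Biobank (survival outcome)|rs66838809|268712|A|0.08|HR|1.036|0.021|9.14e-02
Myocardial infarction|UK Biobank (survival outcome)|rs7220711|269065|G|0.38|HR|1.027|0.014|5.60e-02
Myocardial infarction|UK Biobank (survival outcome)|rs66838809|268608|A|0.08|HR|0.984|0.026|5.49e-01
Ischaemic stroke|UK Biobank (survival outcome)|rs7220711|269168|G|0.38|HR|1.002|0.024|9.21e-01
Ischaemic stroke|UK Biobank (survival outcome)|rs66838809|268712|A|0.08|HR|1.037|0.043|4.02e-01
Hypertension|UK Biobank (survival outcome)|rs7220711|264485|G|0.38|HR|1.003|0.005|5.48e-01
Hypertension|UK Biobank (survival outcome)|rs66838809|264045|A|0.08|HR|1.012|0.009|1.71e-01
Type 2 diabetes|UK Biobank (survival outcome)|rs7220711|259515|G|0.38|HR|1.019|0.014|1.67e-01
Type 2 diabetes|UK Biobank (survival outcome)|rs66838809|259093|A|0.08|HR|1.041|0.025|1.02e-01"
  utils::read.table(text = txt, header = TRUE, sep = "|",
                    stringsAsFactors = FALSE)
}

#' Synthetic LD between the two published sclerostin instruments
#'
#' The signed correlation between rs7220711 and rs66838809 used by the
#' published analysis comes from a 1000 Genomes European reference panel
#' and is not printed; this is a synthetic stand-in with a configurable
#' signed correlation (default 0.25, a mid-range value consistent with the
#' instruments having survived pruning at r^2 <= 0.3, i.e. |r| <= 0.55).
#'
#' @param r signed correlation between the two instruments.
#' @return A 2x2 [ld_matrix].
#' @export
sclerostin_instrument_ld_synthetic <- function(r = 0.25) {
  stopifnot(abs(r) <= 1)
  ld_matrix(matrix(c(1, r, r, 1), 2, 2),
            variant_ids = c("rs7220711", "rs66838809"))
}

#' Harmonised set for one published outcome
#'
#' Pairs the published instrument-exposure effects
#' ([sclerostin_instruments()]) with the published instrument-outcome
#' effects ([sclerostin_outcomes()]) for one outcome/source, converting
#' printed ORs/HRs to the log scale.
#'
#' @param outcome outcome name as printed (e.g. `"Hip fracture"`).
#' @param source data source as printed (default `"GWAS"`).
#' @return A `harmonised_set` ready for [mr_fit()].
#' @export
sclerostin_harmonised <- function(outcome, source = "GWAS") {
  instruments <- sclerostin_instruments()
  out <- sclerostin_outcomes()
  rows <- out[out$outcome == outcome & out$source == source, ]
  if (nrow(rows) == 0L) {
    stop("no published rows for outcome ", outcome, " / source ", source,
         call. = FALSE)
  }
  idx <- match(rows$variant_id, instruments$variant_id)
  stopifnot(!anyNA(idx))
  ratio <- rows$type[1] %in% c("OR", "HR")
  beta_y <- if (ratio) log(rows$estimate) else rows$estimate
  harmonised_set(rows$variant_id,
                 beta_x = instruments$beta[idx], se_x = instruments$se[idx],
                 beta_y = beta_y, se_y = rows$se,
                 outcome_scale = switch(rows$type[1], OR = "log_or",
                                        HR = "log_hr", Beta = "sd"),
                 outcome_trait = outcome, exposure_trait = "sclerostin")
}
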