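test_that("read_sumstats resolves header synonyms and preserves row order", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "MarkerName\tAllele1\tAllele2\tFreq1\tEffect\tStdErr\tP-value\tN",
    "rs1\tG\tA\t0.33\t-0.04\t0.01\t1.11e-9\t49372",
    "rs2\tA\tG\t0.09\t-0.07\t0.01\t7.76e-9\t49372",
    "rs3\tC\tT\t0.50\t0.01\t0.02\t0.6\t49372"), path)
  s <- read_sumstats(path)
  expect_s3_class(s, "sumstats")
  expect_equal(nrow(s), 3L)
  expect_equal(s$variant_id, c("rs1", "rs2", "rs3"))
  expect_equal(s$beta, c(-0.04, -0.07, 0.01))
  expect_equal(s$eaf[2], 0.09)
})

test_that("read_sumstats fails naming the missing column; empty file fatal", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SNP\tA1\tA2\tFreq\tBeta\tP\tN",
               "rs1\tG\tA\t0.3\t0.1\t0.5\t100"), path)
  expect_error(read_sumstats(path), "se")
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines("SNP\tA1\tA2\tFreq\tBeta\tSE\tP\tN", empty)
  expect_error(read_sumstats(empty), "empty")
})

test_that("read_sumstats routes unparseable numerics to QC, not a crash", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("SNP\tA1\tA2\tFreq\tBeta\tSE\tP\tN",
               "rs1\tG\tA\t0.3\tnot_a_number\t0.01\t0.5\t100",
               "rs2\tA\tG\t0.2\t0.1\t0.01\t0.5\t100"), path)
  s <- read_sumstats(path)
  expect_equal(nrow(s), 2L)
  qc <- qc_filter(s)
  expect_equal(unname(qc$report[["unparseable"]]), 1L)
  expect_equal(qc$stats$variant_id, "rs2")
})

test_that("qc_filter removes one record per rule in order, and is idempotent", {
  bad <- data.frame(
    variant_id = c("rsA,alt", "badid!", "rs10", "rs11", "rs12", "rs13", "rs14",
                   "rs1", "rs2"),
    chromosome = "17", position = 1:9,
    effect_allele = c("A,C", "G", "G", "D", "G", "G", "G", "G", "A"),
    other_allele = c("G", "A", "G", "I", "A", "A", "A", "A", "G"),
    eaf = c(0.3, 0.3, 0.3, 0.3, 1.2, 0.3, 0.3, 0.33, 0.09),
    beta = -0.04, se = c(rep(0.01, 6), -1, 0.01, 0.01),
    p_value = c(rep(0.5, 5), 1.5, 0.5, 0.5, 0.5),
    n = 100, stringsAsFactors = FALSE)
  s <- sumstats(bad, trait = "t")
  qc <- qc_filter(s)
  expect_equal(nrow(qc$stats), 2L)
  expect_equal(unname(qc$report[c("multiallelic", "invalid_id", "same_alleles",
                                  "indel_allele", "eaf_bounds", "p_bounds",
                                  "se_invalid")]),
               rep(1L, 7))
  # idempotence
  qc2 <- qc_filter(qc$stats)
  expect_equal(as.data.frame(qc2$stats), as.data.frame(qc$stats))
  expect_equal(unname(qc2$report[["n_kept"]]), unname(qc2$report[["n_input"]]))
})

test_that("duplicate rsID with two distinct allele pairs is removed as multiallelic", {
  s <- sumstats(data.frame(
    variant_id = c("rs5", "rs5", "rs6"),
    chromosome = "17", position = c(1L, 1L, 2L),
    effect_allele = c("G", "G", "A"), other_allele = c("A", "C", "G"),
    eaf = 0.3, beta = 0.1, se = 0.01, p_value = 0.5, n = 100))
  qc <- qc_filter(s)
  expect_equal(unname(qc$report[["multiallelic"]]), 2L)
  expect_equal(qc$stats$variant_id, "rs6")
})

test_that("all-clean input passes qc_filter unchanged with zero removals", {
  s <- make_tiny_sumstats()
  qc <- qc_filter(s)
  expect_equal(as.data.frame(qc$stats), as.data.frame(s))
  expect_equal(sum(qc$report[seq_len(8)]), 0L)
})

test_that("standardise_alleles handles same, swapped and strand-flipped pairs", {
  s <- make_tiny_sumstats()
  # reference equal to record orientation: unchanged
  same <- standardise_alleles(s, list(rs1 = c("G", "A"), rs2 = c("A", "G"),
                                      rs3 = c("C", "T")))
  expect_equal(as.data.frame(same$stats), as.data.frame(s))
  expect_equal(same$n_dropped, 0L)
  # swapped: beta sign flips, eaf complements
  sw <- standardise_alleles(s, list(rs1 = c("A", "G"), rs2 = c("A", "G"),
                                    rs3 = c("C", "T")))
  expect_equal(sw$stats$beta[1], 0.04)
  expect_equal(sw$stats$eaf[1], 0.67)
  expect_equal(sw$stats$beta[2], -0.07)  # untouched record
  # strand complement: C/T record against G/A reference, beta unchanged
  str <- standardise_alleles(
    sumstats(data.frame(variant_id = "rs9", chromosome = "1", position = 1L,
                        effect_allele = "C", other_allele = "T", eaf = 0.2,
                        beta = 0.5, se = 0.1, p_value = 0.01, n = 10)),
    list(rs9 = c("G", "A")))
  expect_equal(str$stats$beta, 0.5)
  expect_equal(str$stats$effect_allele, "G")
  # irreconcilable pair dropped and counted
  drop <- standardise_alleles(s, list(rs1 = c("C", "A"), rs2 = c("A", "G"),
                                      rs3 = c("C", "T")))
  expect_equal(drop$n_dropped, 1L)
  expect_false("rs1" %in% drop$stats$variant_id)
})

test_that("standardising to a reference and back recovers the input exactly", {
  s <- make_tiny_sumstats()
  flipped_ref <- list(rs1 = c("A", "G"), rs2 = c("G", "A"), rs3 = c("T", "C"))
  original_ref <- list(rs1 = c("G", "A"), rs2 = c("A", "G"), rs3 = c("C", "T"))
  there <- standardise_alleles(s, flipped_ref)$stats
  back <- standardise_alleles(there, original_ref)$stats
  expect_equal(as.data.frame(back), as.data.frame(s))
})

test_that("cis_filter keeps the closed window and partitions the input", {
  s <- sumstats(data.frame(
    variant_id = paste0("rs", 1:4), chromosome = "17",
    position = c(43712597L, 42000000L, 43253738L, 44258791L),
    effect_allele = "G", other_allele = "A", eaf = 0.3, beta = 0, se = 0.01,
    p_value = 0.5, n = 10))
  # SOST-scale region: gene +/- 500 kb spans 43,253,738-44,258,791
  kept <- cis_filter(s, "17", 43753738L, 43758791L, flank = 500000L)
  expect_true("rs1" %in% kept$variant_id)          # inside
  expect_false("rs2" %in% kept$variant_id)         # 42 Mb: outside
  expect_true(all(c("rs3", "rs4") %in% kept$variant_id))  # closed boundaries
  expect_equal(nrow(kept) + 1L, nrow(s))
  # chromosome mismatch excluded with a warning
  s2 <- s
  s2$chromosome <- c("17", "17", "16", "17")
  expect_warning(k2 <- cis_filter(s2, "17", 43753738L, 43758791L, 500000L),
                 "chromosome")
  expect_false("rs3" %in% k2$variant_id)
})

test_that("harmonise_pairs orients both traits to LD alleles in LD order", {
  ex <- make_tiny_sumstats()
  # outcome recorded on opposite allele for rs1: log-OR sign must flip
  ou <- sumstats(data.frame(
    variant_id = c("rs2", "rs1"), chromosome = "17",
    position = c(43721253L, 43712597L),
    effect_allele = c("A", "A"), other_allele = c("G", "G"),
    eaf = c(0.09, 0.67), beta = c(log(0.866), -log(0.932)), se = c(0.031, 0.015),
    p_value = c(2.59e-6, 2.35e-6), n = 735354),
    trait = "hip fracture", effect_scale = "log_or")
  alleles <- list(rs1 = c("G", "A"), rs2 = c("A", "G"))
  h <- harmonise_pairs(ex, ou, alleles)
  expect_equal(h$variant_ids, c("rs1", "rs2"))  # LD-matrix order
  expect_equal(h$beta_y[1], log(0.932))         # flipped back to G
  expect_equal(h$beta_y[2], log(0.866))
  expect_equal(h$beta_x, c(-0.04, -0.07))
})

test_that("identity harmonisation is an identity; no overlap is fatal", {
  ex <- make_tiny_sumstats()
  alleles <- list(rs1 = c("G", "A"), rs2 = c("A", "G"))
  h <- harmonise_pairs(ex, ex, alleles)
  expect_equal(h$beta_x, h$beta_y)
  empty_alleles <- list(rs99 = c("G", "A"))
  expect_error(harmonise_pairs(ex, ex, empty_alleles), "no harmonisable")
})

test_that("ambiguous palindromic variants are dropped, informative ones aligned", {
  pal <- function(eaf_x, eaf_y, beta_y = 0.2) {
    ex <- sumstats(data.frame(variant_id = "rs7", chromosome = "1", position = 1L,
                              effect_allele = "A", other_allele = "T",
                              eaf = eaf_x, beta = 0.1, se = 0.01, p_value = 1e-8,
                              n = 100))
    ou <- sumstats(data.frame(variant_id = "rs7", chromosome = "1", position = 1L,
                              effect_allele = "A", other_allele = "T",
                              eaf = eaf_y, beta = beta_y, se = 0.05, p_value = 1e-4,
                              n = 100))
    harmonise_pairs(ex, ou, list(rs7 = c("A", "T")))
  }
  expect_warning(expect_error(pal(0.50, 0.2), "no harmonisable"), "palindromic")
  concordant <- pal(0.2, 0.25)
  expect_equal(concordant$beta_y, 0.2)
  discordant <- pal(0.2, 0.75)   # frequencies disagree: outcome strand flipped
  expect_equal(discordant$beta_y, -0.2)
  expect_equal(discordant$eaf_y, 0.25)
})
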