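#' GWAS summary statistics container
#'
#' A `sumstats` object is a data frame with one row per variant and the
#' columns `variant_id`, `chromosome`, `position`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `p_value`, `n`, plus the attributes
#' `trait` (trait name), `effect_scale` (one of `"sd"`, `"unit"`,
#' `"log_or"`, `"log_hr"`) and `provenance` (free text: cohort, genome
#' build). Effect sizes are always stored on the additive scale, i.e.
#' log-odds / log-hazard for binary traits, per copy of `effect_allele`.
#'
#' @param x data frame carrying the canonical columns.
#' @param trait trait name.
#' @param effect_scale effect-size scale, one of `"sd"`, `"unit"`,
#'   `"log_or"`, `"log_hr"`.
#' @param provenance free-text provenance (cohort name, genome build).
#' @return A `sumstats` object.
#' @export
sumstats <- function(x, trait = "trait", effect_scale = c("sd", "unit", "log_or", "log_hr"),
                     provenance = "") {
  effect_scale <- match.arg(effect_scale)
  required <- c("variant_id", "chromosome", "position", "effect_allele",
                "other_allele", "eaf", "beta", "se", "p_value", "n")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x)[required]
  x$variant_id <- as.character(x$variant_id)
  x$chromosome <- sub("^chr", "", as.character(x$chromosome))
  x$position <- as.integer(x$position)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("eaf", "beta", "se", "p_value")) x[[col]] <- as.numeric(x[[col]])
  x$n <- as.numeric(x$n)
  rownames(x) <- NULL
  structure(x,
            trait = trait, effect_scale = effect_scale, provenance = provenance,
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s scale)\n",
              attr(x, "trait"), attr(x, "effect_scale")))
  if (nzchar(attr(x, "provenance"))) cat("  provenance:", attr(x, "provenance"), "\n")
  cat(sprintf("  %d variant(s)\n", nrow(x)))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}

# Column-synonym table, frozen: canonical name -> accepted headers
# (matched case-insensitively after stripping non-alphanumerics).
.sumstats_synonyms <- list(
  variant_id    = c("variant_id", "snp", "rsid", "rs_id", "markername", "marker", "id", "variant"),
  chromosome    = c("chromosome", "chr", "chrom", "hg38_chr"),
  position      = c("position", "pos", "bp", "base_pair_location", "hg38_pos"),
  effect_allele = c("effect_allele", "allele1", "a1", "ea", "alt", "tested_allele"),
  other_allele  = c("other_allele", "allele2", "a2", "oa", "ref", "reference_allele", "nea", "noneffect_allele"),
  eaf           = c("eaf", "freq1", "af", "effect_allele_frequency", "maf", "freq", "eaf_a1"),
  beta          = c("beta", "b", "effect", "est", "estimate"),
  se            = c("se", "stderr", "standard_error", "sebeta"),
  p_value       = c("p_value", "p", "pval", "pvalue"),
  n             = c("n", "samplesize", "sample_size", "neff", "n_total")
)

.norm_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads tab- or whitespace-delimited text with a header row (gzip input is
#' accepted) and resolves column names through a frozen synonym table
#' (e.g. `SNP`/`rsid`/`MarkerName` map to `variant_id`, `Effect`/`b` to
#' `beta`). Unknown extra columns are ignored. Rows whose numeric fields do
#' not parse are kept, flagged with `NA`, and removed (and counted) by
#' [qc_filter()] rather than causing a failure here.
#'
#' @param path file path.
#' @param column_map optional named character vector overriding synonym
#'   resolution, e.g. `c(beta = "my_effect_column")`.
#' @inheritParams sumstats
#' @return A [sumstats] object, rows in file order.
#' @export
read_sumstats <- function(path, column_map = NULL, trait = "trait",
                          effect_scale = "sd", provenance = path) {
  raw <- utils::read.table(path, header = TRUE, sep = "", quote = "\"",
                           colClasses = "character", comment.char = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path, call. = FALSE)
  norm <- .norm_header(names(raw))
  # chromosome/position are optional (classic meta-analysis outputs omit
  # them); every other canonical column is mandatory
  optional <- c("chromosome", "position")
  resolved <- list()
  for (canon in names(.sumstats_synonyms)) {
    src <- NULL
    if (!is.null(column_map) && canon %in% names(column_map)) {
      src <- match(.norm_header(column_map[[canon]]), norm)
    } else {
      hits <- match(.sumstats_synonyms[[canon]], norm)
      hits <- hits[!is.na(hits)]
      if (length(hits) > 0L) src <- hits[1L]
    }
    if (is.null(src) || is.na(src)) {
      if (canon %in% optional) {
        resolved[[canon]] <- rep(NA_character_, nrow(raw))
        next
      }
      stop("missing mandatory column after synonym resolution: ", canon,
           call. = FALSE)
    }
    resolved[[canon]] <- raw[[src]]
  }
  out <- as.data.frame(resolved, stringsAsFactors = FALSE)
  suppress_num <- function(v) suppressWarnings(as.numeric(v))
  out$position <- suppress_num(out$position)
  out$eaf <- suppress_num(out$eaf)
  out$beta <- suppress_num(out$beta)
  out$se <- suppress_num(out$se)
  out$p_value <- suppress_num(out$p_value)
  out$n <- suppress_num(out$n)
  sumstats(out, trait = trait, effect_scale = effect_scale, provenance = provenance)
}

#' Write summary statistics to tab-delimited text
#'
#' @param x a [sumstats] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Quality-control filter for summary statistics
#'
#' Removes records failing any of seven rules, applied in a fixed order with
#' per-rule counts; a record is tallied under the first rule it violates.
#' The rules: (1) multiallelic variants (one `variant_id` with more than one
#' allele pair, or comma-listed alleles); (2) invalid identifiers (empty, or
#' neither `rs<digits>` nor `chr:pos[...]`); (3) `effect_allele` equal to
#' `other_allele`; (4) indel codes `D`/`I` (or any non-ACGT allele);
#' (5) allele frequency at or outside (0, 1); (6) p-value outside [0, 1];
#' (7) non-finite or non-positive standard error. Records with unparseable
#' numeric fields (`NA` after read) are removed under an eighth counter,
#' `unparseable`. Survivors are returned unchanged, in order.
#'
#' @param x a [sumstats] object.
#' @return A list with elements `stats` (the filtered [sumstats]) and
#'   `report` (named integer vector of per-rule removal counts, plus
#'   `n_input`/`n_kept`).
#' @export
qc_filter <- function(x) {
  stopifnot(inherits(x, "sumstats"))
  df <- as.data.frame(x)
  n_in <- nrow(df)
  removed <- rep(NA_character_, n_in)
  mark <- function(bad, rule) {
    bad <- bad & is.na(removed)
    removed[bad] <<- rule
  }
  pair <- paste(df$effect_allele, df$other_allele)
  n_pairs <- tapply(pair, df$variant_id, function(p) length(unique(p)))
  multi_dup <- n_pairs[df$variant_id] > 1
  multi_comma <- grepl(",", df$effect_allele) | grepl(",", df$other_allele)
  mark(multi_dup | multi_comma, "multiallelic")
  valid_id <- grepl("^rs[0-9]+$", df$variant_id) |
    grepl("^(chr)?[0-9XYM]+:[0-9]+(:[ACGT]+:[ACGT]+)?$", df$variant_id, ignore.case = TRUE)
  mark(is.na(df$variant_id) | !nzchar(df$variant_id) | !valid_id, "invalid_id")
  mark(!is.na(df$effect_allele) & df$effect_allele == df$other_allele, "same_alleles")
  nonacgt <- !(df$effect_allele %in% c("A", "C", "G", "T")) |
    !(df$other_allele %in% c("A", "C", "G", "T"))
  mark(nonacgt, "indel_allele")
  mark(!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1), "eaf_bounds")
  mark(!is.na(df$p_value) & (df$p_value < 0 | df$p_value > 1), "p_bounds")
  mark(!is.na(df$se) & (!is.finite(df$se) | df$se <= 0), "se_invalid")
  numeric_na <- is.na(df$eaf) | is.na(df$beta) | is.na(df$se) | is.na(df$p_value)
  mark(numeric_na, "unparseable")
  rules <- c("multiallelic", "invalid_id", "same_alleles", "indel_allele",
             "eaf_bounds", "p_bounds", "se_invalid", "unparseable")
  report <- vapply(rules, function(r) sum(removed == r, na.rm = TRUE), integer(1))
  keep <- is.na(removed)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- c(report, n_input = n_in, n_kept = sum(keep))
  list(stats = sumstats(out, trait = attr(x, "trait"),
                        effect_scale = attr(x, "effect_scale"),
                        provenance = attr(x, "provenance")),
       report = report)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a1, a2) .complement[a1] == a2

#' Standardise effect alleles to a reference orientation
#'
#' Re-orients every record to the allele pair given in `reference`. A record
#' already in reference orientation is unchanged; a swapped record has its
#' `beta` sign flipped and `eaf` replaced by `1 - eaf`; strand-complemented
#' pairs (e.g. C/T against reference G/A) are complemented first and then
#' aligned. Records whose alleles cannot be reconciled with the reference,
#' or that are missing from it, are dropped and counted.
#'
#' @param x a [sumstats] object.
#' @param reference named list (or list-like) mapping `variant_id` to a
#'   length-2 character vector `c(effect, other)`.
#' @return A list with `stats` (re-oriented [sumstats]) and `n_dropped`.
#' @export
standardise_alleles <- function(x, reference) {
  stopifnot(inherits(x, "sumstats"))
  df <- as.data.frame(x)
  ref_e <- vapply(reference, `[`, character(1), 1L)
  ref_o <- vapply(reference, `[`, character(1), 2L)
  idx <- match(df$variant_id, names(reference))
  r1 <- ref_e[idx]
  r2 <- ref_o[idx]
  a1 <- df$effect_allele
  a2 <- df$other_allele
  ori <- .match_orientation_vec(a1, a2, r1, r2)
  keep <- !is.na(idx) & !is.na(ori)
  swap <- keep & ori == "swap"
  df$beta[swap] <- -df$beta[swap]
  df$eaf[swap] <- 1 - df$eaf[swap]
  df$effect_allele[keep] <- r1[keep]
  df$other_allele[keep] <- r2[keep]
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(stats = sumstats(out, trait = attr(x, "trait"),
                        effect_scale = attr(x, "effect_scale"),
                        provenance = attr(x, "provenance")),
       n_dropped = sum(!keep))
}

# Orientation of allele pair (a1, a2) relative to reference (r1, r2):
# "same" (possibly via strand complement), "swap", or NA if irreconcilable.
# Exact letter match takes precedence over the strand-complement match, so
# palindromic pairs resolve as written.
.match_orientation <- function(a1, a2, r1, r2) {
  .match_orientation_vec(a1, a2, r1, r2)
}

.match_orientation_vec <- function(a1, a2, r1, r2) {
  out <- rep(NA_character_, length(a1))
  same <- !is.na(r1) & a1 == r1 & a2 == r2
  swap <- !is.na(r1) & a1 == r2 & a2 == r1
  out[swap] <- "swap"
  out[same] <- "same"   # exact match takes precedence over swap and complement
  open <- is.na(out) & !is.na(r1)
  if (any(open)) {
    c1 <- unname(.complement[a1[open]])
    c2 <- unname(.complement[a2[open]])
    o <- rep(NA_character_, sum(open))
    o[!is.na(c1) & !is.na(c2) & c1 == r2[open] & c2 == r1[open]] <- "swap"
    o[!is.na(c1) & !is.na(c2) & c1 == r1[open] & c2 == r2[open]] <- "same"
    out[open] <- o
  }
  out
}

#' Restrict summary statistics to a cis-window around a gene
#'
#' Keeps variants with `gene_start - flank <= position <= gene_end + flank`
#' (closed interval, 1-based coordinates). Records on a different chromosome
#' than `chromosome` are excluded with a warning.
#'
#' @param x a [sumstats] object.
#' @param chromosome chromosome of the gene (e.g. `"17"`).
#' @param gene_start,gene_end gene coordinates (bp, `gene_start <= gene_end`).
#' @param flank flank in bp; 500000 for instrument selection, 20000 for the
#'   colocalization window.
#' @return A [sumstats] object restricted to the window.
#' @export
cis_filter <- function(x, chromosome, gene_start, gene_end, flank = 500000L) {
  stopifnot(inherits(x, "sumstats"), gene_start <= gene_end, flank >= 0)
  chromosome <- sub("^chr", "", as.character(chromosome))
  df <- as.data.frame(x)
  off_chrom <- df$chromosome != chromosome
  if (any(off_chrom)) {
    warning(sum(off_chrom), " record(s) on a different chromosome excluded")
  }
  keep <- !off_chrom &
    df$position >= gene_start - flank &
    df$position <= gene_end + flank
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  sumstats(out, trait = attr(x, "trait"), effect_scale = attr(x, "effect_scale"),
           provenance = attr(x, "provenance"))
}

#' Harmonise exposure and outcome statistics to LD-matrix alleles
#'
#' Re-orients both traits to the effect alleles of the LD reference
#' (sign-flipping `beta`, complementing `eaf`, resolving strand flips as in
#' [standardise_alleles()]). Palindromic variants (A/T or C/G), for which
#' strand cannot be resolved from alleles, are kept only when the allele
#' frequency is informative: both traits' eafs below 0.42 or both above
#' 0.58 after nominal alignment; discordant frequencies flip the outcome,
#' ambiguous mid-range frequencies drop the variant with a warning. The
#' result is ordered as in `ld_alleles`.
#'
#' @param exposure,outcome [sumstats] objects sharing variants.
#' @param ld_alleles named list mapping `variant_id` to `c(effect, other)`,
#'   in LD-matrix order (e.g. from [ld_alleles()]).
#' @return A `harmonised_set`: list with `variant_ids`, `beta_x`, `se_x`,
#'   `eaf_x`, `beta_y`, `se_y`, `eaf_y`, `outcome_scale`.
#' @export
harmonise_pairs <- function(exposure, outcome, ld_alleles) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  ex <- as.data.frame(exposure)
  ou <- as.data.frame(outcome)
  ids <- names(ld_alleles)
  common <- ids[ids %in% ex$variant_id & ids %in% ou$variant_id]
  if (length(common) == 0L) stop("no harmonisable instruments", call. = FALSE)
  rows <- list()
  dropped_palindromic <- 0L
  for (id in common) {
    ref <- ld_alleles[[id]]
    e <- ex[match(id, ex$variant_id), ]
    o <- ou[match(id, ou$variant_id), ]
    palindromic <- .is_palindromic(ref[1], ref[2])
    orient_e <- .match_orientation(e$effect_allele, e$other_allele, ref[1], ref[2])
    orient_o <- .match_orientation(o$effect_allele, o$other_allele, ref[1], ref[2])
    if (is.na(orient_e) || is.na(orient_o)) next
    bx <- if (orient_e == "swap") -e$beta else e$beta
    fx <- if (orient_e == "swap") 1 - e$eaf else e$eaf
    by <- if (orient_o == "swap") -o$beta else o$beta
    fy <- if (orient_o == "swap") 1 - o$eaf else o$eaf
    if (palindromic) {
      if (fx > 0.42 && fx < 0.58 || fy > 0.42 && fy < 0.58) {
        dropped_palindromic <- dropped_palindromic + 1L
        next
      }
      if ((fx < 0.42) != (fy < 0.42)) {  # discordant strand assumption: flip outcome
        by <- -by
        fy <- 1 - fy
      }
    }
    rows[[id]] <- data.frame(variant_id = id, beta_x = bx, se_x = e$se, eaf_x = fx,
                             beta_y = by, se_y = o$se, eaf_y = fy,
                             stringsAsFactors = FALSE)
  }
  if (dropped_palindromic > 0L) {
    warning(dropped_palindromic,
            " palindromic variant(s) with ambiguous allele frequency dropped")
  }
  if (length(rows) == 0L) stop("no harmonisable instruments", call. = FALSE)
  h <- do.call(rbind, rows)
  rownames(h) <- NULL
  structure(list(variant_ids = h$variant_id,
                 beta_x = h$beta_x, se_x = h$se_x, eaf_x = h$eaf_x,
                 beta_y = h$beta_y, se_y = h$se_y, eaf_y = h$eaf_y,
                 outcome_scale = attr(outcome, "effect_scale"),
                 exposure_trait = attr(exposure, "trait"),
                 outcome_trait = attr(outcome, "trait")),
            class = "harmonised_set")
}

#' Construct a harmonised instrument-outcome set directly
#'
#' Low-level constructor for a `harmonised_set`, for effects already on a
#' common allele orientation (e.g. the bundled published per-SNP tables).
#'
#' @param variant_ids variant identifiers.
#' @param beta_x,se_x exposure effects and standard errors (SD units).
#' @param beta_y,se_y outcome effects and standard errors.
#' @param outcome_scale scale of `beta_y`.
#' @param outcome_trait,exposure_trait trait labels.
#' @return A `harmonised_set`.
#' @export
harmonised_set <- function(variant_ids, beta_x, se_x, beta_y, se_y,
                           outcome_scale = c("sd", "unit", "log_or", "log_hr"),
                           outcome_trait = "outcome", exposure_trait = "exposure") {
  outcome_scale <- match.arg(outcome_scale)
  k <- length(variant_ids)
  stopifnot(length(beta_x) == k, length(se_x) == k,
            length(beta_y) == k, length(se_y) == k,
            all(se_x > 0), all(se_y > 0))
  structure(list(variant_ids = as.character(variant_ids),
                 beta_x = as.numeric(beta_x), se_x = as.numeric(se_x),
                 eaf_x = rep(NA_real_, k),
                 beta_y = as.numeric(beta_y), se_y = as.numeric(se_y),
                 eaf_y = rep(NA_real_, k),
                 outcome_scale = outcome_scale,
                 exposure_trait = exposure_trait, outcome_trait = outcome_trait),
            class = "harmonised_set")
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("Harmonised set: %s -> %s (%d variant(s), outcome scale %s)\n",
              x$exposure_trait, x$outcome_trait, length(x$variant_ids),
              x$outcome_scale))
  print(data.frame(variant_id = x$variant_ids, beta_x = x$beta_x, se_x = x$se_x,
                   beta_y = x$beta_y, se_y = x$se_y))
  invisible(x)
}
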