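#' Signed LD correlation matrix
#'
#' Validates a square matrix of signed LD correlations `r`: symmetric within
#' `1e-8` (symmetrised), unit diagonal, all `|r| <= 1`, positive
#' semi-definite within tolerance (smallest eigenvalue `>= -1e-8`;
#' marginally negative eigenvalues are clipped to zero with a warning).
#'
#' @param r square numeric matrix of signed correlations with variant ids
#'   as row and column names (or supplied via `variant_ids`).
#' @param variant_ids optional variant ids overriding dimnames.
#' @return An `ld_matrix`: the validated matrix with class attribute.
#' @export
ld_matrix <- function(r, variant_ids = NULL) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) {
    stop(sprintf("LD matrix is not square: %d x %d", nrow(r), ncol(r)), call. = FALSE)
  }
  if (!is.null(variant_ids)) dimnames(r) <- list(variant_ids, variant_ids)
  if (is.null(rownames(r))) {
    stop("LD matrix needs variant ids (dimnames or variant_ids)", call. = FALSE)
  }
  if (!identical(rownames(r), colnames(r))) {
    stop("LD matrix row/column labels disagree: first mismatch at ",
         rownames(r)[which(rownames(r) != colnames(r))[1]], call. = FALSE)
  }
  bad <- which(abs(r) > 1 + 1e-12, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("LD entry out of [-1, 1]: [%s, %s] = %g",
                 rownames(r)[bad[1, 1]], colnames(r)[bad[1, 2]],
                 r[bad[1, , drop = FALSE]]), call. = FALSE)
  }
  asym <- max(abs(r - t(r)))
  if (asym > 1e-8) {
    stop(sprintf("LD matrix asymmetric beyond tolerance (max |r - t(r)| = %g)", asym),
         call. = FALSE)
  }
  r <- (r + t(r)) / 2
  if (max(abs(diag(r) - 1)) > 1e-8) {
    stop("LD matrix diagonal is not 1", call. = FALSE)
  }
  diag(r) <- 1
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf("LD matrix is not positive semi-definite (min eigenvalue %g)",
                 min(ev)), call. = FALSE)
  }
  structure(r, class = c("ld_matrix", "matrix", "array"))
}

#' Read and validate a signed LD matrix from delimited text
#'
#' Expects square tab- or whitespace-delimited text with variant-id column
#' headers (and optionally matching row names).
#'
#' @param path file path.
#' @return An [ld_matrix].
#' @export
read_ld <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) == nrow(raw) + 1L && !is.numeric(raw[[1]])) {
    rownames(raw) <- raw[[1]]
    raw <- raw[-1L]
  }
  m <- as.matrix(raw)
  if (is.null(rownames(m)) || all(rownames(m) == as.character(seq_len(nrow(m))))) {
    rownames(m) <- colnames(m)
  }
  ld_matrix(m)
}

#' Write an LD matrix to tab-delimited text
#' @param ld an [ld_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld <- function(ld, path) {
  utils::write.table(as.data.frame(unclass(ld)), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Restrict an LD matrix to a set of variants, in the given order
#' @param ld an [ld_matrix].
#' @param ids variant ids to keep (all must be present).
#' @return An [ld_matrix] over `ids`.
#' @export
ld_subset <- function(ld, ids) {
  missing <- setdiff(ids, rownames(ld))
  if (length(missing) > 0L) {
    stop("variant(s) missing from LD matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ld_matrix(unclass(ld)[ids, ids, drop = FALSE])
}

#' Instrument strength F-statistic
#'
#' `F = (beta/se)^2`, equivalently `z^2`. When only a (two-sided) p-value
#' is available, the equivalent route is the 1-df chi-square quantile at
#' `1 - p`; the two routes agree on unrounded data.
#'
#' @param beta exposure effect size(s).
#' @param se standard error(s), > 0; ignored when `p` is given.
#' @param p optional two-sided p-value(s); when supplied, the chi-square
#'   route is used.
#' @return F-statistic(s). Values above 10 conventionally indicate no weak
#'   instrument bias.
#' @export
f_statistic <- function(beta = NULL, se = NULL, p = NULL) {
  if (!is.null(p)) {
    stopifnot(all(p > 0), all(p <= 1))
    return(stats::qchisq(p, df = 1, lower.tail = FALSE))
  }
  stopifnot(!is.null(beta), !is.null(se))
  if (any(se <= 0)) stop("standard errors must be positive", call. = FALSE)
  (beta / se)^2
}

#' Select cis-instruments by significance and greedy LD clumping
#'
#' Candidates are the variants with `p_value < p_threshold`, sorted by
#' p-value ascending (ties: smaller position, then lexicographic id). The
#' greedy pass repeatedly keeps the top candidate and removes every
#' remaining candidate with `r^2 > r2_threshold` against it *and* within
#' `window_bp` of its position, until the list is exhausted. F-statistics
#' are computed for the survivors and the LD matrix is restricted to them.
#'
#' @param stats cis-filtered [sumstats] (typically meta-analysed).
#' @param ld [ld_matrix] covering every candidate.
#' @param p_threshold significance threshold (default `1e-6`, the usual
#'   single-region cis threshold rather than the genome-wide `5e-8`).
#' @param r2_threshold maximum squared correlation between kept instruments
#'   (default 0.3).
#' @param window_bp clumping window in bp around the index variant
#'   (default 500000).
#' @return An `instrument_set`: list with `variants` (data frame, selection
#'   order), `f_stats`, `ld` (restricted [ld_matrix]), `n_candidates`,
#'   `selection_params`. Empty selection (no candidate passes) gives a
#'   zero-row set with a warning.
#' @export
select_instruments <- function(stats, ld, p_threshold = 1e-6,
                               r2_threshold = 0.3, window_bp = 500000L) {
  stopifnot(inherits(stats, "sumstats"), inherits(ld, "ld_matrix"))
  df <- as.data.frame(stats)
  cand <- df[df$p_value < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning("no candidate passes the p-value threshold; empty instrument set")
    return(structure(list(variants = df[0, , drop = FALSE], f_stats = numeric(0),
                          ld = NULL, n_candidates = 0L,
                          selection_params = list(p_threshold = p_threshold,
                                                  r2_threshold = r2_threshold,
                                                  window_bp = window_bp)),
                     class = "instrument_set"))
  }
  missing <- setdiff(cand$variant_id, rownames(ld))
  if (length(missing) > 0L) {
    stop("candidate(s) missing from LD matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ord <- order(cand$p_value, cand$position, cand$variant_id)
  cand <- cand[ord, , drop = FALSE]
  kept <- character(0)
  pool <- cand
  while (nrow(pool) > 0L) {
    index <- pool[1L, ]
    kept <- c(kept, index$variant_id)
    r2 <- unclass(ld)[index$variant_id, pool$variant_id]^2
    near <- abs(pool$position - index$position) <= window_bp
    drop <- (r2 > r2_threshold & near) | pool$variant_id == index$variant_id
    pool <- pool[!drop, , drop = FALSE]
  }
  sel <- cand[match(kept, cand$variant_id), , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(variants = sel,
                 f_stats = stats::setNames(f_statistic(sel$beta, sel$se),
                                           sel$variant_id),
                 ld = ld_subset(ld, sel$variant_id),
                 n_candidates = nrow(cand),
                 selection_params = list(p_threshold = p_threshold,
                                         r2_threshold = r2_threshold,
                                         window_bp = window_bp)),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  p <- x$selection_params
  cat(sprintf("Instrument set: %d variant(s) (from %d candidate(s); p < %g, r2 <= %g, window %d bp)\n",
              nrow(x$variants), x$n_candidates, p$p_threshold, p$r2_threshold,
              p$window_bp))
  if (nrow(x$variants) > 0L) {
    print(cbind(x$variants[c("variant_id", "position", "effect_allele",
                             "other_allele", "eaf", "beta", "se", "p_value")],
                F = unname(x$f_stats)))
  }
  invisible(x)
}

#' Allele orientation map of an instrument set
#'
#' Convenience accessor returning the named list mapping variant id to
#' `c(effect, other)` expected by [harmonise_pairs()], in LD-matrix order.
#'
#' @param instruments an `instrument_set` (or a [sumstats] object).
#' @return Named list of length-2 character vectors.
#' @export
ld_alleles <- function(instruments) {
  df <- if (inherits(instruments, "instrument_set")) instruments$variants else as.data.frame(instruments)
  out <- Map(function(e, o) c(e, o), df$effect_allele, df$other_allele)
  names(out) <- df$variant_id
  out
}

#' Principal-component basis for component-based MR
#'
#' Eigendecomposition of the weighted matrix
#' `Psi_ij = (beta_Xi * beta_Xj / (se_Yi * se_Yj)) * rho_ij`
#' (the Burgess principal-components construction for correlated
#' cis-instruments); the smallest `k` with cumulative eigenvalue fraction
#' at or above `variance_threshold` is retained.
#'
#' @param beta_x exposure effects per instrument.
#' @param se_y outcome standard errors per instrument (same order).
#' @param ld [ld_matrix] over the instruments, same order.
#' @param variance_threshold cumulative variance fraction to retain
#'   (default 0.999).
#' @return A `pca_basis`: list with `loadings` (variants x k, orthonormal),
#'   `variance_fractions` (all components, descending), `k`.
#' @export
pca_basis <- function(beta_x, se_y, ld, variance_threshold = 0.999) {
  stopifnot(length(beta_x) >= 1L, length(beta_x) == length(se_y),
            inherits(ld, "ld_matrix"), nrow(ld) == length(beta_x))
  w <- beta_x / se_y
  psi <- tcrossprod(w) * unclass(ld)
  es <- eigen((psi + t(psi)) / 2, symmetric = TRUE)
  ev <- es$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop(sprintf("weighted variant matrix not positive semi-definite (min eigenvalue %g)",
                 min(ev)), call. = FALSE)
  }
  ev <- pmax(ev, 0)
  frac <- ev / sum(ev)
  k <- which(cumsum(frac) >= variance_threshold)[1]
  if (is.na(k)) k <- length(ev)
  structure(list(loadings = es$vectors[, seq_len(k), drop = FALSE],
                 variance_fractions = frac, k = k),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("PCA basis: %d of %d component(s) retained (%.4f%% variance)\n",
              x$k, length(x$variance_fractions),
              100 * sum(x$variance_fractions[seq_len(x$k)])))
  invisible(x)
}
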