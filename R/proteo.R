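# Label-free proteomics statistics: reproducibility filtering,
# left-censored (down-shifted normal) imputation, differential protein
# calling by t-test with a fold-change gate, and detection of
# state-exclusive proteins.

#' Filter proteins for reproducible quantification
#'
#' Keeps a protein when it has at least `min_valid` non-missing intensities
#' in all replicates of at least one condition.
#'
#' @param intensity Protein-group x sample log2 matrix with `NA` for
#'   missing values.
#' @param meta Sample metadata (`sample`, `condition`).
#' @param min_valid Required non-missing replicates within one condition.
#' @return The filtered intensity matrix.
#' @export
filter_reproducible <- function(intensity, meta, min_valid = 3) {
  conds <- unique(meta$condition)
  keep <- rep(FALSE, nrow(intensity))
  for (cond in conds) {
    smp <- intersect(meta$sample[meta$condition == cond], colnames(intensity))
    if (!length(smp)) next
    keep <- keep |
      rowSums(!is.na(intensity[, smp, drop = FALSE])) >= min_valid
  }
  intensity[keep, , drop = FALSE]
}

#' Impute left-censored missing intensities
#'
#' Missing cells are drawn from a down-shifted normal per sample:
#' `Normal(mu_s - downshift * sd_s, (width * sd_s)^2)` with `mu_s`, `sd_s`
#' estimated from the observed values of sample `s`.  This mimics the
#' standard treatment of intensities missing because they fall below the
#' detection limit.  Observed cells are never altered.
#'
#' @param intensity log2 matrix with `NA` for missing values.
#' @param width Imputation sd as a fraction of the sample sd (default 0.3).
#' @param downshift Center shift in sample-sd units (default 1.8).
#' @param seed Integer seed; identical seeds give identical imputations.
#' @param min_observed Minimum observed values a sample must have.
#' @return Matrix without missing values.
#' @export
impute_missing <- function(intensity, width = 0.3, downshift = 1.8,
                           seed = NULL, min_observed = 2) {
  if (width <= 0) stopf("'width' must be > 0")
  with_seed(seed, {
    out <- intensity
    for (j in seq_len(ncol(out))) {
      obs <- out[, j][!is.na(out[, j])]
      if (length(obs) < min_observed)
        stopf("sample '%s' has fewer than %d observed values",
              colnames(out)[j], min_observed)
      miss <- which(is.na(out[, j]))
      if (!length(miss)) next
      mu <- mean(obs); s <- stats::sd(obs)
      out[miss, j] <- stats::rnorm(length(miss), mu - downshift * s,
                                   width * s)
    }
    out
  })
}

#' Differential protein expression between two conditions
#'
#' Two-sample t-test per protein on log2 intensities (pooled-variance
#' Student's t by default, Welch optional), BH adjustment across proteins,
#' and a fold-change gate: called when `fdr < fdr_max` and
#' `2^|log2fc| >= fc_min`.
#'
#' @param intensity Imputed log2 matrix (no missing values allowed).
#' @param meta Sample metadata (`sample`, `condition`).
#' @param cond_a Reference condition; `cond_b` the alternative.
#' @param fc_min Fold-change gate (default 3).
#' @param fdr_max FDR threshold (default 0.05).
#' @param welch Use Welch's unequal-variance t instead of Student's.
#' @return data.frame: `protein_group_id`, `mean_a`, `mean_b`, `log2fc`
#'   (`mean_b - mean_a`), `t`, `df`, `p`, `fdr`, `called`.
#' @export
differential_protein <- function(intensity, meta, cond_a, cond_b,
                                 fc_min = 3, fdr_max = 0.05, welch = FALSE) {
  if (anyNA(intensity))
    stopf("intensity matrix contains missing values; impute first")
  cols <- function(cond) {
    smp <- intersect(meta$sample[meta$condition == cond], colnames(intensity))
    if (length(smp) < 3)
      stopf("condition '%s' needs >= 3 replicates", cond)
    intensity[, smp, drop = FALSE]
  }
  a <- cols(cond_a); b <- cols(cond_b)
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(ma))
  }
  tstat <- ifelse(se2 > 0, (mb - ma) / sqrt(se2), 0)
  p <- 2 * stats::pt(-abs(tstat), df)
  fdr <- bh_adjust(p)
  data.frame(protein_group_id = rownames(intensity),
             mean_a = ma, mean_b = mb, log2fc = mb - ma,
             t = tstat, df = df, p = p, fdr = fdr,
             called = fdr < fdr_max & 2^abs(mb - ma) >= fc_min,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' State-exclusive protein detection patterns
#'
#' A protein counts as detected in a condition when it has at least
#' `min_valid` observed (non-missing) replicates there.  Proteins detected
#' in a strict, non-empty subset of the conditions are "exclusive" to that
#' detection pattern (e.g. detected in SL and EPI but absent from the
#' ground state).
#'
#' @param intensity Pre-imputation log2 matrix with `NA` for missing.
#' @param meta Sample metadata.
#' @param conditions Conditions defining the patterns (default: all).
#' @param min_valid Observed replicates needed for detection.
#' @return data.frame: `protein_group_id`, `pattern`
#'   (`"+"`-joined condition labels, `"none"` if empty), `exclusive`.
#' @export
state_exclusive_proteins <- function(intensity, meta, conditions = NULL,
                                     min_valid = 3) {
  conditions <- conditions %||% unique(meta$condition)
  det <- vapply(conditions, function(cond) {
    smp <- intersect(meta$sample[meta$condition == cond], colnames(intensity))
    rowSums(!is.na(intensity[, smp, drop = FALSE])) >= min_valid
  }, logical(nrow(intensity)))
  det <- matrix(det, nrow = nrow(intensity),
                dimnames = list(rownames(intensity), conditions))
  pattern <- apply(det, 1, function(r) {
    if (!any(r)) "none" else paste(conditions[r], collapse = "+")
  })
  n_det <- rowSums(det)
  data.frame(protein_group_id = rownames(intensity), pattern = pattern,
             exclusive = n_det > 0 & n_det < length(conditions),
             stringsAsFactors = FALSE, row.names = NULL)
}
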