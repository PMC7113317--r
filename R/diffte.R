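# Translation-efficiency analysis: count normalisation, expression
# filtering, TE computation, and a fully specified surrogate test for
# differential TE between two conditions.
#
# The differential test works on Delta(log TE) = log2FC(RFP) - log2FC(RNA).
# The variance of each condition/layer log2 mean is obtained by the delta
# method under a negative binomial model, Var(log2 mu_hat) ~=
# (1/ln 2)^2 * (1/mu + phi) / n, with phi taken from a trended
# (mean-binned, monotone-smoothed) method-of-moments dispersion estimate
# pooled across genes.  Calls use the conventional thresholds FDR < 0.1 and
# |TE fold change| > 1.5.

#' Normalise a count matrix
#'
#' `cpm`: counts per million (column scaled to 1e6).  `median_of_ratios`:
#' DESeq-style size factors -- each sample is divided by the median, over
#' genes with all-positive counts, of its ratio to the per-gene geometric
#' mean; values stay on the count scale.
#'
#' @param counts Non-negative gene x sample matrix.
#' @param method `"cpm"` or `"median_of_ratios"`.
#' @return Normalised numeric matrix (same dimensions); for
#'   `median_of_ratios` the size factors are attached as attribute
#'   `"size_factors"`.
#' @export
normalize_counts <- function(counts, method = c("median_of_ratios", "cpm")) {
  method <- match.arg(method)
  check_count_matrix(counts)
  zero <- colSums(counts) == 0
  if (any(zero))
    stopf("sample(s) with all-zero counts: %s",
          paste(colnames(counts)[zero], collapse = ", "))
  if (method == "cpm") {
    return(sweep(counts, 2, colSums(counts), "/") * 1e6)
  }
  pos <- rowSums(counts == 0) == 0
  if (!any(pos))
    stopf("median-of-ratios needs at least one gene with no zero counts")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- exp(apply(lg - ref, 2, stats::median))
  out <- sweep(counts, 2, sf, "/")
  attr(out, "size_factors") <- sf
  out
}

#' Expression filter on normalised counts
#'
#' A gene is kept when its normalised RNA value exceeds `rna_min` in every
#' replicate of at least one condition, and its normalised RFP value exceeds
#' `rfp_min` in every replicate of at least one condition (strict
#' inequalities).
#'
#' @param rna_norm,rfp_norm Normalised matrices sharing the gene index.
#' @param meta Sample metadata (`sample`, `condition`, `layer`).
#' @param rna_min,rfp_min Normalised-count thresholds (default 50 / 25).
#' @param conditions Conditions considered (default: all in `meta`).
#' @return Character vector of gene ids passing the filter.
#' @export
filter_expressed <- function(rna_norm, rfp_norm, meta,
                             rna_min = 50, rfp_min = 25,
                             conditions = NULL) {
  if (!identical(rownames(rna_norm), rownames(rfp_norm)))
    stopf("RNA and RFP matrices must share an identical gene index")
  conditions <- conditions %||% unique(meta$condition)
  pass_layer <- function(mat, layer, min_val) {
    ok <- rep(FALSE, nrow(mat))
    for (cond in conditions) {
      smp <- meta$sample[meta$condition == cond & meta$layer == layer]
      smp <- intersect(smp, colnames(mat))
      if (!length(smp)) next
      ok <- ok | rowSums(mat[, smp, drop = FALSE] > min_val) == length(smp)
    }
    ok
  }
  keep <- pass_layer(rna_norm, "rna", rna_min) &
    pass_layer(rfp_norm, "rfp", rfp_min)
  rownames(rna_norm)[keep]
}

#' Translation efficiency matrix
#'
#' TE = (normalised RFP + pseudocount) / (normalised RNA + pseudocount) for
#' samples paired by condition and replicate.
#'
#' @param rfp_norm,rna_norm Normalised matrices.
#' @param meta Sample metadata used to pair columns across layers.
#' @param pseudocount Added to both numerator and denominator.
#' @return Gene x pair TE matrix; columns named `<condition>_<replicate>`.
#' @export
compute_te <- function(rfp_norm, rna_norm, meta, pseudocount = 0.5) {
  if (pseudocount < 0) stopf("'pseudocount' must be >= 0")
  rna_meta <- meta[meta$layer == "rna" & meta$sample %in% colnames(rna_norm), ]
  rfp_meta <- meta[meta$layer == "rfp" & meta$sample %in% colnames(rfp_norm), ]
  key <- function(m) paste(m$condition, m$replicate, sep = "_")
  pairs <- intersect(key(rna_meta), key(rfp_meta))
  if (!length(pairs) || length(pairs) < max(nrow(rna_meta), nrow(rfp_meta)))
    stopf("RNA and RFP samples cannot be fully paired by condition+replicate")
  rna_cols <- rna_meta$sample[match(pairs, key(rna_meta))]
  rfp_cols <- rfp_meta$sample[match(pairs, key(rfp_meta))]
  te <- (rfp_norm[, rfp_cols, drop = FALSE] + pseudocount) /
    (rna_norm[, rna_cols, drop = FALSE] + pseudocount)
  colnames(te) <- pairs
  te
}

# Trended method-of-moments dispersion.  Per gene, phi_hat =
# (s^2 - m) / m^2 pooled over conditions (weights n_c - 1); per-bin means
# (not medians: the n=2 estimator is unbiased but skewed) over ~20
# equal-count bins of log mean, smoothed to be monotone non-increasing.
# Returns a function mu -> phi.
dispersion_trend <- function(counts, group, nbins = 20) {
  groups <- unique(group)
  m_all <- rowMeans(counts)
  num <- rep(0, nrow(counts)); den <- rep(0, nrow(counts))
  for (g in groups) {
    x <- counts[, group == g, drop = FALSE]
    n <- ncol(x)
    if (n < 2) next
    m <- rowMeans(x)
    v <- apply(x, 1, stats::var)
    ok <- m > 0
    phi_g <- ifelse(ok, (v - m) / m^2, NA_real_)
    w <- ifelse(ok, n - 1, 0)
    num <- num + ifelse(ok, w * phi_g, 0)
    den <- den + w
  }
  phi <- ifelse(den > 0, num / den, NA_real_)
  use <- !is.na(phi) & m_all > 0
  if (sum(use) < 10) {
    flat <- max(mean(phi[use], na.rm = TRUE), 0)
    return(function(mu) rep(flat, length(mu)))
  }
  lm_ <- log(m_all[use])
  nb <- min(nbins, max(1, floor(sum(use) / 50)))
  if (nb < 2) {
    flat <- max(mean(phi[use]), 0)
    return(function(mu) rep(flat, length(mu)))
  }
  brk <- stats::quantile(lm_, probs = seq(0, 1, length.out = nb + 1))
  brk[1] <- -Inf; brk[length(brk)] <- Inf
  bin <- cut(lm_, unique(brk), labels = FALSE)
  bin_mu <- tapply(lm_, bin, mean)
  bin_phi <- tapply(phi[use], bin, mean)
  # Monotone non-increasing smoothing: isotonic regression on -phi.
  iso <- stats::isoreg(bin_mu, -bin_phi)
  fit <- pmax(-iso$yf, 0)
  xs <- bin_mu[order(bin_mu)]
  function(mu) {
    stats::approx(xs, fit, xout = log(pmax(mu, 1e-8)), rule = 2)$y
  }
}

#' Differential translation efficiency between two conditions
#'
#' Surrogate for a dedicated differential-translation caller: a delta-method
#' z-test on Delta(log2 TE) with trended NB dispersion (details in the
#' package vignette).  Genes are tested when they pass the normalised
#' expression filter (RNA > `rna_min`, RFP > `rfp_min` in all replicates of
#' at least one condition) and have mean normalised counts >=
#' `min_mean_count` in both layers across the compared samples.  A gene is
#' called differentially translated when `fdr < fdr_max` and
#' `2^|delta_te| > fc_min`.
#'
#' @param rna,rfp Raw count matrices (genes x samples).
#' @param meta Sample metadata (`sample`, `condition`, `layer`,
#'   `replicate`).
#' @param cond_a Reference condition; `cond_b` the alternative.
#' @param norm_method Normalisation passed to [normalize_counts()].
#' @param pseudocount Pseudocount on normalised means for fold changes.
#' @param rna_min,rfp_min Per-replicate expression thresholds.
#' @param min_mean_count Mean normalised-count threshold per layer.
#' @param fdr_max,fc_min Call thresholds (FDR < 0.1, fold change > 1.5).
#' @return data.frame with one row per gene: `gene_id`, `passes_filter`,
#'   `mean_rna`, `mean_rfp`, `log2fc_rna`, `log2fc_rfp`, `delta_te`, `se`,
#'   `z`, `p`, `fdr`, `called`, `direction` (`higher_in_reference` /
#'   `higher_in_alt` for called genes).
#' @export
differential_te <- function(rna, rfp, meta, cond_a, cond_b,
                            norm_method = "median_of_ratios",
                            pseudocount = 0.5, rna_min = 50, rfp_min = 25,
                            min_mean_count = 50, fdr_max = 0.1,
                            fc_min = 1.5) {
  for (cond in c(cond_a, cond_b))
    if (!cond %in% meta$condition)
      stopf("condition '%s' absent from metadata", cond)
  if (!identical(rownames(rna), rownames(rfp)))
    stopf("RNA and RFP matrices must share an identical gene index")
  sel <- meta[meta$condition %in% c(cond_a, cond_b), ]
  take <- function(mat, layer) {
    smp <- sel$sample[sel$layer == layer]
    smp <- intersect(colnames(mat), smp)
    mat[, smp, drop = FALSE]
  }
  rna_c <- take(rna, "rna"); rfp_c <- take(rfp, "rfp")
  grp <- function(mat) sel$condition[match(colnames(mat), sel$sample)]
  for (mat in list(rna_c, rfp_c)) {
    tab <- table(grp(mat))
    if (length(tab) < 2 || any(tab < 2))
      stopf("need >= 2 replicates per condition per layer")
  }
  rna_n <- normalize_counts(rna_c, norm_method)
  rfp_n <- normalize_counts(rfp_c, norm_method)
  expressed <- filter_expressed(rna_n, rfp_n, sel, rna_min, rfp_min,
                                conditions = c(cond_a, cond_b))
  mean_rna <- rowMeans(rna_n); mean_rfp <- rowMeans(rfp_n)
  tested <- rownames(rna) %in% expressed &
    mean_rna >= min_mean_count & mean_rfp >= min_mean_count

  phi_rna <- dispersion_trend(rna_c, grp(rna_c))
  phi_rfp <- dispersion_trend(rfp_c, grp(rfp_c))

  stats_layer <- function(norm, raw, phi_fun) {
    g <- grp(raw)
    out <- list()
    for (cond in c(cond_a, cond_b)) {
      x <- norm[, g == cond, drop = FALSE]
      n <- ncol(x)
      mu <- rowMeans(x)
      v <- (1 / log(2))^2 * (1 / (mu + pseudocount) + phi_fun(mu)) / n
      out[[cond]] <- list(mu = mu, var = v)
    }
    out
  }
  sr <- stats_layer(rna_n, rna_c, phi_rna)
  sf <- stats_layer(rfp_n, rfp_c, phi_rfp)
  l2 <- function(s) log2(s[[cond_b]]$mu + pseudocount) -
    log2(s[[cond_a]]$mu + pseudocount)
  fc_rna <- l2(sr); fc_rfp <- l2(sf)
  se <- sqrt(sr[[cond_a]]$var + sr[[cond_b]]$var +
             sf[[cond_a]]$var + sf[[cond_b]]$var)
  delta <- fc_rfp - fc_rna
  z <- ifelse(se > 0, delta / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  res <- data.frame(gene_id = rownames(rna), passes_filter = tested,
                    mean_rna = mean_rna, mean_rfp = mean_rfp,
                    log2fc_rna = fc_rna, log2fc_rfp = fc_rfp,
                    delta_te = delta, se = se, z = z, p = p,
                    fdr = NA_real_, called = FALSE,
                    direction = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$p[!tested] <- NA_real_
  res$z[!tested] <- NA_real_
  if (any(tested))
    res$fdr[tested] <- bh_adjust(res$p[tested])
  res$called <- !is.na(res$fdr) & res$fdr < fdr_max &
    2^abs(res$delta_te) > fc_min
  res$direction[res$called] <-
    ifelse(res$delta_te[res$called] < 0, "higher_in_reference",
           "higher_in_alt")
  res
}

#' Partition differential-TE calls from two comparisons
#'
#' Splits genes called in comparison X only, comparison Y only, or in both
#' ("common"), with TE direction labels per comparison.
#'
#' @param results_x,results_y [differential_te()] results computed against
#'   the same reference condition.
#' @param labels Length-2 names for the comparisons (e.g. `c("SL",
#'   "EPI")`).
#' @return List with `only_x`, `only_y`, `common` gene-id vectors (named
#'   after `labels`) and a `table` data.frame (`gene_id`, `set`,
#'   `direction_x`, `direction_y`).
#' @export
partition_te_sets <- function(results_x, results_y, labels = c("x", "y")) {
  called_x <- results_x$gene_id[results_x$called]
  called_y <- results_y$gene_id[results_y$called]
  common <- intersect(called_x, called_y)
  only_x <- setdiff(called_x, called_y)
  only_y <- setdiff(called_y, called_x)
  all_genes <- union(called_x, called_y)
  dir_of <- function(res, genes) res$direction[match(genes, res$gene_id)]
  tab <- data.frame(
    gene_id = all_genes,
    set = ifelse(all_genes %in% common, "common",
                 ifelse(all_genes %in% only_x, paste0(labels[1], "_only"),
                        paste0(labels[2], "_only"))),
    direction_x = dir_of(results_x, all_genes),
    direction_y = dir_of(results_y, all_genes),
    stringsAsFactors = FALSE
  )
  out <- list(only_x = only_x, only_y = only_y, common = common, table = tab)
  names(out)[1:2] <- paste0(labels, "_only")
  out
}
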