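# UTR/CDS sequence features: composition, exact AU-rich-element scanning,
# PWM log-odds scanning with a relative-score threshold, rank-sum
# comparison of feature distributions, and motif presence enrichment.

check_rna_alphabet <- function(seqs, what = "sequence") {
  bad <- regexpr("[^ACGU]", seqs)
  hit <- which(bad > 0)
  if (length(hit))
    stopf("non-ACGU character in %s %d at position %d",
          what, hit[1], bad[hit[1]])
  invisible(seqs)
}

#' Length and base composition per transcript region
#'
#' @param transcripts Transcript table (`gene_id`, `utr5`, `cds`, `utr3`).
#' @return data.frame: `gene_id`, `region` (`utr5`/`cds`/`utr3`),
#'   `length`, `gc_fraction`, `au_fraction` (fractions are `NA` for empty
#'   regions; they sum to 1 for pure ACGU sequences).
#' @export
sequence_composition <- function(transcripts) {
  res <- lapply(c("utr5", "cds", "utr3"), function(region) {
    s <- transcripts[[region]]
    check_rna_alphabet(s, paste0(region, " sequence"))
    len <- nchar(s)
    gc <- nchar(gsub("[AU]", "", s))
    data.frame(gene_id = transcripts$gene_id, region = region,
               length = len,
               gc_fraction = ifelse(len > 0, gc / len, NA_real_),
               au_fraction = ifelse(len > 0, (len - gc) / len, NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Count exact motif occurrences (overlaps included)
#'
#' Counts every position `i` with `substr(seq, i, i + w - 1) == motif`,
#' overlapping occurrences included, on the given strand only.
#'
#' @param sequences Character vector (RNA alphabet).
#' @param motif Motif string, default the AU-rich element heptamer
#'   `UAUUUAU`.
#' @return Integer vector of per-sequence hit counts.
#' @export
scan_exact_motif <- function(sequences, motif = "UAUUUAU") {
  if (!nzchar(motif)) stopf("'motif' must be non-empty")
  check_rna_alphabet(motif, "motif")
  pat <- paste0("(?=", motif, ")")
  vapply(sequences, function(s) {
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) 0L else length(m)
  }, 0L, USE.NAMES = FALSE)
}

#' Scan sequences with a position weight matrix
#'
#' Scores every start position with the log2-odds of the PWM against its
#' background (probabilities floored at 1e-3 before the log-odds), positive
#' strand only.  A position is a hit when its score reaches
#' `rel_threshold` times the maximum achievable log-odds of the PWM.
#' Sequences shorter than the motif simply yield no hits.
#'
#' @param sequences Character vector (RNA alphabet).
#' @param pwm Motif as returned by [read_meme()]: list with `motif_id`,
#'   `matrix` (positions x A/C/G/U probabilities) and `background`.
#' @param rel_threshold Fraction of the maximum log-odds, in `(0, 1]`.
#' @return data.frame: `seq_index`, `position` (1-based), `score`.
#' @export
scan_pwm <- function(sequences, pwm, rel_threshold = 0.9) {
  if (rel_threshold <= 0 || rel_threshold > 1)
    stopf("'rel_threshold' must be in (0, 1]")
  m <- pwm$matrix
  if (any(abs(rowSums(m) - 1) > 1e-6))
    stopf("PWM rows must sum to 1")
  bg <- pwm$background[colnames(m)]
  lo <- log2(pmax(m, 1e-3)) -
    matrix(log2(pmax(bg, 1e-3)), nrow(m), 4, byrow = TRUE)
  max_score <- sum(apply(lo, 1, max))
  thr <- rel_threshold * max_score
  w <- nrow(m)
  base_idx <- stats::setNames(1:4, c("A", "C", "G", "U"))
  hits <- lapply(seq_along(sequences), function(si) {
    s <- sequences[[si]]
    check_rna_alphabet(s, "sequence")
    n <- nchar(s)
    if (n < w) return(NULL)
    code <- base_idx[strsplit(s, "")[[1]]]
    npos <- n - w + 1
    per_pos <- vapply(seq_len(w), function(j) {
      lo[j, ][code[(j):(j + npos - 1)]]
    }, numeric(npos))
    score <- rowSums(matrix(per_pos, nrow = npos))
    keep <- which(score >= thr)
    if (!length(keep)) return(NULL)
    data.frame(seq_index = si, position = keep, score = score[keep])
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(seq_index = integer(0), position = integer(0),
                      score = numeric(0))
  rownames(out) <- NULL
  out
}

#' Two-sided Wilcoxon rank-sum comparison of two samples
#'
#' Exact permutation null (full enumeration of group assignments, average
#' ranks for ties) when `length(a) + length(b) <= max_exact`; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric samples (each non-empty).
#' @param max_exact Total size up to which the exact null is enumerated.
#' @return Two-sided p-value.
#' @export
compare_distributions <- function(a, b, max_exact = 12) {
  if (!length(a) || !length(b)) stopf("both samples must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (n <= max_exact) {
    combs <- utils::combn(n, na)
    Ws <- colSums(matrix(r[combs], nrow = na))
    return(mean(abs(Ws - mu) >= abs(W - mu) - 1e-9))
  }
  ties <- table(r)
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 == 0) return(1)
  z <- (abs(W - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Motif presence enrichment in a gene set
#'
#' Tests whether genes carrying a motif are over-represented in a query set
#' relative to a background universe, via the upper-tail hypergeometric
#' test.
#'
#' @param hit_genes Genes with at least one motif occurrence (subset of
#'   `background_set`).
#' @param query_set Query genes (subset of `background_set`).
#' @param background_set Universe of genes.
#' @return One-row data.frame: `k` (query hits), `K` (total hits), `n`
#'   (query size), `N` (universe size), `p`.
#' @export
motif_presence_enrichment <- function(hit_genes, query_set, background_set) {
  background_set <- unique(background_set)
  hit_genes <- unique(hit_genes)
  query_set <- unique(query_set)
  if (length(setdiff(query_set, background_set)))
    stopf("query set must be a subset of the background set")
  if (length(setdiff(hit_genes, background_set)))
    stopf("hit genes must be a subset of the background set")
  k <- length(intersect(hit_genes, query_set))
  K <- length(hit_genes); n <- length(query_set); N <- length(background_set)
  data.frame(k = k, K = K, n = n, N = N,
             p = hypergeometric_tail(k, K, n, N))
}
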