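# Ribosome-profiling quality control in transcript coordinates:
# P-site offset estimation against annotated start codons, metagene
# coverage profiles in fixed-width bins, and union-mode CDS read counting.

check_reads <- function(reads, transcripts) {
  needed <- c("read_id", "transcript_id", "start", "length")
  if (!all(needed %in% names(reads)))
    stopf("'reads' must have columns %s", paste(needed, collapse = ", "))
  missing_tx <- setdiff(unique(reads$transcript_id), transcripts$gene_id)
  if (length(missing_tx))
    stopf("unknown transcript id(s): %s",
          paste(utils::head(missing_tx, 3), collapse = ", "))
  invisible(reads)
}

#' Estimate the P-site offset from read 5' ends
#'
#' Computes the histogram of distances between footprint 5' ends and the
#' annotated translation initiation site (TIS; first nucleotide of the AUG,
#' position 0).  Negative offsets are upstream of the TIS.  In a healthy
#' library the start-codon peak appears at -12 nt, the canonical distance
#' from a footprint's 5' end to the P-site codon.
#'
#' @param reads Footprint alignments (`read_id`, `transcript_id`, `start`,
#'   `length`).
#' @param transcripts Transcript table with `gene_id` and `u5_len`.
#' @param window Integer bounds `c(lo, hi)` of offsets kept in the
#'   histogram.
#' @return List: `histogram` (data.frame `offset`, `count`, covering every
#'   offset in the window) and `mode` (all tied modal offsets, ascending).
#' @export
estimate_psite_offset <- function(reads, transcripts, window = c(-30, 30)) {
  if (nrow(reads) == 0) stopf("no reads")
  check_reads(reads, transcripts)
  tis <- stats::setNames(transcripts$u5_len, transcripts$gene_id)
  off <- reads$start - tis[reads$transcript_id]
  keep <- off >= window[1] & off <= window[2]
  offs <- window[1]:window[2]
  counts <- tabulate(match(off[keep], offs), nbins = length(offs))
  hist <- data.frame(offset = offs, count = counts)
  mode <- offs[counts == max(counts)]
  list(histogram = hist, mode = sort(mode))
}

# Per-transcript binned coverage of read 5' ends over [from, to) in
# transcript coordinates.  Positions outside the transcript are clipped;
# partial bins are normalised by their true width.
bin_coverage <- function(starts, from, to, tx_len, bin_width) {
  lo <- max(from, 0L)
  hi <- min(to, tx_len)
  nbins <- ceiling((to - from) / bin_width)
  out <- rep(NA_real_, nbins)
  if (hi <= lo) return(out)
  cov <- tabulate(starts[starts >= lo & starts < hi] - lo + 1L, nbins = hi - lo)
  pos0 <- (lo:(hi - 1L)) - from           # offsets within the region
  b <- pos0 %/% bin_width + 1L
  sums <- tapply(cov, b, sum)
  widths <- tapply(cov, b, length)
  idx <- as.integer(names(sums))
  out[idx] <- as.numeric(sums) / as.numeric(widths)
  out
}

#' Metagene coverage profile around coding sequences
#'
#' Mean 5'-end coverage (reads per nt) in fixed-width bins over three
#' regions: the 5' flank upstream of the TIS, the CDS, and the 3' flank
#' downstream of the stop codon.  Only transcripts with CDS length strictly
#' greater than `min_cds_len` contribute; coverage is binned per transcript
#' (partial bins normalised by true width) and then averaged across the
#' transcripts that possess each bin.
#'
#' @inheritParams estimate_psite_offset
#' @param bin_width Bin width in nt.
#' @param flank5 Nt upstream of the TIS profiled (`utr5_flank` region).
#' @param flank3 Nt downstream of the stop codon profiled (`utr3_flank`).
#' @param min_cds_len Minimum CDS length (strict) for a transcript to
#'   qualify.
#' @param tis_margin Nt upstream of the TIS counted as coding positions
#'   (default 15): footprints of initiating ribosomes protrude upstream of
#'   the start codon, so the region immediately 5' of the TIS belongs to
#'   the coding profile, not the UTR background.
#' @return data.frame with `region` (`utr5_flank`/`cds`/`utr3_flank`),
#'   `bin` (0-based index from the region start) and `mean_coverage`.
#' @export
metagene_profile <- function(reads, transcripts, bin_width = 10,
                             flank5 = 50, flank3 = 200, min_cds_len = 1000,
                             tis_margin = 15) {
  if (bin_width < 1) stopf("'bin_width' must be >= 1")
  check_reads(reads, transcripts)
  tx <- transcripts[transcripts$cds_len > min_cds_len, , drop = FALSE]
  if (nrow(tx) == 0)
    stopf("no transcript passes min_cds_len = %d", min_cds_len)
  by_tx <- split(reads$start, reads$transcript_id)
  regions <- list()
  for (region in c("utr5_flank", "cds", "utr3_flank")) {
    mats <- lapply(seq_len(nrow(tx)), function(i) {
      u5 <- tx$u5_len[i]; cd <- tx$cds_len[i]
      L <- u5 + cd + tx$u3_len[i]
      rng <- switch(region,
                    utr5_flank = c(u5 - flank5 - tis_margin, u5 - tis_margin),
                    cds = c(u5 - tis_margin, u5 + cd),
                    utr3_flank = c(u5 + cd, u5 + cd + flank3))
      starts <- by_tx[[tx$gene_id[i]]] %||% integer(0)
      bin_coverage(starts, rng[1], rng[2], L, bin_width)
    })
    nb <- max(lengths(mats))
    m <- vapply(mats, function(v) c(v, rep(NA_real_, nb - length(v))),
                numeric(nb))
    m <- matrix(m, nrow = nb)
    mean_cov <- rowMeans(m, na.rm = TRUE)
    regions[[region]] <- data.frame(region = region,
                                    bin = seq_len(nb) - 1L,
                                    mean_coverage = mean_cov,
                                    stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out[!is.nan(out$mean_coverage), , drop = FALSE]
}

#' Count reads per gene over coding sequences (union mode)
#'
#' A read is assigned to a gene if its `[start, start + length)` interval
#' overlaps that gene's CDS.  Following HTSeq's union-mode convention, reads
#' whose footprint is compatible with the CDS of more than one gene are
#' discarded as ambiguous, and reads overlapping no CDS are discarded.
#'
#' @inheritParams estimate_psite_offset
#' @param gene_map Optional data.frame (`transcript_id`, `gene_id`) mapping
#'   transcripts to genes; transcripts mapping to several genes make their
#'   reads ambiguous.  Default: each transcript is its own gene.
#' @return Named integer vector of CDS read counts per gene (zero-count
#'   genes included).
#' @export
count_cds_reads <- function(reads, transcripts, gene_map = NULL) {
  check_reads(reads, transcripts)
  if (is.null(gene_map))
    gene_map <- data.frame(transcript_id = transcripts$gene_id,
                           gene_id = transcripts$gene_id,
                           stringsAsFactors = FALSE)
  genes_of <- split(gene_map$gene_id, gene_map$transcript_id)
  n_genes_tx <- lengths(lapply(genes_of, unique))
  cds_lo <- stats::setNames(transcripts$u5_len, transcripts$gene_id)
  cds_hi <- cds_lo + stats::setNames(transcripts$cds_len, transcripts$gene_id)
  lo <- cds_lo[reads$transcript_id]
  hi <- cds_hi[reads$transcript_id]
  overlaps <- reads$start < hi & (reads$start + reads$length) > lo
  unique_gene <- n_genes_tx[reads$transcript_id] == 1
  keep <- overlaps & unique_gene
  gene <- vapply(genes_of, `[[`, "", 1)[reads$transcript_id[keep]]
  all_genes <- sort(unique(gene_map$gene_id))
  counts <- table(factor(gene, levels = all_genes))
  stats::setNames(as.integer(counts), all_genes)
}
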