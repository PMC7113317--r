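# Cross-layer integration: assemble per-gene RNA/RFP/protein fold-change
# triplets, decompose protein changes into regulatory modes, detect
# translational buffering, classify single-inhibitor withdrawal
# dependencies, and compute layer-layer correlations.

#' Assemble uniquely assigned RNA-RFP-protein triplets
#'
#' Joins the three layers per gene for one condition-vs-reference
#' comparison.  Protein groups mapping to more than one gene are dropped
#' (unique assignment), as are genes absent or unquantified in any layer.
#'
#' @param te_results [differential_te()] output for the comparison; only
#'   genes with `passes_filter` and finite statistics are usable.
#' @param protein_results [differential_protein()] output.
#' @param protein_groups data.frame (`protein_group_id`, `gene_ids`
#'   semicolon-joined) mapping groups to genes.
#' @return data.frame, one row per gene: `gene_id`, `protein_group_id`,
#'   `log2fc_rna`, `log2fc_rfp`, `delta_te`, `log2fc_protein`, `te_called`,
#'   `protein_called`.
#' @export
assemble_triplets <- function(te_results, protein_results, protein_groups) {
  if (anyDuplicated(te_results$gene_id))
    stopf("duplicate gene rows in TE results")
  if (anyDuplicated(protein_results$protein_group_id))
    stopf("duplicate protein-group rows in protein results")
  genes_of <- strsplit(protein_groups$gene_ids, ";", fixed = TRUE)
  uniq <- lengths(genes_of) == 1
  map <- data.frame(protein_group_id = protein_groups$protein_group_id[uniq],
                    gene_id = unlist(genes_of[uniq]),
                    stringsAsFactors = FALSE)
  map <- map[map$protein_group_id %in% protein_results$protein_group_id, ]
  if (anyDuplicated(map$gene_id))
    stopf("a gene maps to several unique protein groups")
  te <- te_results[te_results$passes_filter & !is.na(te_results$p), ]
  m <- merge(map, te, by = "gene_id")
  pr <- protein_results[, c("protein_group_id", "log2fc", "called")]
  names(pr) <- c("protein_group_id", "log2fc_protein", "protein_called")
  m <- merge(m, pr, by = "protein_group_id")
  out <- data.frame(gene_id = m$gene_id,
                    protein_group_id = m$protein_group_id,
                    log2fc_rna = m$log2fc_rna, log2fc_rfp = m$log2fc_rfp,
                    delta_te = m$delta_te,
                    log2fc_protein = m$log2fc_protein,
                    te_called = m$called, protein_called = m$protein_called,
                    stringsAsFactors = FALSE)
  out[order(out$gene_id), , drop = FALSE]
}

#' Decompose protein changes into regulatory modes
#'
#' For genes whose protein is called differentially expressed, attributes
#' the protein change to one mutually exclusive mode using absolute fold
#' changes `F = 2^|log2fc|`:
#' \itemize{
#'   \item transcriptional: `F_rna > rna_fc` with RNA and protein changing
#'     in the same direction;
#'   \item translational: otherwise, `F_rfp > rfp_fc` and `F_rna < rna_fc`
#'     with RFP and protein concordant;
#'   \item post_translational: otherwise, `F_rna < rna_fc` and
#'     `F_rfp < rfp_fc`;
#'   \item unclassified: anything else (e.g. discordant signs).
#' }
#' The sign-concordance requirement is an extension of the plain magnitude
#' thresholds: it prevents attributing a protein increase to transcription
#' when the mRNA decreases.
#'
#' @param triplets [assemble_triplets()] output.
#' @param rna_fc,rfp_fc Fold-change thresholds (default 2).
#' @return data.frame: `gene_id`, `mode`, the three fold changes.
#' @export
classify_regulatory_mode <- function(triplets, rna_fc = 2, rfp_fc = 2) {
  t <- triplets[triplets$protein_called, , drop = FALSE]
  f_rna <- 2^abs(t$log2fc_rna)
  f_rfp <- 2^abs(t$log2fc_rfp)
  conc_rna <- sign(t$log2fc_rna) == sign(t$log2fc_protein)
  conc_rfp <- sign(t$log2fc_rfp) == sign(t$log2fc_protein)
  mode <- ifelse(f_rna > rna_fc & conc_rna, "transcriptional",
          ifelse(f_rfp > rfp_fc & f_rna < rna_fc & conc_rfp, "translational",
          ifelse(f_rna < rna_fc & f_rfp < rfp_fc, "post_translational",
                 "unclassified")))
  data.frame(gene_id = t$gene_id, mode = mode,
             log2fc_rna = t$log2fc_rna, log2fc_rfp = t$log2fc_rfp,
             log2fc_protein = t$log2fc_protein,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Detect translationally buffered genes
#'
#' A gene is buffered when it is called differentially translated, its TE
#' change opposes its mRNA change (sign(delta_te) = -sign(log2fc_rna), with
#' a non-zero mRNA change), and its protein stays stable
#' (`2^|log2fc_protein| < protein_fc_max`): opposite mRNA/TE shifts that
#' cancel in protein output.
#'
#' @param triplets [assemble_triplets()] output (with `te_called`).
#' @param protein_fc_max Protein stability gate (default 2-fold).
#' @return data.frame of buffered genes with their fold changes.
#' @export
detect_buffering <- function(triplets, protein_fc_max = 2) {
  buffered <- triplets$te_called &
    2^abs(triplets$log2fc_protein) < protein_fc_max &
    abs(triplets$log2fc_rna) > 0 &
    sign(triplets$delta_te) == -sign(triplets$log2fc_rna)
  out <- triplets[buffered, c("gene_id", "log2fc_rna", "log2fc_rfp",
                              "delta_te", "log2fc_protein")]
  rownames(out) <- NULL
  out
}

#' Classify single-inhibitor withdrawal dependency
#'
#' For proteins differential between the committed states and the ground
#' state, decides which inhibitor maintains their ground-state expression,
#' from two withdrawal cultures: `CHL` (MEK inhibitor PD removed, CH/LIF
#' kept) and `PDL` (GSK3 inhibitor CH removed, PD/LIF kept).  A protein
#' "responds" in a culture when it changes significantly
#' (`fdr < fdr_max`, `2^|log2fc| > fc_min`) in the committed-state
#' direction.  Classes:
#' \itemize{
#'   \item `P`: responds only when PD is removed (PD maintains it);
#'   \item `C`: responds only when CH is removed;
#'   \item `2i`: responds in both withdrawals (needs both inhibitors);
#'   \item `CP`: responds in neither (either inhibitor suffices).
#' }
#'
#' @param prot_calls [differential_protein()] rows for the committed-state
#'   vs ground-state comparison, restricted to called proteins (their
#'   `log2fc` sign defines the committed-state direction).
#' @param fc_chl,fc_pdl [differential_protein()] outputs for the CHL / PDL
#'   cultures vs the ground state.
#' @param fc_min,fdr_max Response thresholds (default 2-fold, FDR 0.05).
#' @return data.frame: `protein_group_id`, `class` (`CP`, `2i`, `P`, `C`,
#'   or `none` when a withdrawal measurement is missing).
#' @export
classify_inhibitor_dependency <- function(prot_calls, fc_chl, fc_pdl,
                                          fc_min = 2, fdr_max = 0.05) {
  ids <- prot_calls$protein_group_id
  dir <- sign(prot_calls$log2fc)
  responds <- function(tbl) {
    i <- match(ids, tbl$protein_group_id)
    ok <- !is.na(i)
    r <- rep(NA, length(ids))
    r[ok] <- !is.na(tbl$fdr[i[ok]]) & tbl$fdr[i[ok]] < fdr_max &
      2^abs(tbl$log2fc[i[ok]]) > fc_min &
      sign(tbl$log2fc[i[ok]]) == dir[ok]
    r
  }
  r_chl <- responds(fc_chl)
  r_pdl <- responds(fc_pdl)
  cls <- ifelse(is.na(r_chl) | is.na(r_pdl), "none",
         ifelse(r_chl & r_pdl, "2i",
         ifelse(r_chl & !r_pdl, "P",
         ifelse(!r_chl & r_pdl, "C", "CP"))))
  if (any(cls == "none"))
    warning(sum(cls == "none"),
            " protein(s) lack a withdrawal measurement; labelled 'none'")
  data.frame(protein_group_id = ids, class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson correlations between fold-change layers
#'
#' Correlation matrix over `log2fc_rna`, `log2fc_rfp`, `log2fc_protein` and
#' `delta_te` across triplet genes.  Zero-variance vectors yield `NA` for
#' their pairs.
#'
#' @param triplets [assemble_triplets()] output with at least 3 genes.
#' @return Symmetric 4x4 correlation matrix with unit diagonal.
#' @export
layer_correlations <- function(triplets) {
  if (nrow(triplets) < 3) stopf("need >= 3 genes for correlations")
  cols <- c("log2fc_rna", "log2fc_rfp", "log2fc_protein", "delta_te")
  x <- as.matrix(triplets[, cols])
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}
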