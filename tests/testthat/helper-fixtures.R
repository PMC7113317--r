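# Shared fixtures, built in code at test time.

# A tiny hand-written transcript table: coordinates are fully known so QC
# expectations can be computed by hand.
toy_transcripts <- function() {
  data.frame(
    gene_id = c("tx1", "tx2"),
    utr5 = c(strrep("A", 20), strrep("C", 30)),
    cds = c(paste0("AUG", strrep("GCU", 30), "UAA"),   # 96 nt
            paste0("AUG", strrep("CGA", 40), "UGA")),  # 126 nt
    utr3 = c(strrep("U", 40), strrep("G", 50)),
    u5_len = c(20L, 30L), cds_len = c(96L, 126L), u3_len = c(40L, 50L),
    stringsAsFactors = FALSE
  )
}

make_reads <- function(transcript_id, start, length = 30L) {
  n <- max(length(transcript_id), length(start))
  data.frame(read_id = sprintf("r%04d", seq_len(n)),
             transcript_id = rep_len(transcript_id, n),
             start = rep_len(start, n),
             length = rep_len(length, n),
             strand = "+", stringsAsFactors = FALSE)
}

# Small protein matrix with a known design.
toy_protein <- function() {
  meta <- data.frame(
    sample = c(paste0("2iL_prot_", 1:3), paste0("SL_prot_", 1:3)),
    condition = rep(c("2iL", "SL"), each = 3),
    layer = "protein", replicate = rep(1:3, 2),
    stringsAsFactors = FALSE
  )
  m <- matrix(rnorm(60, 25, 0.2), nrow = 10,
              dimnames = list(sprintf("P%02d", 1:10), meta$sample))
  list(intensity = m, meta = meta)
}

# The default synthetic cohort used by integration-level checks; built once
# per test run and cached.
default_cohort <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    specs <- generate_gene_specs(2000, seed = 20260101)
    design <- experiment_design()
    counts <- simulate_counts(specs, design, seed = 20260102)
    prot_design <- experiment_design(
      conditions = c("2iL", "SL", "EPI", "CHL", "PDL"), library_depth = 0)
    prot <- simulate_proteins(specs, prot_design,
                              conditions = prot_design$conditions,
                              seed = 20260103)
    te_sl <- differential_te(counts$rna, counts$rfp, counts$meta,
                             "2iL", "SL")
    imputed <- impute_missing(filter_reproducible(prot$intensity, prot$meta),
                              seed = 20260104)
    prot_sl <- differential_protein(imputed, prot$meta, "2iL", "SL")
    prot_chl <- differential_protein(imputed, prot$meta, "2iL", "CHL")
    prot_pdl <- differential_protein(imputed, prot$meta, "2iL", "PDL")
    triplets <- assemble_triplets(te_sl, prot_sl, prot$groups)
    cache <<- list(specs = specs, design = design, counts = counts,
                   prot = prot, te_sl = te_sl, imputed = imputed,
                   prot_sl = prot_sl, prot_chl = prot_chl,
                   prot_pdl = prot_pdl, triplets = triplets)
    cache
  }
})
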