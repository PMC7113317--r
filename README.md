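# ribobuffer

Integrated analysis of the three layers that set protein abundance —
mRNA level (RNA-seq), ribosome occupancy (ribosome profiling), and protein
intensity (label-free proteomics) — across cell states.  The package is
aimed at computational biologists studying translational control, e.g.
during pluripotency-state transitions, who need to answer two questions
per gene:

1. **Is translation efficiency changing?**  TE is the ratio of normalised
   ribosome-footprint (RFP) abundance to normalised mRNA abundance; the
   package tests ΔTE = log₂FC(RFP) − log₂FC(RNA) between conditions.
2. **What drives each protein change?**  Transcription, translation, or
   post-translational control — and in particular, which TE changes are
   *translational buffering*: opposite mRNA/TE shifts that cancel, leaving
   protein output stable.

## The statistics at the core

For each gene passing expression filters (normalised RNA > 50 and
RFP > 25 in all replicates of at least one condition; mean normalised
count ≥ 50 per layer), a delta-method z-test on ΔTE:

    Var(log₂ μ̂) ≈ (1/ln 2)² (1/μ̂ + φ)/n        (NB model, n replicates)
    z = ΔTE / se,   se² = Σ (four condition/layer variance terms)

with φ from a trended (mean-binned, monotone-smoothed) method-of-moments
dispersion estimate.  Calls: BH FDR < 0.1 and TE fold change > 1.5.
Protein calls are pooled-variance t-tests with BH FDR < 0.05 and a
fold-change ≥ 3 gate, after per-sample down-shifted imputation of
left-censored missing values (Normal(μ − 1.8σ, (0.3σ)²)).  Joined
RNA–RFP–protein triplets (unique gene↔protein-group assignment only) are
then classified:

* transcriptional — RNA FC > 2, concordant with the protein change;
* translational — RFP FC > 2, RNA FC < 2, concordant with protein;
* post-translational — RNA and RFP FC < 2;
* buffered — significant ΔTE opposing the RNA change with protein FC < 2.

Supporting machinery: ribosome-profiling QC (P-site offset histogram,
10-nt-bin metagene coverage, union-mode CDS counting), single-inhibitor
withdrawal classes (CP / 2i / P / C truth table), 3'UTR composition and
AU-rich-element (`UAUUUAU`) / PWM motif scanning, exact hypergeometric
enrichment with Benjamini–Hochberg correction, and a seeded synthetic
multi-omics generator with planted ground truth that the test suite
validates every stage against.

## Worked example

```r
library(ribobuffer)
cfg <- pipeline_config(n_genes = 2000, seed = 1)
out <- run_pipeline(cfg, out_dir = "ribobuffer_out")

out$summary$qc$psite_mode
#> [1] -12
unlist(out$summary$regulatory_modes$percent)
#>    transcriptional      translational post_translational       unclassified
#>               80.1                8.8               11.1                0.0
out$summary$buffering
#> $n_buffered
#> [1] 225
#> $n_triplets
#> [1] 1505
unlist(out$summary$correlations)
#>     rna_rfp  te_protein rna_protein
#>   0.7933373   0.1148770   0.7246928
```

Reading the numbers: the P-site offset of −12 nt confirms healthy
footprint geometry; of the proteins called differential, ~80% are
explained by mRNA changes, ~9% by translation and ~11% by
post-translational control; 225 of 1505 triplet genes are translationally
buffered; and the correlation pattern — mRNA and footprint changes tightly
coupled (r = 0.79) while ΔTE barely correlates with protein change
(r = 0.11) — is the signature of pervasive buffering.  `ribobuffer_out/`
contains per-stage TSVs and `summary.json`, all stamped with the
configuration hash; reruns with the same seed are byte-identical.

A command-line wrapper for the same run ships in
`inst/scripts/run_pipeline.R`.

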