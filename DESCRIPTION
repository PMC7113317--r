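Package: ribobuffer
Title: Translational Buffering and Regulatory-Mode Decomposition from
    Ribosome Profiling, RNA-Seq and Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates matched mRNA abundance (RNA-seq), ribosome
    occupancy (ribosome profiling) and label-free protein intensities
    across cell states to quantify translation efficiency (TE), test for
    differential TE, detect translational buffering (opposite mRNA/TE
    changes that leave protein output stable), and decompose protein
    abundance changes into transcriptional, translational and
    post-translational regulatory modes.  Includes ribosome-profiling
    quality control (P-site offset estimation, metagene coverage,
    union-mode CDS counting), left-censored proteomics imputation and
    differential calling, 3'UTR composition and AU-rich-element / PWM
    motif scanning, exact hypergeometric gene-set enrichment with
    Benjamini-Hochberg correction, and a seeded synthetic multi-omics
    generator with planted regulatory ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
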