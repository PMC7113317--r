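# Synthetic multi-omics generator: planted composition, noise models,
# transcript structure, footprint geometry.

test_that("mode apportionment follows largest-remainder rounding exactly", {
  s <- generate_gene_specs(100, c(null = 1.0), seed = 1)
  expect_equal(nrow(s), 100)
  expect_true(all(s$mode == "null"))
  expect_true(all(s$rna_shift == 0 & s$te_shift == 0 & s$protein_shift == 0))

  s <- generate_gene_specs(1000, c(buffered = 0.2, null = 0.8), seed = 1)
  expect_equal(sum(s$mode == "buffered"), 200)

  # Fractions that do not divide n evenly still produce exact totals.
  s <- generate_gene_specs(10, c(transcriptional = 1 / 3, buffered = 1 / 3,
                                 null = 1 / 3), seed = 1)
  expect_equal(nrow(s), 10)
  expect_equal(sort(as.integer(table(s$mode))), c(3L, 3L, 4L))
})

test_that("gene specs are deterministic and obey the mode constraints", {
  a <- generate_gene_specs(300, seed = 42)
  b <- generate_gene_specs(300, seed = 42)
  expect_identical(a, b)

  with(a[a$mode == "buffered", ], {
    expect_true(all(te_shift == -rna_shift) && all(protein_shift == 0))
  })
  with(a[a$mode == "transcriptional", ], {
    expect_true(all(te_shift == 0) && all(protein_shift == rna_shift))
  })
  with(a[a$mode == "translational", ], {
    expect_true(all(rna_shift == 0) && all(protein_shift == te_shift))
  })
  with(a[a$mode == "post_translational", ], {
    expect_true(all(rna_shift == 0) && all(te_shift == 0) &&
                  all(protein_shift != 0))
  })
  expect_true(all(abs(a$rna_shift[a$mode == "null"]) == 0))
})

test_that("gene spec validation rejects bad configurations", {
  expect_error(generate_gene_specs(10, c(null = 0.5)), "sum to 1")
  expect_error(generate_gene_specs(10, c(florp = 1)), "unknown")
  expect_error(generate_gene_specs(10, c(buffered = 1),
                                   effect_sizes = c(buffered = Inf)),
               "finite")
})

test_that("count simulation respects depth, dispersion and planted shifts", {
  specs <- generate_gene_specs(50, c(null = 1), seed = 3)
  des <- experiment_design(library_depth = c(`2iL` = 1e5, SL = 0, EPI = 1e5))
  cnt <- simulate_counts(specs, des, seed = 5)
  expect_true(all(cnt$rna[, grepl("^SL", colnames(cnt$rna))] == 0))
  expect_true(all(cnt$rna >= 0) && all(cnt$rfp >= 0))

  # Poisson limit: dispersion 0 gives variance ~= mean.
  specs1 <- data.frame(gene_id = sprintf("g%d", 1:10000), mode = "null",
                       base_log2_cpm = 5, rna_shift = 0, te_shift = 0,
                       protein_shift = 0, has_are = FALSE,
                       inhibitor_class = NA_character_)
  des1 <- experiment_design(conditions = c("A", "B"),
                            library_depth = 100 * 10000)
  cnt1 <- simulate_counts(specs1, des1, simulation_config(dispersion = 0),
                          seed = 9)
  x <- cnt1$rna[, "A_rna_1"]
  expect_gt(var(x) / mean(x), 0.9)
  expect_lt(var(x) / mean(x), 1.1)

  # A planted rna_shift of 1 log2 unit doubles the mean.
  specs2 <- specs1
  specs2$rna_shift[1:5000] <- 1
  cnt2 <- simulate_counts(specs2, des1, simulation_config(dispersion = 0),
                          seed = 9)
  fc <- mean(cnt2$rna[1:5000, "B_rna_1"]) / mean(cnt2$rna[1:5000, "A_rna_1"])
  # Normalisation of weights within the sample damps the raw 2x slightly;
  # compare against the exact compositional expectation instead.
  expected <- 2 / mean(2^specs2$rna_shift)
  expect_gt(fc / expected, 0.95)
  expect_lt(fc / expected, 1.05)

  expect_error(simulation_config(dispersion = -1), "dispersion")
})

test_that("protein simulation censors on the left and keeps buffered genes flat", {
  specs <- generate_gene_specs(400, seed = 11)
  des <- experiment_design()
  p0 <- simulate_proteins(specs, des,
                          simulation_config(censor_quantile = 0), seed = 2)
  expect_false(anyNA(p0$intensity))

  p <- simulate_proteins(specs, des, seed = 2)
  p2 <- simulate_proteins(specs, des, seed = 2)
  expect_identical(p$intensity, p2$intensity)
  expect_true(anyNA(p$intensity))
  # Missing-marked cells sit below the overall mean (left censoring).
  miss_mean <- mean(p0$intensity[is.na(p$intensity)])
  expect_lt(miss_mean, mean(p0$intensity))

  # Buffered genes have no planted protein shift: fold changes stay within
  # the noise envelope for at least 95% of them.
  sig <- simulation_config()$protein_sigma
  buf <- sprintf("PG_%s", specs$gene_id[specs$mode == "buffered"])
  buf <- intersect(buf, rownames(p0$intensity))
  sl <- grepl("^SL", colnames(p0$intensity))
  il <- grepl("^2iL", colnames(p0$intensity))
  fc <- rowMeans(p0$intensity[buf, sl]) - rowMeans(p0$intensity[buf, il])
  expect_gt(mean(abs(fc) < 3 * sig * sqrt(2 / 3)), 0.95)

  expect_error(simulation_config(censor_quantile = 1), "censor_quantile")
})

test_that("withdrawal cultures respond according to the planted inhibitor class", {
  specs <- generate_gene_specs(600, seed = 13)
  des <- experiment_design(conditions = c("2iL", "SL", "CHL", "PDL"),
                           library_depth = 0)
  p <- simulate_proteins(specs, des,
                         simulation_config(censor_quantile = 0,
                                           ambiguous_fraction = 0,
                                           protein_sigma = 0.05),
                         conditions = des$conditions, seed = 4)
  fc_of <- function(cond) {
    rowMeans(p$intensity[, grepl(paste0("^", cond, "_"), colnames(p$intensity))]) -
      rowMeans(p$intensity[, grepl("^2iL_", colnames(p$intensity))])
  }
  fc_chl <- fc_of("CHL"); fc_pdl <- fc_of("PDL")
  cls <- specs$inhibitor_class[match(sub("^PG_", "", rownames(p$intensity)),
                                     specs$gene_id)]
  shift <- specs$protein_shift[match(sub("^PG_", "", rownames(p$intensity)),
                                     specs$gene_id)]
  expect_true(all(abs(fc_chl[cls %in% c("P", "2i")] -
                        shift[cls %in% c("P", "2i")]) < 0.3))
  expect_true(all(abs(fc_chl[cls %in% c("C", "CP")]) < 0.3))
  expect_true(all(abs(fc_pdl[cls %in% c("C", "2i")] -
                        shift[cls %in% c("C", "2i")]) < 0.3))
  expect_true(all(abs(fc_pdl[cls %in% c("P", "CP")]) < 0.3))
})

test_that("simulated transcripts are structurally valid with planted AREs", {
  specs <- generate_gene_specs(150, seed = 21)
  tx <- simulate_transcripts(specs, seed = 22)
  expect_true(all(substr(tx$cds, 1, 3) == "AUG"))
  last <- substr(tx$cds, tx$cds_len - 2, tx$cds_len)
  expect_true(all(last %in% c("UAA", "UAG", "UGA")))
  expect_true(all(tx$cds_len %% 3 == 0))
  expect_false(any(grepl("[^ACGU]", paste0(tx$utr5, tx$cds, tx$utr3))))

  hits <- scan_exact_motif(tx$utr3, "UAUUUAU")
  expect_true(all(hits[specs$has_are] >= 1))

  # Requested AU content is realised within a tight band on long UTRs.
  specs2 <- generate_gene_specs(40, c(null = 1), seed = 5)
  tx2 <- simulate_transcripts(specs2, utr3_range = c(1000, 1000),
                              utr3_au = 0.8, seed = 6)
  au <- 1 - nchar(gsub("[AU]", "", tx2$utr3)) / nchar(tx2$utr3)
  expect_true(all(au > 0.75 & au < 0.85))

  expect_error(simulate_transcripts(specs, utr3_range = c(2, 3)),
               "impossible")
})

test_that("footprints obey count conservation, lengths, and P-site geometry", {
  specs <- generate_gene_specs(60, seed = 31)
  tx <- simulate_transcripts(specs, cds_range = c(900, 1500), seed = 32)
  fp <- simulate_footprints(tx, n_reads = 1000, seed = 33)
  expect_equal(nrow(fp), 1000)
  expect_true(all(fp$length %in% 28:32))
  tot <- with(tx, u5_len + cds_len + u3_len)
  names(tot) <- tx$gene_id
  expect_true(all(fp$start >= 0))
  expect_true(all(fp$start + fp$length <= tot[fp$transcript_id]))

  # >= 95% of reads have their 5' end 12 nt upstream of a codon boundary.
  u5 <- setNames(tx$u5_len, tx$gene_id)
  rel <- fp$start - u5[fp$transcript_id] + 12
  expect_gt(mean(rel %% 3 == 0 & rel >= 0), 0.95)

  # Multinomial allocation: weights 9:1 recovered within 3 sigma.
  tx2 <- tx[1:2, ]
  fp2 <- simulate_footprints(tx2, te_weights = c(G00001 = 9, G00002 = 1),
                             n_reads = 10000, seed = 34)
  n1 <- sum(fp2$transcript_id == "G00001")
  expect_lt(abs(n1 - 9000), 3 * sqrt(10000 * 0.9 * 0.1))

  expect_error(simulate_footprints(tx[0, ], n_reads = 10), "no transcripts")
  expect_error(simulate_footprints(tx, te_weights = rep(0, nrow(tx)),
                                   n_reads = 10), "te_weights")
})

test_that("generator outputs round-trip through their text formats", {
  specs <- generate_gene_specs(20, seed = 41)
  tx <- simulate_transcripts(specs, seed = 42)
  fa <- tempfile(fileext = ".fa")
  write_transcript_fasta(tx, fa)
  tx2 <- read_transcript_fasta(fa)
  expect_equal(tx2, tx)

  fp <- simulate_footprints(tx, n_reads = 50, seed = 43)
  tf <- tempfile(fileext = ".tsv")
  write_footprint_tsv(fp, tf)
  expect_equal(read_footprint_tsv(tf), fp)

  des <- experiment_design()
  cnt <- simulate_counts(specs, des, seed = 44)
  tm <- tempfile(fileext = ".tsv")
  write_matrix_tsv(cnt$rna, tm, comment = "fixture")
  expect_equal(read_matrix_tsv(tm), cnt$rna)
})
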