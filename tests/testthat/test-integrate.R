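# Cross-layer integration: triplet assembly, regulatory-mode
# classification, buffering detection, inhibitor-withdrawal classes,
# layer correlations.

mk_te <- function(genes, fc_rna = 0, fc_rfp = 0, called = FALSE) {
  n <- length(genes)
  data.frame(gene_id = genes, passes_filter = TRUE,
             log2fc_rna = rep_len(fc_rna, n), log2fc_rfp = rep_len(fc_rfp, n),
             delta_te = rep_len(fc_rfp, n) - rep_len(fc_rna, n),
             p = 0.5, fdr = 0.5, called = rep_len(called, n),
             stringsAsFactors = FALSE)
}

mk_prot <- function(ids, fc = 0, called = FALSE, fdr = 0.5) {
  data.frame(protein_group_id = ids, log2fc = rep_len(fc, length(ids)),
             fdr = rep_len(fdr, length(ids)),
             called = rep_len(called, length(ids)), stringsAsFactors = FALSE)
}

test_that("triplet assembly enforces unique assignment and completeness", {
  te <- mk_te(c("g1", "g2", "g3"))
  prot <- mk_prot(c("PG_g1", "PG_amb", "PG_g3"))
  groups <- data.frame(protein_group_id = c("PG_g1", "PG_amb", "PG_g3"),
                       gene_ids = c("g1", "g2;g4", "g3"),
                       stringsAsFactors = FALSE)
  tr <- assemble_triplets(te, prot, groups)
  expect_setequal(tr$gene_id, c("g1", "g3"))   # ambiguous group dropped

  # A gene unquantified at the TE layer is dropped too.
  te2 <- te; te2$p[te2$gene_id == "g1"] <- NA
  tr2 <- assemble_triplets(te2, prot, groups)
  expect_equal(tr2$gene_id, "g3")

  expect_error(assemble_triplets(rbind(te, te[1, ]), prot, groups),
               "duplicate")
})

test_that("regulatory modes follow the threshold rules from worked examples", {
  tr <- data.frame(
    gene_id = c("t1", "t2", "t3", "t4", "weird"),
    protein_group_id = paste0("PG_", c("t1", "t2", "t3", "t4", "weird")),
    log2fc_rna = c(log2(3), log2(1.5), log2(1.3), -log2(3), log2(1.2)),
    log2fc_rfp = c(log2(3), log2(2.5), log2(1.4), -log2(2.6), log2(2.8)),
    delta_te = 0, log2fc_protein = c(2, 1.8, 1.68, -1.7, -1.9),
    te_called = FALSE, protein_called = TRUE, stringsAsFactors = FALSE)
  res <- classify_regulatory_mode(tr)
  expect_equal(res$mode[match(c("t1", "t2", "t3", "t4"), res$gene_id)],
               c("transcriptional", "translational", "post_translational",
                 "transcriptional"))
  # RFP up but protein down: no rule fits, lands in unclassified.
  expect_equal(res$mode[res$gene_id == "weird"], "unclassified")
  # Partition: every protein-differential gene gets exactly one label.
  expect_equal(nrow(res), sum(tr$protein_called))
  expect_false(anyNA(res$mode))
})

test_that("mode classification matches a truth-table oracle on a sign/threshold grid", {
  oracle <- function(rna, rfp, prot) {
    f_rna <- 2^abs(rna); f_rfp <- 2^abs(rfp)
    if (f_rna > 2 && sign(rna) == sign(prot)) "transcriptional"
    else if (f_rfp > 2 && f_rna < 2 && sign(rfp) == sign(prot)) "translational"
    else if (f_rna < 2 && f_rfp < 2) "post_translational"
    else "unclassified"
  }
  grid <- expand.grid(rna = c(-1.5, -0.5, 0.5, 1.5),
                      rfp = c(-1.5, -0.5, 0.5, 1.5),
                      prot = c(-2, 2))
  tr <- data.frame(gene_id = sprintf("g%d", seq_len(nrow(grid))),
                   protein_group_id = sprintf("p%d", seq_len(nrow(grid))),
                   log2fc_rna = grid$rna, log2fc_rfp = grid$rfp,
                   delta_te = grid$rfp - grid$rna,
                   log2fc_protein = grid$prot,
                   te_called = FALSE, protein_called = TRUE,
                   stringsAsFactors = FALSE)
  res <- classify_regulatory_mode(tr)
  want <- mapply(oracle, grid$rna, grid$rfp, grid$prot)
  expect_equal(res$mode, unname(want))
})

test_that("buffering requires a TE call, opposite signs and stable protein", {
  tr <- data.frame(
    gene_id = c("buf", "same_sign", "prot_moves", "no_call"),
    protein_group_id = paste0("PG_", 1:4),
    log2fc_rna = c(-1.5, 1.2, -1.5, -1.5),
    log2fc_rfp = c(0.1, 2.6, 0.1, 0.1),
    delta_te = c(1.6, 1.4, 1.6, 1.6),
    log2fc_protein = c(0.2, 0.1, 1.5, 0.2),
    te_called = c(TRUE, TRUE, TRUE, FALSE),
    protein_called = FALSE, stringsAsFactors = FALSE)
  res <- detect_buffering(tr)
  expect_equal(res$gene_id, "buf")
})

test_that("inhibitor dependency matches the four-way truth table", {
  calls <- mk_prot(sprintf("p%d", 1:4), fc = 2.5, called = TRUE, fdr = 0.01)
  respond <- function(yes) {
    mk_prot(sprintf("p%d", 1:4),
            fc = ifelse(yes, 2.5, 0.1),
            fdr = ifelse(yes, 0.001, 0.9))
  }
  combos <- expand.grid(chl = c(FALSE, TRUE), pdl = c(FALSE, TRUE))
  for (i in seq_len(nrow(combos))) {
    chl <- respond(rep(combos$chl[i], 4))
    pdl <- respond(rep(combos$pdl[i], 4))
    got <- classify_inhibitor_dependency(calls, chl, pdl)
    want <- if (combos$chl[i] && combos$pdl[i]) "2i"
            else if (combos$chl[i]) "P"
            else if (combos$pdl[i]) "C"
            else "CP"
    expect_equal(got$class, rep(want, 4))
  }

  # Response must be in the committed-state direction: a significant change
  # the other way does not count.
  wrong_dir <- mk_prot(sprintf("p%d", 1:4), fc = -2.5, fdr = 0.001)
  none <- mk_prot(sprintf("p%d", 1:4), fc = 0, fdr = 0.9)
  got <- classify_inhibitor_dependency(calls, wrong_dir, none)
  expect_equal(got$class, rep("CP", 4))

  # Missing withdrawal measurements yield 'none' with a warning.
  expect_warning(
    got2 <- classify_inhibitor_dependency(calls, wrong_dir[1:2, ], none),
    "none")
  expect_equal(got2$class[3:4], c("none", "none"))
})

test_that("layer correlations handle identity, orthogonality and degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  tr <- data.frame(gene_id = sprintf("g%d", 1:5),
                   log2fc_rna = x, log2fc_rfp = x,
                   log2fc_protein = c(1, -1, 0, 1, -1) -
                     mean(c(1, -1, 0, 1, -1)),
                   delta_te = rep(0, 5))
  # Orthogonal by construction: mean-centred dot product zero.
  tr$log2fc_protein <- c(-1, 1, 0, 1, -1)
  r <- layer_correlations(tr)
  expect_equal(r["log2fc_rna", "log2fc_rfp"], 1)
  expect_equal(r["log2fc_rna", "log2fc_protein"], 0)
  expect_true(is.na(r["log2fc_rna", "delta_te"]))  # zero variance
  expect_equal(diag(r), rep(1, 4), ignore_attr = TRUE)
  expect_error(layer_correlations(tr[1:2, ]), ">= 3")
})
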