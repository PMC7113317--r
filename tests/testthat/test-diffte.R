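# Normalisation, expression filtering, TE computation, and the surrogate
# differential-TE test.

mini_meta <- function(conds = c("A", "B"), reps = 2) {
  do.call(rbind, lapply(c("rna", "rfp"), function(layer) {
    do.call(rbind, lapply(conds, function(cond) {
      data.frame(sample = sprintf("%s_%s_%d", cond, layer, seq_len(reps)),
                 condition = cond, layer = layer, replicate = seq_len(reps),
                 stringsAsFactors = FALSE)
    }))
  }))
}

mini_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), dimnames = list(genes, samples))
}

test_that("CPM and median-of-ratios normalisation behave as defined", {
  m <- mini_matrix(c(1, 1, 2), c("g1", "g2", "g3"), "s1")
  expect_equal(as.vector(normalize_counts(m, "cpm")),
               c(250000, 250000, 500000))

  m2 <- mini_matrix(rpois(40, 50) + 1, sprintf("g%d", 1:10),
                    sprintf("s%d", 1:4))
  expect_equal(unname(colSums(normalize_counts(m2, "cpm"))), rep(1e6, 4))

  # Identical samples get identical size factors.
  m3 <- cbind(s1 = c(10, 20, 30), s2 = c(10, 20, 30))
  rownames(m3) <- c("g1", "g2", "g3")
  sf <- attr(normalize_counts(m3, "median_of_ratios"), "size_factors")
  expect_equal(sf[["s1"]], sf[["s2"]])

  m4 <- m3; m4[, 2] <- 0
  expect_error(normalize_counts(m4, "cpm"), "s2")
})

test_that("median-of-ratios size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(31)
  m <- matrix(rnbinom(600, mu = 200, size = 20), nrow = 100,
              dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:6)))
  m[, 4:6] <- m[, 4:6] * 2L
  ours <- attr(normalize_counts(m, "median_of_ratios"), "size_factors")
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("expression filter applies strict per-replicate thresholds", {
  meta <- mini_meta()
  # 3 genes x 4 RNA samples (conditions A and B, 2 replicates each).
  rna <- rbind(pass = c(60, 55, 70, 80), rfp_fail = c(60, 55, 70, 80),
               edge = c(50, 50, 50, 50))
  colnames(rna) <- meta$sample[meta$layer == "rna"]
  rfp <- rbind(pass = c(30, 26, 40, 50), rfp_fail = c(30, 20, 24, 20),
               edge = c(30, 30, 30, 30))
  colnames(rfp) <- meta$sample[meta$layer == "rfp"]
  kept <- filter_expressed(rna, rfp, meta)
  expect_true("pass" %in% kept)
  expect_false("rfp_fail" %in% kept)   # one replicate at 20 <= 25 everywhere
  expect_false("edge" %in% kept)       # RNA exactly 50 fails the strict >
})

test_that("TE is the pseudocounted RFP/RNA ratio on paired samples", {
  meta <- mini_meta(reps = 2)
  genes <- c("g1", "g2", "g3")
  rna <- mini_matrix(rep(10, 12), genes, meta$sample[meta$layer == "rna"])
  rfp <- mini_matrix(rep(20, 12), genes, meta$sample[meta$layer == "rfp"])
  te <- compute_te(rfp, rna, meta, pseudocount = 0)
  expect_equal(unname(te[1, ]), rep(2, 4))
  rfp_same <- mini_matrix(rep(10, 12), genes,
                          meta$sample[meta$layer == "rfp"])
  expect_equal(unname(compute_te(rfp_same, rna, meta, pseudocount = 0.5)[1, ]),
               rep(1, 4))
  rfp0 <- rfp; rfp0[] <- 0
  expect_equal(unname(compute_te(rfp0, rna, meta, 0.5)[1, 1]), 0.5 / 10.5)
  # Unpairable layers are rejected.
  expect_error(compute_te(rfp[, 1:3], rna, meta), "paired")
})

test_that("identical counts give a null differential-TE result", {
  meta <- mini_meta()
  genes <- sprintf("g%d", 1:60)
  set.seed(5)
  base <- matrix(rnbinom(240, mu = 400, size = 50), nrow = 60)
  rna <- base; colnames(rna) <- meta$sample[meta$layer == "rna"]
  rfp <- base; colnames(rfp) <- meta$sample[meta$layer == "rfp"]
  rownames(rna) <- rownames(rfp) <- genes
  # Make condition B an exact copy of condition A in both layers.
  rna[, 3:4] <- rna[, 1:2]; rfp[, 3:4] <- rfp[, 1:2]
  res <- differential_te(rna, rfp, meta, "A", "B")
  expect_equal(res$delta_te, rep(0, 60))
  expect_equal(res$p[res$passes_filter], rep(1, sum(res$passes_filter)))
  expect_false(any(res$called))
})

test_that("differential TE is antisymmetric and scale invariant", {
  specs <- generate_gene_specs(300, seed = 61)
  cnt <- simulate_counts(specs, experiment_design(), seed = 62)
  ab <- differential_te(cnt$rna, cnt$rfp, cnt$meta, "2iL", "SL")
  ba <- differential_te(cnt$rna, cnt$rfp, cnt$meta, "SL", "2iL")
  expect_equal(ab$delta_te, -ba$delta_te, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)

  # Scaling one sample by k leaves CPM-based delta_te essentially unchanged.
  rna2 <- cnt$rna; rna2[, "SL_rna_1"] <- rna2[, "SL_rna_1"] * 5L
  sc <- differential_te(rna2, cnt$rfp, cnt$meta, "2iL", "SL",
                        norm_method = "cpm")
  base <- differential_te(cnt$rna, cnt$rfp, cnt$meta, "2iL", "SL",
                          norm_method = "cpm")
  keep <- base$passes_filter & base$mean_rna > 100
  expect_lt(max(abs(sc$delta_te[keep] - base$delta_te[keep])), 1e-6)

  expect_error(differential_te(cnt$rna, cnt$rfp, cnt$meta, "2iL", "XX"),
               "absent")
})

test_that("planted TE shifts are detected with correct direction", {
  specs <- generate_gene_specs(800, seed = 71)
  cnt <- simulate_counts(specs, experiment_design(), seed = 72)
  res <- differential_te(cnt$rna, cnt$rfp, cnt$meta, "2iL", "SL")
  truth <- specs$te_shift
  called <- res$called
  shifted <- abs(truth) > 0
  expect_gt(mean(called[shifted]), 0.85)
  # Direction: planted higher TE in the reference means delta_te < 0.
  dir_ok <- sign(res$delta_te[called & shifted]) ==
    sign(truth[called & shifted])
  expect_gt(mean(dir_ok), 0.95)
})

test_that("TE set partition equals direct set algebra", {
  mk <- function(genes, called) {
    data.frame(gene_id = genes, called = called,
               delta_te = ifelse(called, 1, 0),
               direction = ifelse(called, "higher_in_alt", NA),
               stringsAsFactors = FALSE)
  }
  genes <- sprintf("g%d", 1:8)
  set.seed(3)
  for (rep in 1:10) {
    ca <- sample(c(TRUE, FALSE), 8, replace = TRUE)
    cb <- sample(c(TRUE, FALSE), 8, replace = TRUE)
    part <- partition_te_sets(mk(genes, ca), mk(genes, cb),
                              labels = c("SL", "EPI"))
    expect_setequal(part$common, genes[ca & cb])
    expect_setequal(part$SL_only, genes[ca & !cb])
    expect_setequal(part$EPI_only, genes[cb & !ca])
    expect_equal(nrow(part$table), sum(ca | cb))
  }
})
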