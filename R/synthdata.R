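# Synthetic multi-omics generator with planted regulatory ground truth.
#
# Every downstream stage of the package (QC, differential TE, proteomics,
# integration, motif analysis) can be validated against the ground truth
# planted here: each simulated gene carries a regulatory mode and per-layer
# log2 effect sizes, and the count / protein / transcript / footprint
# simulators realise those effects under explicit noise models.

REGULATORY_MODES <- c("transcriptional", "translational", "buffered",
                      "post_translational", "null")

#' Default mode fractions for the synthetic cohort
#'
#' The cohort emulates the quantifiable gene subset of a naive-to-primed
#' ESC transition experiment: most genes are unchanged, protein-level changes
#' are predominantly transcriptional in origin, differential-TE genes are
#' mostly translationally buffered, and purely translational regulation of
#' protein output is rare.
#' @return Named numeric vector of fractions summing to 1.
#' @export
default_mode_fractions <- function() {
  c(transcriptional = 0.20, translational = 0.02, buffered = 0.15,
    post_translational = 0.03, null = 0.60)
}

#' Default planted effect sizes (log2 units)
#' @return Named numeric vector: driver shift per non-null mode.
#' @export
default_effect_sizes <- function() {
  c(transcriptional = 2, translational = 2, buffered = 1.5,
    post_translational = 2)
}

#' Generate planted gene specifications
#'
#' Creates the ground-truth table for a synthetic cohort.  Per-mode gene
#' counts follow largest-remainder rounding of `n_genes * mode_fractions`,
#' so the composition is exact and deterministic.  Each non-null gene gets a
#' random sign on its planted shift; the per-layer shifts obey the mode
#' constraints:
#' \itemize{
#'   \item transcriptional: `te_shift = 0`, `protein_shift = rna_shift`
#'   \item translational: `rna_shift = 0`, `protein_shift = te_shift`
#'   \item buffered: `te_shift = -rna_shift`, `protein_shift = 0`
#'   \item post_translational: `rna_shift = te_shift = 0`, `protein_shift != 0`
#'   \item null: all shifts 0
#' }
#' Genes whose protein level is planted to change also receive an
#' `inhibitor_class` (CP / 2i / P / C) used by [simulate_proteins()] to
#' generate single-inhibitor withdrawal cultures.
#'
#' @param n_genes Number of genes.
#' @param mode_fractions Named fractions over the five modes; must sum to 1.
#' @param effect_sizes Named log2 shift magnitudes per non-null mode.
#' @param are_fraction Named per-mode probability that a gene carries a
#'   planted AU-rich element in its 3'UTR; unnamed modes fall back to
#'   `are_background`.
#' @param are_background Baseline ARE probability (default 0.25).
#' @param base_log2_cpm_mean,base_log2_cpm_sd Normal parameters for baseline
#'   expression (log2 CPM of the quantifiable subset).
#' @param seed Integer seed; identical seeds give identical spec tables.
#' @return `data.frame` with columns `gene_id`, `mode`, `base_log2_cpm`,
#'   `rna_shift`, `te_shift`, `protein_shift`, `has_are`, `inhibitor_class`.
#' @export
generate_gene_specs <- function(n_genes,
                                mode_fractions = default_mode_fractions(),
                                effect_sizes = default_effect_sizes(),
                                are_fraction = c(buffered = 0.6),
                                are_background = 0.25,
                                base_log2_cpm_mean = 7.5,
                                base_log2_cpm_sd = 1,
                                seed = NULL) {
  if (n_genes < 1) stopf("'n_genes' must be >= 1")
  if (is.null(names(mode_fractions)) || any(names(mode_fractions) == ""))
    stopf("'mode_fractions' must be a named vector")
  unknown <- setdiff(names(mode_fractions), REGULATORY_MODES)
  if (length(unknown))
    stopf("unknown regulatory mode(s): %s", paste(unknown, collapse = ", "))
  if (abs(sum(mode_fractions) - 1) > 1e-9)
    stopf("'mode_fractions' must sum to 1 (got %.12g)", sum(mode_fractions))
  if (any(!is.finite(effect_sizes)))
    stopf("'effect_sizes' must be finite")

  # Largest-remainder apportionment of genes to modes.
  frac <- mode_fractions[mode_fractions > 0]
  quota <- n_genes * frac
  n_mode <- floor(quota)
  left <- n_genes - sum(n_mode)
  if (left > 0) {
    rem <- quota - n_mode
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    n_mode[take] <- n_mode[take] + 1L
  }
  modes <- rep(names(n_mode), n_mode)

  with_seed(seed, {
    n <- length(modes)
    sign <- sample(c(-1, 1), n, replace = TRUE)
    eff <- ifelse(modes == "null", 0,
                  unname(effect_sizes[modes]) * sign)
    if (any(is.na(eff)))
      stopf("missing effect size for mode(s): %s",
            paste(unique(modes[is.na(eff) & modes != "null"]), collapse = ", "))
    rna <- ifelse(modes %in% c("transcriptional", "buffered"), eff, 0)
    te <- ifelse(modes == "translational", eff,
                 ifelse(modes == "buffered", -eff, 0))
    prot <- ifelse(modes %in% c("transcriptional", "translational",
                                "post_translational"), eff, 0)
    p_are <- ifelse(modes %in% names(are_fraction),
                    unname(are_fraction[modes]), are_background)
    has_are <- stats::runif(n) < p_are
    cls <- rep(NA_character_, n)
    idx <- which(prot != 0)
    if (length(idx))
      cls[idx] <- sample(c("CP", "2i", "P", "C"), length(idx),
                         replace = TRUE, prob = c(0.55, 0.15, 0.20, 0.10))
    data.frame(
      gene_id = sprintf("G%05d", seq_len(n)),
      mode = modes,
      base_log2_cpm = stats::rnorm(n, base_log2_cpm_mean, base_log2_cpm_sd),
      rna_shift = rna,
      te_shift = te,
      protein_shift = prot,
      has_are = has_are,
      inhibitor_class = cls,
      stringsAsFactors = FALSE
    )
  })
}

#' Describe an experiment design
#'
#' @param conditions Ordered character vector of state labels; the first is
#'   the reference state (e.g. `c("2iL", "SL", "EPI")`).  Withdrawal cultures
#'   (`"CHL"` = PD removed, `"PDL"` = CH removed) and transition timepoints
#'   may be appended; they only affect the protein layer unless counts are
#'   simulated for them too.
#' @param n_rna_reps,n_rfp_reps Replicates per condition for the sequencing
#'   layers (minimum 2, mirroring biological duplicates).
#' @param n_prot_reps Protein replicates per condition (minimum 3,
#'   mirroring biological triplicates).
#' @param library_depth Expected reads per RNA/RFP library; either a single
#'   number or a named vector per condition.
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(conditions = c("2iL", "SL", "EPI"),
                              n_rna_reps = 2, n_rfp_reps = 2,
                              n_prot_reps = 3, library_depth = 2e6) {
  if (length(conditions) < 2 || anyDuplicated(conditions))
    stopf("'conditions' must be >= 2 distinct labels (reference first)")
  if (n_rna_reps < 2 || n_rfp_reps < 2)
    stopf("RNA and RFP layers need >= 2 replicates per condition")
  if (n_prot_reps < 3)
    stopf("protein layer needs >= 3 replicates per condition")
  if (any(library_depth < 0)) stopf("'library_depth' must be >= 0")
  depth <- if (length(library_depth) == 1L)
    stats::setNames(rep(library_depth, length(conditions)), conditions)
  else {
    if (!all(conditions %in% names(library_depth)))
      stopf("'library_depth' must name every condition")
    library_depth[conditions]
  }
  structure(list(conditions = conditions, reference = conditions[[1L]],
                 n_rna_reps = as.integer(n_rna_reps),
                 n_rfp_reps = as.integer(n_rfp_reps),
                 n_prot_reps = as.integer(n_prot_reps),
                 library_depth = depth),
            class = "experiment_design")
}

#' Simulation configuration
#'
#' Houses the noise model of the generator.  Counts are negative binomial
#' with `var = mu + dispersion * mu^2` (the common RNA-seq parameterisation;
#' `dispersion = 0` is the Poisson limit).  Protein log2 intensities are
#' normal with sd `protein_sigma`, left-censored: values in the lowest
#' `censor_quantile` of each sample go missing with probability
#' `censor_prob` (missing-not-at-random, the regime that motivates
#' down-shifted imputation).
#'
#' @param dispersion NB dispersion phi >= 0.
#' @param protein_sigma Protein log2 noise sd.
#' @param censor_quantile Fraction of lowest intensities eligible for
#'   missingness, in `[0, 1)`.
#' @param censor_prob Missingness probability inside the censor quantile.
#' @param rfp_scale Ratio of RFP to RNA library depth.
#' @param ambiguous_fraction Fraction of genes hidden inside two-gene
#'   protein groups (exercises the unique-assignment filter).
#' @param protein_base_mean,protein_base_sd Baseline log2 LFQ intensity.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(dispersion = 0.01, protein_sigma = 0.25,
                              censor_quantile = 0.2, censor_prob = 0.8,
                              rfp_scale = 1, ambiguous_fraction = 0.05,
                              protein_base_mean = 26, protein_base_sd = 2) {
  if (dispersion < 0) stopf("'dispersion' must be >= 0")
  if (censor_quantile < 0 || censor_quantile >= 1)
    stopf("'censor_quantile' must be in [0, 1)")
  if (censor_prob < 0 || censor_prob > 1)
    stopf("'censor_prob' must be in [0, 1]")
  if (rfp_scale <= 0) stopf("'rfp_scale' must be > 0")
  if (ambiguous_fraction < 0 || ambiguous_fraction > 0.5)
    stopf("'ambiguous_fraction' must be in [0, 0.5]")
  structure(list(dispersion = dispersion, protein_sigma = protein_sigma,
                 censor_quantile = censor_quantile, censor_prob = censor_prob,
                 rfp_scale = rfp_scale, ambiguous_fraction = ambiguous_fraction,
                 protein_base_mean = protein_base_mean,
                 protein_base_sd = protein_base_sd),
            class = "simulation_config")
}

rnbinom_phi <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate RNA and ribosome-footprint count matrices
#'
#' RNA mean for gene g in sample s of condition c:
#' `2^(base + rna_shift * I[c != reference]) / sum * depth_s`; the RFP mean
#' multiplies in `2^(te_shift * I[c != reference])` and `rfp_scale`.  Counts
#' are NB draws with the configured dispersion.
#'
#' @param specs Gene spec table from [generate_gene_specs()].
#' @param design An [experiment_design()].
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List with integer matrices `rna`, `rfp` (genes x samples) and a
#'   `meta` data.frame (sample, condition, layer, replicate).
#' @export
simulate_counts <- function(specs, design, config = simulation_config(),
                            seed = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(config, "simulation_config"))
  with_seed(seed, {
    layers <- list(rna = design$n_rna_reps, rfp = design$n_rfp_reps)
    meta <- list()
    out <- list()
    for (layer in names(layers)) {
      nrep <- layers[[layer]]
      cols <- list()
      for (cond in design$conditions) {
        shift <- specs$rna_shift * (cond != design$reference)
        if (layer == "rfp")
          shift <- shift + specs$te_shift * (cond != design$reference)
        w <- 2^(specs$base_log2_cpm + shift)
        depth <- design$library_depth[[cond]] *
          if (layer == "rfp") config$rfp_scale else 1
        mu <- w / sum(w) * depth
        for (r in seq_len(nrep)) {
          nm <- sprintf("%s_%s_%d", cond, layer, r)
          cols[[nm]] <- rnbinom_phi(nrow(specs), mu, config$dispersion)
          meta[[nm]] <- data.frame(sample = nm, condition = cond,
                                   layer = layer, replicate = r,
                                   stringsAsFactors = FALSE)
        }
      }
      m <- do.call(cbind, cols)
      rownames(m) <- specs$gene_id
      out[[layer]] <- m
    }
    out$meta <- do.call(rbind, c(meta, list(make.row.names = FALSE)))
    out
  })
}

#' Simulate a label-free proteomics layer
#'
#' Log2 intensity = gene baseline + `protein_shift` (applied in non-reference
#' conditions) + N(0, `protein_sigma`) noise, then left-censored per sample.
#' A fraction of protein groups aggregates two genes (intensities summed on
#' the linear scale) to exercise unique-assignment filtering.  For withdrawal
#' cultures the planted `inhibitor_class` decides whether the shift is
#' realised: in `"CHL"` (PD withdrawn) classes P and 2i respond; in `"PDL"`
#' (CH withdrawn) classes C and 2i respond; class CP responds in neither.
#'
#' @inheritParams simulate_counts
#' @param conditions Conditions to simulate (default: the design's); may
#'   include `"CHL"` / `"PDL"`.
#' @return List: `intensity` (group x sample log2 matrix with `NA` for
#'   missing), `groups` (`protein_group_id`, `gene_ids` semicolon-joined,
#'   `n_genes`), `meta` (sample, condition, layer, replicate).
#' @export
simulate_proteins <- function(specs, design, config = simulation_config(),
                              conditions = design$conditions, seed = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(config, "simulation_config"))
  if (config$censor_quantile >= 1) stopf("'censor_quantile' must be < 1")
  with_seed(seed, {
    n <- nrow(specs)
    base <- stats::rnorm(n, config$protein_base_mean, config$protein_base_sd)
    # Pair off a subset of genes into two-gene protein groups.
    k <- round(config$ambiguous_fraction * n)
    k <- min(k, floor(n / 2))
    amb <- if (k > 0) matrix(sample(n, 2 * k), ncol = 2) else
      matrix(integer(0), ncol = 2)
    single <- setdiff(seq_len(n), as.vector(amb))
    groups <- data.frame(
      protein_group_id = c(sprintf("PG_%s", specs$gene_id[single]),
                           if (k > 0) sprintf("PG_AMB%03d", seq_len(k))),
      gene_ids = c(specs$gene_id[single],
                   if (k > 0) paste(specs$gene_id[amb[, 1]],
                                    specs$gene_id[amb[, 2]], sep = ";")),
      n_genes = c(rep(1L, length(single)), rep(2L, k)),
      stringsAsFactors = FALSE
    )

    shift_for <- function(cond) {
      if (cond == design$reference) return(rep(0, n))
      if (cond == "CHL")
        return(ifelse(specs$inhibitor_class %in% c("P", "2i"),
                      specs$protein_shift, 0))
      if (cond == "PDL")
        return(ifelse(specs$inhibitor_class %in% c("C", "2i"),
                      specs$protein_shift, 0))
      specs$protein_shift
    }

    cols <- list()
    meta <- list()
    for (cond in conditions) {
      mu_gene <- base + shift_for(cond)
      for (r in seq_len(design$n_prot_reps)) {
        val_gene <- mu_gene + stats::rnorm(n, 0, config$protein_sigma)
        lin <- 2^val_gene
        v <- c(val_gene[single],
               if (k > 0) log2(lin[amb[, 1]] + lin[amb[, 2]]))
        nm <- sprintf("%s_prot_%d", cond, r)
        cols[[nm]] <- v
        meta[[nm]] <- data.frame(sample = nm, condition = cond,
                                 layer = "protein", replicate = r,
                                 stringsAsFactors = FALSE)
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- groups$protein_group_id
    # Left-censoring: lowest quantile of each sample goes missing w.p.
    # censor_prob (missing-not-at-random).
    if (config$censor_quantile > 0 && config$censor_prob > 0) {
      for (j in seq_len(ncol(m))) {
        thr <- stats::quantile(m[, j], config$censor_quantile, names = FALSE)
        low <- which(m[, j] <= thr)
        drop <- low[stats::runif(length(low)) < config$censor_prob]
        m[drop, j] <- NA_real_
      }
    }
    list(intensity = m, groups = groups,
         meta = do.call(rbind, c(meta, list(make.row.names = FALSE))))
  })
}

#' Simulate transcript models (5'UTR + CDS + 3'UTR)
#'
#' Sequences are in the RNA alphabet; the CDS starts with AUG, ends with a
#' stop codon and contains no internal stops.  3'UTR base composition is
#' tuned to the requested AU fraction, and genes flagged `has_are` get at
#' least one planted `UAUUUAU` AU-rich element in the 3'UTR.
#'
#' @param specs Gene spec table.
#' @param utr5_range,cds_range,utr3_range Length ranges in nt; CDS lengths
#'   are rounded to codon multiples (minimum 9 nt = start + codon + stop).
#' @param utr3_au Target AU fraction of 3'UTRs.
#' @param are_motif Planted AU-rich element (RNA alphabet).
#' @param seed Integer seed.
#' @return `data.frame` with `gene_id`, `utr5`, `cds`, `utr3` plus length
#'   columns `u5_len`, `cds_len`, `u3_len`.  Transcript coordinates are
#'   0-based half-open; the TIS sits at position `u5_len`.
#' @export
simulate_transcripts <- function(specs, utr5_range = c(30, 150),
                                 cds_range = c(300, 1800),
                                 utr3_range = c(150, 600),
                                 utr3_au = 0.55, are_motif = "UAUUUAU",
                                 seed = NULL) {
  if (cds_range[2] < 9) stopf("'cds_range' cannot accommodate start + codon + stop")
  if (utr5_range[1] < 0 || utr3_range[1] < length(strsplit(are_motif, "")[[1]]))
    stopf("impossible length constraints")
  codons <- apply(expand.grid(B1 = c("A", "C", "G", "U"),
                              B2 = c("A", "C", "G", "U"),
                              B3 = c("A", "C", "G", "U")), 1, paste0,
                  collapse = "")
  stops <- c("UAA", "UAG", "UGA")
  sense <- setdiff(codons, stops)
  rand_seq <- function(len, au) {
    if (len == 0) return("")
    p <- c(A = au / 2, C = (1 - au) / 2, G = (1 - au) / 2, U = au / 2)
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }
  rint <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))
  with_seed(seed, {
    n <- nrow(specs)
    u5l <- rint(n, utr5_range[1], utr5_range[2])
    u3l <- rint(n, utr3_range[1], utr3_range[2])
    cdl <- rint(n, max(9, cds_range[1]), cds_range[2])
    cdl <- pmax(9, (cdl %/% 3) * 3)
    utr5 <- vapply(u5l, rand_seq, "", au = 0.5)
    utr3 <- vapply(u3l, rand_seq, "", au = utr3_au)
    cds <- vapply(cdl, function(L) {
      paste0("AUG",
             paste(sample(sense, L / 3 - 2, replace = TRUE), collapse = ""),
             sample(stops, 1))
    }, "")
    # Plant the ARE by overwriting a random 3'UTR window.
    w <- nchar(are_motif)
    for (i in which(specs$has_are)) {
      pos <- sample(u3l[i] - w + 1, 1)
      substr(utr3[i], pos, pos + w - 1) <- are_motif
    }
    data.frame(gene_id = specs$gene_id, utr5 = utr5, cds = cds, utr3 = utr3,
               u5_len = u5l, cds_len = cdl, u3_len = u3l,
               stringsAsFactors = FALSE)
  })
}

#' Simulate ribosome footprint alignments in transcript coordinates
#'
#' Reads are allocated to transcripts multinomially in proportion to
#' `te_weights`.  Within a transcript most reads decode CDS codons with a
#' fixed P-site geometry: the 5' end sits `p_offset` nt upstream of the
#' decoded codon.  A fraction `tis_fraction` of CDS reads decodes the
#' initiation codon (the start-codon accumulation seen in
#' cycloheximide-treated libraries, which produces the canonical P-site peak
#' upstream of the TIS), the rest are uniform over codons.  A small
#' `utr_fraction` of reads is background placed in UTRs.  Read lengths are
#' uniform on 28-32 nt.
#'
#' @param transcripts Transcript table from [simulate_transcripts()].
#' @param te_weights Named non-negative weights per gene (default uniform).
#' @param n_reads Total reads to emit.
#' @param p_offset P-site offset in nt (default 12 nt upstream).
#' @param tis_fraction Fraction of CDS reads at the initiation codon.
#' @param utr_fraction Fraction of reads placed in UTRs as background.
#' @param read_lengths Candidate footprint lengths.
#' @param seed Integer seed.
#' @return `data.frame` with `read_id`, `transcript_id`, `start` (0-based 5'
#'   end), `length`, `strand` (always `"+"`).
#' @export
simulate_footprints <- function(transcripts, te_weights = NULL,
                                n_reads = 10000, p_offset = 12,
                                tis_fraction = 0.10, utr_fraction = 0.03,
                                read_lengths = 28:32, seed = NULL) {
  if (n_reads < 0) stopf("'n_reads' must be >= 0")
  if (nrow(transcripts) == 0) {
    if (n_reads > 0) stopf("no transcripts to place %d reads on", n_reads)
    return(data.frame(read_id = character(0), transcript_id = character(0),
                      start = integer(0), length = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  w <- if (is.null(te_weights)) stats::setNames(rep(1, nrow(transcripts)),
                                                transcripts$gene_id)
       else te_weights[transcripts$gene_id]
  if (any(is.na(w)) || any(w < 0) || sum(w) <= 0)
    stopf("'te_weights' must be non-negative, cover all genes, and not all zero")
  with_seed(seed, {
    per_tx <- as.vector(stats::rmultinom(1, n_reads, w))
    tot_len <- transcripts$u5_len + transcripts$cds_len + transcripts$u3_len
    res_tx <- rep(transcripts$gene_id, per_tx)
    starts <- integer(n_reads)
    lens <- sample(read_lengths, n_reads, replace = TRUE)
    pos <- 1L
    for (i in seq_len(nrow(transcripts))) {
      m <- per_tx[i]
      if (m == 0) next
      u5 <- transcripts$u5_len[i]; L <- tot_len[i]
      ncod <- transcripts$cds_len[i] / 3
      idx <- pos:(pos + m - 1L)
      li <- lens[idx]
      # Valid decoded-codon range so the read stays inside the transcript.
      kmin <- max(0, ceiling((p_offset - u5) / 3))
      in_utr <- stats::runif(m) < utr_fraction
      kmax <- pmin(floor((L - li + p_offset - u5) / 3), ncod - 1)
      kmax <- pmax(kmax, kmin)
      at_tis <- !in_utr & (stats::runif(m) < tis_fraction) & kmin == 0
      k <- kmin + floor(stats::runif(m) * (kmax - kmin + 1))
      k[at_tis] <- 0L
      s <- u5 + 3 * k - p_offset
      # Background reads: uniform over UTR positions where the read fits.
      if (any(in_utr)) {
        for (j in which(in_utr)) {
          cand_u5 <- if (u5 > 0) seq.int(0L, u5 - 1L) else integer(0)
          lo3 <- u5 + transcripts$cds_len[i]
          cand_u3 <- if (L - li[j] >= lo3) seq.int(lo3, L - li[j]) else integer(0)
          cand <- c(cand_u5, cand_u3)
          s[j] <- if (length(cand)) cand[sample.int(length(cand), 1)] else s[j]
        }
      }
      s <- pmax(0L, pmin(as.integer(s), L - li))
      starts[idx] <- s
      pos <- pos + m
    }
    data.frame(read_id = sprintf("r%06d", seq_len(n_reads)),
               transcript_id = res_tx, start = starts, length = lens,
               strand = "+", stringsAsFactors = FALSE)
  })
}
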