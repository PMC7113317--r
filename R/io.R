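# Readers and writers for the plain-text interchange formats used across
# the package: count TSVs with a sample-metadata sidecar, transcript FASTA
# with UTR/CDS structure encoded in the header, BED-like footprint TSVs,
# GMT gene sets and MEME-minimal motifs.

#' Write / read a gene x sample count or intensity matrix as TSV
#'
#' First column `gene_id`, one column per sample.  Missing values are
#' written as `NA`.
#' @param mat Numeric matrix with row and column names.
#' @param path Output file.
#' @param comment Optional comment line(s) written with a `#` prefix.
#' @export
write_matrix_tsv <- function(mat, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @return `read_matrix_tsv`: the numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a sample metadata sidecar TSV
#'
#' Columns: sample, condition, layer, replicate.
#' @param meta Metadata data.frame.
#' @param path File path.
#' @param comment Optional `#` comment line(s).
#' @export
write_meta_tsv <- function(meta, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(meta, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meta_tsv
#' @export
read_meta_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write transcript models to FASTA
#'
#' Header convention: `>gene_id|u5=<len>|cds=<len>|u3=<len>`; the sequence is
#' the concatenated 5'UTR + CDS + 3'UTR in the RNA alphabet.
#' @param transcripts Transcript table ([simulate_transcripts()] layout).
#' @param path Output FASTA.
#' @export
write_transcript_fasta <- function(transcripts, path) {
  seqs <- Biostrings::RNAStringSet(paste0(transcripts$utr5, transcripts$cds,
                                          transcripts$utr3))
  names(seqs) <- sprintf("%s|u5=%d|cds=%d|u3=%d", transcripts$gene_id,
                         transcripts$u5_len, transcripts$cds_len,
                         transcripts$u3_len)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read transcript models from FASTA
#'
#' Inverse of [write_transcript_fasta()]; the UTR/CDS segmentation is parsed
#' from the header.
#' @param path FASTA file.
#' @return Transcript table with `gene_id`, `utr5`, `cds`, `utr3`, `u5_len`,
#'   `cds_len`, `u3_len`.
#' @export
read_transcript_fasta <- function(path) {
  seqs <- Biostrings::readRNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- lengths(parts) != 4
  if (any(bad))
    stopf("malformed FASTA header: %s", names(seqs)[which(bad)[1]])
  field <- function(p, i, key) {
    v <- sub(paste0("^", key, "="), "", p[[i]])
    as.integer(v)
  }
  gene <- vapply(parts, `[[`, "", 1)
  u5 <- vapply(parts, field, 0L, i = 2, key = "u5")
  cd <- vapply(parts, field, 0L, i = 3, key = "cds")
  u3 <- vapply(parts, field, 0L, i = 4, key = "u3")
  s <- as.character(seqs)
  data.frame(gene_id = gene,
             utr5 = unname(substr(s, 1, u5)),
             cds = unname(substr(s, u5 + 1, u5 + cd)),
             utr3 = unname(substr(s, u5 + cd + 1, u5 + cd + u3)),
             u5_len = u5, cds_len = cd, u3_len = u3,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write / read footprint alignments as a BED-like TSV
#'
#' Six columns, 0-based half-open: transcript_id, start, end, read_id,
#' length, strand.
#' @param reads Footprint table ([simulate_footprints()] layout).
#' @param path File path.
#' @export
write_footprint_tsv <- function(reads, path) {
  bed <- data.frame(transcript_id = reads$transcript_id, start = reads$start,
                    end = reads$start + reads$length, read_id = reads$read_id,
                    length = reads$length, strand = reads$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_footprint_tsv
#' @export
read_footprint_tsv <- function(path) {
  bed <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(read_id = bed$read_id, transcript_id = bed$transcript_id,
             start = bed$start, length = bed$length, strand = bed$strand,
             stringsAsFactors = FALSE)
}

#' Read / write gene sets in GMT format
#'
#' One term per line: term id, description, then tab-separated members.
#' @param path GMT file.
#' @return `read_gmt`: named list of character vectors (the descriptions are
#'   kept in a `"descriptions"` attribute).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3))
    stopf("malformed GMT line (need term, description, >=1 member)")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, "", 2), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets Named list of member vectors.
#' @param descriptions Optional named descriptions (defaults to term ids).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  desc <- descriptions %||% stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix` sections and
#' the optional `Background letter frequencies` line.  DNA alphabets are
#' converted to RNA (T -> U).
#' @param path MEME minimal file.
#' @return List of motifs; each is a list with `motif_id`, `matrix`
#'   (positions x 4, columns A/C/G/U) and `background` (length-4 vector).
#' @export
read_meme <- function(path) {
  lines <- trimws(readLines(path))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(lines[bg_at[1] + 1], "\\s+")[[1]]
    if (length(toks) >= 8) {
      vals <- as.numeric(toks[seq(2, 8, by = 2)])
      keys <- chartr("T", "U", toupper(toks[seq(1, 7, by = 2)]))
      bg[keys] <- vals
    }
  }
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stopf("no MOTIF blocks in '%s'", path)
  motifs <- lapply(starts, function(i) {
    id <- strsplit(lines[i], "\\s+")[[1]][2]
    j <- i + 1
    while (j <= length(lines) &&
           !grepl("^letter-probability matrix", lines[j])) j <- j + 1
    if (j > length(lines))
      stopf("motif '%s' lacks a letter-probability matrix", id)
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
    rows <- lines[(j + 1):(j + w)]
    m <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
    if (ncol(m) != 4) stopf("motif '%s': expected 4 columns", id)
    colnames(m) <- c("A", "C", "G", "U")
    if (any(abs(rowSums(m) - 1) > 1e-4))
      stopf("motif '%s': probability rows must sum to 1", id)
    list(motif_id = id, matrix = m, background = bg)
  })
  stats::setNames(motifs, vapply(motifs, `[[`, "", "motif_id"))
}
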