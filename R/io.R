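# Small readers/writers around the standard formats. FASTA/FASTQ I/O goes
# through Biostrings; tables are plain TSV written deterministically.

read_seq_file <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  Biostrings::readDNAStringSet(path, format = fmt)
}

#' Read a FASTQ file with qualities
#'
#' @param path FASTQ file (Phred+33).
#' @return `QualityScaledDNAStringSet`.
#' @export
read_fastq <- function(path) {
  # this Biostrings version warns about dropped metadata columns while
  # assembling the quality-scaled set; the columns are not used here
  suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
}

write_fasta <- function(seqs, path, names = NULL) {
  x <- Biostrings::DNAStringSet(seqs)
  if (!is.null(names)) names(x) <- names
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# dummy-quality FASTQ ('I' = Q40), the on-disk form of simulated reads
write_fastq <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%07d", seq_along(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  qual <- strrep("I", nchar(seqs))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- formatC(df[[j]], digits = digits,
                                           format = "g")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write per-library collapsed FASTA of unique tags
#'
#' Headers follow the `tag{serial}_x{count}` convention.
#'
#' @param tags a `tag_set`.
#' @param dir output directory.
#' @return paths of the written files, one per library.
#' @export
write_collapsed_fasta <- function(tags, dir) {
  libs <- attr(tags, "libraries")
  cnt <- tag_counts(tags)
  paths <- character(0)
  for (lib in libs) {
    keep <- cnt[, lib] > 0
    p <- file.path(dir, paste0("tags_", lib, ".fa"))
    write_fasta(tags$sequence[keep], p,
                names = sprintf("tag%d_x%d", which(keep), cnt[keep, lib]))
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a collapsed FASTA (`tag{serial}_x{count}` headers) into sequences
#' and counts
#'
#' @param path collapsed FASTA file.
#' @return data frame with `sequence` and `count`.
#' @export
read_collapsed_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  cnt <- suppressWarnings(as.integer(sub("^.*_x", "", names(ss))))
  if (anyNA(cnt)) stop("headers are not in tag{serial}_x{count} form")
  data.frame(sequence = as.character(ss), count = cnt,
             stringsAsFactors = FALSE)
}

# GFF3 of precursor/mature/star spans on the unigenes
write_precursor_gff3 <- function(precursors, path) {
  if (!length(precursors)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  feat <- function(id, prec, type, span) {
    if (is.null(span)) return(NULL)
    if (prec$strand == "+") {
      s <- prec$start + span[1] - 1L
      e <- prec$start + span[2] - 1L
    } else {
      e <- prec$end - span[1] + 1L
      s <- prec$end - span[2] + 1L
    }
    GenomicRanges::GRanges(prec$unigene,
                           IRanges::IRanges(s, e), strand = prec$strand,
                           type = type, ID = paste0(id, "_", type))
  }
  grl <- list()
  for (id in names(precursors)) {
    prec <- precursors[[id]]
    n <- nchar(prec$sequence)
    grl <- c(grl, list(feat(id, prec, "miRNA_primary_transcript", c(1L, n)),
                       feat(id, prec, "miRNA", prec$mature_span),
                       feat(id, prec, "miRNA_star", prec$star_span)))
  }
  gr <- do.call(c, grl[!vapply(grl, is.null, logical(1))])
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
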