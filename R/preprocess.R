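# Cleaning of raw sRNA reads into per-library unique tags with counts.

#' Trim the 3' adaptor from raw sRNA reads
#'
#' Removes everything from the leftmost adaptor occurrence onward. Adaptor
#' evidence is either a full-adaptor match anywhere in the read or an exact
#' match of at least `min_overlap` nt of the adaptor 5' end at the read
#' 3' end. Reads with no adaptor evidence pass through unchanged; empty
#' reads are rejected (returned as `NA`).
#'
#' @param reads character vector of raw read sequences.
#' @param adaptor3 3' adaptor sequence (DNA).
#' @param min_overlap minimum adaptor prefix length accepted at the read
#'   3' end (default 5).
#' @return character vector of trimmed inserts; `NA` marks rejected reads.
#' @export
trim_adaptor <- function(reads, adaptor3, min_overlap = 5L) {
  if (!nzchar(adaptor3)) stop("adaptor3 must be non-empty")
  if (min_overlap < 1) stop("min_overlap must be positive")
  reads <- toupper(reads)
  n <- length(reads)
  len <- nchar(reads)
  insert <- len
  # full adaptor anywhere
  pos <- regexpr(adaptor3, reads, fixed = TRUE)
  hit <- pos > 0
  insert[hit] <- pmin(insert[hit], pos[hit] - 1L)
  # partial adaptor prefix at the read 3' end
  la <- nchar(adaptor3)
  for (k in seq(min_overlap, la - 1L)) {
    pre <- substr(adaptor3, 1L, k)
    suf <- endsWith(reads, pre)
    insert[suf] <- pmin(insert[suf], len[suf] - k)
  }
  out <- substr(reads, 1L, insert)
  out[len == 0L | is.na(reads)] <- NA_character_
  out
}

junk_read <- function(seqs, max_mono = 0.8) {
  x <- Biostrings::DNAStringSet(seqs)
  freq <- Biostrings::letterFrequency(x, c("A", "C", "G", "T", "N"))
  has_n <- freq[, "N"] > 0
  mono <- apply(freq[, c("A", "C", "G", "T"), drop = FALSE], 1, max) /
    Biostrings::width(x)
  has_n | mono >= max_mono
}

#' Filter trimmed reads and collapse them into unique tags
#'
#' Removes junk reads (containing N, or with one nucleotide making up at
#' least 80% of the read), keeps lengths within `len_range`, collapses
#' identical sequences into unique tags with per-library counts, and
#' computes reads-per-million against each library's clean-read total
#' (the total of all surviving reads, fixed at this step).
#'
#' @param reads named list, one character vector of trimmed reads per
#'   library (`NA` entries, e.g. from [trim_adaptor()] rejections, are
#'   dropped and reported).
#' @param len_range inclusive length window, default 18-30 nt.
#' @param max_mono homopolymer fraction above which a read is junk.
#' @return a `tag_set`: data frame with `sequence`, `count.<lib>` and
#'   `rpm.<lib>` columns; attributes `totals` (clean-read totals) and
#'   `removed` (per-library removal counts by reason).
#' @export
filter_and_collapse <- function(reads, len_range = c(18L, 30L),
                                max_mono = 0.8) {
  stopifnot(is.list(reads), !is.null(names(reads)))
  libs <- names(reads)
  kept <- list()
  removed <- matrix(0L, nrow = length(libs), ncol = 4,
                    dimnames = list(libs, c("empty", "junk", "too_short",
                                            "too_long")))
  for (lib in libs) {
    r <- reads[[lib]]
    bad <- is.na(r) | !nzchar(r)
    removed[lib, "empty"] <- sum(bad)
    r <- toupper(r[!bad])
    if (length(r)) {
      jk <- junk_read(r, max_mono)
      removed[lib, "junk"] <- sum(jk)
      r <- r[!jk]
    }
    ln <- nchar(r)
    removed[lib, "too_short"] <- sum(ln < len_range[1])
    removed[lib, "too_long"] <- sum(ln > len_range[2])
    r <- r[ln >= len_range[1] & ln <= len_range[2]]
    if (!length(r)) stop("library empty after cleaning: ", lib)
    kept[[lib]] <- r
  }
  all_seq <- sort(unique(unlist(kept, use.names = FALSE)))
  counts <- vapply(libs, function(lib) {
    tab <- table(factor(kept[[lib]], levels = all_seq))
    as.integer(tab)
  }, integer(length(all_seq)))
  counts <- matrix(counts, ncol = length(libs),
                   dimnames = list(NULL, libs))
  totals <- setNames(colSums(counts), libs)
  rpm <- sweep(counts, 2, totals, "/") * 1e6
  df <- data.frame(sequence = all_seq, stringsAsFactors = FALSE)
  for (lib in libs) df[[paste0("count.", lib)]] <- counts[, lib]
  for (lib in libs) df[[paste0("rpm.", lib)]] <- rpm[, lib]
  structure(df, totals = totals, libraries = libs,
            removed = removed, class = c("tag_set", "data.frame"))
}

#' Accessors for a `tag_set`
#'
#' `tag_counts()` and `tag_rpm()` return the per-library count and RPM
#' matrices (tags x libraries); `tag_totals()` returns the clean-read
#' totals used as RPM denominators.
#'
#' @param tags a `tag_set` from [filter_and_collapse()].
#' @export
tag_counts <- function(tags) {
  libs <- attr(tags, "libraries")
  m <- as.matrix(tags[paste0("count.", libs)])
  colnames(m) <- libs
  m
}

#' @rdname tag_counts
#' @export
tag_rpm <- function(tags) {
  libs <- attr(tags, "libraries")
  m <- as.matrix(tags[paste0("rpm.", libs)])
  colnames(m) <- libs
  m
}

#' @rdname tag_counts
#' @export
tag_totals <- function(tags) attr(tags, "totals")

# rebuild a tag_set from a subset of rows, preserving totals
subset_tags <- function(tags, keep) {
  structure(tags[keep, , drop = FALSE], totals = attr(tags, "totals"),
            libraries = attr(tags, "libraries"),
            removed = attr(tags, "removed"),
            class = c("tag_set", "data.frame"))
}

#' Remove structural-RNA contaminant tags
#'
#' A tag is removed if and only if its sequence occurs as an exact
#' substring, on either strand, of any contaminant record (rRNA, tRNA,
#' snRNA, snoRNA, ...). The contaminant class is taken from the first
#' `_`/whitespace-delimited token of each FASTA header.
#'
#' @param tags a `tag_set` from [filter_and_collapse()].
#' @param contaminants path to a contaminant FASTA file, or a named
#'   character vector of contaminant sequences.
#' @return list with `tags` (filtered `tag_set`) and `report`
#'   (data frame of removed tag/read counts per contaminant class).
#' @export
remove_contaminants <- function(tags, contaminants) {
  if (is.character(contaminants) && length(contaminants) == 1 &&
      !grepl("^[ACGTUNacgtun]+$", contaminants)) {
    if (!file.exists(contaminants))
      stop("contaminant file not found: ", contaminants)
    ss <- Biostrings::readDNAStringSet(contaminants)
    contaminants <- setNames(as.character(ss), names(ss))
  }
  if (is.null(names(contaminants)))
    stop("contaminant sequences must be named by class")
  classes <- sub("[_ \t].*$", "", names(contaminants))
  widths <- sort(unique(nchar(tags$sequence)))
  idx <- window_index(unname(as_dna(contaminants)), classes, widths)
  hit_class <- vapply(tags$sequence, function(s) {
    v <- idx[[s]]
    if (is.null(v)) NA_character_ else v
  }, character(1), USE.NAMES = FALSE)
  removed <- !is.na(hit_class)
  cnt <- tag_counts(tags)
  libs <- attr(tags, "libraries")
  if (any(removed)) {
    by_class <- split(seq_len(nrow(tags))[removed], hit_class[removed])
    report <- data.frame(
      class = names(by_class),
      tags_removed = vapply(by_class, length, integer(1)),
      reads_removed = vapply(by_class, function(i)
        sum(cnt[i, , drop = FALSE]), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    report <- data.frame(class = character(0), tags_removed = integer(0),
                         reads_removed = numeric(0))
  }
  list(tags = subset_tags(tags, !removed), report = report,
       removed_reads = colSums(cnt[removed, , drop = FALSE]))
}

#' Length distribution of unique tags and of clean reads
#'
#' @param tags a `tag_set`.
#' @param len_range length window to tabulate over (default 18-30).
#' @return data frame with one row per length: `unique_tags`, per-library
#'   read counts `reads.<lib>`, and `reads_total`.
#' @export
length_distribution <- function(tags, len_range = c(18L, 30L)) {
  lens <- seq(len_range[1], len_range[2])
  L <- nchar(tags$sequence)
  cnt <- tag_counts(tags)
  libs <- attr(tags, "libraries")
  out <- data.frame(length = lens)
  out$unique_tags <- vapply(lens, function(l) sum(L == l), integer(1))
  for (lib in libs)
    out[[paste0("reads.", lib)]] <-
      vapply(lens, function(l) sum(cnt[L == l, lib]), numeric(1))
  out$reads_total <- rowSums(out[paste0("reads.", libs)])
  out
}
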