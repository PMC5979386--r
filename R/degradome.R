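# Degradome (PARE) target identification: tag cleaning and exact mapping,
# degradation profiles, Allen complementarity scoring, cleavage-site
# calling, category 0-4 classification and permutation p-values.

#' Clean degradome tags and map them exactly to the unigenes
#'
#' Tags shorter than `min_tag_len`, containing N, or occurring as exact
#' substrings (either strand) of a contaminant record are removed. The
#' survivors are matched as exact sense-strand substrings of the unigenes;
#' a tag mapping to m positions contributes count/m to each (fractional
#' multireads). Profiles are indexed by the 5'-end position of the tag.
#'
#' @param tags character vector of tag sequences (one element per read),
#'   or a path to a FASTA/FASTQ file.
#' @param unigenes `DNAStringSet` or FASTA path.
#' @param contaminants optional contaminant FASTA path or named sequence
#'   vector (see [remove_contaminants()]).
#' @param min_tag_len minimal tag length kept after cleaning (default 15).
#' @return a `degradome_profile`: list with `profiles` (named list of
#'   per-transcript numeric vectors of 5'-end counts), `total_tags`,
#'   `n_mapped`, `n_removed`.
#' @export
clean_and_map_tags <- function(tags, unigenes, contaminants = NULL,
                               min_tag_len = 15L) {
  if (is.character(unigenes) && length(unigenes) == 1 &&
      file.exists(unigenes))
    unigenes <- Biostrings::readDNAStringSet(unigenes)
  if (!length(unigenes)) stop("empty unigene set")
  names(unigenes) <- sub("\\s.*$", "", names(unigenes))
  if (length(tags) == 1 && file.exists(tags))
    tags <- as.character(read_seq_file(tags))
  tags <- toupper(tags)
  n_in <- length(tags)
  keep <- nchar(tags) >= min_tag_len & !grepl("N", tags, fixed = TRUE)
  tags <- tags[keep]
  # collapse
  tab <- table(tags)
  useq <- names(tab)
  ucnt <- as.numeric(tab)
  if (!is.null(contaminants)) {
    if (is.character(contaminants) && length(contaminants) == 1 &&
        file.exists(contaminants)) {
      ss <- Biostrings::readDNAStringSet(contaminants)
      contaminants <- setNames(as.character(ss), names(ss))
    }
    classes <- sub("[_ \t].*$", "", names(contaminants))
    idx <- window_index(unname(as_dna(contaminants)), classes,
                        sort(unique(nchar(useq))))
    contam <- vapply(useq, function(s) !is.null(idx[[s]]), logical(1),
                     USE.NAMES = FALSE)
    useq <- useq[!contam]
    ucnt <- ucnt[!contam]
  }
  profiles <- lapply(Biostrings::width(unigenes), numeric)
  names(profiles) <- names(unigenes)
  n_mapped <- 0
  if (length(useq)) {
    by_w <- split(seq_along(useq), nchar(useq))
    for (w in names(by_w)) {
      ii <- by_w[[w]]
      pd <- Biostrings::PDict(useq[ii])
      hits <- vector("list", length(ii))  # per tag: list of (tx, start)
      for (u in seq_along(unigenes)) {
        mt <- Biostrings::matchPDict(pd, unigenes[[u]])
        st <- Biostrings::startIndex(mt)
        for (t in seq_along(ii)) {
          if (!is.null(st[[t]]) && length(st[[t]]))
            hits[[t]] <- c(hits[[t]], list(cbind(u, st[[t]])))
        }
      }
      for (t in seq_along(ii)) {
        if (is.null(hits[[t]])) next
        locs <- do.call(rbind, hits[[t]])
        m <- nrow(locs)
        frac <- ucnt[ii[t]] / m
        for (r in seq_len(m)) {
          u <- locs[r, 1]; s <- locs[r, 2]
          profiles[[u]][s] <- profiles[[u]][s] + frac
        }
        n_mapped <- n_mapped + ucnt[ii[t]]
      }
    }
  }
  profiles <- profiles[vapply(profiles, function(p) any(p > 0),
                              logical(1))]
  structure(list(profiles = profiles, total_tags = sum(ucnt),
                 n_mapped = n_mapped, n_removed = n_in - sum(ucnt)),
            class = "degradome_profile")
}

#' Allen complementarity score of a miRNA against one target window
#'
#' Position penalties against the reverse complement of the miRNA:
#' match 0, G:U wobble 0.5, mismatch 1, doubled at miRNA positions 2-13
#' (the 5' core). A perfect complement scores 0; low scores are good.
#'
#' @param mirna miRNA sequence (RNA or DNA, read 5' to 3').
#' @param window transcript subsequence of the same length (sense strand).
#' @param core_from,core_to,core_mult core-doubling region and factor.
#' @return list with `score` and `pattern` (per miRNA position:
#'   match/GU/mismatch, 5' to 3').
#' @export
score_alignment <- function(mirna, window, core_from = 2L, core_to = 13L,
                            core_mult = 2) {
  mirna <- as_rna(mirna); window <- as_dna(window)
  if (!grepl("^[ACGU]+$", mirna) || !grepl("^[ACGT]+$", window))
    stop("non-nucleotide characters in miRNA or window")
  L <- nchar(mirna)
  if (nchar(window) != L) stop("window length must equal miRNA length")
  sc <- .allen_scan_cpp(mirna, window, core_from, core_to, core_mult)[1]
  mb <- strsplit(mirna, "")[[1]]
  tb <- rev(strsplit(window, "")[[1]])  # tb[k] pairs miRNA position k
  pattern <- vapply(seq_len(L), function(k) {
    m <- mb[k]; t <- tb[k]
    if ((m == "A" && t == "T") || (m == "C" && t == "G") ||
        (m == "G" && t == "C") || (m == "U" && t == "A")) "match"
    else if ((m == "G" && t == "T") || (m == "U" && t == "G")) "GU"
    else "mismatch"
  }, character(1))
  list(score = sc, pattern = pattern)
}

#' Candidate cleavage sites of a miRNA on one transcript
#'
#' Slides the miRNA over every window of the transcript, keeps alignments
#' with Allen score <= `score_cutoff`, sets the cleavage position to the
#' transcript coordinate pairing miRNA nucleotide `cut_pos` (default 10,
#' the canonical 10-11 cut), and requires at least one degradome tag
#' 5' end at that position.
#'
#' @param mirna miRNA sequence.
#' @param transcript transcript sequence (sense strand, DNA).
#' @param profile numeric vector of per-position degradome 5'-end counts
#'   for this transcript.
#' @param score_cutoff maximal Allen score (default 7).
#' @param cut_pos miRNA nucleotide opposite the cut (default 10).
#' @inheritParams score_alignment
#' @return data frame: window start/end (`target_start`, `target_end`),
#'   `score`, `cleavage_pos`, `tags_at_site`.
#' @export
find_sites <- function(mirna, transcript, profile, score_cutoff = 7,
                       cut_pos = 10L, core_from = 2L, core_to = 13L,
                       core_mult = 2) {
  mirna <- as_rna(mirna); transcript <- as_dna(transcript)
  L <- nchar(mirna)
  n <- nchar(transcript)
  empty <- data.frame(target_start = integer(0), target_end = integer(0),
                      score = numeric(0), cleavage_pos = integer(0),
                      tags_at_site = numeric(0))
  if (n < L) return(empty)
  if (length(profile) != n)
    stop("profile length must equal transcript length")
  sc <- .allen_scan_cpp(mirna, transcript, core_from, core_to, core_mult)
  w <- which(sc <= score_cutoff + 1e-9)
  if (!length(w)) return(empty)
  cpos <- w + L - cut_pos
  ok <- cpos >= 1 & cpos <= n
  w <- w[ok]; cpos <- cpos[ok]
  ok <- profile[cpos] >= 1 - 1e-9
  w <- w[ok]; cpos <- cpos[ok]
  if (!length(w)) return(empty)
  data.frame(target_start = w, target_end = w + L - 1L,
             score = sc[w], cleavage_pos = cpos,
             tags_at_site = profile[cpos])
}

#' Classify a cleavage site into categories 0-4
#'
#' Category 0: more than one tag at the site, abundance equal to the
#' transcript maximum, a unique maximum. Category 1: as 0 but the maximum
#' is attained at more than one position. Category 2: more than one tag,
#' below the maximum but above the median. Category 3: more than one tag,
#' at or below the median. Category 4: exactly one tag. The median is
#' taken over positions with nonzero counts.
#'
#' @param tags_at_site degradome 5'-end count at the cleavage position.
#' @param profile per-position count vector of the transcript.
#' @return integer category 0-4.
#' @export
categorize <- function(tags_at_site, profile) {
  eps <- 1e-9
  if (tags_at_site < 1 - eps) stop("not a site: no tag at the position")
  nz <- profile[profile > eps]
  mx <- max(nz)
  if (tags_at_site <= 1 + eps) return(4L)
  if (tags_at_site >= mx - eps) {
    n_max <- sum(nz >= mx - eps)
    return(if (n_max == 1L) 0L else 1L)
  }
  med <- median(nz)
  if (tags_at_site > med + eps) 2L else 3L
}

#' Permutation p-value for a cleavage site
#'
#' Mononucleotide shuffles of the miRNA form the null: the p-value is
#' `(1 + b) / (n_perm + 1)` where `b` counts shuffles achieving, anywhere
#' on the transcript, an alignment at least as good as the observed score
#' whose cleavage position carries at least the observed tag count.
#'
#' @inheritParams find_sites
#' @param observed_score Allen score of the called site.
#' @param tags_at_site observed tag count at the cleavage position.
#' @param n_perm number of shuffles (>= 100; default 1000).
#' @param seed optional RNG seed for reproducibility.
#' @export
site_pvalue <- function(mirna, transcript, profile, observed_score,
                        tags_at_site, n_perm = 1000L, seed = NULL,
                        cut_pos = 10L, core_from = 2L, core_to = 13L,
                        core_mult = 2) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  mirna <- as_rna(mirna); transcript <- as_dna(transcript)
  if (!is.null(seed)) set.seed(seed)
  .site_pvalue_cpp(mirna, transcript, as.numeric(profile),
                   observed_score, tags_at_site, as.integer(n_perm),
                   as.integer(cut_pos), core_from, core_to, core_mult)
}

#' Call miRNA targets from degradome profiles
#'
#' Runs [find_sites()] for every miRNA x transcript with degradome
#' evidence in one library, classifies each candidate with [categorize()],
#' computes permutation p-values and reports sites with p <= `alpha`.
#' When several overlapping windows of the same miRNA on the same
#' transcript share a cleavage position, the best-scoring one is kept.
#'
#' @param mirnas data frame with `id` and `sequence` columns.
#' @param unigenes `DNAStringSet` or FASTA path.
#' @param profile a `degradome_profile` from [clean_and_map_tags()].
#' @param library_id label stored in the output rows.
#' @param alpha p-value cutoff (default 0.05).
#' @inheritParams find_sites
#' @inheritParams site_pvalue
#' @return data frame of target sites: mirna_id, transcript, target span,
#'   score, cleavage_pos, tags_at_site, category, p_value, library.
#' @export
call_targets <- function(mirnas, unigenes, profile, library_id = "lib",
                         score_cutoff = 7, alpha = 0.05, n_perm = 1000L,
                         cut_pos = 10L, core_from = 2L, core_to = 13L,
                         core_mult = 2) {
  if (is.character(unigenes))
    unigenes <- Biostrings::readDNAStringSet(unigenes)
  names(unigenes) <- sub("\\s.*$", "", names(unigenes))
  useq <- setNames(as.character(unigenes), names(unigenes))
  rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    mir <- as_rna(mirnas$sequence[i])
    for (tx in names(profile$profiles)) {
      prof <- profile$profiles[[tx]]
      cand <- find_sites(mir, useq[[tx]], prof, score_cutoff, cut_pos,
                         core_from, core_to, core_mult)
      if (!nrow(cand)) next
      # one candidate per cleavage position: best score wins
      cand <- cand[order(cand$cleavage_pos, cand$score), , drop = FALSE]
      cand <- cand[!duplicated(cand$cleavage_pos), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        cat_r <- categorize(cand$tags_at_site[r], prof)
        p <- site_pvalue(mir, useq[[tx]], prof, cand$score[r],
                         cand$tags_at_site[r], n_perm,
                         cut_pos = cut_pos, core_from = core_from,
                         core_to = core_to, core_mult = core_mult)
        if (p > alpha) next
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mirnas$id[i], transcript = tx,
          target_start = cand$target_start[r],
          target_end = cand$target_end[r], score = cand$score[r],
          cleavage_pos = cand$cleavage_pos[r],
          tags_at_site = cand$tags_at_site[r], category = cat_r,
          p_value = p, library = library_id, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(mirna_id = character(0), transcript = character(0),
                      target_start = integer(0), target_end = integer(0),
                      score = numeric(0), cleavage_pos = integer(0),
                      tags_at_site = numeric(0), category = integer(0),
                      p_value = numeric(0), library = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$mirna_id, out$transcript, out$cleavage_pos), ,
      drop = FALSE]
}

#' Human-readable miRNA:target alignment report
#'
#' For each called site, renders the duplex with pairing symbols
#' (`|` match, `o` G:U wobble, space mismatch), an arrow at the cleavage
#' position, and the supporting degradome tag count printed above the
#' arrow column. The header line carries the category and p-value.
#'
#' @param sites data frame from [call_targets()].
#' @param mirnas data frame with `id` and `sequence`.
#' @param unigenes `DNAStringSet` or named character vector.
#' @return character vector of report lines.
#' @export
render_alignment_report <- function(sites, mirnas, unigenes) {
  if (methods::is(unigenes, "DNAStringSet")) {
    names(unigenes) <- sub("\\s.*$", "", names(unigenes))
    unigenes <- setNames(as.character(unigenes), names(unigenes))
  }
  mir_seq <- setNames(as_rna(mirnas$sequence), mirnas$id)
  out <- character(0)
  for (r in seq_len(nrow(sites))) {
    mir <- mir_seq[[sites$mirna_id[r]]]
    L <- nchar(mir)
    win <- substr(unigenes[[sites$transcript[r]]],
                  sites$target_start[r], sites$target_end[r])
    al <- score_alignment(mir, win)
    sym <- c(match = "|", GU = "o", mismatch = " ")[al$pattern]
    header <- sprintf(
      "%s -> %s | library %s | category %d | p = %.4g | score %.1f",
      sites$mirna_id[r], sites$transcript[r], sites$library[r],
      sites$category[r], sites$p_value[r], sites$score[r])
    # rows are padded to equal length; target printed 5'->3', miRNA 3'->5'
    tgt <- sprintf("5' %s 3'  %s:%d-%d", as_rna(win),
                   sites$transcript[r], sites$target_start[r],
                   sites$target_end[r])
    pairing <- paste0("   ", paste(rev(sym), collapse = ""), "   ")
    mrow <- sprintf("3' %s 5'  %s", paste(rev(strsplit(mir, "")[[1]]),
                                          collapse = ""),
                    sites$mirna_id[r])
    width <- max(nchar(tgt), nchar(pairing), nchar(mrow))
    pad <- function(x) formatC(x, width = -width, flag = " ")
    # arrow above the target base at the cleavage position
    col <- 3L + (sites$cleavage_pos[r] - sites$target_start[r] + 1L)
    cnt <- format(sites$tags_at_site[r])
    cnt_line <- paste0(strrep(" ", max(0L, col - nchar(cnt))), cnt)
    arrow_line <- paste0(strrep(" ", col - 1L), "v")
    out <- c(out, header, pad(cnt_line), pad(arrow_line), pad(tgt),
             pad(pairing), pad(mrow), "")
  }
  out
}

#' T-plot data for one transcript
#'
#' @param profile a `degradome_profile`.
#' @param transcript transcript id.
#' @return data frame of position vs degradome 5'-end count (all
#'   positions, zeros included).
#' @export
tplot_data <- function(profile, transcript) {
  v <- profile$profiles[[transcript]]
  if (is.null(v)) stop("no degradome profile for ", transcript)
  data.frame(position = seq_along(v), count = v)
}
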