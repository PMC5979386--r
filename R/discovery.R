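# Known-miRNA identification (catalog matching, family templates,
# mismatch-tolerant quantification), Mireap-style novel miRNA prediction
# by hairpin folding of unigene flanking sequence, miRNA* detection and
# palindromic-precursor flagging.

#' Parse the family key of a miRBase-style miRNA identifier
#'
#' Strips the species prefix, the -5p/-3p arm suffix, letter variants and
#' numeric isoform suffixes: `ath-miR166a-3p` and `ath-miR166b` both give
#' `miR166`. Identifiers that do not contain a `miR<number>` (or
#' `miR-<number>`) core are returned with only the species prefix removed.
#'
#' @param id character vector of miRNA identifiers.
#' @return character vector of family keys.
#' @export
mirna_family <- function(id) {
  x <- sub("^[A-Za-z]+-(?=miR)", "", id, perl = TRUE)
  out <- x
  has <- grepl("^miR-?[0-9]+", x)
  out[has] <- regmatches(x[has], regexpr("^miR-?[0-9]+", x[has]))
  out
}

#' Read a miRBase-style mature miRNA catalog
#'
#' @param path FASTA file of mature miRNAs (`species-family-variant-arm`
#'   identifiers; U or T alphabet).
#' @return data frame with `id`, `family` and `sequence` (DNA alphabet).
#' @export
read_mature_catalog <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  data.frame(id = ids, family = mirna_family(ids),
             sequence = as_dna(as.character(ss)),
             stringsAsFactors = FALSE)
}

#' Match unique tags against a known mature miRNA catalog
#'
#' A tag is a `perfect` hit when it is full-length identical to a catalog
#' mature. Otherwise it is an `overlap` hit when some ungapped offset
#' aligns tag and mature with a mismatch-free overlapping span of at least
#' `min_overlap` nt. Each tag reports its best hit: perfect beats overlap,
#' then longest overlap, ties broken by catalog order.
#'
#' @param tags a `tag_set`.
#' @param catalog data frame from [read_mature_catalog()].
#' @param min_overlap minimum mismatch-free overlap (default 16 nt).
#' @return data frame of hits: `sequence`, `mature_id`, `family`, `tier`,
#'   `overlap_len`, `mismatches_in_overlap` (always 0 by construction).
#' @export
match_known <- function(tags, catalog, min_overlap = 16L) {
  if (!nrow(catalog)) stop("catalog is empty")
  seqs <- tags$sequence
  cat_seq <- as_dna(catalog$sequence)

  if (min_overlap >= 16L) {
    # a mismatch-free overlap >= 16 nt implies a shared 16-mer; hash the
    # catalog 16-mers to prune the tag x catalog search
    k <- 16L
    env <- new.env(hash = TRUE, parent = emptyenv())
    for (j in seq_along(cat_seq)) {
      s <- cat_seq[j]
      L <- nchar(s)
      if (L < k) next
      for (p in seq_len(L - k + 1L)) {
        km <- substr(s, p, p + k - 1L)
        env[[km]] <- c(env[[km]], j)
      }
    }
    cand <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
      s <- seqs[i]
      L <- nchar(s)
      if (L < k) next
      js <- integer(0)
      for (p in seq_len(L - k + 1L)) {
        v <- env[[substr(s, p, p + k - 1L)]]
        if (!is.null(v)) js <- c(js, v)
      }
      if (length(js)) cand[[i]] <- sort(unique(js))
    }
  } else {
    cand <- rep(list(seq_along(cat_seq)), length(seqs))
  }

  rows <- list()
  for (i in seq_along(seqs)) {
    js <- cand[[i]]
    if (is.null(js)) next
    best_j <- 0L; best_ov <- 0L; best_perfect <- FALSE
    for (j in js) {
      if (seqs[i] == cat_seq[j]) {
        best_j <- j; best_ov <- nchar(seqs[i]); best_perfect <- TRUE
        break
      }
      ov <- .best_clean_overlap_cpp(seqs[i], cat_seq[j])
      if (ov >= min_overlap && ov > best_ov) {
        best_j <- j; best_ov <- ov
      }
    }
    if (best_j > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = seqs[i], mature_id = catalog$id[best_j],
        family = catalog$family[best_j],
        tier = if (best_perfect) "perfect" else "overlap",
        overlap_len = best_ov, mismatches_in_overlap = 0L,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(sequence = character(0), mature_id = character(0),
                      family = character(0), tier = character(0),
                      overlap_len = integer(0),
                      mismatches_in_overlap = integer(0)))
  do.call(rbind, rows)
}

#' Choose one expression template per miRNA family
#'
#' The template is the member tag with the highest summed raw count across
#' libraries; ties are broken by the lexicographically smaller sequence.
#'
#' @param hits data frame from [match_known()].
#' @param tags the `tag_set` the hits were called on.
#' @return data frame with `family`, `template`, `tier`, `total_count`.
#' @export
select_family_template <- function(hits, tags) {
  if (!nrow(hits))
    return(data.frame(family = character(0), template = character(0),
                      tier = character(0), total_count = numeric(0)))
  total <- rowSums(tag_counts(tags))
  names(total) <- tags$sequence
  hits$count <- total[hits$sequence]
  out <- lapply(split(hits, hits$family), function(h) {
    h <- h[order(-h$count, h$sequence), , drop = FALSE]
    data.frame(family = h$family[1], template = h$sequence[1],
               tier = h$tier[1], total_count = h$count[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$family), , drop = FALSE]
}

#' Quantify miRNA expression by assigning tags to family templates
#'
#' Each tag is compared end-to-end (ungapped) against every template at
#' offsets allowing at most `max_overhang` nt of tag overhang on either
#' side; it contributes its counts to the single best template reachable
#' with at most `max_mismatch` mismatches in the overlapping span (best =
#' fewest mismatches, then longest overlap). Per-template counts are
#' converted to RPM and the abundance cutoff (RPM > `rpm_cutoff` in at
#' least `min_libraries` libraries) is applied.
#'
#' @param tags a `tag_set`.
#' @param templates data frame from [select_family_template()] (or any
#'   data frame with `family` and `template` columns).
#' @param max_mismatch,max_overhang alignment tolerances (defaults 2, 2).
#' @param rpm_cutoff,min_libraries abundance acceptance rule
#'   (defaults > 2 RPM in >= 2 libraries).
#' @return data frame with `family`, `sequence`, `tier` (if present),
#'   per-library `count.*` and `rpm.*`, and `accepted`.
#' @export
assign_to_templates <- function(tags, templates, max_mismatch = 2L,
                                max_overhang = 2L, rpm_cutoff = 2,
                                min_libraries = 2L) {
  libs <- attr(tags, "libraries")
  totals <- tag_totals(tags)
  asg <- .assign_templates_cpp(tags$sequence, templates$template,
                               max_mismatch, max_overhang)
  cnt <- tag_counts(tags)
  out <- templates[, intersect(c("family", "template", "tier"),
                               names(templates)), drop = FALSE]
  names(out)[names(out) == "template"] <- "sequence"
  m <- matrix(0, nrow = nrow(templates), ncol = length(libs),
              dimnames = list(NULL, libs))
  hit <- asg$template > 0L
  if (any(hit)) {
    agg <- rowsum(cnt[hit, , drop = FALSE], group = asg$template[hit])
    m[as.integer(rownames(agg)), ] <- agg
  }
  for (lib in libs) out[[paste0("count.", lib)]] <- m[, lib]
  rpm <- sweep(m, 2, totals, "/") * 1e6
  for (lib in libs) out[[paste0("rpm.", lib)]] <- rpm[, lib]
  out$accepted <- rowSums(rpm > rpm_cutoff) >= min_libraries
  attr(out, "assignment") <- asg
  attr(out, "libraries") <- libs
  out
}

# --- hairpin validation ------------------------------------------------

# stem chain of an innermost pair: follow enclosing pairs outward while
# each has exactly one child (no multiloop branching) and consecutive
# pairs are separated by at most max_gap unpaired bases (a helix stack
# region interrupted only by small bulges/internal loops)
stem_chains <- function(pt, max_gap = 6L) {
  n <- length(pt)
  pairs <- which(pt > seq_len(n))
  if (!length(pairs)) return(list())
  parent <- rep(NA_integer_, n)   # for pair opening at i, opening of parent
  nchild <- rep(0L, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (pt[i] > i) {
      if (length(stack)) {
        parent[i] <- stack[length(stack)]
        nchild[stack[length(stack)]] <- nchild[stack[length(stack)]] + 1L
      }
      stack <- c(stack, i)
    } else if (pt[i] > 0 && pt[i] < i) {
      stack <- stack[-length(stack)]
    }
  }
  innermost <- pairs[vapply(pairs, function(i) nchild[i] == 0L, logical(1))]
  lapply(innermost, function(h) {
    chain <- h
    p <- parent[h]
    while (!is.na(p) && nchild[p] == 1L) {
      cur <- chain[length(chain)]
      gap <- (cur - p - 1L) + (pt[p] - pt[cur] - 1L)
      if (gap > max_gap) break
      chain <- c(chain, p)
      p <- parent[p]
    }
    list(loop = c(h, pt[h]), outer = c(min(chain), pt[min(chain)]),
         n_pairs = length(chain))
  })
}

# star span paired to the mature with 2-nt 3' overhangs, from the pair table
star_span_from_pt <- function(pt, mature_span) {
  n <- length(pt)
  nearest_paired <- function(pos, dir) {
    while (pos >= 1 && pos <= n && pt[pos] == 0) pos <- pos + dir
    if (pos < 1 || pos > n) return(NA_integer_)
    pos
  }
  a <- nearest_paired(mature_span[1], +1L)        # 5'-most paired mature base
  b <- nearest_paired(mature_span[2] - 2L, -1L)   # partner of mature end - 2
  if (is.na(a) || is.na(b) || b < a) return(NULL)
  ends <- sort(c(pt[b], pt[a] + 2L))
  c(max(1L, ends[1]), min(n, ends[2]))
}

#' Validate a candidate miRNA precursor hairpin
#'
#' Accepts the candidate iff (a) a single dominant stem-loop holds at
#' least `dominance` of all paired bases, (b) the mature lies entirely on
#' one arm of that stem-loop without spanning the terminal loop, (c) at
#' least `min_paired` mature bases are paired, and (d) the minimum free
#' energy does not exceed `mfe_ceiling` (kcal/mol).
#'
#' @param sequence candidate precursor sequence (DNA or RNA).
#' @param mature_span integer c(start, end), 1-based inclusive, of the
#'   mature within the candidate.
#' @param params folding parameters.
#' @param mfe_ceiling maximal acceptable MFE, default -18.2 kcal/mol.
#' @param min_paired minimum paired mature bases, default 14.
#' @param dominance minimum fraction of paired bases in the main stem.
#' @param fold optional precomputed [fold_rna()] result for `sequence`.
#' @return list with `accept`, `reason`, and on acceptance a `precursor`
#'   record (sequence, structure, mfe, mature_span, mature_arm,
#'   star_span, loop_span).
#' @export
validate_hairpin <- function(sequence, mature_span,
                             params = rna_energy_params(),
                             mfe_ceiling = -18.2, min_paired = 14L,
                             dominance = 0.7, fold = NULL) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  mature_span <- as.integer(mature_span)
  if (mature_span[1] < 1 || mature_span[2] > n ||
      mature_span[1] > mature_span[2])
    stop("mature_span outside the precursor candidate")
  if (is.null(fold)) fold <- fold_rna(as_rna(sequence), params)
  pt <- fold$pt
  paired_total <- sum(pt > 0)
  rej <- function(reason) list(accept = FALSE, reason = reason,
                               fold = fold)
  if (paired_total == 0) return(rej("no base pairs"))
  chains <- stem_chains(pt)
  if (!length(chains)) return(rej("no stem-loop"))
  np <- vapply(chains, `[[`, integer(1), "n_pairs")
  main <- chains[[which.max(np)]]
  if (2 * main$n_pairs / paired_total < dominance)
    return(rej("no dominant stem-loop"))
  i_h <- main$loop[1]; j_h <- main$loop[2]
  arm <- if (mature_span[2] <= i_h) "5p"
         else if (mature_span[1] >= j_h) "3p"
         else return(rej("mature spans the terminal loop"))
  if (sum(pt[mature_span[1]:mature_span[2]] > 0) < min_paired)
    return(rej("mature insufficiently paired"))
  if (fold$mfe > mfe_ceiling) return(rej("MFE above ceiling"))
  star <- star_span_from_pt(pt, mature_span)
  list(accept = TRUE, reason = "ok",
       precursor = list(sequence = as_dna(sequence),
                        structure = fold$structure, mfe = fold$mfe,
                        mature_span = mature_span, mature_arm = arm,
                        star_span = star,
                        loop_span = c(i_h + 1L, j_h - 1L),
                        stem_outer = main$outer),
       fold = fold)
}

# Locate perfect-match loci of a tag on the unigenes (both strands),
# excise +/- flank, fold, localise the stem-loop containing the tag, trim
# and re-validate. Returns the first validated precursor or NULL.
predict_precursor <- function(tag, unigenes, flank = 250L,
                              params = rna_energy_params(),
                              mfe_ceiling = -18.2, min_paired = 14L,
                              dominance = 0.7, max_loci = 20L) {
  tag <- as_dna(tag)
  L <- nchar(tag)
  loci <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") tag else revcomp(tag)
    mt <- Biostrings::vmatchPattern(pat, unigenes)
    for (u in seq_along(mt)) {
      st <- Biostrings::start(mt[[u]])
      for (s in st) loci[[length(loci) + 1L]] <-
        list(unigene = u, start = s, strand = strand)
    }
  }
  if (length(loci) == 0L || length(loci) > max_loci) return(NULL)
  for (loc in loci) {
    useq <- as.character(unigenes[[loc$unigene]])
    ulen <- nchar(useq)
    w1 <- max(1L, loc$start - flank)
    w2 <- min(ulen, loc$start + L - 1L + flank)
    win <- substr(useq, w1, w2)
    m1 <- loc$start - w1 + 1L
    if (loc$strand == "-") {
      win <- revcomp(win)
      m1 <- nchar(win) - (m1 + L - 1L) + 1L
    }
    m2 <- m1 + L - 1L
    if (nchar(win) < 54L) next
    f <- fold_rna(as_rna(win), params)
    v <- NULL
    # widen the excised candidate until the localised hairpin validates
    for (ctx in c(10L, 25L, 45L)) {
      cand <- localise_hairpin(f$pt, c(m1, m2), context = ctx)
      if (is.null(cand)) break
      t1 <- cand[1]; t2 <- cand[2]
      sub <- substr(win, t1, t2)
      if (nchar(sub) < 54L) {  # pad with context to the minimal length
        pad <- ceiling((54L - nchar(sub)) / 2)
        t1 <- max(1L, t1 - pad)
        t2 <- min(nchar(win), t1 + max(54L, t2 - t1 + 1L) - 1L)
        sub <- substr(win, t1, t2)
      }
      v <- validate_hairpin(sub, c(m1, m2) - t1 + 1L, params, mfe_ceiling,
                            min_paired, dominance)
      if (v$accept) break
    }
    if (is.null(v) || !v$accept) {
      # fallback: candidate windows of typical precursor extent on either
      # side of the mature (the mature may sit on the 5' or the 3' arm)
      for (ext in list(c(15L, 60L), c(60L, 15L), c(15L, 85L),
                       c(85L, 15L), c(30L, 110L), c(110L, 30L),
                       c(55L, 55L))) {
        t1 <- max(1L, m1 - ext[1]); t2 <- min(nchar(win), m2 + ext[2])
        if (t2 - t1 + 1L < 54L) next
        sub <- substr(win, t1, t2)
        v <- validate_hairpin(sub, c(m1, m2) - t1 + 1L, params,
                              mfe_ceiling, min_paired, dominance)
        if (v$accept) break
      }
    }
    if (is.null(v) || !v$accept) next
    prec <- v$precursor
    # coordinates of the trimmed precursor on the unigene (plus strand)
    if (loc$strand == "+") {
      prec$start <- w1 + t1 - 1L
      prec$end <- w1 + t2 - 1L
    } else {
      prec$start <- w1 + (nchar(win) - t2)
      prec$end <- w1 + (nchar(win) - t1)
    }
    prec$unigene <- names(unigenes)[loc$unigene]
    prec$strand <- loc$strand
    return(prec)
  }
  NULL
}

# pick the stem-loop whose arm hosts the mature and return a trimmed span
localise_hairpin <- function(pt, mature_span, context = 10L) {
  chains <- stem_chains(pt)
  if (!length(chains)) return(NULL)
  best <- NULL; best_np <- -1L
  for (ch in chains) {
    i_h <- ch$loop[1]; j_h <- ch$loop[2]
    a_o <- ch$outer[1]; b_o <- ch$outer[2]
    on_arm <- (mature_span[2] <= i_h) || (mature_span[1] >= j_h)
    near <- mature_span[1] >= a_o - 5L && mature_span[2] <= b_o + 5L
    if (on_arm && near && ch$n_pairs > best_np) {
      best <- ch; best_np <- ch$n_pairs
    }
  }
  if (is.null(best)) return(NULL)
  t1 <- max(1L, min(best$outer[1], mature_span[1]) - context)
  t2 <- min(length(pt), max(best$outer[2], mature_span[2]) + context)
  c(t1, t2)
}

#' Detect the miRNA* (passenger strand) of a validated precursor
#'
#' The star span is the opposite-arm segment pairing the mature with 2-nt
#' 3' overhangs under the precursor structure. The star is reported as
#' `detected` when some sequenced tag matches the star-span sequence
#' exactly, allowing each end to vary by at most 1 nt.
#'
#' @param precursor a precursor record (from [validate_hairpin()] or
#'   [predict_precursor()]).
#' @param tags a `tag_set`.
#' @return list with `span`, `sequence`, `detected` and per-library
#'   `counts` (zero when not detected).
#' @export
detect_star <- function(precursor, tags) {
  libs <- attr(tags, "libraries")
  zero <- setNames(numeric(length(libs)), libs)
  span <- precursor$star_span
  if (is.null(span))
    return(list(span = NULL, sequence = NA_character_,
                detected = FALSE, counts = zero))
  n <- nchar(precursor$sequence)
  variants <- character(0)
  for (d1 in -1:1) for (d2 in -1:1) {
    s1 <- span[1] + d1; s2 <- span[2] + d2
    if (s1 >= 1 && s2 <= n && s2 > s1)
      variants <- c(variants, substr(precursor$sequence, s1, s2))
  }
  hit <- tags$sequence %in% variants
  counts <- if (any(hit)) colSums(tag_counts(tags)[hit, , drop = FALSE])
            else zero
  list(span = span,
       sequence = substr(precursor$sequence, span[1], span[2]),
       detected = any(hit), counts = counts)
}

#' Test whether a precursor locus is palindromic
#'
#' TRUE iff bidirectional transcription of the locus yields the same
#' hairpin: the reverse complement must validate as a hairpin hosting the
#' reverse complement of the mature, *and* its structure, mirrored back
#' onto the forward coordinates, must reproduce at least `same_frac` of
#' the forward base pairs. G:U wobbles and asymmetric loops of ordinary
#' precursors break this symmetry (a G:U pair maps to unpairable C:A on
#' the antisense strand), so only genuinely palindromic loci pass.
#'
#' @inheritParams validate_hairpin
#' @param precursor a precursor record.
#' @param same_frac minimum fraction of forward pairs reproduced by the
#'   mirrored antisense structure (default 0.8).
#' @export
detect_palindrome <- function(precursor, params = rna_energy_params(),
                              mfe_ceiling = -18.2, min_paired = 14L,
                              dominance = 0.7, same_frac = 0.8) {
  n <- nchar(precursor$sequence)
  rc <- revcomp(precursor$sequence)
  span <- c(n - precursor$mature_span[2] + 1L,
            n - precursor$mature_span[1] + 1L)
  v <- validate_hairpin(rc, span, params, mfe_ceiling, min_paired,
                        dominance)
  if (!isTRUE(v$accept)) return(FALSE)
  fwd_pt <- db_to_pt(precursor$structure)
  fwd <- which(fwd_pt > seq_along(fwd_pt))
  fwd_pairs <- paste(fwd, fwd_pt[fwd])
  rc_pt <- v$fold$pt
  i <- which(rc_pt > seq_along(rc_pt))
  mirrored <- paste(n - rc_pt[i] + 1L, n - i + 1L)
  if (!length(fwd_pairs)) return(FALSE)
  mean(fwd_pairs %in% mirrored) >= same_frac
}

#' Predict novel miRNAs from unannotated tags
#'
#' Tags not matched to known miRNAs are mapped perfectly to the unigenes
#' (both strands); around each locus the flanking sequence is excised and
#' folded, and the hairpin is validated with the tag as the mature.
#' Candidates are restricted to 20-23 nt matures above the abundance
#' cutoff, deduplicated by precursor locus (the most abundant tag at a
#' locus wins; this also absorbs star and isomiR reads of the same
#' hairpin), and loci overlapping `exclude_loci` (e.g. accepted known
#' precursors) are dropped.
#'
#' @param tags a `tag_set` of unannotated tags.
#' @param unigenes `DNAStringSet` of unigene sequences.
#' @param flank flanking sequence excised on each side (default 250 nt).
#' @param mature_len allowed mature length range (default 20-23 nt).
#' @param max_loci tags mapping to more loci are discarded as
#'   repeat-derived (default 20).
#' @param exclude_loci data frame with `unigene`, `start`, `end` of loci
#'   to skip.
#' @inheritParams validate_hairpin
#' @inheritParams assign_to_templates
#' @return list with `profiles` (data frame, one row per accepted novel
#'   miRNA) and `precursors` (list of precursor records, same order).
#' @export
find_novel <- function(tags, unigenes, flank = 250L,
                       params = rna_energy_params(),
                       mfe_ceiling = -18.2, min_paired = 14L,
                       dominance = 0.7, mature_len = c(20L, 23L),
                       max_loci = 20L, rpm_cutoff = 2, min_libraries = 2L,
                       exclude_loci = NULL) {
  libs <- attr(tags, "libraries")
  rpm <- tag_rpm(tags)
  L <- nchar(tags$sequence)
  cand <- which(L >= mature_len[1] & L <= mature_len[2] &
                rowSums(rpm > rpm_cutoff) >= min_libraries)
  cand <- cand[order(-rowSums(tag_counts(tags))[cand],
                     tags$sequence[cand])]
  overlaps <- function(loci, unigene, start, end) {
    if (is.null(loci) || !nrow(loci)) return(FALSE)
    any(loci$unigene == unigene & loci$start <= end & loci$end >= start)
  }
  taken <- exclude_loci
  precs <- list()
  rows <- list()
  for (i in cand) {
    prec <- predict_precursor(tags$sequence[i], unigenes, flank, params,
                              mfe_ceiling, min_paired, dominance, max_loci)
    if (is.null(prec)) next
    if (overlaps(taken, prec$unigene, prec$start, prec$end)) next
    taken <- rbind(taken, data.frame(unigene = prec$unigene,
                                     start = prec$start, end = prec$end,
                                     stringsAsFactors = FALSE))
    precs[[length(precs) + 1L]] <- prec
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = tags$sequence[i], unigene = prec$unigene,
      start = prec$start, end = prec$end, strand = prec$strand,
      mfe = prec$mfe, arm = prec$mature_arm, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(profiles = data.frame(), precursors = list()))
  prof <- do.call(rbind, rows)
  # quantify novel matures like known templates (isomiR-tolerant)
  tpl <- data.frame(family = prof$sequence, template = prof$sequence,
                    stringsAsFactors = FALSE)
  q <- assign_to_templates(tags, tpl, rpm_cutoff = rpm_cutoff,
                           min_libraries = min_libraries)
  for (lib in libs) {
    prof[[paste0("count.", lib)]] <- q[[paste0("count.", lib)]]
    prof[[paste0("rpm.", lib)]] <- q[[paste0("rpm.", lib)]]
  }
  prof$accepted <- q$accepted
  keep <- prof$accepted
  list(profiles = prof[keep, , drop = FALSE],
       precursors = precs[keep])
}

#' Run the full miRNA discovery stage
#'
#' Executes the four-step known-miRNA identification (catalog matching at
#' >= 16-nt mismatch-free overlap, family template selection, tag
#' assignment with <= 2 mismatches, precursor hairpin validation on the
#' unigenes) followed by novel miRNA prediction from the remaining tags,
#' star detection and palindrome flagging.
#'
#' @param tags a `tag_set` (after contaminant removal).
#' @param catalog mature catalog data frame (or FASTA path).
#' @param unigenes `DNAStringSet` (or FASTA path).
#' @param flank,rpm_cutoff,min_libraries,mfe_ceiling,min_paired,dominance,
#'   mature_len,max_loci stage parameters, see the operation functions.
#' @param params folding parameters.
#' @return list with `mirnas` (result table: id, class, sequence,
#'   counts/RPM, precursor locus, MFE, star, palindrome), `precursors`
#'   (named list of precursor records), `hits`, `pseudo` (families
#'   rejected for lack of a hairpin).
#' @export
discover_mirnas <- function(tags, catalog, unigenes, flank = 250L,
                            rpm_cutoff = 2, min_libraries = 2L,
                            mfe_ceiling = -18.2, min_paired = 14L,
                            dominance = 0.7, mature_len = c(20L, 23L),
                            max_loci = 20L,
                            params = rna_energy_params()) {
  if (is.character(catalog)) catalog <- read_mature_catalog(catalog)
  if (is.character(unigenes))
    unigenes <- Biostrings::readDNAStringSet(unigenes)
  names(unigenes) <- sub("\\s.*$", "", names(unigenes))
  libs <- attr(tags, "libraries")

  hits <- match_known(tags, catalog)
  templates <- select_family_template(hits, tags)
  known <- if (nrow(templates))
    assign_to_templates(tags, templates, rpm_cutoff = rpm_cutoff,
                        min_libraries = min_libraries)
  else data.frame()

  rows <- list(); precs <- list(); pseudo <- character(0)
  if (nrow(known)) for (r in which(known$accepted)) {
    prec <- predict_precursor(known$sequence[r], unigenes, flank, params,
                              mfe_ceiling, min_paired, dominance, max_loci)
    if (is.null(prec)) {  # no hairpin precursor: pseudo-miRNA
      pseudo <- c(pseudo, known$family[r])
      next
    }
    star <- detect_star(prec, tags)
    id <- known$family[r]
    precs[[id]] <- prec
    row <- data.frame(
      id = id,
      class = if (known$tier[r] == "perfect") "known_perfect"
              else "known_variant",
      sequence = known$sequence[r], stringsAsFactors = FALSE)
    for (lib in libs) {
      row[[paste0("count.", lib)]] <- known[[paste0("count.", lib)]][r]
      row[[paste0("rpm.", lib)]] <- known[[paste0("rpm.", lib)]][r]
    }
    row$unigene <- prec$unigene; row$start <- prec$start
    row$end <- prec$end; row$strand <- prec$strand
    row$mfe <- prec$mfe; row$arm <- prec$mature_arm
    row$star_detected <- star$detected
    row$star_sequence <- star$sequence
    row$palindrome <- detect_palindrome(prec, params, mfe_ceiling,
                                        min_paired, dominance)
    rows[[length(rows) + 1L]] <- row
  }

  known_loci <- if (length(precs)) data.frame(
    unigene = vapply(precs, `[[`, character(1), "unigene"),
    start = vapply(precs, `[[`, numeric(1), "start"),
    end = vapply(precs, `[[`, numeric(1), "end"),
    stringsAsFactors = FALSE) else NULL
  unannotated <- subset_tags(tags, !(tags$sequence %in% hits$sequence))
  nov <- find_novel(unannotated, unigenes, flank, params, mfe_ceiling,
                    min_paired, dominance, mature_len, max_loci,
                    rpm_cutoff, min_libraries, exclude_loci = known_loci)
  if (nrow(nov$profiles)) {
    ord <- order(-rowSums(as.matrix(
      nov$profiles[paste0("count.", libs)])), nov$profiles$sequence)
    nov$profiles <- nov$profiles[ord, , drop = FALSE]
    nov$precursors <- nov$precursors[ord]
    for (r in seq_len(nrow(nov$profiles))) {
      prec <- nov$precursors[[r]]
      id <- sprintf("novel-%03d", r)
      star <- detect_star(prec, tags)
      precs[[id]] <- prec
      row <- data.frame(id = id, class = "novel",
                        sequence = nov$profiles$sequence[r],
                        stringsAsFactors = FALSE)
      for (lib in libs) {
        row[[paste0("count.", lib)]] <- nov$profiles[[paste0("count.", lib)]][r]
        row[[paste0("rpm.", lib)]] <- nov$profiles[[paste0("rpm.", lib)]][r]
      }
      row$unigene <- prec$unigene; row$start <- prec$start
      row$end <- prec$end; row$strand <- prec$strand
      row$mfe <- prec$mfe; row$arm <- prec$mature_arm
      row$star_detected <- star$detected
      row$star_sequence <- star$sequence
      row$palindrome <- detect_palindrome(prec, params, mfe_ceiling,
                                          min_paired, dominance)
      rows[[length(rows) + 1L]] <- row
    }
  }

  mirnas <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(mirnas) <- NULL
  if (nrow(mirnas)) attr(mirnas, "libraries") <- libs
  list(mirnas = mirnas, precursors = precs, hits = hits,
       templates = templates, known = known, pseudo = pseudo)
}
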