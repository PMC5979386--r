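# Synthetic sequencing study with planted ground truth: unigenes hosting
# planted miRNA precursors, three tissue sRNA libraries with
# tissue-specific expression, star reads at low abundance, degradome
# libraries peaked at planted cleavage sites, contaminant and adaptor
# noise, GO annotations with planted enrichment, and a truth table.

#' Configuration of the synthetic study
#'
#' Defaults describe the emulated design: three tissue libraries
#' (flowers, young fruit, ripe fruit) of 100,000 reads each, 30 planted
#' known miRNAs (half perfect catalog matches, half >= 16-nt-overlap
#' variants), 20 planted novel miRNAs, 20 shuffled decoy catalog entries
#' that receive no reads, all planted miRNAs expressed above 2 RPM in at
#' least two libraries, star reads at low abundance, and degradome
#' libraries with 80% of each target's tags exactly at the planted
#' cleavage position.
#'
#' @param seed RNG seed; identical seed + config gives byte-identical
#'   output files.
#' @param n_unigenes,unigene_len_range unigene set size and length range.
#' @param n_known_mirnas,n_novel_mirnas,n_decoy_mirnas planted/decoy
#'   counts.
#' @param libraries library labels.
#' @param reads_per_library sRNA reads per library (exact).
#' @param contaminant_fraction fraction of reads drawn from the
#'   rRNA/tRNA/snRNA/snoRNA records.
#' @param junk_fraction fraction of N-containing/homopolymer reads.
#' @param unigene_noise_fraction fraction of noise reads that are unigene
#'   (degradation) fragments rather than random sequence.
#' @param isomir_fraction fraction of each miRNA's reads with 1-nt
#'   trimmed/extended ends.
#' @param adaptor3 3' adaptor appended to every read on disk.
#' @param star_to_mature_ratio star read abundance relative to the
#'   mature (star RPM additionally capped at 8).
#' @param cleavage_peak_fraction fraction of a target transcript's
#'   degradome tags placed exactly at the planted cleavage position.
#' @param n_target_sites planted cleavage sites (one per transcript).
#' @param degradome_tags_per_library degradome tags per library.
#' @param site_tag_range per-site degradome tag total range.
#' @param error_rate per-base sequencing error rate (default 0).
#' @param expression_profiles optional matrix (planted miRNAs x
#'   libraries) of expected RPM; generated when NULL.
#' @param outdir default output directory for [generate_dataset()].
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 42L, n_unigenes = 300L,
                             unigene_len_range = c(600L, 1800L),
                             n_known_mirnas = 30L, n_novel_mirnas = 20L,
                             n_decoy_mirnas = 20L,
                             libraries = c("flowers", "young_fruit",
                                           "ripe_fruit"),
                             reads_per_library = 100000L,
                             contaminant_fraction = 0.05,
                             junk_fraction = 0.01,
                             unigene_noise_fraction = 0.15,
                             isomir_fraction = 0.10,
                             adaptor3 = "TGGAATTCTCGGGTGCCAAGG",
                             star_to_mature_ratio = 0.05,
                             cleavage_peak_fraction = 0.8,
                             n_target_sites = 40L,
                             degradome_tags_per_library = 20000L,
                             site_tag_range = c(30L, 70L),
                             error_rate = 0,
                             expression_profiles = NULL,
                             outdir = NULL) {
  cfg <- list(seed = as.integer(seed), n_unigenes = as.integer(n_unigenes),
              unigene_len_range = as.integer(unigene_len_range),
              n_known_mirnas = as.integer(n_known_mirnas),
              n_novel_mirnas = as.integer(n_novel_mirnas),
              n_decoy_mirnas = as.integer(n_decoy_mirnas),
              libraries = libraries,
              reads_per_library = as.integer(reads_per_library),
              contaminant_fraction = contaminant_fraction,
              junk_fraction = junk_fraction,
              unigene_noise_fraction = unigene_noise_fraction,
              isomir_fraction = isomir_fraction,
              adaptor3 = toupper(adaptor3),
              star_to_mature_ratio = star_to_mature_ratio,
              cleavage_peak_fraction = cleavage_peak_fraction,
              n_target_sites = as.integer(n_target_sites),
              degradome_tags_per_library =
                as.integer(degradome_tags_per_library),
              site_tag_range = as.integer(site_tag_range),
              error_rate = error_rate,
              expression_profiles = expression_profiles,
              outdir = outdir)
  props <- c(cfg$contaminant_fraction, cfg$junk_fraction,
             cfg$unigene_noise_fraction, cfg$isomir_fraction,
             cfg$star_to_mature_ratio, cfg$cleavage_peak_fraction,
             cfg$error_rate)
  if (any(props < 0 | props > 1))
    stop("all proportions must lie in [0, 1]")
  counts <- c(cfg$n_unigenes, cfg$reads_per_library,
              cfg$degradome_tags_per_library)
  if (any(counts <= 0)) stop("counts must be positive")
  if (any(c(cfg$n_known_mirnas, cfg$n_novel_mirnas,
            cfg$n_decoy_mirnas, cfg$n_target_sites) < 0))
    stop("planted counts must be non-negative")
  if (length(cfg$libraries) < 1) stop("at least one library is required")
  structure(cfg, class = "synthetic_config")
}

#' Construct a stem-loop precursor hosting a given mature miRNA
#'
#' Builds a hairpin in which the mature/star duplex sits on one arm pair
#' and the stem continues below the duplex through a complementary
#' extension (imperfect, with planted mismatches and G:U wobbles), closed
#' by short unpaired tails. The star arm is the reverse complement of the
#' mature carrying 1-2 planted interior mismatches and several G:U
#' wobbles, giving the canonical duplex with 2-nt 3' overhangs. Random
#' draws are repeated until the folded candidate passes
#' [validate_hairpin()] at the MFE ceiling. Typical products are
#' 70-160 nt, within the 54-363 nt range observed for plant precursors.
#'
#' @param mature mature sequence, 20-23 nt (DNA or RNA).
#' @param loop_len terminal loop length (>= 3; default 10).
#' @param seed RNG seed; identical inputs and seed give an identical
#'   precursor.
#' @param arm arm carrying the mature, "5p" or "3p".
#' @param ext_range length range of the lower-stem extension drawn on
#'   each attempt (default 8-45 nt, giving 70-160 nt precursors).
#' @param params,mfe_ceiling folding model and acceptance ceiling.
#' @param max_tries attempts before giving up.
#' @return a precursor record as from [validate_hairpin()].
#' @export
build_precursor <- function(mature, loop_len = 10L, seed = 1L,
                            arm = "5p", ext_range = c(8L, 45L),
                            params = rna_energy_params(),
                            mfe_ceiling = -18.2, max_tries = 25L) {
  mature <- as_dna(mature)
  L <- nchar(mature)
  if (L < 20 || L > 23) stop("mature length must be 20-23 nt")
  if (loop_len < 3) stop("loop_len < 3: sterically impossible loop")
  mono <- max(vapply(c("A", "C", "G", "T"), function(b)
    lengths(regmatches(mature, gregexpr(b, mature, fixed = TRUE))),
    integer(1))) / L
  if (mono >= 0.8)
    stop("low-complexity mature (homopolymer) cannot form a specific ",
         "miRNA/miRNA* duplex")
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      star <- strsplit(revcomp(mature), "")[[1]]
      n_mm <- sample(1:2, 1)
      at <- sample(4:(L - 4), n_mm)
      for (p in at) star[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                              star[p]), 1)
      # G:U wobbles against the mature break reverse-complement symmetry,
      # so an ordinary precursor is not a structural palindrome
      elig <- setdiff(which(star %in% c("C", "A")), c(seq_len(3), L - 0:2,
                                                      at))
      n_wob <- min(length(elig), sample(5:7, 1))
      for (p in sample(elig, n_wob))
        star[p] <- if (star[p] == "C") "T" else "G"
      star <- paste(star, collapse = "")
      loop <- random_dna(1, loop_len)
      # lower stem: imperfect complementary extension below the duplex
      el <- sample(seq(ext_range[1], ext_range[2]), 1)
      e5 <- random_dna(1, el)
      e3 <- strsplit(revcomp(e5), "")[[1]]
      n_em <- min(el %/% 6L, sample(1:3, 1))
      if (n_em > 0) for (p in sample(el, n_em))
        e3[p] <- sample(setdiff(c("A", "C", "G", "T"), e3[p]), 1)
      # wobbles along the extension keep the antisense strand from
      # folding into the mirrored hairpin
      ew <- which(e3 %in% c("C", "A"))
      n_ew <- min(length(ew), max(2L, el %/% 5L))
      if (n_ew > 0) for (p in sample(ew, n_ew))
        e3[p] <- if (e3[p] == "C") "T" else "G"
      e3 <- paste(e3, collapse = "")
      t5 <- random_dna(1, sample(2:6, 1))
      t3 <- random_dna(1, sample(2:6, 1))
      if (arm == "5p") {
        prec <- paste0(t5, e5, mature, loop, star, e3, t3)
        m1 <- nchar(t5) + el + 1L
      } else {
        prec <- paste0(t5, e5, star, loop, mature, e3, t3)
        m1 <- nchar(t5) + el + nchar(star) + loop_len + 1L
      }
      if (nchar(prec) < 54L)
        prec <- paste0(prec, random_dna(1, 54L - nchar(prec)))
      v <- validate_hairpin(prec, c(m1, m1 + L - 1L), params, mfe_ceiling)
      if (v$accept) return(v$precursor)
    }
    stop("could not construct a precursor below the MFE ceiling for ",
         mature)
  })
}

# built-in structural-RNA contaminant records (drawn once per dataset)
make_contaminants <- function() {
  lens <- c(rRNA_1 = 1500L, rRNA_2 = 900L, tRNA_1 = 76L, tRNA_2 = 74L,
            tRNA_3 = 75L, snRNA_1 = 150L, snRNA_2 = 140L,
            snoRNA_1 = 110L, snoRNA_2 = 105L)
  setNames(random_dna(length(lens), lens), names(lens))
}

# Fig-3-like sRNA length profile: modal 24 nt, secondary peak 21 nt
srna_length_weights <- function() {
  w <- c(2, 3, 4, 14, 6, 5, 20, 8, 5, 4, 3, 2, 2)
  setNames(w / sum(w), 18:30)
}

plant_in_sequence <- function(host, insert, pos) {
  paste0(substr(host, 1L, pos - 1L), insert,
         substr(host, pos, nchar(host)))
}

apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < rate
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate the synthetic file bundle and truth table
#'
#' Writes, under `outdir`: `unigenes.fa` (with planted precursors and
#' target sites), `srna_<library>.fastq` (Phred+33, dummy qualities),
#' `degradome_<library>.fa`, `mature_catalog.fa` (miRBase-style, U
#' alphabet, including the decoys), `contaminants.fa`,
#' `go_annotation.tsv`, `fragment_counts.tsv` and `truth.json`.
#'
#' @param config a [synthetic_config()].
#' @param outdir output directory (defaults to `config$outdir`).
#' @return (invisibly) a list with `paths`, `truth` and `config`.
#' @export
generate_dataset <- function(config, outdir = config$outdir) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(outdir)) stop("an output directory must be named")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  libs <- config$libraries
  nlib <- length(libs)
  params <- rna_energy_params()
  n_known <- config$n_known_mirnas
  n_novel <- config$n_novel_mirnas
  n_mir <- n_known + n_novel

  if (config$n_unigenes < n_mir + config$n_target_sites)
    stop("n_unigenes too small to host all precursors and target sites")

  ## unigenes -----------------------------------------------------------
  ulen <- sample(seq(config$unigene_len_range[1],
                     config$unigene_len_range[2]),
                 config$n_unigenes, replace = TRUE)
  unigenes <- random_dna(config$n_unigenes, ulen)
  names(unigenes) <- sprintf("Unigene%05d", seq_len(config$n_unigenes))

  ## mature catalog -----------------------------------------------------
  fam_num <- c(156, 157, 159, 160, 162, 164, 165, 166, 167, 168, 169,
               171, 172, 319, 390, 393, 394, 395, 396, 397, 398, 399,
               403, 408, 477, 482, 530, 535, 828, 858, 2111, 3627, 5021,
               5077, 6149, 7122, 7532, 8175)
  n_extra <- 10L  # catalog entries never planted
  need <- n_known + n_extra
  if (need > length(fam_num)) fam_num <- c(fam_num, 8999 + seq_len(need))
  fam_num <- fam_num[seq_len(need)]
  cat_seq <- random_dna(need, 21L, gc = c(0.40, 0.65))
  cat_id <- sprintf("ath-miR%d%s%s", fam_num,
                    sample(letters[1:3], need, replace = TRUE),
                    sample(c("", "-5p", "-3p"), need, replace = TRUE,
                           prob = c(0.4, 0.4, 0.2)))

  planted <- list()
  if (n_known > 0) for (i in seq_len(n_known)) {
    perfect <- i %% 2L == 1L
    if (perfect) seqd <- cat_seq[i]
    else repeat {
      k <- sample(2:4, 1)
      seqd <- paste0(substr(cat_seq[i], k + 1L, 21L), random_dna(1, k))
      if (!seqd %in% cat_seq) break
    }
    planted[[length(planted) + 1L]] <- list(
      id = paste0("vas-", mirna_family(cat_id[i])),
      family = mirna_family(cat_id[i]), sequence = seqd,
      class = if (perfect) "known_perfect" else "known_variant")
  }
  if (n_novel > 0) for (i in seq_len(n_novel)) {
    repeat {
      L <- sample(20:23, 1, prob = c(6, 63, 12, 20) / 101)
      seqd <- random_dna(1, L, gc = c(0.40, 0.65))
      clash <- any(vapply(cat_seq, function(cs)
        .best_clean_overlap_cpp(seqd, cs) >= 16L, logical(1)))
      if (!clash) break
    }
    planted[[length(planted) + 1L]] <- list(
      id = sprintf("vas-miR-%d", i), family = sprintf("miR-%d", i),
      sequence = seqd, class = "novel")
  }
  planted_seq <- vapply(planted, `[[`, character(1), "sequence")

  decoys <- list()
  if (config$n_decoy_mirnas > 0 && n_mir > 0) {
    src <- planted_seq[rep_len(seq_len(n_mir), config$n_decoy_mirnas)]
    for (i in seq_len(config$n_decoy_mirnas)) {
      repeat {
        d <- shuffle_seq(src[i])
        clash <- any(vapply(planted_seq, function(ps)
          .best_clean_overlap_cpp(d, ps) >= 16L, logical(1)))
        if (!clash && !d %in% cat_seq) break
      }
      decoys[[i]] <- list(id = sprintf("osa-miR%d", 9100L + i),
                          sequence = d)
    }
  }
  decoy_seq <- vapply(decoys, `[[`, character(1), "sequence")

  ## precursor planting -------------------------------------------------
  hosts <- if (n_mir > 0) sample(config$n_unigenes, n_mir) else integer(0)
  precs <- vector("list", n_mir)
  if (n_mir > 0) for (i in seq_len(n_mir)) {
    arm <- sample(c("5p", "3p"), 1, prob = c(0.7, 0.3))
    prec <- build_precursor(planted[[i]]$sequence,
                            loop_len = sample(8:15, 1),
                            seed = sample.int(1e8, 1), arm = arm,
                            params = params)
    strand <- sample(c("+", "-"), 1, prob = c(0.85, 0.15))
    u <- hosts[i]
    plen <- nchar(prec$sequence)
    pos <- sample(seq(40L, nchar(unigenes[u]) - 40L), 1)
    ins <- if (strand == "+") prec$sequence else revcomp(prec$sequence)
    unigenes[u] <- plant_in_sequence(unigenes[u], ins, pos)
    prec$unigene <- names(unigenes)[u]
    prec$start <- pos
    prec$end <- pos + plen - 1L
    prec$strand <- strand
    precs[[i]] <- prec
    planted[[i]]$unigene <- prec$unigene
    planted[[i]]$start <- prec$start
    planted[[i]]$end <- prec$end
    planted[[i]]$strand <- strand
    planted[[i]]$arm <- prec$mature_arm
    planted[[i]]$star_sequence <-
      if (is.null(prec$star_span)) NA_character_
      else substr(prec$sequence, prec$star_span[1], prec$star_span[2])
  }

  ## expression design --------------------------------------------------
  if (!is.null(config$expression_profiles)) {
    rpm_exp <- as.matrix(config$expression_profiles)
    stopifnot(nrow(rpm_exp) == n_mir, ncol(rpm_exp) == nlib)
  } else if (n_mir > 0) {
    base <- 10^runif(n_mir, 1, 3)
    mult <- t(vapply(seq_len(n_mir), function(i) {
      kind <- sample(c("flat", "high", "low", "specific"), 1,
                     prob = c(0.4, 0.2, 0.2, 0.2))
      m <- rep(1, nlib)
      pick <- sample(nlib, 1)
      if (kind == "high") m[pick] <- 4
      if (kind == "low") m[pick] <- 0.2
      if (kind == "specific") { m[] <- 0.02; m[pick] <- 1 }
      m
    }, numeric(nlib)))
    rpm_exp <- base * mult
  } else rpm_exp <- matrix(0, 0, nlib)
  if (n_mir > 0) colnames(rpm_exp) <- libs

  ## sRNA libraries -----------------------------------------------------
  contam <- make_contaminants()
  lw <- srna_length_weights()
  R <- config$reads_per_library
  n_junk <- round(config$junk_fraction * R)
  D <- R - n_junk  # expected clean denominator
  cnt_mat <- if (n_mir > 0) round(rpm_exp * D / 1e6) else rpm_exp
  if (n_mir > 0) {
    # keep every planted miRNA clearly above the acceptance cutoff
    # (> 2 RPM in >= 2 libraries) in read units
    floor_cnt <- max(2, ceiling(3 * D / 1e6))
    for (i in seq_len(n_mir)) {
      ord <- order(rpm_exp[i, ], decreasing = TRUE)
      for (j in ord[1:2])
        if (cnt_mat[i, j] < floor_cnt) cnt_mat[i, j] <- floor_cnt
    }
    rpm_exp <- cnt_mat * 1e6 / D  # truth reflects the realised design
  }
  # star reads: a fixed fraction of the mature, kept at low absolute
  # abundance (at most ~8 RPM equivalent, never half the mature or more)
  cnt_star <- if (n_mir > 0)
    pmin(round(config$star_to_mature_ratio * cnt_mat),
         max(1, floor(8 * D / 1e6)), floor(cnt_mat / 2))
  else cnt_mat
  srna_paths <- character(0)
  realized <- matrix(0, n_mir, nlib, dimnames = list(NULL, libs))
  star_realized <- matrix(0, n_mir, nlib, dimnames = list(NULL, libs))

  for (li in seq_len(nlib)) {
    pool <- character(0)
    for (i in seq_len(n_mir)) {
      c_i <- cnt_mat[i, li]
      if (c_i <= 0) next
      n_iso <- round(config$isomir_fraction * c_i)
      prec <- precs[[i]]
      m1 <- prec$mature_span[1]; m2 <- prec$mature_span[2]
      trimmed <- substr(prec$sequence, m1, m2 - 1L)
      extended <- substr(prec$sequence, m1,
                         min(m2 + 1L, nchar(prec$sequence)))
      iso <- rep(c(trimmed, extended), length.out = n_iso)
      pool <- c(pool, rep(planted[[i]]$sequence, c_i - n_iso), iso)
      realized[i, li] <- c_i
      s_i <- cnt_star[i, li]
      if (s_i > 0 && !is.na(planted[[i]]$star_sequence)) {
        pool <- c(pool, rep(planted[[i]]$star_sequence, s_i))
        star_realized[i, li] <- s_i
      }
    }
    n_contam <- round(config$contaminant_fraction * R)
    cl <- sample(seq_along(contam), n_contam, replace = TRUE,
                 prob = nchar(contam))
    wlen <- as.integer(sample(names(lw), n_contam, replace = TRUE,
                              prob = lw))
    cst <- vapply(seq_len(n_contam), function(t)
      sample(nchar(contam[cl[t]]) - wlen[t] + 1L, 1), integer(1))
    cw <- substr(contam[cl], cst, cst + wlen - 1L)
    flip <- runif(n_contam) < 0.3
    cw[flip] <- revcomp(cw[flip])
    pool <- c(pool, unname(cw))

    n_noise <- R - n_junk - length(pool)
    if (n_noise < 0)
      stop("reads_per_library too small for the planted design")
    n_ug <- round(config$unigene_noise_fraction * n_noise)
    if (n_ug > 0) {
      ui <- sample(config$n_unigenes, n_ug, replace = TRUE,
                   prob = nchar(unigenes))
      nl <- as.integer(sample(names(lw), n_ug, replace = TRUE, prob = lw))
      st <- vapply(seq_len(n_ug), function(t)
        sample(nchar(unigenes[ui[t]]) - nl[t] + 1L, 1), integer(1))
      pool <- c(pool, unname(substr(unigenes[ui], st, st + nl - 1L)))
    }
    n_rand <- n_noise - n_ug
    if (n_rand > 0) {
      rl <- as.integer(sample(names(lw), n_rand, replace = TRUE,
                              prob = lw))
      pool <- c(pool, random_dna(n_rand, rl))
    }
    pool <- apply_errors(pool, config$error_rate)
    # junk reads: homopolymers and N-containing
    if (n_junk > 0) {
      n_hp <- n_junk %/% 2L
      hp <- strrep(sample(c("A", "C", "G", "T"), n_hp, replace = TRUE),
                   sample(18:30, n_hp, replace = TRUE))
      n_nn <- n_junk - n_hp
      nn <- random_dna(n_nn, sample(18:30, n_nn, replace = TRUE))
      nn <- vapply(nn, function(s) {
        p <- sample(nchar(s), 1)
        paste0(substr(s, 1, p - 1L), "N", substr(s, p + 1L, nchar(s)))
      }, character(1), USE.NAMES = FALSE)
      pool <- c(pool, hp, nn)
    }
    stopifnot(length(pool) == R)
    pool <- sample(pool)
    path <- file.path(outdir, paste0("srna_", libs[li], ".fastq"))
    write_fastq(paste0(pool, config$adaptor3), path,
                ids = sprintf("%s_read%07d", libs[li], seq_along(pool)))
    srna_paths <- c(srna_paths, path)
  }

  ## degradome: planted cleavage sites ----------------------------------
  n_sites <- if (n_mir > 0) config$n_target_sites else 0L
  free_ug <- setdiff(seq_len(config$n_unigenes), hosts)
  site_hosts <- if (n_sites > 0) sample(free_ug, n_sites) else integer(0)
  sites <- list()
  if (n_sites > 0) for (s in seq_len(n_sites)) {
    mi <- sample(n_mir, 1)
    mseq <- planted[[mi]]$sequence
    L <- nchar(mseq)
    u <- site_hosts[s]
    pos <- sample(seq(30L, nchar(unigenes[u]) - L - 30L), 1)
    unigenes[u] <- plant_in_sequence(unigenes[u], revcomp(mseq), pos)
    k_lib <- min(nlib, sample(c(3L, 2L, 1L), 1, prob = c(0.5, 0.3, 0.2)))
    in_libs <- sort(sample(nlib, k_lib))
    sites[[s]] <- list(mirna_id = planted[[mi]]$id,
                       mirna_index = mi,
                       transcript = names(unigenes)[u],
                       site_start = pos, site_end = pos + L - 1L,
                       cleavage_pos = pos + L - 10L,
                       libraries = libs[in_libs],
                       expected_category = 0L)
  }

  deg_paths <- character(0)
  tag_w <- 20L
  for (li in seq_len(nlib)) {
    pool <- character(0)
    for (s in seq_along(sites)) {
      if (!(libs[li] %in% sites[[s]]$libraries)) next
      Tt <- sample(seq(config$site_tag_range[1], config$site_tag_range[2]),
                   1)
      n_peak <- round(config$cleavage_peak_fraction * Tt)
      tx <- unigenes[[sites[[s]]$transcript]]
      cp <- sites[[s]]$cleavage_pos
      pool <- c(pool, rep(substr(tx, cp, cp + tag_w - 1L), n_peak))
      n_bg <- Tt - n_peak
      if (n_bg > 0) {
        st <- sample(nchar(tx) - tag_w + 1L, n_bg, replace = TRUE)
        pool <- c(pool, substr(rep(tx, n_bg), st, st + tag_w - 1L))
      }
      sites[[s]][[paste0("tags_", libs[li])]] <- n_peak
      sites[[s]][[paste0("total_", libs[li])]] <- Tt
    }
    n_dcon <- round(0.02 * config$degradome_tags_per_library)
    cl <- sample(seq_along(contam), n_dcon, replace = TRUE,
                 prob = nchar(contam))
    cst <- vapply(cl, function(j)
      sample(nchar(contam[j]) - tag_w + 1L, 1), integer(1))
    pool <- c(pool, unname(substr(contam[cl], cst, cst + tag_w - 1L)))
    n_short <- 50L
    pool <- c(pool, random_dna(n_short, 10L))
    n_bg <- config$degradome_tags_per_library - length(pool)
    if (n_bg < 0) stop("degradome_tags_per_library too small")
    ui <- sample(config$n_unigenes, n_bg, replace = TRUE,
                 prob = nchar(unigenes))
    st <- vapply(ui, function(u)
      sample(nchar(unigenes[u]) - tag_w + 1L, 1), integer(1))
    pool <- c(pool, unname(substr(unigenes[ui], st, st + tag_w - 1L)))
    pool <- sample(pool)
    path <- file.path(outdir, paste0("degradome_", libs[li], ".fa"))
    write_fasta(pool, path,
                names = sprintf("%s_dtag%06d", libs[li], seq_along(pool)))
    deg_paths <- c(deg_paths, path)
  }

  ## GO annotation with planted enrichment ------------------------------
  go_terms <- data.frame(
    go_id = c("GO:0008152", "GO:0009987", "GO:0050896", "GO:0032502",
              "GO:0040007", "GO:0000003", "GO:0065007", "GO:0051179",
              "GO:0009058", "GO:0006950", "GO:0007154", "GO:0009056",
              "GO:0048511",
              "GO:0005623", "GO:0043226", "GO:0016020", "GO:0005576",
              "GO:0030054", "GO:0045202", "GO:0031974", "GO:0009579",
              "GO:0005618",
              "GO:0003824", "GO:0005488", "GO:0000988", "GO:0005215",
              "GO:0060089", "GO:0016209", "GO:0045182", "GO:0038024"),
    namespace = c(rep("biological_process", 13),
                  rep("cellular_component", 9),
                  rep("molecular_function", 8)),
    stringsAsFactors = FALSE)
  term_w <- runif(nrow(go_terms), 0.2, 1)
  ann <- list()
  target_tx <- unique(vapply(sites, `[[`, character(1), "transcript"))
  for (u in seq_len(config$n_unigenes)) {
    gid <- names(unigenes)[u]
    n_t <- stats::rpois(1, 1.2)
    picked <- if (n_t > 0)
      sample(nrow(go_terms), min(n_t, nrow(go_terms)), prob = term_w)
    else integer(0)
    if (gid %in% target_tx) {
      if (runif(1) < 0.6) picked <- union(picked, 1L)    # GO:0008152
      if (runif(1) < 0.5) picked <- union(picked, 23L)   # GO:0003824
    }
    if (length(picked))
      ann[[length(ann) + 1L]] <- data.frame(
        gene = gid, go_id = go_terms$go_id[picked],
        namespace = go_terms$namespace[picked], stringsAsFactors = FALSE)
  }
  go_df <- if (length(ann)) do.call(rbind, ann)
           else data.frame(gene = character(0), go_id = character(0),
                           namespace = character(0))
  go_path <- file.path(outdir, "go_annotation.tsv")
  write_tsv(go_df, go_path)

  ## per-unigene fragment counts (transcriptome stand-in) ---------------
  frag <- data.frame(unigene = names(unigenes),
                     length = nchar(unigenes),
                     stringsAsFactors = FALSE)
  for (lib in libs)
    frag[[paste0("fragments.", lib)]] <-
      round(rlnorm(config$n_unigenes, meanlog = 4, sdlog = 1))
  frag_path <- file.path(outdir, "fragment_counts.tsv")
  write_tsv(frag, frag_path)

  ## remaining FASTA outputs --------------------------------------------
  ug_path <- file.path(outdir, "unigenes.fa")
  write_fasta(unname(unigenes), ug_path, names = names(unigenes))
  cat_path <- file.path(outdir, "mature_catalog.fa")
  cat_all_id <- c(cat_id, vapply(decoys, `[[`, character(1), "id"))
  cat_all_seq <- c(cat_seq, decoy_seq)
  writeLines(paste0(">", cat_all_id, "\n", as_rna(cat_all_seq)), cat_path)
  con_path <- file.path(outdir, "contaminants.fa")
  write_fasta(unname(contam), con_path, names = names(contam))

  ## truth table --------------------------------------------------------
  truth <- list(
    planted_mirnas = lapply(seq_len(n_mir), function(i) {
      p <- planted[[i]]
      c(p[c("id", "family", "sequence", "class", "unigene", "start",
            "end", "strand", "arm", "star_sequence")],
        list(expected_rpm = as.list(setNames(rpm_exp[i, ], libs)),
             planted_counts = as.list(setNames(realized[i, ], libs)),
             star_counts = as.list(setNames(star_realized[i, ], libs))))
    }),
    decoys = decoys,
    planted_sites = sites,
    clean_denominator = D,
    libraries = libs,
    go_enriched_terms = c("GO:0008152", "GO:0003824"),
    seed = config$seed)
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  paths <- list(unigenes = ug_path, catalog = cat_path,
                contaminants = con_path,
                srna = setNames(srna_paths, libs),
                degradome = setNames(deg_paths, libs),
                go_annotation = go_path, fragment_counts = frag_path,
                truth = truth_path)
  invisible(list(paths = paths, truth = truth, config = config))
}
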