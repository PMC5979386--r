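# Degradome tag mapping, Allen scoring, site calling, categories and
# permutation p-values.

test_that("tags map exactly on the sense strand with fractional multireads", {
  set.seed(2)
  core <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  shared <- substr(core, 100, 119)
  u <- Biostrings::DNAStringSet(c(
    t1 = core,
    t2 = paste0(paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                      collapse = ""), shared)))
  tag_uni <- substr(core, 50, 69)
  tag_mis <- paste0(if (substr(tag_uni, 1, 1) == "A") "C" else "A",
                    substr(tag_uni, 2, 20))
  prof <- clean_and_map_tags(c(rep(tag_uni, 4), rep(shared, 2), tag_mis,
                               "ACGTACGT"),  # 8-mer: below min length
                             u)
  expect_equal(prof$profiles$t1[50], 4)
  expect_equal(prof$profiles$t1[100], 1)    # 2 copies split over 2 loci
  expect_equal(prof$profiles$t2[81], 1)
  expect_false(any(prof$profiles$t1 == 7))  # mismatched tag unmapped
  expect_equal(prof$n_removed, 1)           # the short tag
  expect_error(clean_and_map_tags("ACGTACGTACGTACGTACGT",
                                  Biostrings::DNAStringSet()), "empty")
})

test_that("Allen scores penalise by position with core doubling", {
  mir <- "UGACAGAAGAGAGUGAGCACA"          # 21 nt
  perfect <- as_dna(revcomp(mir))
  expect_equal(score_alignment(mir, perfect)$score, 0)
  # G:U wobble opposite miRNA position 5 (inside the doubled core)
  w5 <- perfect
  k <- 5
  substr(w5, 21 - k + 1, 21 - k + 1) <- "T"  # A at mir pos5? ensure G:U
  # mir position 5 is A; force a wobble by using position with G instead
  mirG <- mir
  substr(mirG, 5, 5) <- "G"
  wG <- as_dna(revcomp(mirG))
  substr(wG, 21 - 5 + 1, 21 - 5 + 1) <- "T"  # G:U at position 5
  al <- score_alignment(mirG, wG)
  expect_equal(al$score, 1.0)               # 0.5 doubled in the core
  expect_equal(al$pattern[5], "GU")
  # single mismatch opposite position 20 (outside the core)
  m20 <- perfect
  b <- substr(m20, 2, 2)
  substr(m20, 2, 2) <- if (b == "A") "C" else "A"
  al2 <- score_alignment(mir, m20)
  expect_equal(al2$score, 1.0)
  expect_equal(al2$pattern[20], "mismatch")
  expect_error(score_alignment("UGAX", "ACGT"), "non-nucleotide")
  expect_error(score_alignment(mir, "ACGT"), "length")
})

test_that("site calling keeps low scores over tagged cleavage positions", {
  set.seed(9)
  mir <- "UGACAGAAGAGAGUGAGCACA"
  tx <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
              collapse = "")
  site <- as_dna(revcomp(mir))
  tx <- paste0(substr(tx, 1, 150), site, substr(tx, 151 + 21, 400))
  cpos <- 151 + 21 - 10
  prof <- numeric(nchar(tx)); prof[cpos] <- 12
  hits <- find_sites(mir, tx, prof)
  expect_true(any(hits$cleavage_pos == cpos & hits$score == 0))
  # without a tag at the cleavage position nothing is called there
  prof0 <- numeric(nchar(tx))
  expect_equal(nrow(find_sites(mir, tx, prof0)), 0L)
  # four doubled-core mismatches score 8 and fall above the cutoff
  mir8 <- mir
  for (k in c(3, 5, 8, 11)) {
    b <- substr(mir8, k, k)
    substr(mir8, k, k) <- if (b == "A") "C" else "A"
  }
  sc <- score_alignment(mir8, site)$score
  expect_equal(sc, 8)
  expect_equal(nrow(find_sites(mir8, tx, prof)), 0L)
})

test_that("categories follow the max/median rules", {
  prof <- numeric(60)
  prof[10] <- 5; prof[50] <- 1
  expect_equal(categorize(5, prof), 0L)
  prof2 <- numeric(60); prof2[10] <- 5; prof2[30] <- 5
  expect_equal(categorize(5, prof2), 1L)
  prof3 <- numeric(60); prof3[10] <- 1
  expect_equal(categorize(1, prof3), 4L)
  prof4 <- numeric(60); prof4[c(5, 15, 25, 35)] <- c(9, 4, 2, 2)
  expect_equal(categorize(4, prof4), 2L)   # below max 9, above median 3
  expect_equal(categorize(2, prof4), 3L)   # at/below the nonzero median
  expect_equal(categorize(4, prof4), brute_categorize(4, prof4))
  expect_error(categorize(0, prof), "not a site")
})

test_that("categorize agrees with brute force on random profiles", {
  set.seed(13)
  for (i in 1:300) {
    prof <- numeric(sample(30:120, 1))
    nz <- sample(length(prof), sample(3:12, 1))
    prof[nz] <- sample(1:8, length(nz), replace = TRUE)
    pos <- sample(nz, 1)
    expect_identical(categorize(prof[pos], prof),
                     brute_categorize(prof[pos], prof))
  }
})

test_that("category never worsens as site support grows", {
  set.seed(14)
  for (i in 1:100) {
    prof <- numeric(80)
    nz <- sample(80, 6)
    prof[nz] <- sample(1:9, 6, replace = TRUE)
    counts <- sort(unique(prof[nz]))
    cats <- vapply(counts, categorize, integer(1), profile = prof)
    expect_true(all(diff(cats) <= 0L))
  }
})

test_that("permutation p-values hit the floor for planted perfect sites", {
  set.seed(21)
  mir <- "UGACAGAAGAGAGUGAGCACA"
  tx <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
              collapse = "")
  tx <- paste0(substr(tx, 1, 100), as_dna(revcomp(mir)),
               substr(tx, 122, 300))
  cpos <- 101 + 21 - 10
  prof <- numeric(nchar(tx)); prof[cpos] <- 40
  prof[sample(setdiff(seq_len(nchar(tx)), cpos), 10)] <- 1
  p <- site_pvalue(mir, tx, prof, 0, 40, n_perm = 200, seed = 42)
  expect_equal(p, 1 / 201)
  expect_lt(p, 0.05)
  expect_error(site_pvalue(mir, tx, prof, 0, 40, n_perm = 0), "at least")
})

test_that("p-values are diffuse for random miRNA-transcript pairs", {
  set.seed(42)
  ps <- replicate(50, {
    mir <- random_rna(21)
    tx <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
    prof <- numeric(400); prof[sample(400, 20)] <- 1
    tagged <- which(prof >= 1)
    cp <- sample(tagged, 1)
    w <- cp - 21 + 10
    if (w < 1 || w + 20 > 400) return(NA)
    sc <- score_alignment(mir, substr(tx, w, w + 20))$score
    site_pvalue(mir, tx, prof, sc, prof[cp], n_perm = 120)
  })
  expect_gt(mean(ps, na.rm = TRUE), 0.3)
})

test_that("alignment reports carry counts, arrows and aligned rows", {
  run <- small_run()
  skip_if(is.null(run$sites) || nrow(run$sites) == 0)
  rep_lines <- render_alignment_report(run$sites[1, , drop = FALSE],
                                       run$mirnas,
                                       Biostrings::readDNAStringSet(
                                         small_bundle()$paths$unigenes))
  expect_match(rep_lines[1], sprintf("category %d", run$sites$category[1]))
  cnt_line <- rep_lines[2]; arrow_line <- rep_lines[3]
  expect_match(cnt_line, format(run$sites$tags_at_site[1]), fixed = TRUE)
  # the count ends in the arrow column
  arrow_col <- regexpr("v", arrow_line)
  expect_equal(nchar(trimws(cnt_line, "right")), arrow_col[1])
  # miRNA, pairing and target rows are padded to equal length
  expect_equal(nchar(rep_lines[4]), nchar(rep_lines[5]))
  expect_equal(nchar(rep_lines[5]), nchar(rep_lines[6]))
})
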