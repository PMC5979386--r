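# Known-miRNA matching, family templates, mismatch-tolerant assignment,
# hairpin validation, star and palindrome detection.

test_that("family keys are parsed from miRBase-style identifiers", {
  expect_equal(mirna_family(c("ath-miR166a-3p", "ath-miR166b", "vas-miR156",
                              "osa-miR2111b-5p", "vas-miR-14")),
               c("miR166", "miR166", "miR156", "miR2111", "miR-14"))
})

test_that("catalog matching distinguishes perfect and overlap tiers", {
  mat <- paste0(strrep("ACGT", 5), "A")  # 21 nt
  catalog <- data.frame(id = c("ath-miR001a", "ath-miR002a"),
                        family = c("miR001", "miR002"),
                        sequence = c(mat, "GGGGGGGGGGCCCCCCCCCCC"),
                        stringsAsFactors = FALSE)
  # a tag identical to a catalog mature; a tag sharing a 16-nt end block;
  # a tag sharing only 15 nt
  shift5 <- paste0(substr(mat, 6, 21), "TTTTT")  # 16-nt end-aligned block
  shift6 <- paste0(substr(mat, 7, 21), "TTTTTT") # only 15 identical
  tags <- toy_tags(list(x = c(mat, shift5, shift6)))
  hits <- match_known(tags, catalog)
  expect_equal(hits$tier[hits$sequence == mat], "perfect")
  expect_equal(hits$overlap_len[hits$sequence == mat], 21L)
  expect_equal(hits$tier[hits$sequence == shift5], "overlap")
  expect_equal(hits$overlap_len[hits$sequence == shift5], 16L)
  expect_false(shift6 %in% hits$sequence)
  # agreement with the brute-force offset scanner
  expect_equal(brute_clean_overlap(shift5, mat), 16L)
  expect_lt(brute_clean_overlap(shift6, mat), 16L)
  # an internal substitution leaves no mismatch-free overlap >= 16
  sub <- mat
  substr(sub, 11, 11) <- if (substr(mat, 11, 11) == "A") "C" else "A"
  expect_lt(brute_clean_overlap(sub, mat), 16L)
  expect_error(match_known(tags, catalog[0, ]), "empty")
})

test_that("family templates take the highest count, ties lexicographic", {
  s1 <- paste(rep("ACGGT", 4), collapse = "")  # 20 nt
  s2 <- paste(rep("TGCCA", 4), collapse = "")
  tags <- toy_tags(list(x = c(rep(s1, 100), rep(s2, 7))))
  hits <- data.frame(sequence = c(s1, s2), mature_id = "m", family = "f",
                     tier = "perfect", overlap_len = 20L,
                     mismatches_in_overlap = 0L)
  expect_equal(select_family_template(hits, tags)$template, s1)
  # constructed tie: the lexicographically smaller sequence wins
  tags2 <- toy_tags(list(x = c(rep(s1, 50), rep(s2, 50))))
  expect_equal(select_family_template(hits, tags2)$template, min(s1, s2))
})

test_that("tags assign to templates within two mismatches and 2-nt overhangs", {
  tpl <- paste0(strrep("GATC", 5), "G")  # 21 nt
  two_sub <- tpl
  substr(two_sub, 5, 5) <- "T"; substr(two_sub, 15, 15) <- "A"
  three_sub <- two_sub
  substr(three_sub, 10, 10) <- "C"
  overhang <- paste0(substr(two_sub, 1, 21), "A")  # 2 subs + 1-nt 3' over
  tags <- toy_tags(list(a = c(rep(tpl, 10), rep(two_sub, 4),
                              rep(three_sub, 2), rep(overhang, 3)),
                        b = rep(tpl, 10)))
  templates <- data.frame(family = "miR900", template = tpl)
  prof <- assign_to_templates(tags, templates)
  asg <- attr(prof, "assignment")
  by_tag <- setNames(asg$template, tags$sequence)
  expect_equal(unname(by_tag[tpl]), 1L)
  expect_equal(unname(by_tag[two_sub]), 1L)
  expect_equal(unname(by_tag[overhang]), 1L)
  expect_equal(unname(by_tag[three_sub]), 0L)  # 3 mismatches: unassigned
  expect_equal(prof$count.a, 10 + 4 + 3)
})

test_that("accepted set grows monotonically as the RPM cutoff drops", {
  run <- small_run()
  tags <- run$tags
  templates <- data.frame(family = c("a", "b"),
                          template = run$mirnas$sequence[1:2])
  prev <- character(0)
  for (cut in c(50, 10, 2, 0.5)) {
    prof <- assign_to_templates(tags, templates, rpm_cutoff = cut)
    acc <- prof$family[prof$accepted]
    expect_true(all(prev %in% acc))
    prev <- acc
  }
})

test_that("hairpin validation enforces arm placement and pairing", {
  mat <- "TGTTCTCAGGTCACCCATTCG"
  prec <- build_precursor(mat, loop_len = 10, seed = 2)
  expect_true(validate_hairpin(prec$sequence, prec$mature_span)$accept)
  # a mature placed across the terminal loop is rejected
  loop_mid <- floor(mean(prec$loop_span))
  v <- validate_hairpin(prec$sequence, c(loop_mid - 10L, loop_mid + 10L))
  expect_false(v$accept)
  expect_match(v$reason, "loop")
  expect_error(validate_hairpin(prec$sequence, c(-1L, 20L)), "outside")
})

test_that("shuffled precursors are rarely accepted as hairpins", {
  mat <- "TGTTCTCAGGTCACCCATTCG"
  # a precursor of the typical (average ~150 nt) length
  prec <- build_precursor(mat, loop_len = 10, seed = 1,
                          ext_range = c(40L, 55L))
  set.seed(42)
  acc <- 0L
  for (i in 1:100) {
    sh <- degradomiR:::shuffle_seq(prec$sequence)
    acc <- acc + validate_hairpin(sh, prec$mature_span)$accept
  }
  expect_lt(acc / 100, 0.05)
})

test_that("star detection finds planted passenger strands", {
  b <- small_bundle(); run <- small_run()
  withstar <- vapply(b$truth$planted_mirnas, function(p)
    !is.na(p$star_sequence) && sum(unlist(p$star_counts)) > 0, logical(1))
  planted <- b$truth$planted_mirnas[withstar]
  skip_if(length(planted) == 0)
  ids_by_seq <- setNames(run$mirnas$id, run$mirnas$sequence)
  hit <- 0L
  for (p in planted) {
    id <- ids_by_seq[p$sequence]
    if (is.na(id)) next
    prec <- run$precursors[[id]]
    star <- detect_star(prec, run$tags)
    if (star$detected) hit <- hit + 1L
    # star and mature never overlap
    expect_true(star$span[2] < prec$mature_span[1] ||
                star$span[1] > prec$mature_span[2])
  }
  expect_gt(hit, 0L)
  # without any matching reads the span is computed but not detected
  empty <- toy_tags(list(x = strrep("ACGT", 6)))
  prec1 <- build_precursor("TGTTCTCAGGTCACCCATTCG", seed = 4)
  s <- detect_star(prec1, empty)
  expect_false(s$detected)
  expect_false(is.na(s$sequence))
})

test_that("star abundance stays below the mature in the planted design", {
  b <- small_bundle()
  for (p in b$truth$planted_mirnas) {
    sc <- unlist(p$star_counts); mc <- unlist(p$planted_counts)
    expect_true(all(sc <= mc))
  }
})

test_that("palindromic precursors are recognised and ordinary ones are not", {
  half <- "GCCGTAGCTAGGCATCGATCGGAACGATCG"
  pal <- paste0(half, revcomp(half))  # its own reverse complement
  expect_identical(pal, revcomp(pal))
  v <- validate_hairpin(pal, c(2L, 22L))
  expect_true(v$accept)
  expect_true(detect_palindrome(v$precursor))
  ordinary <- build_precursor("TGTTCTCAGGTCACCCATTCG", seed = 2)
  expect_false(detect_palindrome(ordinary))
})

test_that("novel discovery rejects tags lying in a terminal loop", {
  b <- small_bundle()
  unigenes <- Biostrings::readDNAStringSet(b$paths$unigenes)
  names(unigenes) <- sub("\\s.*$", "", names(unigenes))
  p <- b$truth$planted_mirnas[[1]]
  # a 21-mer centred on the terminal loop of the planted hairpin
  prec <- substr(as.character(unigenes[[p$unigene]]), p$start, p$end)
  if (p$strand == "-") prec <- revcomp(prec)
  f <- fold_rna(as_rna(prec))
  ch <- degradomiR:::stem_chains(f$pt)
  main <- ch[[which.max(vapply(ch, `[[`, integer(1), "n_pairs"))]]
  mid <- floor(mean(main$loop))
  looptag <- substr(prec, mid - 10L, mid + 10L)
  v <- validate_hairpin(prec, c(mid - 10L, mid + 10L), fold = f)
  expect_false(v$accept)
})
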