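# The synthetic study generator: determinism, planted structure and
# composition guarantees, and truth-table consistency.

test_that("precursor construction is deterministic and within bounds", {
  mat <- "TGTTCTCAGGTCACCCATTCG"
  p1 <- build_precursor(mat, loop_len = 10, seed = 9)
  p2 <- build_precursor(mat, loop_len = 10, seed = 9)
  expect_identical(p1$sequence, p2$sequence)
  expect_gte(nchar(p1$sequence), 54L)
  expect_lte(nchar(p1$sequence), 363L)
  expect_lt(p1$mfe, -18.2)
  # mature and star sit on opposite arms of the hairpin
  expect_true(p1$star_span[1] > p1$mature_span[2] ||
              p1$star_span[2] < p1$mature_span[1])
  expect_error(build_precursor(mat, loop_len = 2, seed = 1), "loop")
  expect_error(build_precursor("ACGT", seed = 1), "20-23")
})

test_that("an unpairable homopolymer mature is rejected", {
  expect_error(build_precursor(strrep("T", 21), seed = 3),
               "low-complexity|homopolymer")
})

test_that("identical seed and config give byte-identical bundles", {
  d1 <- file.path(tempdir(), "dgr-det1")
  d2 <- file.path(tempdir(), "dgr-det2")
  cfg <- synthetic_config(seed = 5, n_unigenes = 40, n_known_mirnas = 3,
                          n_novel_mirnas = 2, n_decoy_mirnas = 2,
                          reads_per_library = 5000, n_target_sites = 4,
                          degradome_tags_per_library = 2000)
  b1 <- generate_dataset(cfg, outdir = d1)
  b2 <- generate_dataset(cfg, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("library composition matches the configured proportions", {
  b <- small_bundle()
  cfg <- b$config
  fq <- readLines(b$paths$srna[[1]])
  expect_equal(length(fq) / 4L, cfg$reads_per_library)
  reads <- trim_adaptor(fq[seq(2, length(fq), by = 4)], cfg$adaptor3)
  # contaminant reads: recount against the contaminant records
  cons <- Biostrings::readDNAStringSet(b$paths$contaminants)
  idx <- degradomiR:::window_index(as.character(cons),
                                   sub("_.*", "", names(cons)),
                                   sort(unique(nchar(reads))))
  is_con <- vapply(reads, function(s) !is.null(idx[[s]]), logical(1),
                   USE.NAMES = FALSE)
  expected <- cfg$contaminant_fraction * cfg$reads_per_library
  sigma <- sqrt(expected * (1 - cfg$contaminant_fraction))
  expect_lt(abs(sum(is_con) - expected), max(4 * sigma, 0.01 * expected))
})

test_that("planted loci, sites and stars are consistent in the truth table", {
  b <- small_bundle()
  unigenes <- Biostrings::readDNAStringSet(b$paths$unigenes)
  names(unigenes) <- sub("\\s.*$", "", names(unigenes))
  for (p in b$truth$planted_mirnas) {
    expect_true(p$unigene %in% names(unigenes))
    seg <- substr(as.character(unigenes[[p$unigene]]), p$start, p$end)
    if (p$strand == "-") seg <- revcomp(seg)
    expect_true(grepl(p$sequence, seg, fixed = TRUE))
    if (!is.na(p$star_sequence))
      expect_true(grepl(p$star_sequence, seg, fixed = TRUE))
  }
  for (s in b$truth$planted_sites) {
    expect_true(s$transcript %in% names(unigenes))
    mir <- NULL
    for (p in b$truth$planted_mirnas) if (p$id == s$mirna_id) mir <- p
    win <- substr(as.character(unigenes[[s$transcript]]),
                  s$site_start, s$site_end)
    expect_identical(win, revcomp(mir$sequence))
  }
})

test_that("degradome tags peak at the planted cleavage positions", {
  b <- small_bundle()
  cfg <- b$config
  unigenes <- Biostrings::readDNAStringSet(b$paths$unigenes)
  names(unigenes) <- sub("\\s.*$", "", names(unigenes))
  lib <- cfg$libraries[1]
  tags <- as.character(Biostrings::readDNAStringSet(
    b$paths$degradome[[lib]]))
  for (s in b$truth$planted_sites) {
    if (!(lib %in% unlist(s$libraries))) next
    tx <- as.character(unigenes[[s$transcript]])
    peak <- substr(tx, s$cleavage_pos, s$cleavage_pos + 19L)
    n_peak <- sum(tags == peak)
    total <- s[[paste0("total_", lib)]]
    expect_gte(n_peak, s[[paste0("tags_", lib)]])
    frac <- cfg$cleavage_peak_fraction
    expect_gte(n_peak / total, frac - 3 * sqrt(frac * (1 - frac) / total))
  }
})

test_that("an empty design yields an empty truth table and no discoveries", {
  dir <- file.path(tempdir(), "dgr-empty")
  cfg <- synthetic_config(seed = 3, n_unigenes = 30, n_known_mirnas = 0,
                          n_novel_mirnas = 0, n_decoy_mirnas = 0,
                          reads_per_library = 3000, n_target_sites = 0,
                          degradome_tags_per_library = 1000, outdir = dir)
  b <- generate_dataset(cfg)
  expect_length(b$truth$planted_mirnas, 0)
  expect_length(b$truth$planted_sites, 0)
  reads <- lapply(b$paths$srna, degradomiR:::read_srna_library)
  trimmed <- lapply(reads, trim_adaptor, adaptor3 = cfg$adaptor3)
  tags <- remove_contaminants(filter_and_collapse(trimmed),
                              b$paths$contaminants)$tags
  disc <- discover_mirnas(tags, b$paths$catalog, b$paths$unigenes)
  expect_equal(nrow(disc$mirnas), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(contaminant_fraction = 1.2), "proportions")
  expect_error(synthetic_config(reads_per_library = 0), "positive")
  expect_error(generate_dataset(
    synthetic_config(n_unigenes = 5, n_known_mirnas = 10,
                     outdir = tempdir())), "too small")
})
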