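# Minimum free energy folding against the exhaustive-enumeration oracle
# and on hand-constructed sequences.

test_that("DP folding reaches the enumeration minimum on short RNAs", {
  set.seed(1)
  for (i in 1:150) {
    s <- random_rna(sample(10:12, 1))
    f <- fold_rna(s)
    expect_equal(f$mfe, oracle_fold_min(s), tolerance = 1e-9,
                 info = s)
    # the returned structure evaluates to the reported energy
    expect_equal(structure_energy(s, f$structure), f$mfe,
                 tolerance = 1e-9, info = s)
  }
})

test_that("constructed sequences fold as expected", {
  f <- fold_rna("GGGAAAACCC")
  expect_equal(f$structure, "(((....)))")
  expect_lt(f$mfe, 0)

  f0 <- fold_rna("AAAAAAAAAA")
  expect_equal(f0$structure, "..........")
  expect_equal(f0$mfe, 0)

  # a sequence joined to its reverse complement by a short loop folds
  # into a full stem
  s <- "GCGC"
  hp <- paste0(s, "GAAA", revcomp(s))
  f2 <- fold_rna(as_rna(hp))
  expect_equal(f2$pt[1:4], 12:9)
  expect_equal(f2$mfe, oracle_fold_min(as_rna(hp)), tolerance = 1e-9)
})

test_that("fold_rna rejects invalid input", {
  expect_error(fold_rna("ACGUX ACGU"), "non-RNA")
  expect_error(fold_rna("ACGUACGUT"), "at least 10")  # 9 nt
})

test_that("structure energies decompose as stacks, loops and multiloops", {
  p <- rna_energy_params()
  # two stacked CG pairs closing a 4-nt loop
  e <- structure_energy("GGAAAACC", "((....))")
  expect_equal(e, p$stack["GC", "GC"] + p$hairpin[4], tolerance = 1e-12)
  # unbalanced or malformed structures are rejected
  expect_error(structure_energy("GGAAAACC", "((....)"), "length")
  expect_error(structure_energy("GGAAAACC", "((....(("), "unbalanced")
})
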