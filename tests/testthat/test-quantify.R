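# RPM/FPKM arithmetic and the fold-change differential expression rule.

test_that("rpm and fpkm compute the standard normalisations", {
  expect_equal(rpm(100, 1e6), 100)
  expect_equal(rpm(0, 5e5), 0)
  expect_equal(rpm(25, 12.1e6), 25 / 12.1e6 * 1e6)
  expect_error(rpm(1, 0), "positive")

  expect_equal(fpkm(10, 1000, 1e6), 10)
  expect_equal(fpkm(0, 1000, 1e6), 0)
  expect_equal(fpkm(7, 2500, 4e6), 0.7)
  expect_error(fpkm(1, 0, 1e6), "length")
  expect_error(fpkm(1, 100, 0), ">= 1")
})

test_that("the |log2fc| > 1 rule flags differential features", {
  feats <- data.frame(id = c("m1", "m2", "m3"),
                      rpm.a = c(1, 2, 0), rpm.b = c(4, 3, 0))
  d <- differential(feats, c("a", "b"))
  expect_true(d$significant[1])            # ~2-fold in log2
  expect_false(d$significant[2])           # |log2(3.01/2.01)| < 1
  expect_equal(d$log2fc[3], 0)             # 0 vs 0
  expect_false(d$significant[3])
  expect_equal(d$direction[1], "higher")
  expect_error(differential(feats, c("a", "zz")), "unknown")
  expect_error(differential(feats, c("a", "b"), pseudocount = 0), "> 0")
})

test_that("log2 fold changes are antisymmetric and scale invariant", {
  grid <- expand.grid(a = c(0, 0.5, 1, 2, 3, 16.37, 1000),
                      b = c(0, 0.5, 1, 2, 3, 16.37, 1000))
  feats <- data.frame(id = seq_len(nrow(grid)),
                      rpm.x = grid$a, rpm.y = grid$b)
  fwd <- differential(feats, c("x", "y"))
  rev <- differential(feats, c("y", "x"))
  expect_equal(fwd$log2fc, -rev$log2fc)
  expect_equal(fwd$significant, rev$significant)
  # multiplying counts and totals by k leaves RPM (hence calls) unchanged
  k <- 7
  expect_equal(rpm(k * 25, k * 12.1e6), rpm(25, 12.1e6))
})
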