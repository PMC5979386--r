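# Hypergeometric enrichment against a whole-genome background.

test_that("hypergeometric tails match hand-derived values", {
  expect_equal(hypergeom_tail(0, 5, 3, 20), 1)
  expect_equal(hypergeom_tail(5, 5, 5, 20), 1 / choose(20, 5))
  expect_equal(hypergeom_tail(4, 4, 4, 4), 1)
  expect_error(hypergeom_tail(6, 5, 5, 20), "bounds")
  expect_error(hypergeom_tail(2, 5, 1, 20), "bounds")
})

test_that("tails agree with draw enumeration and are monotone in k", {
  for (N in c(6, 8, 10)) for (n in c(0, 2, N %/% 2)) for (K in c(1, N %/% 2)) {
    for (k in 0:min(n, K)) {
      expect_equal(hypergeom_tail(k, n, K, N), hyper_tail_enum(k, n, K, N),
                   tolerance = 1e-12,
                   info = sprintf("k=%d n=%d K=%d N=%d", k, n, K, N))
    }
    ks <- 0:min(n, K)
    if (length(ks) > 1) {
      p <- hypergeom_tail(ks, n, K, N)
      expect_true(all(diff(p) <= 1e-15))
    }
  }
})

test_that("enrichment ranks terms and respects the target set", {
  bg <- sprintf("g%03d", 1:100)
  ann <- data.frame(
    gene = c(bg[1:10], bg[1:40], bg[90:95]),
    go_id = c(rep("GO:1", 10), rep("GO:2", 40), rep("GO:3", 6)),
    namespace = "biological_process")
  targets <- bg[1:8]   # all carry GO:1 (K = 10) and GO:2 (K = 40)
  e <- enrich_go(targets, ann, bg)
  expect_false("GO:3" %in% e$term)                  # no target carries it
  expect_lt(e$p_value[e$term == "GO:1"], e$p_value[e$term == "GO:2"])
  expect_true(e$shown[e$term == "GO:1"])
  expect_true(all(e$k <= pmin(e$n, e$K)))
  expect_error(enrich_go(targets, ann, character(0)), "empty")
  expect_error(enrich_go(c(targets, "nope"), ann, bg), "subset")
})

test_that("random target sets are flagged at close to the nominal rate", {
  set.seed(42)
  bg <- sprintf("g%04d", 1:2000)
  ann <- do.call(rbind, lapply(1:20, function(t) data.frame(
    gene = sample(bg, 100), go_id = sprintf("GO:%07d", t),
    namespace = "biological_process")))
  fr <- replicate(200, {
    e <- enrich_go(sample(bg, 50), ann, bg)
    c(sum(e$p_value < 0.05), nrow(e))
  })
  frac <- sum(fr[1, ]) / sum(fr[2, ])
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})
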