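# Read cleaning: adaptor trimming, junk/length filtering, tag collapsing,
# contaminant removal and length distributions.

adaptor <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adaptor trimming returns the insert before the leftmost hit", {
  insert <- "ACGTACGTACGTACGTACGT"
  expect_equal(trim_adaptor(paste0(insert, adaptor), adaptor), insert)
  # read equal to the adaptor trims to an empty insert
  expect_equal(trim_adaptor(adaptor, adaptor), "")
  # untouched when there is no adaptor evidence
  expect_equal(trim_adaptor(insert, adaptor), insert)
  # empty read is rejected
  expect_true(is.na(trim_adaptor("", adaptor)))
  expect_error(trim_adaptor("ACGT", ""), "non-empty")
})

test_that("partial-adaptor trimming agrees with a brute-force scan", {
  set.seed(3)
  # oracle: smallest insert over full-adaptor hits and >=k-nt suffix hits
  oracle <- function(read, min_overlap) {
    L <- nchar(read)
    cand <- L
    p <- regexpr(adaptor, read, fixed = TRUE)
    if (p > 0) cand <- min(cand, p - 1L)
    for (k in seq(min_overlap, nchar(adaptor) - 1L))
      if (endsWith(read, substr(adaptor, 1, k))) cand <- min(cand, L - k)
    substr(read, 1, cand)
  }
  for (i in 1:200) {
    ins <- paste(sample(c("A", "C", "G", "T"), sample(10:30, 1),
                        replace = TRUE), collapse = "")
    k <- sample(0:nchar(adaptor), 1)
    read <- paste0(ins, substr(adaptor, 1, k))
    expect_identical(trim_adaptor(read, adaptor), oracle(read, 5L))
  }
  # a 4-nt adaptor suffix is below the default overlap and is kept
  read4 <- paste0("ACGTACGTACGTACGTAC", substr(adaptor, 1, 4))
  expect_identical(trim_adaptor(read4, adaptor), read4)
})

test_that("collapsing filters junk and out-of-range lengths", {
  mer21 <- paste0(strrep("ACGT", 5), "A")
  reads <- list(libA = c(rep(mer21, 3),            # collapsed to count 3
                         strrep("A", 21),          # homopolymer junk
                         paste0(substr(mer21, 1, 10), "N",
                                substr(mer21, 12, 21)),  # N junk
                         substr(strrep("GA", 10), 1, 17), # 17-mer: short
                         strrep("ACGT", 8)))       # 32-mer: too long
  tags <- filter_and_collapse(reads)
  expect_equal(nrow(tags), 1L)
  expect_equal(tags$count.libA, 3L)
  rem <- attr(tags, "removed")
  expect_equal(unname(rem["libA", c("junk", "too_short", "too_long")]),
               c(2L, 1L, 1L))
  # conservation: kept + removed = raw reads
  expect_equal(sum(tag_totals(tags)) + sum(rem), length(reads$libA))
  expect_error(filter_and_collapse(list(libB = strrep("A", 21))),
               "empty after cleaning")
})

test_that("RPM sums to one million per library and collapsing is idempotent", {
  set.seed(8)
  reads <- list(
    a = sample(replicate(40, paste(sample(c("A", "C", "G", "T"), 21,
                                          replace = TRUE), collapse = "")),
               500, replace = TRUE),
    b = sample(replicate(40, paste(sample(c("A", "C", "G", "T"), 24,
                                          replace = TRUE), collapse = "")),
               300, replace = TRUE))
  tags <- filter_and_collapse(reads)
  r <- tag_rpm(tags)
  expect_equal(unname(colSums(r)), c(1e6, 1e6), tolerance = 1e-9)
  expect_equal(unname(tag_totals(tags)), c(500, 300))
  # idempotence: re-cleaning the clean reads reproduces the tag set
  again <- filter_and_collapse(list(
    a = rep(tags$sequence, tag_counts(tags)[, "a"]),
    b = rep(tags$sequence, tag_counts(tags)[, "b"])))
  expect_equal(again$sequence, tags$sequence)
  expect_equal(tag_counts(again), tag_counts(tags))
})

test_that("contaminant removal is exact-substring on either strand", {
  set.seed(5)
  rrna <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  trna <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                collapse = "")
  win <- substr(rrna, 100, 120)                 # 21-nt rRNA window
  mis <- paste0("T", substr(win, 2, 21))
  if (substr(win, 1, 1) == "T") mis <- paste0("A", substr(win, 2, 21))
  rc <- revcomp(substr(trna, 10, 30))           # tRNA window, minus strand
  tags <- filter_and_collapse(list(x = c(win, mis, rc, strrep("ACGT", 5))))
  out <- remove_contaminants(tags, c(rRNA_1 = rrna, tRNA_1 = trna))
  expect_false(any(c(win, rc) %in% out$tags$sequence))
  expect_true(mis %in% out$tags$sequence)
  expect_equal(sort(out$report$class), c("rRNA", "tRNA"))
  expect_error(remove_contaminants(tags, "/no/such/file.fa"), "not found")
})

test_that("length distributions count unique tags and reads", {
  tags <- filter_and_collapse(list(L1 = rep(strrep("ACGTT", 5), 5)[1:5]))
  ld <- length_distribution(tags)
  expect_equal(ld$unique_tags[ld$length == 25], 1L)
  expect_equal(ld$reads.L1[ld$length == 25], 5)
  expect_equal(sum(ld$unique_tags), nrow(tags))
  expect_equal(sum(ld$reads_total), sum(tag_totals(tags)))
})
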