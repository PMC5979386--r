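# Independent oracles used to freeze expected values: exhaustive
# enumeration of secondary structures, brute-force category derivation,
# hypergeometric tail by draw enumeration, and a naive overlap scanner.

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# all non-crossing structures with WC+GU pairs and hairpin loops >= 3
enum_structs <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  pairable <- function(a, b)
    paste0(a, b) %in% c("CG", "GC", "GU", "UG", "AU", "UA")
  rec <- function(i, j) {
    if (i > j) return("")
    out <- paste0(".", rec(i + 1L, j))
    k <- i + 4L
    while (k <= j) {
      if (pairable(ch[i], ch[k])) {
        inner <- rec(i + 1L, k - 1L)
        rest <- rec(k + 1L, j)
        out <- c(out, as.vector(outer(inner, rest, function(a, b)
          paste0("(", a, ")", b))))
      }
      k <- k + 1L
    }
    out
  }
  rec(1L, length(ch))
}

# minimum energy over every enumerable structure
oracle_fold_min <- function(seq, params = rna_energy_params()) {
  sts <- enum_structs(seq)
  min(vapply(sts, function(db) structure_energy(seq, db, params),
             numeric(1)))
}

# direct restatement of the five category rules: more than one tag at the
# site equal to a unique maximum (0) / a tied maximum (1); more than one
# tag below the maximum but above (2) or at/below (3) the median of the
# nonzero positions; a single tag (4)
brute_categorize <- function(count, profile) {
  nz <- profile[profile > 1e-9]
  if (count <= 1 + 1e-9) return(4L)
  mx <- max(nz)
  if (abs(count - mx) < 1e-9) {
    if (sum(abs(nz - mx) < 1e-9) == 1L) return(0L) else return(1L)
  }
  med <- stats::median(nz)
  if (count > med + 1e-9) return(2L)
  3L
}

# P(X >= k) by enumerating every size-n draw from N genes of which the
# first K carry the term
hyper_tail_enum <- function(k, n, K, N) {
  if (n == 0L) return(if (k == 0L) 1 else 0)
  draws <- utils::combn(N, n)
  cnt <- colSums(draws <= K)
  mean(cnt >= k)
}

# naive scan of every ungapped offset for the longest fully-identical
# overlap between two sequences
brute_clean_overlap <- function(tag, mature) {
  a <- strsplit(tag, "")[[1]]; b <- strsplit(mature, "")[[1]]
  best <- 0L
  for (d in seq(-(length(a) - 1L), length(b) - 1L)) {
    p <- seq_along(a)
    q <- p + d
    keep <- q >= 1L & q <= length(b)
    if (!any(keep)) next
    if (all(a[keep] == b[q[keep]])) best <- max(best, sum(keep))
  }
  best
}
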