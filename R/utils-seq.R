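# Sequence utilities. On-disk alphabet is DNA (T); folding and duplex
# scoring work on RNA (U). Conversion happens at these boundaries only.

#' Convert between DNA and RNA alphabets
#'
#' @param x character vector of sequences.
#' @return `as_rna()` replaces T with U; `as_dna()` replaces U with T.
#'   Case is normalised to upper.
#' @export
as_rna <- function(x) chartr("tT", "uU", toupper(x))

#' @rdname as_rna
#' @export
as_dna <- function(x) chartr("uU", "tT", toupper(x))

#' Reverse complement of DNA/RNA strings
#'
#' @param x character vector (DNA or RNA; output alphabet follows input).
#' @export
revcomp <- function(x) {
  rna <- grepl("U", toupper(x), fixed = TRUE)
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(as_dna(x))))
  ifelse(rna, as_rna(out), out)
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, len, gc = NULL) {
  if (is.null(gc)) {
    vapply(rep(len, length.out = n), function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
      character(1))
  } else {
    vapply(rep(len, length.out = n), function(l) {
      g <- runif(1, gc[1], gc[2])
      p <- c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE, prob = p),
            collapse = "")
    }, character(1))
  }
}

shuffle_seq <- function(x) {
  vapply(strsplit(x, ""), function(ch)
    paste(sample(ch), collapse = ""), character(1))
}

# exact-substring index over a set of reference records (both strands):
# returns an environment mapping every window of the given widths to the
# class label of the first record containing it
window_index <- function(seqs, classes, widths) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  both <- c(seqs, revcomp(seqs))
  cls <- c(classes, classes)
  for (i in seq_along(both)) {
    s <- both[[i]]
    L <- nchar(s)
    for (w in widths) {
      if (w > L) next
      starts <- seq_len(L - w + 1L)
      wins <- substring(s, starts, starts + w - 1L)
      for (win in unique(wins))
        if (is.null(env[[win]])) env[[win]] <- cls[[i]]
    }
  }
  env
}
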