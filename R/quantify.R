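# Abundance normalisation and fold-change differential expression.

#' Reads per million
#'
#' @param count raw read count(s).
#' @param clean_total clean-read total of the library (denominator).
#' @return `count / clean_total * 1e6`.
#' @export
rpm <- function(count, clean_total) {
  if (any(clean_total <= 0)) stop("clean_total must be positive")
  count / clean_total * 1e6
}

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' @param fragments mapped fragment count(s).
#' @param length_nt transcript length in nt.
#' @param total_mapped total mapped fragments in the library.
#' @export
fpkm <- function(fragments, length_nt, total_mapped) {
  if (any(length_nt < 1)) stop("transcript length must be >= 1")
  if (any(total_mapped < 1)) stop("total_mapped must be >= 1")
  fragments / (length_nt / 1e3) / (total_mapped / 1e6)
}

#' Fold-change differential expression between two libraries
#'
#' Computes `log2((rpm_b + pseudocount) / (rpm_a + pseudocount))` per
#' feature and flags `|log2fc| > 1` as significant, the rule used when no
#' biological replicates are available. Direction is reported relative to
#' `lib_b` ("higher"/"lower" expression in `lib_b`).
#'
#' @param features data frame with a feature `id` column and `rpm.<lib>`
#'   columns.
#' @param pair character vector `c(lib_a, lib_b)`.
#' @param pseudocount RPM pseudocount for zero handling (default 0.01).
#' @return data frame: id, lib_a, lib_b, rpm_a, rpm_b, log2fc,
#'   significant, direction.
#' @export
differential <- function(features, pair, pseudocount = 0.01) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  ca <- paste0("rpm.", pair[1]); cb <- paste0("rpm.", pair[2])
  if (!all(c(ca, cb) %in% names(features)))
    stop("unknown library label in pair: ", paste(pair, collapse = ", "))
  id_col <- if ("id" %in% names(features)) features$id
            else features[[1]]
  a <- features[[ca]]; b <- features[[cb]]
  # difference of logs: antisymmetric under pair swap to the last bit
  lfc <- log2(b + pseudocount) - log2(a + pseudocount)
  data.frame(id = id_col, lib_a = pair[1], lib_b = pair[2],
             rpm_a = a, rpm_b = b, log2fc = lfc,
             significant = abs(lfc) > 1,
             direction = ifelse(lfc > 0, "higher", "lower"),
             stringsAsFactors = FALSE)
}
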