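# Hypergeometric GO term enrichment against a whole-genome background.

#' Upper tail of the hypergeometric distribution
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn from a background
#' of `N` genes of which `K` carry the term.
#'
#' @param k observed annotated genes in the draw.
#' @param n draw size (annotated target genes).
#' @param K background genes carrying the term.
#' @param N background size.
#' @export
hypergeom_tail <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0))
    stop("all arguments must be non-negative")
  if (any(k > n) || any(n > N) || any(k > K) || any(K > N))
    stop("bounds violated: need k <= n <= N and k <= K <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO term enrichment of a miRNA target gene set
#'
#' One-sided hypergeometric test per term annotating at least one target.
#' The whole background (annotated or not) is N and, symmetrically, the
#' whole target set (annotated or not) is the draw size n, which keeps
#' the test calibrated under random labelling; `n_annotated` reports how
#' many targets carry any annotation. No multiple-testing correction is
#' applied to the primary p-value; a Benjamini-Hochberg column (`p_bh`)
#' is emitted additionally as an extension.
#'
#' @param targets character vector of target gene ids (must be a subset
#'   of `background`).
#' @param annotation data frame with columns `gene`, `go_id`, `namespace`.
#' @param background character vector of all background gene ids.
#' @param alpha display threshold; results with `p_value < alpha` are
#'   flagged `shown` (default 0.05).
#' @return data frame sorted by namespace then p-value: term, namespace,
#'   k, n, K, N, p_value, p_bh, shown.
#' @export
enrich_go <- function(targets, annotation, background, alpha = 0.05) {
  background <- unique(background)
  targets <- unique(targets)
  if (!length(background)) stop("empty background set")
  if (!all(targets %in% background))
    stop("targets must be a subset of the background")
  annotation <- annotation[annotation$gene %in% background, , drop = FALSE]
  N <- length(background)
  # the whole target set is the draw; unannotated genes stay in both the
  # draw and the background so that the test is calibrated against the
  # whole-genome null
  n <- length(targets)
  n_annotated <- length(intersect(targets, annotation$gene))
  terms <- unique(annotation[annotation$gene %in% targets,
                             c("go_id", "namespace")])
  if (!nrow(terms))
    return(data.frame(term = character(0), namespace = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p_value = numeric(0),
                      p_bh = numeric(0), shown = logical(0)))
  res <- do.call(rbind, lapply(seq_len(nrow(terms)), function(i) {
    tg <- unique(annotation$gene[annotation$go_id == terms$go_id[i]])
    data.frame(term = terms$go_id[i], namespace = terms$namespace[i],
               k = length(intersect(tg, targets)), n = n,
               K = length(tg), N = N, stringsAsFactors = FALSE)
  }))
  res$n_annotated <- n_annotated
  res$p_value <- hypergeom_tail(res$k, res$n, res$K, res$N)
  res$p_bh <- p.adjust(res$p_value, method = "BH")
  res$shown <- res$p_value < alpha
  res <- res[order(res$namespace, res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}
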