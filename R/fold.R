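# RNA secondary structure: minimum free energy folding under a simplified
# nearest-neighbor model (Watson-Crick + G:U pairs, stacking energies,
# tabulated loop initiations with logarithmic extrapolation, affine
# multiloops; no dangling ends or terminal-AU terms).

PAIR_LEVELS <- c("CG", "GC", "GU", "UG", "AU", "UA")

#' Energy parameters for the built-in RNA folding model
#'
#' Returns the parameter set used by [fold_rna()] and [structure_energy()]:
#' a 6x6 stacking matrix over the pair types CG, GC, GU, UG, AU, UA
#' (kcal/mol at 37 degrees C, approximate Turner-magnitude values), loop
#' initiation energies by size for hairpin, bulge and internal loops
#' (tabulated for small sizes, extrapolated as `E(max) + 1.75 RT log(l/max)`
#' beyond), an asymmetry penalty for internal loops, and affine multiloop
#' coefficients.
#'
#' @param max_size largest loop size for which penalties are precomputed;
#'   must be at least the length of any sequence to be folded.
#' @return a list with components `stack`, `hairpin`, `bulge`, `internal`,
#'   `asym_coef`, `asym_max`, `ml_close`, `ml_branch`, `ml_unpaired`,
#'   `min_hairpin`, `max_loop`.
#' @export
rna_energy_params <- function(max_size = 800L) {
  lxc <- 1.75 * 0.616  # 1.75 * RT at 37C
  stack <- matrix(c(
    # inner:  CG    GC    GU    UG    AU    UA        closing:
    -3.3, -3.4, -2.1, -1.4, -2.1, -2.4,  # CG
    -2.4, -3.3, -2.5, -2.1, -2.2, -2.1,  # GC
    -1.4, -2.5, -0.5, -0.4, -1.3, -1.0,  # GU
    -2.1, -2.1, -0.4, -0.5, -1.0, -1.3,  # UG
    -2.1, -2.4, -1.4, -1.0, -0.9, -1.1,  # AU
    -2.4, -2.1, -1.0, -1.3, -1.3, -0.9   # UA
  ), nrow = 6, byrow = TRUE, dimnames = list(PAIR_LEVELS, PAIR_LEVELS))

  sz <- seq_len(max_size)
  hairpin <- rep(Inf, max_size)
  hp_tab <- c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4)  # sizes 3..9
  hairpin[3:9] <- hp_tab
  hairpin[sz > 9] <- hp_tab[7] + lxc * log(sz[sz > 9] / 9)

  bulge <- rep(Inf, max_size)
  bu_tab <- c(3.8, 2.8, 3.2, 3.6, 4.0, 4.4)  # sizes 1..6
  bulge[1:6] <- bu_tab
  bulge[sz > 6] <- bu_tab[6] + lxc * log(sz[sz > 6] / 6)

  internal <- rep(Inf, max_size)
  in_tab <- c(1.5, 1.6, 1.7, 2.0, 2.2)  # sizes 2..6
  internal[2:6] <- in_tab
  internal[sz > 6] <- in_tab[5] + lxc * log(sz[sz > 6] / 6)

  list(stack = stack, hairpin = hairpin, bulge = bulge, internal = internal,
       asym_coef = 0.5, asym_max = 3.0,
       ml_close = 3.4, ml_branch = 0.4, ml_unpaired = 0.1,
       min_hairpin = 3L, max_loop = 30L)
}

pair_type <- function(a, b) {
  key <- paste0(a, b)
  match(key, PAIR_LEVELS)  # NA = not pairable
}

seq_to_int <- function(x) {
  v <- match(strsplit(x, "")[[1]], c("A", "C", "G", "U")) - 1L
  if (anyNA(v)) stop("sequence contains non-RNA characters (need A/C/G/U)")
  v
}

pt_to_db <- function(pt) {
  db <- rep(".", length(pt))
  db[pt > seq_along(pt)] <- "("
  db[pt > 0 & pt < seq_along(pt)] <- ")"
  paste(db, collapse = "")
}

db_to_pt <- function(db) {
  ch <- strsplit(db, "")[[1]]
  pt <- integer(length(ch))
  stk <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stk <- c(stk, i)
    else if (ch[i] == ")") {
      if (!length(stk)) stop("unbalanced structure string")
      j <- stk[length(stk)]
      stk <- stk[-length(stk)]
      pt[i] <- j
      pt[j] <- i
    } else if (ch[i] != ".") stop("structure may contain only '(', ')', '.'")
  }
  if (length(stk)) stop("unbalanced structure string")
  pt
}

#' Fold an RNA sequence to its minimum free energy structure
#'
#' Computes the minimum free energy secondary structure under the built-in
#' simplified nearest-neighbor model (see [rna_energy_params()]), by exact
#' dynamic programming with internal/bulge loops capped at
#' `params$max_loop` unpaired bases. Only non-crossing structures with
#' Watson-Crick and G:U pairs and hairpin loops of at least 3 nt are
#' considered.
#'
#' @param sequence RNA string (A/C/G/U), length at least 10.
#' @param params energy parameter set from [rna_energy_params()].
#' @return list with `structure` (dot-bracket string), `mfe` (kcal/mol)
#'   and `pt` (integer pairing-partner table, 0 = unpaired).
#' @examples
#' fold_rna("GGGAAAACCC")
#' @export
fold_rna <- function(sequence, params = rna_energy_params()) {
  sequence <- as_rna(sequence)
  n <- nchar(sequence)
  if (n < 10) stop("fold_rna() requires a sequence of at least 10 nt")
  if (n > length(params$hairpin))
    params <- rna_energy_params(max_size = n)
  res <- .fold_mfe_cpp(seq_to_int(sequence), params)
  list(structure = pt_to_db(res$pt), mfe = res$energy, pt = res$pt)
}

#' Free energy of a given RNA secondary structure
#'
#' Evaluates the energy of an explicit dot-bracket structure under the same
#' model as [fold_rna()], by loop decomposition: stacked pairs score the
#' stacking table, loops score their initiation penalties, multiloops score
#' the affine multiloop term, and external-loop bases are free. Used as the
#' scoring half of the exhaustive-enumeration folding oracle.
#'
#' @param sequence RNA string.
#' @param structure dot-bracket string of the same length.
#' @param params energy parameter set.
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(sequence, structure,
                             params = rna_energy_params()) {
  sequence <- as_rna(sequence)
  ch <- strsplit(sequence, "")[[1]]
  if (nchar(structure) != length(ch))
    stop("sequence and structure lengths differ")
  pt <- db_to_pt(structure)
  n <- length(pt)
  if (n > length(params$hairpin)) params <- rna_energy_params(max_size = n)

  loop_e <- function(n1, n2) {
    sz <- n1 + n2
    if (n1 == 0L || n2 == 0L) return(params$bulge[sz])
    params$internal[sz] +
      min(params$asym_max, params$asym_coef * abs(n1 - n2))
  }

  energy_of_pair <- function(i, j) {
    p <- pair_type(ch[i], ch[j])
    if (is.na(p)) stop("structure pairs non-complementary bases ",
                       ch[i], "-", ch[j])
    # direct children and unpaired count inside (i, j)
    kids <- list()
    unpaired <- 0L
    k <- i + 1L
    while (k < j) {
      if (pt[k] > k) {
        kids[[length(kids) + 1L]] <- c(k, pt[k])
        k <- pt[k] + 1L
      } else {
        unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    e <- if (length(kids) == 0L) {
      params$hairpin[j - i - 1L]
    } else if (length(kids) == 1L) {
      k1 <- kids[[1]][1]; l1 <- kids[[1]][2]
      n1 <- k1 - i - 1L; n2 <- j - l1 - 1L
      if (n1 == 0L && n2 == 0L) {
        q <- pair_type(ch[k1], ch[l1])
        params$stack[p, q]
      } else loop_e(n1, n2)
    } else {
      params$ml_close + params$ml_branch * (length(kids) + 1L) +
        params$ml_unpaired * unpaired
    }
    e + sum(vapply(kids, function(kl) energy_of_pair(kl[1], kl[2]),
                   numeric(1)))
  }

  total <- 0
  k <- 1L
  while (k <= n) {
    if (pt[k] > k) {
      total <- total + energy_of_pair(k, pt[k])
      k <- pt[k] + 1L
    } else k <- k + 1L
  }
  total
}
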