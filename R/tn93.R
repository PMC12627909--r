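# Tamura-Nei (1993) distance with pairwise deletion of gap/ambiguous sites.
#
# Sites where either sequence holds a non-ACGT symbol are excluded. Base
# frequencies are averaged over both sequences at the compared sites. The
# distance uses the three-term log formula with P1 (A<->G transitions),
# P2 (C<->T transitions) and Q (transversions); saturated pairs (any log
# argument <= 0) are flagged undefined rather than fabricated.

# Evaluate the TN93 three-term formula from observed proportions and
# averaged frequencies. Returns NA when undefined.
#' @noRd
tn93_formula <- function(P1, P2, Q, gA, gC, gG, gT) {
  gR <- gA + gG
  gY <- gC + gT
  if (gR <= 0 || gY <= 0) {
    return(if (P1 == 0 && P2 == 0 && Q == 0) 0 else NA_real_)
  }
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w3 <- 1 - Q / (2 * gR * gY)
  t1 <- if (k1 > 0) {
    w1 <- 1 - P1 / k1 - Q / (2 * gR)
    if (w1 <= 0) return(NA_real_)
    -k1 * log(w1)
  } else if (P1 > 0) return(NA_real_) else 0
  t2 <- if (k2 > 0) {
    w2 <- 1 - P2 / k2 - Q / (2 * gY)
    if (w2 <= 0) return(NA_real_)
    -k2 * log(w2)
  } else if (P2 > 0) return(NA_real_) else 0
  if (w3 <= 0) return(NA_real_)
  t1 + t2 - k3 * log(w3)
}

#' Pairwise TN93 distance between two aligned sequences
#'
#' Computes the Tamura-Nei (1993) distance, which allows distinct rates for
#' the two transition types (A<->G, C<->T) and for transversions, under
#' unequal base frequencies. Sites with a gap or ambiguity code in either
#' sequence are excluded (pairwise deletion); base frequencies are averaged
#' over both sequences at the remaining sites. Saturated pairs, for which
#' a logarithm argument is non-positive, are returned with `d = NA` and
#' `undefined = TRUE` rather than raising an error; so is the degenerate
#' case of zero comparable sites.
#'
#' @param a,b Aligned sequences of equal length: single strings or
#'   character vectors of residues (case-insensitive, IUPAC alphabet plus
#'   gap).
#'
#' @return An object of class `tn93_stats`: a list with base frequencies
#'   `gA`, `gC`, `gG`, `gT`, transition proportions `P1` (A<->G) and `P2`
#'   (C<->T), transversion proportion `Q`, compared-site count `n_sites`,
#'   distance `d` (substitutions/site) and logical `undefined`.
#' @export
#' @examples
#' tn93("ACGTACGT", "ACGTACGA")
tn93 <- function(a, b) {
  av <- if (length(a) == 1L) strsplit(toupper(a), "", fixed = TRUE)[[1]] else toupper(a)
  bv <- if (length(b) == 1L) strsplit(toupper(b), "", fixed = TRUE)[[1]] else toupper(b)
  if (length(av) != length(bv)) {
    stop("sequences must have equal aligned lengths", call. = FALSE)
  }
  ok <- av %in% DNA_BASES & bv %in% DNA_BASES
  n <- sum(ok)
  if (n == 0L) {
    return(structure(list(gA = NA_real_, gC = NA_real_, gG = NA_real_,
                          gT = NA_real_, P1 = NA_real_, P2 = NA_real_,
                          Q = NA_real_, n_sites = 0L, d = NA_real_,
                          undefined = TRUE),
                     class = "tn93_stats"))
  }
  av <- av[ok]; bv <- bv[ok]
  cnt <- (tabulate(match(av, DNA_BASES), 4L) +
          tabulate(match(bv, DNA_BASES), 4L)) / (2 * n)
  diff <- av != bv
  pair_ag <- diff & ((av == "A" & bv == "G") | (av == "G" & bv == "A"))
  pair_ct <- diff & ((av == "C" & bv == "T") | (av == "T" & bv == "C"))
  P1 <- sum(pair_ag) / n
  P2 <- sum(pair_ct) / n
  Q <- sum(diff & !pair_ag & !pair_ct) / n
  d <- tn93_formula(P1, P2, Q, cnt[1], cnt[2], cnt[3], cnt[4])
  structure(list(gA = cnt[1], gC = cnt[2], gG = cnt[3], gT = cnt[4],
                 P1 = P1, P2 = P2, Q = Q, n_sites = n, d = d,
                 undefined = is.na(d)),
            class = "tn93_stats")
}

#' @export
print.tn93_stats <- function(x, ...) {
  cat(sprintf("TN93: d = %s over %d sites (P1 = %.4g, P2 = %.4g, Q = %.4g)%s\n",
              if (is.na(x$d)) "undefined" else format(x$d, digits = 6),
              x$n_sites, x$P1, x$P2, x$Q,
              if (x$undefined) " [undefined]" else ""))
  invisible(x)
}

#' Pairwise distance matrix for an alignment
#'
#' All pairwise distances under the TN93 model or the raw proportion of
#' differing sites (p-distance), with pairwise deletion of non-ACGT sites.
#' The computation is vectorized through indicator-matrix cross-products,
#' so each cell equals exactly what [tn93()] returns for that pair.
#' Undefined (saturated or zero-overlap) pairs are recorded as `NA`,
#' never as zero.
#'
#' @param alignment Character matrix (rows = sequences), named character
#'   vector of aligned strings, or anything [tn93()] accepts pairwise.
#' @param estimator `"tn93"` or `"p"` (raw p-distance).
#'
#' @return Symmetric numeric matrix with zero diagonal and the sequence
#'   ids as dimnames.
#' @export
distance_matrix <- function(alignment, estimator = c("tn93", "p")) {
  estimator <- match.arg(estimator)
  m <- as_alignment_matrix(alignment)
  if (nrow(m) < 2L) stop("need at least 2 sequences", call. = FALSE)

  ind <- lapply(DNA_BASES, function(b) (m == b) * 1)
  names(ind) <- DNA_BASES
  V <- ind$A + ind$C + ind$G + ind$T
  N <- tcrossprod(V)                      # shared valid sites
  AG <- tcrossprod(ind$A, ind$G)
  CT <- tcrossprod(ind$C, ind$T)
  R <- ind$A + ind$G
  Y <- ind$C + ind$T
  RY <- tcrossprod(R, Y)
  p1 <- AG + t(AG)
  p2 <- CT + t(CT)
  qq <- RY + t(RY)

  Nsafe <- ifelse(N > 0, N, NA_real_)
  if (estimator == "p") {
    D <- (p1 + p2 + qq) / Nsafe
    diag(D) <- 0
    dimnames(D) <- list(rownames(m), rownames(m))
    return(D)
  }

  # per-pair base counts over shared valid sites, averaged over both seqs
  g <- lapply(ind, function(Mb) {
    cb <- tcrossprod(Mb, V)
    (cb + t(cb)) / (2 * Nsafe)
  })
  P1 <- p1 / Nsafe; P2 <- p2 / Nsafe; Q <- qq / Nsafe

  n <- nrow(m)
  D <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (is.na(N[i, j]) || N[i, j] == 0) next
      D[i, j] <- D[j, i] <- tn93_formula(P1[i, j], P2[i, j], Q[i, j],
                                         g$A[i, j], g$C[i, j],
                                         g$G[i, j], g$T[i, j])
    }
  }
  diag(D) <- 0
  D
}
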