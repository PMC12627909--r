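# Independent oracles used to validate the package's estimators. These are
# deliberately coded from scratch (different algorithms and algebraic
# arrangements than the implementation) so agreement is evidence, not
# tautology.

# Tamura-Nei (1993) distance, recoded directly from the published formula.
tn93_oracle <- function(a, b) {
  A <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  B <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  keep <- A %in% c("A", "C", "G", "T") & B %in% c("A", "C", "G", "T")
  A <- A[keep]; B <- B[keep]
  n <- length(A)
  if (n == 0L) return(NA_real_)
  lv <- c("A", "C", "G", "T")
  fr <- (table(factor(A, lv)) + table(factor(B, lv))) / (2 * n)
  gA <- fr[["A"]]; gC <- fr[["C"]]; gG <- fr[["G"]]; gT <- fr[["T"]]
  P1 <- sum((A == "A" & B == "G") | (A == "G" & B == "A")) / n
  P2 <- sum((A == "C" & B == "T") | (A == "T" & B == "C")) / n
  Q <- sum(A != B) / n - P1 - P2
  gR <- gA + gG; gY <- gC + gT
  if (gA * gG == 0 && P1 > 0) return(NA_real_)
  if (gC * gT == 0 && P2 > 0) return(NA_real_)
  a1 <- if (gA * gG > 0) 1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR) else 1
  a2 <- if (gC * gT > 0) 1 - gY * P2 / (2 * gC * gT) - Q / (2 * gY) else 1
  b3 <- 1 - Q / (2 * gR * gY)
  if (a1 <= 0 || a2 <= 0 || b3 <= 0) return(NA_real_)
  t1 <- if (gA * gG > 0) -(2 * gA * gG / gR) * log(a1) else 0
  t2 <- if (gC * gT > 0) -(2 * gC * gT / gY) * log(a2) else 0
  t3 <- -2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY) * log(b3)
  t1 + t2 + t3
}

# Patristic distances by explicit parent-climbing path enumeration.
patristic_oracle <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  parent <- integer(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- numeric(nn)
  elen[tree$edge[, 2]] <- tree$edge.length
  path_up <- function(i) {
    out <- i
    while (parent[i] != 0L) {
      i <- parent[i]
      out <- c(out, i)
    }
    out
  }
  d <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt - 1L)) {
    pi <- path_up(i)
    for (j in (i + 1L):nt) {
      pj <- path_up(j)
      lca <- pi[pi %in% pj][1L]
      di <- sum(elen[pi[seq_len(which(pi == lca) - 1L)]])
      dj <- sum(elen[pj[seq_len(which(pj == lca) - 1L)]])
      d[i, j] <- d[j, i] <- di + dj
    }
  }
  d
}

# Jukes-Cantor distance from a raw proportion of differing sites.
jc69_from_p <- function(p) -0.75 * log(1 - 4 * p / 3)

random_dna <- function(n, gaps = FALSE) {
  alpha <- if (gaps) c("A", "C", "G", "T", "-", "N") else c("A", "C", "G", "T")
  prob <- if (gaps) c(0.23, 0.22, 0.22, 0.23, 0.05, 0.05) else rep(0.25, 4)
  paste(sample(alpha, n, replace = TRUE, prob = prob), collapse = "")
}

# A pair of correlated random sequences (shared fraction `keep`).
random_pair <- function(n, keep = 0.85, gaps = TRUE) {
  a <- strsplit(random_dna(n, gaps), "", fixed = TRUE)[[1]]
  b <- strsplit(random_dna(n, gaps), "", fixed = TRUE)[[1]]
  same <- runif(n) < keep
  b[same] <- a[same]
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}
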