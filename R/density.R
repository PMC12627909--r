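#' Count SNPs in a pileup at a minimum allele frequency
#'
#' A position is a SNP when its counted depth (A+C+G+T) reaches
#' `min_depth` and the most frequent non-reference base has a frequency of
#' at least `f` among counted bases. This emulates the site filter of
#' pooled-sample SNP callers: `f = 0.2` is the usual default and `f = 0.1`
#' the sensitive setting that keeps minor pool components near 10%
#' frequency visible.
#'
#' @param pile Pileup tibble from [pileup()].
#' @param f Minimum allele frequency, in (0, 0.5].
#' @param min_depth Minimum counted depth per position (>= 1).
#'
#' @return Integer SNP count.
#' @export
count_snps <- function(pile, f = 0.2, min_depth = 10L) {
  if (!is.numeric(f) || f <= 0 || f > 0.5) {
    stop("'f' must be in (0, 0.5]", call. = FALSE)
  }
  if (min_depth < 1L) stop("'min_depth' must be >= 1", call. = FALSE)
  if (nrow(pile) == 0L) return(0L)
  cnt <- as.matrix(pile[, DNA_BASES])
  counted <- rowSums(cnt)
  ref_ix <- match(pile$ref_base, DNA_BASES)
  alt <- cnt
  ok_ref <- !is.na(ref_ix)
  alt[cbind(which(ok_ref), ref_ix[ok_ref])] <- 0L
  top_alt <- apply(alt, 1L, max)
  sum(counted >= min_depth & top_alt >= f * counted)
}

#' SNP density
#'
#' The number of SNPs divided by the reference length: the homogeneity
#' statistic for pooled samples. A pool of one species measured against
#' its own species' plastome shows near-zero density; against another
#' species' plastome, density approaches the interspecific divergence.
#'
#' @param snp_count Number of SNPs (>= 0).
#' @param ref_length Reference length in bp (> 0).
#' @return `snp_count / ref_length`.
#' @export
snp_density <- function(snp_count, ref_length) {
  if (!is.numeric(ref_length) || ref_length <= 0) {
    stop("'ref_length' must be positive", call. = FALSE)
  }
  if (snp_count < 0) stop("'snp_count' must be >= 0", call. = FALSE)
  snp_count / ref_length
}

#' Build a per-reference density report for one pool
#'
#' Convenience wrapper: maps the pool's reads against a candidate
#' reference, piles up, counts SNPs and returns one density-report row.
#'
#' @param reads Pool read tibble.
#' @param reference Candidate reference sequence (named string; the name is
#'   the reference id).
#' @param pool_id Pool identifier.
#' @param f Minimum allele frequency (see [count_snps()]).
#' @param min_depth Minimum counted depth.
#' @param k,max_mismatch_frac Mapper parameters (see [naive_map()]).
#'
#' @return One-row tibble: `pool_id`, `reference`, `f`, `min_depth`,
#'   `snp_count`, `ref_length`, `density`.
#' @export
density_report <- function(reads, reference, pool_id = NULL, f = 0.2,
                           min_depth = 10L, k = 21L, max_mismatch_frac = 0.1) {
  pool_id <- pool_id %||% attr(reads, "origin") %||% "pool"
  ref_id <- names(reference)[1] %||% "reference"
  aln <- naive_map(reads, reference, k = k, max_mismatch_frac = max_mismatch_frac)
  pile <- pileup(aln, reference)
  nsnp <- count_snps(pile, f = f, min_depth = min_depth)
  L <- nchar(toupper(unname(reference[1])))
  tibble::tibble(pool_id = pool_id, reference = ref_id, f = f,
                 min_depth = as.integer(min_depth),
                 snp_count = as.integer(nsnp), ref_length = L,
                 density = snp_density(nsnp, L))
}

#' Classify a pool from its per-reference density reports
#'
#' The best candidate reference is the one with the lowest SNP density.
#' The pool is called homogeneous (a single species) when either a single
#' candidate was tested and its density is below `intra_ceiling`, or the
#' best density times `gap_ratio` does not exceed the second-lowest
#' density - i.e. one reference is markedly closer than every other,
#' mirroring the visual gap between intra- and interspecific control
#' mixes.
#'
#' @param reports Density-report tibble for one pool across candidate
#'   references (equal `pool_id` and `f`).
#' @param gap_ratio Required ratio between second-lowest and lowest
#'   density (default 3).
#' @param intra_ceiling Absolute density ceiling used when only one
#'   candidate reference is available (default 0.002).
#'
#' @return A list of class `pool_verdict`: `pool_id`, `best_reference`,
#'   `homogeneous`, `margin` (second-lowest minus lowest density, 0 for a
#'   single candidate) and `densities` (the input reports).
#' @export
classify_pool <- function(reports, gap_ratio = 3, intra_ceiling = 0.002) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1L)
  if (length(unique(reports$f)) != 1L) {
    stop("inconsistent 'f' across density reports", call. = FALSE)
  }
  if (length(unique(reports$pool_id)) != 1L) {
    stop("density reports span multiple pools", call. = FALSE)
  }
  ord <- order(reports$density)
  best <- reports[ord[1L], ]
  if (nrow(reports) == 1L) {
    homog <- best$density <= intra_ceiling
    margin <- 0
  } else {
    second <- reports$density[ord[2L]]
    homog <- best$density * gap_ratio <= second
    margin <- second - best$density
  }
  structure(list(pool_id = best$pool_id,
                 best_reference = best$reference,
                 homogeneous = homog,
                 margin = margin,
                 densities = reports),
            class = "pool_verdict")
}

#' @export
print.pool_verdict <- function(x, ...) {
  cat(sprintf("Pool %s: best reference %s (%s, margin %.3g)\n",
              x$pool_id, x$best_reference,
              if (x$homogeneous) "homogeneous" else "NOT homogeneous",
              x$margin))
  invisible(x)
}

#' Full factorial density table for control pools
#'
#' Evaluates every (pool, candidate reference, allele-frequency filter)
#' combination, producing the long table behind control-mix density plots:
#' intraspecific control pools show near-zero density against their own
#' species' reference, while mixed-species pools show elevated density
#' against every reference.
#'
#' @param pools Named list of pool read tibbles.
#' @param references Named character vector of candidate reference
#'   sequences.
#' @param f_values Allele-frequency filters to apply (default `c(0.2, 0.1)`).
#' @param min_depth,k,max_mismatch_frac See [count_snps()] / [naive_map()].
#'
#' @return Density-report tibble with one row per (pool, reference, f).
#'   Mapping and pileup are computed once per (pool, reference) and reused
#'   across `f` values.
#' @export
control_panel <- function(pools, references, f_values = c(0.2, 0.1),
                          min_depth = 10L, k = 21L, max_mismatch_frac = 0.1) {
  if (!length(pools)) {
    return(tibble::tibble(pool_id = character(), reference = character(),
                          f = numeric(), min_depth = integer(),
                          snp_count = integer(), ref_length = integer(),
                          density = numeric()))
  }
  stopifnot(!is.null(names(references)))
  out <- list()
  for (p in names(pools)) {
    for (r in names(references)) {
      ref <- references[r]
      aln <- naive_map(pools[[p]], ref, k = k,
                       max_mismatch_frac = max_mismatch_frac)
      pile <- pileup(aln, ref)
      L <- nchar(unname(ref))
      for (f in f_values) {
        nsnp <- count_snps(pile, f = f, min_depth = min_depth)
        out[[length(out) + 1L]] <- tibble::tibble(
          pool_id = p, reference = r, f = f,
          min_depth = as.integer(min_depth),
          snp_count = as.integer(nsnp), ref_length = L,
          density = snp_density(nsnp, L))
      }
    }
  }
  dplyr::bind_rows(out)
}
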