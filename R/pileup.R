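#' Per-position base counts from ungapped alignments
#'
#' Tabulates A/C/G/T counts and depth at every reference position covered
#' by at least one read. Non-ACGT read bases contribute to depth but not to
#' the base counts. Coordinates are 1-based.
#'
#' @param alignments Placement tibble from [naive_map()] or
#'   [read_sam_alignments()] (columns `pos`, `seq`).
#' @param reference Reference sequence (single string).
#'
#' @return A tibble of covered positions: `position`, `ref_base`, `depth`,
#'   `A`, `C`, `G`, `T`.
#' @export
pileup <- function(alignments, reference) {
  stopifnot(is.data.frame(alignments), all(c("pos", "seq") %in% names(alignments)))
  reference <- toupper(unname(reference[1]))
  L <- nchar(reference)
  if (nrow(alignments) == 0L) {
    return(tibble::tibble(position = integer(), ref_base = character(),
                          depth = integer(), A = integer(), C = integer(),
                          G = integer(), T = integer()))
  }
  rl <- nchar(alignments$seq)
  if (any(alignments$pos < 1L) || any(alignments$pos + rl - 1L > L)) {
    stop("alignment extends beyond the reference", call. = FALSE)
  }
  n <- nrow(alignments)
  chars <- strsplit(toupper(alignments$seq), "", fixed = TRUE)
  pos_all <- unlist(lapply(seq_len(n), function(i) {
    alignments$pos[i] + seq_len(rl[i]) - 1L
  }), use.names = FALSE)
  base_all <- unlist(chars, use.names = FALSE)
  base_ix <- match(base_all, DNA_BASES)         # NA for non-ACGT

  depth <- tabulate(pos_all, nbins = L)
  cnt <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))
  okb <- !is.na(base_ix)
  lin <- (pos_all[okb] - 1L) * 4L + base_ix[okb]
  tab <- tabulate(lin, nbins = 4L * L)
  cnt[] <- tab

  covered <- which(depth > 0L)
  tibble::tibble(
    position = covered,
    ref_base = substring(reference, covered, covered),
    depth = depth[covered],
    A = cnt[1L, covered], C = cnt[2L, covered],
    G = cnt[3L, covered], T = cnt[4L, covered]
  )
}

#' Read mapped alignments from a SAM file
#'
#' Ingests a SAM text file (converted to BAM internally via Rsamtools) and
#' returns ungapped placements compatible with [pileup()]. Only primary,
#' mapped records passing the mapping-quality threshold are kept.
#' Soft-clipped bases are removed and hard clips ignored; records whose
#' CIGAR contains indel or skip operations are rejected, since the
#' pool-density model is substitution-only.
#'
#' @param sam_path Path to a SAM file (with header).
#' @param min_mapq Minimum mapping quality (default 0).
#'
#' @return A tibble: `read_id`, `pos` (1-based leftmost reference
#'   position), `seq` (clipped read sequence).
#' @export
read_sam_alignments <- function(sam_path, min_mapq = 0) {
  if (!file.exists(sam_path)) stop("no such file: ", sam_path, call. = FALSE)
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  par <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "pos", "mapq", "cigar", "seq")
  )
  rec <- Rsamtools::scanBam(bam, param = par)[[1]]
  keep <- !is.na(rec$pos) & (is.na(rec$mapq) | rec$mapq >= min_mapq)
  qname <- rec$qname[keep]
  pos <- rec$pos[keep]
  cig <- rec$cigar[keep]
  seqs <- as.character(rec$seq)[keep]

  out <- lapply(seq_along(qname), function(i) {
    ops <- parse_cigar(cig[i])
    bad <- setdiff(ops$op, c("M", "=", "X", "S", "H"))
    if (length(bad)) {
      stop("unsupported CIGAR op(s) ", paste(bad, collapse = ","),
           " in read ", qname[i], " (ungapped model)", call. = FALSE)
    }
    s <- seqs[i]
    # drop leading/trailing soft clips from the stored sequence
    lead <- if (ops$op[1] == "S") ops$len[1] else 0L
    lastq <- length(ops$op)
    trail <- if (ops$op[lastq] == "S") ops$len[lastq] else 0L
    core <- substring(s, lead + 1L, nchar(s) - trail)
    tibble::tibble(read_id = qname[i], pos = pos[i], seq = core)
  })
  dplyr::bind_rows(out)
}

#' @noRd
parse_cigar <- function(cigar) {
  m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(m) || paste(m, collapse = "") != cigar) {
    stop("malformed CIGAR: ", cigar, call. = FALSE)
  }
  list(len = as.integer(sub("[MIDNSHP=X]$", "", m)),
       op = sub("^\\d+", "", m))
}
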