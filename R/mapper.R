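# Seed-and-vote ungapped read placement for substitution-only data.
#
# Every k-mer of the reference is indexed; seeds sampled along each read
# vote for the read start position they imply. The winning position (no
# tie) is kept if the full ungapped alignment has at most
# max_mismatch_frac * read_length mismatches. Reads with no seed hit,
# tied votes, overhanging placements or too many mismatches are discarded.
# Reference k-mers occurring more than once are treated as repeats and do
# not vote.

#' Map reads to a reference by k-mer seed voting
#'
#' @param reads Read tibble (columns `read_id`, `seq`) as produced by
#'   [simulate_reads()]/[make_pool()], or a character vector of read
#'   sequences.
#' @param reference Reference sequence (single string, optionally named).
#' @param k Seed length (<= read length).
#' @param max_mismatch_frac Maximum tolerated mismatch fraction of the
#'   placed read.
#' @param seed_stride Spacing between sampled seed positions along the
#'   read (bp).
#'
#' @return A tibble of placements: `read_id`, `pos` (1-based start on the
#'   reference), `seq`, `mismatches`. Attribute `n_input` records the
#'   number of reads offered.
#' @export
naive_map <- function(reads, reference, k = 21L, max_mismatch_frac = 0.1,
                      seed_stride = 10L) {
  if (is.character(reads)) {
    reads <- tibble::tibble(read_id = paste0("r", seq_along(reads)),
                            seq = toupper(reads))
  }
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)))
  reference <- toupper(unname(reference[1]))
  L <- nchar(reference)
  k <- as.integer(k)
  n_reads <- nrow(reads)
  if (n_reads == 0L) {
    return(structure(tibble::tibble(read_id = character(), pos = integer(),
                                    seq = character(), mismatches = integer()),
                     n_input = 0L))
  }
  rl <- nchar(reads$seq)
  if (length(unique(rl)) != 1L) stop("reads must have equal length", call. = FALSE)
  rl <- rl[1]
  if (k > rl) stop("'k' exceeds the read length", call. = FALSE)
  if (k > L) stop("'k' exceeds the reference length", call. = FALSE)

  # reference k-mer index; repeated k-mers are ambiguous and removed
  ref_kmers <- substring(reference, 1:(L - k + 1L), k:L)
  dup <- duplicated(ref_kmers) | duplicated(ref_kmers, fromLast = TRUE)
  kmer_tab <- ref_kmers
  kmer_tab[dup] <- NA_character_

  offsets <- unique(c(seq(1L, rl - k + 1L, by = as.integer(seed_stride)),
                      rl - k + 1L))
  n_off <- length(offsets)
  seed_str <- substring(rep(reads$seq, each = n_off),
                        rep(offsets, times = n_reads),
                        rep(offsets + k - 1L, times = n_reads))
  hit <- match(seed_str, kmer_tab)               # NA for misses/repeats
  implied <- hit - rep(offsets, times = n_reads) + 1L
  read_ix <- rep(seq_len(n_reads), each = n_off)

  keep <- !is.na(implied) & implied >= 1L & implied <= L - rl + 1L
  implied <- implied[keep]
  read_ix <- read_ix[keep]
  if (!length(implied)) {
    return(structure(tibble::tibble(read_id = character(), pos = integer(),
                                    seq = character(), mismatches = integer()),
                     n_input = n_reads))
  }

  # majority vote per read; ties discarded
  key <- paste(read_ix, implied)
  votes <- table(key)
  first <- !duplicated(key)
  vote_read <- read_ix[first]
  vote_pos <- implied[first]
  vote_n <- as.integer(votes[key[first]])
  o <- order(vote_read, -vote_n)
  vr <- vote_read[o]; vp <- vote_pos[o]; vn <- vote_n[o]
  first_idx <- which(!duplicated(vr))
  nxt <- first_idx + 1L
  tie <- nxt <= length(vr) & vr[pmin(nxt, length(vr))] == vr[first_idx] &
    vn[pmin(nxt, length(vr))] == vn[first_idx]
  sel <- first_idx[!tie]
  placed_read <- vr[sel]
  placed_pos <- vp[sel]

  # mismatch count over the full ungapped alignment
  ref_seg <- substring(reference, placed_pos, placed_pos + rl - 1L)
  read_seq <- reads$seq[placed_read]
  mism <- vapply(seq_along(placed_read), function(i) {
    sum(utf8ToInt(read_seq[i]) != utf8ToInt(ref_seg[i]))
  }, integer(1))
  ok <- mism <= max_mismatch_frac * rl
  structure(
    tibble::tibble(read_id = reads$read_id[placed_read[ok]],
                   pos = as.integer(placed_pos[ok]),
                   seq = read_seq[ok],
                   mismatches = mism[ok]),
    n_input = n_reads
  )
}
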