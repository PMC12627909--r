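DNA_BASES <- c("A", "C", "G", "T")

#' Simulate single-end reads from a sequence
#'
#' Draws `round(coverage * length / read_length)` reads with uniformly
#' distributed start positions and independent per-base errors: an error
#' substitutes a uniformly chosen different base. Read ids carry the true
#' source and start position so downstream placements can be checked
#' against ground truth.
#'
#' @param sequence A single DNA string (uppercase A/C/G/T), optionally
#'   named; the name (or `source`) labels read provenance.
#' @param coverage Fold coverage (> 0).
#' @param read_length Read length in bp (<= sequence length).
#' @param error_rate Per-base error probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param source Source label stored with each read; defaults to the
#'   name of `sequence` or `"seq"`.
#'
#' @return A tibble (one row per read) with columns `read_id`, `seq`,
#'   `source`, `start` (1-based true start on the source sequence), and an
#'   `origin` attribute naming the read set.
#' @export
simulate_reads <- function(sequence, coverage, read_length = 150L,
                           error_rate = 0, seed = 1L, source = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  source <- source %||% names(sequence) %||% "seq"
  sequence <- toupper(unname(sequence))
  L <- nchar(sequence)
  read_length <- as.integer(read_length)
  if (!is.numeric(coverage) || coverage <= 0) {
    stop("'coverage' must be positive", call. = FALSE)
  }
  if (L < read_length) {
    stop("sequence shorter than 'read_length'", call. = FALSE)
  }
  if (error_rate < 0 || error_rate >= 1) {
    stop("'error_rate' must be in [0, 1)", call. = FALSE)
  }
  n_reads <- as.integer(round(coverage * L / read_length))
  with_seed(seed, {
    starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
    seqs <- substring(sequence, starts, starts + read_length - 1L)
    if (error_rate > 0 && n_reads > 0) {
      chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                      nrow = n_reads, byrow = TRUE)
      err <- which(runif(length(chars)) < error_rate)
      if (length(err)) {
        # substitute a uniformly chosen different base
        others <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                        c("A", "C", "T"), c("A", "C", "G"))
        cur <- match(chars[err], DNA_BASES)
        pick <- sample.int(3L, length(err), replace = TRUE)
        chars[err] <- others[cbind(cur, pick)]
      }
      seqs <- apply(chars, 1L, paste0, collapse = "")
    }
    out <- tibble::tibble(
      read_id = sprintf("%s_r%05d", source, seq_len(n_reads)),
      seq = seqs,
      source = source,
      start = starts
    )
    attr(out, "origin") <- source
    out
  })
}

#' Mix read sets into a pool at given proportions
#'
#' Subsamples each member read set (without replacement) so realized read
#' counts match the requested weights within one read (largest-remainder
#' apportionment), and concatenates the survivors. Member provenance is
#' retained in the `source` column.
#'
#' @param readsets List of read tibbles as produced by [simulate_reads()].
#' @param weights Positive mixing weights, one per member (e.g. `c(1, 9)`
#'   for a 1:9 pool).
#' @param n_reads Total pool size; defaults to the largest total the
#'   members can supply at these proportions.
#' @param seed Integer seed for the subsampling.
#' @param pool_id Label stored as the pool's `origin` attribute.
#'
#' @return A tibble of pooled reads with an `origin` attribute and a
#'   `member_counts` attribute (named realized counts).
#' @export
make_pool <- function(readsets, weights, n_reads = NULL, seed = 1L,
                      pool_id = "pool") {
  if (!length(readsets)) stop("need at least one member read set", call. = FALSE)
  if (length(weights) != length(readsets) || any(weights <= 0)) {
    stop("'weights' must be positive, one per member", call. = FALSE)
  }
  sizes <- vapply(readsets, nrow, integer(1))
  if (any(sizes == 0L)) stop("empty member read set", call. = FALSE)
  share <- weights / sum(weights)
  if (is.null(n_reads)) n_reads <- floor(min(sizes / share))
  n_reads <- as.integer(n_reads)
  target <- n_reads * share
  take <- floor(target)
  rem <- target - take
  deficit <- n_reads - sum(take)
  if (deficit > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(deficit)]
    take[bump] <- take[bump] + 1L
  }
  if (any(take > sizes)) {
    stop("member read sets too small for requested pool size", call. = FALSE)
  }
  pooled <- with_seed(seed, {
    picked <- lapply(seq_along(readsets), function(i) {
      rs <- readsets[[i]]
      rs[sample.int(nrow(rs), take[i]), , drop = FALSE]
    })
    dplyr::bind_rows(picked)
  })
  attr(pooled, "origin") <- pool_id
  attr(pooled, "member_counts") <-
    setNames(as.integer(take),
             vapply(readsets, function(r) attr(r, "origin") %||% r$source[1],
                    character(1)))
  pooled
}
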