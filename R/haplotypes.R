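#' Collapse identical haplotypes
#'
#' Identifies duplicate sequences (after case normalization) and keeps one
#' representative per haplotype, returning the mapping from every input id
#' to its haplotype representative. Sequences that differ only at gap
#' columns are treated as distinct haplotypes, since gap placement can be
#' real signal after alignment.
#'
#' @param records Named character vector of aligned sequences, or a data
#'   frame with columns `id` and `seq` (extra columns are carried along on
#'   the representatives).
#'
#' @return A list with `records` (the retained unique records, same shape
#'   as the input subset) and `mapping` (tibble `id` -> `haplotype_id`,
#'   covering every input id; the haplotype id is the id of the first
#'   record carrying that sequence).
#' @export
#' @examples
#' collapse_haplotypes(c(a = "ACGT", b = "acgt", c = "ACGA"))$mapping
collapse_haplotypes <- function(records) {
  if (is.data.frame(records)) {
    if (!all(c("id", "seq") %in% names(records))) {
      stop("data-frame input needs 'id' and 'seq' columns", call. = FALSE)
    }
    ids <- as.character(records$id)
    seqs <- as.character(records$seq)
    df <- records
  } else if (is.character(records)) {
    ids <- names(records) %||% paste0("seq", seq_along(records))
    seqs <- unname(records)
    df <- NULL
  } else {
    stop("'records' must be a named character vector or a data frame",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("sequence ids must be unique", call. = FALSE)
  if (length(unique(nchar(seqs))) > 1L) {
    stop("sequences must all have the same aligned length", call. = FALSE)
  }
  norm <- toupper(seqs)
  first <- match(norm, norm)            # index of first occurrence
  mapping <- tibble::tibble(id = ids, haplotype_id = ids[first])
  keep <- !duplicated(norm)
  records_out <- if (is.null(df)) {
    setNames(seqs[keep], ids[keep])
  } else {
    df[keep, , drop = FALSE]
  }
  list(records = records_out, mapping = mapping)
}
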