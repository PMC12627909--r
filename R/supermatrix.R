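#' Concatenate per-locus alignments into a supermatrix
#'
#' Takes the union of taxa across loci; a taxon absent from a locus is
#' padded with gap characters across that locus's columns. Partition
#' coordinates are 1-based closed column ranges, one per locus, tiling the
#' concatenated alignment in input order.
#'
#' @param alignments Named list of alignments (each a character matrix or
#'   named character vector of aligned strings). Names are the locus
#'   labels; unnamed loci get `locus1`, `locus2`, ...
#'
#' @return An object of class `supermatrix`: list with `alignment`
#'   (character matrix over the taxon union) and `partitions` (tibble:
#'   `locus`, `start`, `end`).
#' @export
#' @examples
#' s <- concatenate_supermatrix(list(
#'   l1 = c(a = "ACGT", b = "ACGA"),
#'   l2 = c(a = "GG", c = "GC")))
#' s$partitions
concatenate_supermatrix <- function(alignments) {
  if (!length(alignments)) stop("no alignments given", call. = FALSE)
  mats <- lapply(alignments, as_alignment_matrix)
  loci <- names(alignments) %||% paste0("locus", seq_along(alignments))
  loci[loci == ""] <- paste0("locus", which(loci == ""))
  for (i in seq_along(mats)) {
    if (anyDuplicated(rownames(mats[[i]]))) {
      stop("duplicate taxon within locus ", loci[i], call. = FALSE)
    }
  }
  taxa <- unique(unlist(lapply(mats, rownames)))
  widths <- vapply(mats, ncol, integer(1))
  total <- sum(widths)
  aln <- matrix("-", nrow = length(taxa), ncol = total,
                dimnames = list(taxa, NULL))
  end <- cumsum(widths)
  start <- end - widths + 1L
  for (i in seq_along(mats)) {
    aln[rownames(mats[[i]]), start[i]:end[i]] <- mats[[i]]
  }
  structure(list(alignment = aln,
                 partitions = tibble::tibble(locus = loci,
                                             start = as.integer(start),
                                             end = as.integer(end))),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("Supermatrix: %d taxa x %d sites, %d partitions\n",
              nrow(x$alignment), ncol(x$alignment), nrow(x$partitions)))
  invisible(x)
}

#' Target-capture recovery statistics
#'
#' Per-sample gene recovery summary for target-capture data: the number of
#' target genes with any recovered sequence, the number recovered to at
#' least 50% of the target length, and the overall recovered length as a
#' percentage of the total target length.
#'
#' @param recovered_lengths Named numeric vector (gene -> recovered bp) or
#'   data frame with columns `gene` and `length`.
#' @param target_lengths Same shape, full target lengths; must cover the
#'   same gene keys.
#' @param sample_id Optional sample label.
#'
#' @return A one-row tibble: `sample_id`, `genes_assembled`, `genes_at_50`,
#'   `length_pct`. Recovered lengths exceeding the target are clamped to
#'   the target with a warning.
#' @export
#' @examples
#' recovery_stats(c(g1 = 100, g2 = 60, g3 = 40, g4 = 0),
#'                c(g1 = 100, g2 = 100, g3 = 100, g4 = 100))
recovery_stats <- function(recovered_lengths, target_lengths,
                           sample_id = "sample") {
  as_len_vec <- function(x, what) {
    if (is.data.frame(x)) {
      if (!all(c("gene", "length") %in% names(x))) {
        stop(what, " needs 'gene' and 'length' columns", call. = FALSE)
      }
      setNames(as.numeric(x$length), as.character(x$gene))
    } else if (is.numeric(x) && !is.null(names(x))) {
      x
    } else {
      stop(what, " must be a named numeric vector or data frame", call. = FALSE)
    }
  }
  rec <- as_len_vec(recovered_lengths, "recovered_lengths")
  tgt <- as_len_vec(target_lengths, "target_lengths")
  if (!setequal(names(rec), names(tgt))) {
    stop("recovered and target tables must share the same gene keys", call. = FALSE)
  }
  rec <- rec[names(tgt)]
  if (any(tgt <= 0)) stop("target lengths must be positive", call. = FALSE)
  over <- rec > tgt
  if (any(over)) {
    warning(sum(over), " recovered length(s) exceed the target; clamped")
    rec[over] <- tgt[over]
  }
  tibble::tibble(
    sample_id = sample_id,
    genes_assembled = sum(rec > 0),
    genes_at_50 = sum(rec >= 0.5 * tgt),
    length_pct = 100 * sum(rec) / sum(tgt)
  )
}
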