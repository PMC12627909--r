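# Readers/writers for the standard interchange formats. FASTA and Newick
# go through ape; tables are plain TSV; reports can be dumped as JSON.

#' Read an aligned FASTA file
#'
#' @param path FASTA file path.
#' @return Uppercase character matrix (rows = sequences).
#' @export
read_alignment_fasta <- function(path) {
  dna <- ape::read.dna(path, format = "fasta", as.character = TRUE,
                       as.matrix = TRUE)
  toupper(dna)
}

#' Read unaligned sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequence strings (lengths
#'   may differ).
#' @export
read_fasta_seqs <- function(path) {
  x <- ape::read.FASTA(path)
  vapply(as.character(x), function(s) toupper(paste(s, collapse = "")),
         character(1))
}

#' Write sequences to FASTA
#'
#' @param x Character matrix (alignment) or named character vector of
#'   sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (is.matrix(x)) alignment_to_strings(x) else x
  stopifnot(!is.null(names(seqs)))
  lines <- character(2L * length(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  lines[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(lines, path)
  invisible(path)
}

#' Write reads to FASTQ
#'
#' Constant quality (`I`) is used; base qualities are not simulated.
#'
#' @param reads Read tibble (`read_id`, `seq`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  lines[seq(1L, length(lines), by = 4L)] <- paste0("@", reads$read_id)
  lines[seq(2L, length(lines), by = 4L)] <- reads$seq
  lines[seq(3L, length(lines), by = 4L)] <- "+"
  lines[seq(4L, length(lines), by = 4L)] <-
    strrep("I", nchar(reads$seq))
  writeLines(lines, path)
  invisible(path)
}

#' Read reads from FASTQ
#'
#' @param path FASTQ file path.
#' @return Read tibble (`read_id`, `seq`).
#' @export
read_reads_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ", call. = FALSE)
  tibble::tibble(
    read_id = sub("^@", "", sub("\\s.*$", "", lines[c(TRUE, FALSE, FALSE, FALSE)])),
    seq = toupper(lines[c(FALSE, TRUE, FALSE, FALSE)])
  )
}

#' Read a two-column species map TSV
#'
#' @param path TSV with columns `id` and `species` (header optional if the
#'   columns are in that order).
#' @return Named character vector id -> species.
#' @export
read_species_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("id", "species") %in% names(df))) {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    names(df)[1:2] <- c("id", "species")
  }
  setNames(as.character(df$species), as.character(df$id))
}

#' Write a distance matrix as square and long-form TSV
#'
#' @param dmat Symmetric distance matrix with dimnames.
#' @param species_map Optional species map used to classify each pair as
#'   intra- or interspecific in the long form.
#' @param square_path,long_path Output paths (`NULL` to skip one form).
#' @return Invisibly, the long-form tibble.
#' @export
write_distance_tsv <- function(dmat, species_map = NULL,
                               square_path = NULL, long_path = NULL) {
  if (!is.null(square_path)) {
    utils::write.table(dmat, square_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  labels <- rownames(dmat)
  ut <- which(upper.tri(dmat), arr.ind = TRUE)
  long <- tibble::tibble(id1 = labels[ut[, 1]], id2 = labels[ut[, 2]],
                         distance = dmat[ut])
  if (!is.null(species_map)) {
    sp <- species_map_vector(species_map)
    long$class <- ifelse(sp[long$id1] == sp[long$id2], "intra", "inter")
  }
  if (!is.null(long_path)) {
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(long)
}
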