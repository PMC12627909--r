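# internal helpers shared across modules

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Round half up at `digits` decimals (presentation rule for printed
# percentages; plain round() is banker's rounding).
#' @noRd
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Coerce sequences to an uppercase character matrix (rows = sequences,
# columns = aligned sites). Accepts a character matrix, a named character
# vector of equal-length strings, or a list of single-character vectors.
#' @noRd
as_alignment_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    n <- nchar(x)
    if (length(unique(n)) != 1L) {
      stop("sequences must all have the same aligned length", call. = FALSE)
    }
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- names(x)
  } else if (is.list(x)) {
    len <- lengths(x)
    if (length(unique(len)) != 1L) {
      stop("sequences must all have the same aligned length", call. = FALSE)
    }
    m <- do.call(rbind, lapply(x, function(s) toupper(as.character(s))))
    if (is.null(rownames(m))) rownames(m) <- names(x)
  } else {
    stop("cannot interpret 'x' as an alignment", call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  if (anyDuplicated(rownames(m))) {
    stop("sequence ids must be unique", call. = FALSE)
  }
  m
}

# Collapse alignment matrix rows back to strings.
#' @noRd
alignment_to_strings <- function(m) {
  setNames(apply(m, 1L, paste0, collapse = ""), rownames(m))
}

#' @noRd
assert_rooted <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths", call. = FALSE)
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  invisible(tree)
}
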