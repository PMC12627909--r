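#' Barcode-gap summary from a distance matrix
#'
#' Partitions all pairwise distances into intraspecific and interspecific
#' classes and, for each species with at least two sequences, reports the
#' largest intraspecific distance, the smallest interspecific distance,
#' and their difference (the barcode gap). A species whose gap is <= 0
#' cannot be discriminated by distance alone; a species sharing an
#' identical haplotype with another species has `min_inter == 0` and is
#' flagged. Undefined (`NA`) distances are skipped, never imputed.
#'
#' @param dmat Symmetric distance matrix with sequence ids as dimnames
#'   (see [distance_matrix()]).
#' @param species_map Named character vector or data frame (`id`,
#'   `species`) mapping every matrix label to a species.
#'
#' @return An object of class `barcode_gap_report`: list with
#'   `per_species` (tibble: `species`, `n_seqs`, `max_intra`, `min_inter`,
#'   `gap`, `shared_haplotype`, `discriminable`), and the global `intra`
#'   and `inter` distance vectors.
#' @export
barcode_gap_summary <- function(dmat, species_map) {
  sp <- species_map_vector(species_map)
  labels <- rownames(dmat)
  if (is.null(labels)) stop("'dmat' must have dimnames", call. = FALSE)
  unmapped <- setdiff(labels, names(sp))
  if (length(unmapped)) {
    stop("unmapped labels: ", paste(unmapped, collapse = ", "), call. = FALSE)
  }
  sp <- sp[labels]
  n <- length(labels)
  same <- outer(sp, sp, "==")
  ut <- upper.tri(dmat)
  intra <- dmat[ut & same]
  inter <- dmat[ut & !same]

  species <- sort(unique(sp))
  per <- lapply(species, function(s) {
    members <- which(sp == s)
    n_seqs <- length(members)
    if (n_seqs < 2L) {
      return(tibble::tibble(species = s, n_seqs = n_seqs,
                            max_intra = NA_real_, min_inter = NA_real_,
                            gap = NA_real_, shared_haplotype = NA,
                            discriminable = NA))
    }
    din <- dmat[members, members][upper.tri(diag(n_seqs))]
    dout <- dmat[members, -members, drop = FALSE]
    max_intra <- if (all(is.na(din))) NA_real_ else max(din, na.rm = TRUE)
    min_inter <- if (all(is.na(dout))) NA_real_ else min(dout, na.rm = TRUE)
    gap <- min_inter - max_intra
    tibble::tibble(species = s, n_seqs = n_seqs, max_intra = max_intra,
                   min_inter = min_inter, gap = gap,
                   shared_haplotype = !is.na(min_inter) && min_inter == 0,
                   discriminable = !is.na(gap) && gap > 0)
  })
  structure(list(per_species = dplyr::bind_rows(per),
                 intra = intra[!is.na(intra)],
                 inter = inter[!is.na(inter)]),
            class = "barcode_gap_report")
}

#' @export
print.barcode_gap_report <- function(x, ...) {
  cat(sprintf("Barcode-gap report: %d species, %d intra / %d inter pairs\n",
              nrow(x$per_species), length(x$intra), length(x$inter)))
  print(x$per_species, n = Inf)
  invisible(x)
}

# species map inputs: named vector or data frame (id, species)
#' @noRd
species_map_vector <- function(species_map) {
  if (is.data.frame(species_map)) {
    if (!all(c("id", "species") %in% names(species_map))) {
      stop("species map needs 'id' and 'species' columns", call. = FALSE)
    }
    sp <- setNames(as.character(species_map$species),
                   as.character(species_map$id))
  } else if (is.character(species_map) && !is.null(names(species_map))) {
    sp <- species_map
  } else {
    stop("'species_map' must be a named character vector or data frame",
         call. = FALSE)
  }
  if (anyDuplicated(names(sp))) stop("duplicate ids in species map", call. = FALSE)
  sp
}

#' Liberal tree-based identification success
#'
#' Scores species identifiability from a phylogeny under the liberal
#' criterion: a leaf is successfully identified when the leaf set of its
#' sibling subtree contains at least one conspecific, or when the smallest
#' clade containing the leaf and any other leaf consists only of
#' conspecifics. A species succeeds when all of its leaves succeed.
#' Species represented by a single sequence cannot be scored by tree
#' placement and are reported separately as `"distance-only"` (identifiable
#' only by genetic distance to the closest relative).
#'
#' @param tree Rooted `phylo` tree (or unrooted with `outgroup` given, in
#'   which case it is rooted on the outgroup first).
#' @param species_map Named character vector or data frame (`id`,
#'   `species`) covering every leaf.
#' @param outgroup Optional leaf label to root an unrooted tree.
#'
#' @return List with `per_species` (tibble: `species`, `n_seqs`,
#'   `category` = `"scored"`/`"distance-only"`, `success`), `overall`
#'   (proportion of scored species that succeed) and `n_scored`.
#' @export
tree_identification_success <- function(tree, species_map, outgroup = NULL) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object", call. = FALSE)
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup)) {
      stop("unrooted tree: supply 'outgroup' to root it", call. = FALSE)
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  sp <- species_map_vector(species_map)
  tips <- tree$tip.label
  if (!all(tips %in% names(sp))) {
    stop("species map must cover every leaf", call. = FALSE)
  }
  sp <- sp[tips]
  counts <- table(sp)
  if (!any(counts >= 2L)) {
    stop("need at least one species with >= 2 sequences", call. = FALSE)
  }

  ntip <- ape::Ntip(tree)
  desc <- phangorn::Descendants(tree, type = "tips")
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  leaf_success <- vapply(seq_len(ntip), function(i) {
    if (counts[[sp[i]]] < 2L) return(NA)
    par <- parent[i]
    sibs <- setdiff(desc[[par]], i)
    sister_ok <- any(sp[sibs] == sp[i])
    clade_ok <- all(sp[desc[[par]]] == sp[i])
    sister_ok || clade_ok
  }, logical(1))

  per <- tibble::tibble(species = names(counts),
                        n_seqs = as.integer(counts))
  per$category <- ifelse(per$n_seqs >= 2L, "scored", "distance-only")
  per$success <- vapply(seq_len(nrow(per)), function(k) {
    if (per$category[k] != "scored") return(NA)
    all(leaf_success[sp == per$species[k]])
  }, logical(1))
  scored <- per$category == "scored"
  list(per_species = per,
       overall = mean(per$success[scored]),
       n_scored = sum(scored))
}
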