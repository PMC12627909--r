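#' Neighbor-joining tree from a distance matrix
#'
#' Desk-scale tree inference for the assignment pipeline: standard
#' neighbor joining with negative branch-length estimates clamped to zero,
#' rooted on an outgroup when one is supplied and at the midpoint
#' otherwise. The assignment logic downstream is tree-agnostic, so any
#' externally inferred tree (e.g. maximum likelihood) can be used in place
#' of this one.
#'
#' @param dmat Complete symmetric distance matrix (>= 3 taxa, no missing
#'   cells) with taxon ids as dimnames.
#' @param outgroup Optional taxon label to root on.
#'
#' @return A rooted `phylo` tree with non-negative branch lengths.
#' @export
nj_tree <- function(dmat, outgroup = NULL) {
  dmat <- as.matrix(dmat)
  if (nrow(dmat) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (anyNA(dmat)) stop("distance matrix has missing cells", call. = FALSE)
  tree <- ape::nj(stats::as.dist(dmat))
  tree$edge.length[tree$edge.length < 0] <- 0
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  } else {
    tree <- phangorn::midpoint(tree)
  }
  tree
}

#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths along the unique path between
#' leaves i and j, computed as `depth(i) + depth(j) - 2 * depth(mrca(i, j))`
#' where depth is the root-to-node path length.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#'
#' @return Symmetric numeric matrix (leaf labels as dimnames) with zero
#'   diagonal.
#' @export
patristic_matrix <- function(tree) {
  assert_rooted(tree)
  ntip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)   # root-to-node path lengths
  mr <- ape::mrca(tree)                       # tip-pair MRCAs
  d <- outer(depth[seq_len(ntip)], depth[seq_len(ntip)], "+") - 2 * depth[mr]
  diag(d) <- 0
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

#' Assign query leaves to species by placement and patristic distance
#'
#' For each query leaf (a leaf absent from the reference species map), two
#' criteria are evaluated on the rooted tree:
#' \describe{
#'   \item{monophyly}{the smallest clade containing the query and at least
#'     one reference contains references of exactly one species.}
#'   \item{distance}{the query's nearest reference (patristic) belongs to
#'     species S and the distance does not exceed the largest intraspecific
#'     reference-reference distance within S; for species with a single
#'     reference, the distance must instead be smaller than the smallest
#'     distance from that reference to any heterospecific reference.}
#' }
#' The query is assigned when the monophyly criterion holds, or when the
#' distance criterion holds with a strictly positive margin over the
#' runner-up species; otherwise it is reported `"unidentified"` together
#' with the species set of its containing clade (ties are conservative:
#' never resolved to one of the tied species).
#'
#' @param tree Rooted `phylo` tree containing reference and query leaves.
#' @param reference_species_map Named character vector or data frame
#'   (`id`, `species`) mapping reference leaf labels to species; leaves
#'   not in the map are treated as queries.
#'
#' @return A tibble with one row per query: `query`, `assigned`,
#'   `monophyly_ok`, `distance_ok`, `nearest_ref`, `nearest_dist`,
#'   `runner_up`, `margin`, `clade_species` (slash-separated species set
#'   of the smallest reference-containing clade).
#' @export
assign_queries <- function(tree, reference_species_map) {
  assert_rooted(tree)
  sp <- species_map_vector(reference_species_map)
  tips <- tree$tip.label
  if (anyDuplicated(tips)) {
    stop("tree leaf labels must be unique (query/reference collision)",
         call. = FALSE)
  }
  refs <- intersect(tips, names(sp))
  queries <- setdiff(tips, refs)
  if (!length(refs)) stop("tree contains no reference leaves", call. = FALSE)
  if (!length(queries)) {
    return(tibble::tibble(query = character(), assigned = character(),
                          monophyly_ok = logical(), distance_ok = logical(),
                          nearest_ref = character(), nearest_dist = numeric(),
                          runner_up = character(), margin = numeric(),
                          clade_species = character()))
  }
  ref_sp <- sp[refs]

  ntip <- ape::Ntip(tree)
  desc <- phangorn::Descendants(tree, type = "tips")
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  is_ref_tip <- tips %in% refs

  pd <- patristic_matrix(tree)
  ref_idx <- match(refs, tips)

  # intraspecific ceiling per species; singleton fallback threshold
  species <- unique(ref_sp)
  intra_max <- setNames(rep(NA_real_, length(species)), species)
  singleton_thr <- setNames(rep(NA_real_, length(species)), species)
  for (s in species) {
    mem <- refs[ref_sp == s]
    if (length(mem) >= 2L) {
      intra_max[s] <- max(pd[mem, mem])
    } else {
      het <- setdiff(refs, mem)
      singleton_thr[s] <- min(pd[mem, het])
    }
  }

  out <- lapply(queries, function(q) {
    qi <- match(q, tips)
    # smallest clade containing the query and >= 1 reference
    node <- qi
    repeat {
      node <- if (node == root) root else parent[node]
      in_clade <- desc[[node]]
      clade_refs <- in_clade[is_ref_tip[in_clade]]
      if (length(clade_refs) || node == root) break
    }
    clade_species <- sort(unique(ref_sp[tips[clade_refs]]))
    monophyly_ok <- length(clade_species) == 1L

    dq <- pd[qi, ref_idx]
    ord <- order(dq)
    nearest_ref <- refs[ord[1L]]
    nearest_dist <- unname(dq[ord[1L]])
    s_near <- ref_sp[[nearest_ref]]
    other <- dq[ref_sp != s_near]
    runner_dist <- if (length(other)) min(other) else Inf
    runner_up <- if (length(other)) {
      cand <- refs[ref_sp != s_near]
      ref_sp[[cand[which.min(other)]]]
    } else NA_character_
    margin <- runner_dist - nearest_dist

    thr <- if (!is.na(intra_max[s_near])) intra_max[s_near] else NA_real_
    distance_ok <- if (!is.na(thr)) {
      nearest_dist <= thr
    } else {
      nearest_dist < singleton_thr[s_near]
    }

    assigned <- if (monophyly_ok) {
      clade_species
    } else if (distance_ok && margin > 0) {
      s_near
    } else {
      "unidentified"
    }
    tibble::tibble(query = q, assigned = assigned,
                   monophyly_ok = monophyly_ok, distance_ok = distance_ok,
                   nearest_ref = nearest_ref, nearest_dist = nearest_dist,
                   runner_up = runner_up, margin = max(margin, 0),
                   clade_species = paste(clade_species, collapse = "/"))
  })
  dplyr::bind_rows(out)
}

#' Intra- vs interspecific patristic distance distributions per group
#'
#' For each group (typically a genus), splits all within-group pairwise
#' patristic distances into intraspecific and interspecific classes and
#' summarizes them, flagging groups whose classes overlap (largest
#' intraspecific >= smallest interspecific distance).
#'
#' @param pd Patristic distance matrix (see [patristic_matrix()]).
#' @param species_map Named vector / data frame mapping labels to species.
#' @param group_map Named vector / data frame (`id`, `species` columns
#'   interpreted as `id`, `group`) mapping labels to groups; labels missing
#'   from it are ignored.
#'
#' @return A tibble with one row per group: `group`, `n_intra`, `n_inter`,
#'   `max_intra`, `min_inter`, `overlap`, plus list-columns `intra` and
#'   `inter` holding the raw distance vectors (for density plots).
#'   Groups with no members are skipped with a warning.
#' @export
intra_inter_density <- function(pd, species_map, group_map) {
  sp <- species_map_vector(species_map)
  if (is.data.frame(group_map)) {
    if (!"id" %in% names(group_map)) {
      stop("group map needs an 'id' column", call. = FALSE)
    }
    gcol <- intersect(c("group", "genus", "species"), names(group_map))[1]
    if (is.na(gcol)) stop("group map needs a 'group' column", call. = FALSE)
    gm <- setNames(as.character(group_map[[gcol]]),
                   as.character(group_map$id))
  } else {
    gm <- species_map_vector(group_map)
  }
  labels <- rownames(pd)
  gm <- gm[names(gm) %in% labels]
  out <- lapply(sort(unique(gm)), function(g) {
    mem <- names(gm)[gm == g]
    if (!length(mem)) {
      warning("group ", g, " has no members; skipped")
      return(NULL)
    }
    if (length(mem) < 2L) {
      return(tibble::tibble(group = g, n_intra = 0L, n_inter = 0L,
                            max_intra = NA_real_, min_inter = NA_real_,
                            overlap = NA, intra = list(numeric(0)),
                            inter = list(numeric(0))))
    }
    sub <- pd[mem, mem]
    same <- outer(sp[mem], sp[mem], "==")
    ut <- upper.tri(sub)
    intra <- sub[ut & same]
    inter <- sub[ut & !same]
    tibble::tibble(
      group = g, n_intra = length(intra), n_inter = length(inter),
      max_intra = if (length(intra)) max(intra) else NA_real_,
      min_inter = if (length(inter)) min(inter) else NA_real_,
      overlap = if (length(intra) && length(inter)) max(intra) >= min(inter) else NA,
      intra = list(intra), inter = list(inter)
    )
  })
  dplyr::bind_rows(out)
}
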