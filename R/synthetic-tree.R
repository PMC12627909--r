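#' Simulate a calibrated species tree
#'
#' Draws a pure-birth (Yule) species tree and rescales its branch lengths so
#' the median tip-to-tip (patristic) distance equals `median_tip_distance`
#' expected substitutions/site. Optionally compresses one clade into a
#' "congener" clade whose species are separated by as little as
#' `congener_sep`, emulating recently diverged congeners (the hard case for
#' barcoding, e.g. within grasses).
#'
#' @param n_species Number of species (tree leaves), >= 2.
#' @param birth_rate Speciation rate of the Yule process.
#' @param seed Integer seed; the same seed yields a byte-identical tree.
#' @param median_tip_distance Target median tip-to-tip distance
#'   (substitutions/site).
#' @param congener_size Size of the congener clade; 0 disables it. A clade
#'   with exactly this many leaves is used when one exists, otherwise the
#'   closest available size in `[2, 2 * congener_size]`.
#' @param congener_sep Minimum between-species tip-to-tip distance inside
#'   the congener clade after rescaling.
#' @param min_species_sep Global floor on between-species tip-to-tip
#'   distance (defaults to `congener_sep`). Pure-birth trees contain
#'   arbitrarily recent splits; pendant branches are lengthened so that no
#'   species pair falls below this floor, which is what keeps the
#'   generator's interspecific divergences at least ten-fold above the
#'   default intraspecific divergence. Set to 0 to disable.
#'
#' @return A rooted binary `phylo` tree with `n_species` uniquely labeled
#'   leaves (`sp01`, `sp02`, ...) and strictly positive branch lengths. The
#'   leaves of the congener clade (if any) are recorded in
#'   `attr(tree, "congener_species")`.
#' @export
#' @examples
#' tr <- simulate_species_tree(20, 1, seed = 3)
#' ape::Ntip(tr)
simulate_species_tree <- function(n_species, birth_rate = 1, seed = 1L,
                                  median_tip_distance = 0.05,
                                  congener_size = 0L,
                                  congener_sep = 0.005,
                                  min_species_sep = congener_sep) {
  n_species <- as.integer(n_species)
  if (is.na(n_species) || n_species < 2L) {
    stop("'n_species' must be >= 2", call. = FALSE)
  }
  if (birth_rate <= 0) stop("'birth_rate' must be positive", call. = FALSE)
  tree <- with_seed(seed, ape::rphylo(n_species, birth = birth_rate, death = 0))
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))

  # calibrate overall divergence
  med <- median(ape::cophenetic.phylo(tree))
  # median over full matrix includes the zero diagonal; use off-diagonal pairs
  cp <- ape::cophenetic.phylo(tree)
  med <- median(cp[upper.tri(cp)])
  tree$edge.length <- tree$edge.length * (median_tip_distance / med)

  # enforce the interspecific separation floor by lengthening pendant edges
  if (min_species_sep > 0) {
    cp <- ape::cophenetic.phylo(tree)
    diag(cp) <- Inf
    bump <- pmax(0, (min_species_sep - apply(cp[tree$tip.label,
                                                tree$tip.label], 1L, min)) / 2)
    if (any(bump > 0)) {
      tip_edge <- match(seq_len(ape::Ntip(tree)), tree$edge[, 2])
      tree$edge.length[tip_edge] <- tree$edge.length[tip_edge] + unname(bump)
    }
  }

  congener <- character(0)
  if (congener_size >= 2L && n_species > congener_size) {
    node <- find_clade_of_size(tree, as.integer(congener_size))
    if (!is.na(node)) {
      desc <- clade_nodes(tree, node)
      tips <- desc[desc <= ape::Ntip(tree)]
      congener <- tree$tip.label[tips]
      inner <- tree$edge[, 1] %in% c(node, desc)  # edges inside the clade
      cp <- ape::cophenetic.phylo(tree)[congener, congener, drop = FALSE]
      cur_min <- min(cp[upper.tri(cp)])
      tree$edge.length[inner] <- tree$edge.length[inner] * (congener_sep / cur_min)
    }
  }
  stopifnot(all(tree$edge.length > 0))
  attr(tree, "congener_species") <- congener
  tree
}

# All descendant nodes (internal and tips) of `node`, excluding `node`.
#' @noRd
clade_nodes <- function(tree, node) {
  out <- integer(0)
  stack <- tree$edge[tree$edge[, 1] == node, 2]
  while (length(stack)) {
    out <- c(out, stack)
    stack <- tree$edge[tree$edge[, 1] %in% stack, 2]
  }
  out
}

# Internal node whose clade size is closest to `size` (preferring exact),
# searched within [2, 2*size]; NA if none.
#' @noRd
find_clade_of_size <- function(tree, size) {
  ntip <- ape::Ntip(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  sizes <- vapply(internal, function(nd) {
    d <- clade_nodes(tree, nd)
    sum(d <= ntip)
  }, integer(1))
  ok <- sizes >= 2L & sizes <= 2L * size & internal != ntip + 1L  # not the root
  if (!any(ok)) return(NA_integer_)
  cand <- internal[ok]
  csz <- sizes[ok]
  cand[order(abs(csz - size), csz)][1L]
}

#' Evolve an alignment along a tree under GTR+Gamma
#'
#' Simulates one aligned sequence per leaf by a continuous-time Markov
#' substitution process along the branches (branch lengths are expected
#' substitutions/site), with discrete-gamma rate heterogeneity across sites.
#' Substitution-only: no indels, so sequences are alignment columns by
#' construction.
#'
#' @param tree A `phylo` tree with branch lengths in expected
#'   substitutions/site.
#' @param locus_length Number of sites (> 0).
#' @param model A [gtr_model()].
#' @param seed Integer seed (byte-identical reruns).
#'
#' @return Character matrix (rows = leaves, columns = sites) of uppercase
#'   bases, with `locus_length` columns.
#' @export
#' @examples
#' tr <- simulate_species_tree(4, seed = 1)
#' aln <- evolve_alignment(tr, 200, gtr_model(), seed = 2)
#' dim(aln)
evolve_alignment <- function(tree, locus_length, model = gtr_model(), seed = 1L) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "gtr_model"))
  locus_length <- as.integer(locus_length)
  if (is.na(locus_length) || locus_length < 1L) {
    stop("'locus_length' must be a positive integer", call. = FALSE)
  }
  if (is.null(tree$edge.length)) stop("tree must have branch lengths", call. = FALSE)

  with_seed(seed, {
    k <- model$n_rate_categories
    if (is.infinite(model$gamma_shape) || k == 1L) {
      rates <- 1
      site_cat <- rep(1L, locus_length)
    } else {
      rates <- phangorn::discrete.gamma(model$gamma_shape, k)
      site_cat <- sample.int(k, locus_length, replace = TRUE)
    }
    out <- matrix(NA_character_, nrow = ape::Ntip(tree), ncol = locus_length)
    for (cat in seq_along(rates)) {
      idx <- which(site_cat == cat)
      if (!length(idx)) next
      sim <- phangorn::simSeq(tree, l = length(idx), Q = model$rates,
                              bf = model$base_freqs, rate = rates[cat])
      m <- toupper(as.character(sim))
      out[, idx] <- m[tree$tip.label, , drop = FALSE]
    }
    rownames(out) <- tree$tip.label
    out
  })
}
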