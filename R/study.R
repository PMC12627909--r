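# High-level drivers composing the synthetic generator into the two
# validation studies: multi-individual reference/query simulation for the
# assignment pipeline, and control read pools for the SNP-density
# diagnostics.

#' Simulate a reference library plus query seedlings
#'
#' Expands a calibrated species tree into a population tree (each species
#' tip becomes a small clade of reference individuals and query
#' individuals, with pendant branches of half the intraspecific pairwise
#' divergence), then evolves per-locus alignments along it and concatenates
#' them into a supermatrix. Query individuals carry no species label in the
#' returned reference map; their true species are recorded separately so
#' assignment accuracy can be scored.
#'
#' @param config A [simulation_config()].
#' @param n_refs_per_species Reference individuals per species.
#' @param n_queries Total query individuals, allocated to species uniformly
#'   at random.
#' @param seed Integer seed (defaults to `config$seed`).
#'
#' @return List: `species_tree`, `population_tree`, `supermatrix`,
#'   `alignments` (per locus), `ref_map` (tibble `id`, `species`),
#'   `truth` (tibble `query`, `species`), `congener_species`.
#' @export
simulate_barcoding_study <- function(config = simulation_config(),
                                     n_refs_per_species = 2L,
                                     n_queries = 100L,
                                     seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                          config$n_loci + 2L))
  tree <- simulate_species_tree(
    config$n_species, config$birth_rate, seed = sub_seeds[1],
    median_tip_distance = config$median_tip_distance,
    congener_size = config$congener_size,
    congener_sep = config$congener_sep)

  # allocate queries to species and build the population tree
  alloc <- with_seed(sub_seeds[2],
                     sample.int(config$n_species, n_queries, replace = TRUE))
  h <- config$intra_divergence / 2
  newick <- ape::write.tree(tree)
  ref_ids <- character(0); ref_species <- character(0)
  query_ids <- character(0); query_species <- character(0)
  for (i in seq_len(config$n_species)) {
    sp_label <- tree$tip.label[i]
    refs <- sprintf("%s_ref%d", sp_label, seq_len(n_refs_per_species))
    qs <- if (any(alloc == i)) {
      sprintf("%s_q%d", sp_label, seq_len(sum(alloc == i)))
    } else character(0)
    members <- c(refs, qs)
    ref_ids <- c(ref_ids, refs)
    ref_species <- c(ref_species, rep(sp_label, length(refs)))
    query_ids <- c(query_ids, qs)
    query_species <- c(query_species, rep(sp_label, length(qs)))
    sub <- paste0("(", paste0(members, ":", format(h, scientific = FALSE),
                              collapse = ","), ")")
    newick <- sub(paste0(sp_label, ":"), paste0(sub, ":"), newick,
                  fixed = TRUE)
  }
  pop_tree <- ape::read.tree(text = newick)

  alns <- lapply(seq_len(config$n_loci), function(l) {
    evolve_alignment(pop_tree, config$locus_length,
                     model = config$substitution_model,
                     seed = sub_seeds[l + 2L])
  })
  names(alns) <- sprintf("locus%02d", seq_len(config$n_loci))
  sm <- concatenate_supermatrix(alns)

  list(species_tree = tree,
       population_tree = pop_tree,
       supermatrix = sm,
       alignments = alns,
       ref_map = tibble::tibble(id = ref_ids, species = ref_species),
       truth = tibble::tibble(query = query_ids, species = query_species),
       congener_species = attr(tree, "congener_species"))
}

#' Simulate control read pools over plastome references
#'
#' Four plastome-like sequences are evolved on a star tree whose tips are
#' all separated by the configured median interspecific divergence; reads
#' are simulated for each species and combined into the control panel of
#' the pooled-sample diagnostics: single-species pools for each of three
#' species, two 1:1 two-species mixes (one replicated) and one 1:9 mix.
#'
#' @param config A [simulation_config()] (plastome length, read length,
#'   coverage, error rate and substitution model are taken from it).
#' @param seed Integer seed.
#'
#' @return List: `references` (named character vector of plastomes),
#'   `pools` (named list of read tibbles), `truth` (tibble `pool_id`,
#'   `members`, `mixed`).
#' @export
simulate_control_pools <- function(config = simulation_config(),
                                   seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max, 12L))
  r <- config$median_tip_distance / 2
  star <- ape::read.tree(text = sprintf(
    "(taxonA:%f,taxonB:%f,taxonC:%f,taxonD:%f);", r, r, r, r))
  plast <- evolve_alignment(star, config$plastome_length,
                            model = config$substitution_model,
                            seed = sub_seeds[1])
  references <- alignment_to_strings(plast)

  reads <- lapply(names(references), function(s) {
    simulate_reads(references[s], coverage = config$coverage,
                   read_length = config$read_length,
                   error_rate = config$error_rate,
                   seed = sub_seeds[1L + match(s, names(references))],
                   source = s)
  })
  names(reads) <- names(references)

  n_pool <- as.integer(round(config$coverage * config$plastome_length /
                               config$read_length))
  mk <- function(members, weights, sd, id) {
    make_pool(reads[members], weights, n_reads = n_pool, seed = sd,
              pool_id = id)
  }
  pools <- list(
    pure_A = mk("taxonA", 1, sub_seeds[6], "pure_A"),
    pure_B = mk("taxonB", 1, sub_seeds[7], "pure_B"),
    pure_C = mk("taxonC", 1, sub_seeds[8], "pure_C"),
    mix11_AB = mk(c("taxonA", "taxonB"), c(1, 1), sub_seeds[9], "mix11_AB"),
    mix11_AC = mk(c("taxonA", "taxonC"), c(1, 1), sub_seeds[10], "mix11_AC"),
    mix19_AD = mk(c("taxonA", "taxonD"), c(1, 9), sub_seeds[11], "mix19_AD")
  )
  truth <- tibble::tibble(
    pool_id = names(pools),
    members = c("taxonA", "taxonB", "taxonC",
                "taxonA+taxonB", "taxonA+taxonC", "taxonA+taxonD"),
    mixed = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  list(references = references, pools = pools, truth = truth)
}
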