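#' Propagate species labels to pooled seedlings
#'
#' Seedlings that were not sequenced individually inherit the species of
#' their OTU/site representative when the pool built from that OTU/site
#' was verdicted homogeneous. Members of non-homogeneous pools remain
#' unidentified and are flagged as conflicted; a representative assignment
#' that contradicts its own pool's best reference flags the whole OTU/site
#' group instead of silently overwriting. Individually sequenced rows are
#' never relabeled and the row count is conserved.
#'
#' @param table Seedling tibble with columns `sample_id`, `site`, `otu`,
#'   `species` (`"unidentified"` or `NA` where unknown) and `evidence`.
#' @param representative_assignments Tibble (`site`, `otu`, `species`) of
#'   individually sequenced representatives.
#' @param pool_verdicts Tibble (`site`, `otu`, `homogeneous`,
#'   `best_species`); `best_species` is the species of the pool's best
#'   reference.
#'
#' @return The input table with updated `species`/`evidence` plus a logical
#'   `conflict` column.
#' @export
propagate_labels <- function(table, representative_assignments, pool_verdicts) {
  stopifnot(all(c("site", "otu", "species") %in% names(table)))
  rep_key <- paste(representative_assignments$site,
                   representative_assignments$otu)
  if (anyDuplicated(rep_key)) {
    stop("multiple representative assignments for one OTU/site group",
         call. = FALSE)
  }
  pv_key <- paste(pool_verdicts$site, pool_verdicts$otu)
  key <- paste(table$site, table$otu)
  ri <- match(key, rep_key)
  pi <- match(key, pv_key)

  out <- table
  if (!"conflict" %in% names(out)) out$conflict <- FALSE
  if (!"evidence" %in% names(out)) out$evidence <- NA_character_
  unlabeled <- is.na(out$species) | out$species == "unidentified"
  sequenced <- !is.na(out$evidence) & out$evidence == "individual-sequencing"

  rep_sp <- representative_assignments$species[ri]
  hom <- pool_verdicts$homogeneous[pi]
  best <- pool_verdicts$best_species[pi]

  # representative vs pool contradiction: flag the whole group
  contradiction <- !is.na(rep_sp) & !is.na(best) & !is.na(hom) & hom &
    rep_sp != best
  out$conflict <- out$conflict | contradiction

  inherit <- unlabeled & !sequenced & !is.na(rep_sp) & !is.na(hom) & hom &
    !contradiction
  out$species[inherit] <- rep_sp[inherit]
  out$evidence[inherit] <- "pool"

  flagged <- unlabeled & !sequenced & !is.na(hom) & !hom
  out$species[flagged] <- "unidentified"
  out$conflict <- out$conflict | flagged
  out
}

#' Incidence summary by species, status, management class and site
#'
#' Tallies a labeled seedling table against the species registry.
#' Status percentages use all seedlings of the chosen origin as the
#' denominator, so unidentified rows dilute both classes (1256 non-native
#' of 1498 soil seedlings gives 83.8%); management-class percentages use
#' the identified non-native seedlings only. Raw fractions are kept
#' alongside percentages rounded half-up to one decimal for display.
#'
#' @param table Labeled seedling tibble (see [make_fixture_tables()] /
#'   [propagate_labels()]).
#' @param registry Species registry (see [sg_species_registry()]).
#' @param origin Which seedlings to summarize: `"soil"` (default),
#'   `"trap"`, or `"all"`.
#'
#' @return An object of class `incidence_summary`: list with `n_total`,
#'   `n_unidentified`, `n_species_identified` (species-group rows expand to
#'   their `n_taxa`), `by_species` (count and number of sites per species),
#'   `by_status` (count, `pct_raw`, `pct`), `by_class` (same over
#'   identified non-native seedlings) and `by_site` (status counts per
#'   site). With an empty table all counts are 0, percentages are `NA` and
#'   `percentages_defined` is `FALSE`.
#' @export
incidence_summary <- function(table, registry = sg_species_registry(),
                              origin = c("soil", "trap", "all")) {
  origin <- match.arg(origin)
  tb <- if (origin == "all") table else table[table$origin == origin, , drop = FALSE]
  labeled <- tb[!is.na(tb$species) & tb$species != "unidentified", , drop = FALSE]
  missing <- setdiff(unique(labeled$species), registry$species)
  if (length(missing)) {
    stop("species missing from registry: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n_total <- nrow(tb)
  n_unid <- n_total - nrow(labeled)

  reg_ix <- match(labeled$species, registry$species)
  labeled$status <- registry$status[reg_ix]
  labeled$mgmt_class <- registry$mgmt_class[reg_ix]

  by_species <- dplyr::summarise(
    dplyr::group_by(labeled, .data$species, .data$status, .data$mgmt_class),
    count = dplyr::n(), n_sites = dplyr::n_distinct(.data$site),
    .groups = "drop")
  by_species <- dplyr::arrange(by_species, dplyr::desc(.data$count))

  status_counts <- c(
    introduced = sum(labeled$status == "introduced"),
    native = sum(labeled$status == "native"),
    unidentified = n_unid
  )
  defined <- n_total > 0
  by_status <- tibble::tibble(
    status = names(status_counts),
    count = as.integer(status_counts),
    pct_raw = if (defined) unname(100 * status_counts / n_total) else NA_real_
  )
  by_status$pct <- round_half_up(by_status$pct_raw, 1L)

  nn <- labeled[labeled$status == "introduced", , drop = FALSE]
  cls_counts <- table(factor(nn$mgmt_class, levels = c("I", "II", "III")))
  by_class <- tibble::tibble(
    mgmt_class = names(cls_counts),
    count = as.integer(cls_counts),
    pct_raw = if (nrow(nn) > 0) 100 * as.integer(cls_counts) / nrow(nn)
              else NA_real_
  )
  by_class$pct <- round_half_up(by_class$pct_raw, 1L)

  by_site <- dplyr::summarise(
    dplyr::group_by(labeled, .data$site, .data$status),
    count = dplyr::n(), .groups = "drop")

  n_species_identified <- sum(
    registry$n_taxa[match(unique(labeled$species), registry$species)])

  structure(list(
    origin = origin,
    n_total = n_total,
    n_unidentified = n_unid,
    n_species_identified = as.integer(n_species_identified %||% 0L),
    by_species = by_species,
    by_status = by_status,
    by_class = by_class,
    by_site = by_site,
    percentages_defined = defined
  ), class = "incidence_summary")
}

#' @export
print.incidence_summary <- function(x, ...) {
  cat(sprintf("Incidence (%s): %d seedlings, %d unidentified, %d species identified\n",
              x$origin, x$n_total, x$n_unidentified, x$n_species_identified))
  print(x$by_status)
  invisible(x)
}

#' Tally wind-trap seed fates and check their additive identities
#'
#' Aggregates a per-site seed-fate record (trapped seeds partitioned into
#' empty, germinated, viable full and non-viable full, with status
#' breakdowns) and verifies every additive identity: the partition must sum
#' to the trapped total per site and overall. Violations are listed in the
#' consistency report, not raised as errors.
#'
#' @param records Seed-fate tibble (see [make_fixture_tables()]):
#'   columns `site`, `trapped`, `empty_nonnative`, `empty_native`,
#'   `empty_unidentified`, `germinated_native`, `germinated_nonnative`,
#'   `full_viable`, `full_nonviable`.
#'
#' @return List with `totals` (named numeric vector including derived
#'   `empty`, `germinated` and `remaining_after_empty`), `consistency`
#'   (tibble `check`, `site`, `ok`) and `consistent` (all checks pass).
#' @export
seed_fate_tally <- function(records) {
  needed <- c("site", "trapped", "empty_nonnative", "empty_native",
              "empty_unidentified", "germinated_native",
              "germinated_nonnative", "full_viable", "full_nonviable")
  if (!all(needed %in% names(records))) {
    stop("seed-fate record lacks columns: ",
         paste(setdiff(needed, names(records)), collapse = ", "), call. = FALSE)
  }
  empty <- with(records, empty_nonnative + empty_native + empty_unidentified)
  germ <- with(records, germinated_native + germinated_nonnative)
  part_ok <- empty + germ + records$full_viable + records$full_nonviable ==
    records$trapped
  consistency <- tibble::tibble(
    check = "empty + germinated + full_viable + full_nonviable == trapped",
    site = records$site,
    ok = part_ok
  )
  totals <- c(
    trapped = sum(records$trapped),
    empty = sum(empty),
    empty_nonnative = sum(records$empty_nonnative),
    empty_native = sum(records$empty_native),
    empty_unidentified = sum(records$empty_unidentified),
    germinated = sum(germ),
    germinated_native = sum(records$germinated_native),
    germinated_nonnative = sum(records$germinated_nonnative),
    full_viable = sum(records$full_viable),
    full_nonviable = sum(records$full_nonviable),
    remaining_after_empty = sum(records$trapped) - sum(empty)
  )
  list(totals = totals, consistency = consistency,
       consistent = all(consistency$ok))
}
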