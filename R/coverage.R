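#' Database-coverage table for selected taxa
#'
#' Distributes the collection's content of each selected taxon among its
#' immediate subtaxa (the next rank down), with optional publication-year
#' and structure-type filters. Each row counts distinct structures (and
#' their share of all structures matching the selected taxa), distinct
#' publications, taxonomically distinct organisms and the total number of
#' per-structure NMR spectra. A final cumulative row counts distinct
#' entities across all rows, so structures shared between subtaxa are not
#' double-counted.
#'
#' @param collection A `glycan_collection`.
#' @param rank Rank of the selected taxa (`domain` ... `species`).
#' @param taxa Character vector of taxon names at `rank`.
#' @param year_range Optional `c(from, to)` filter on publication years; a
#'   structure matches when at least one of its publications falls in the
#'   range, and only those publications are counted.
#' @param structure_type Optional structure-type filter (one of
#'   `mono_oligomer`, `polymer`, `mono_homopolymer`, `cyclic`,
#'   `biological_repeat`).
#' @return A tibble of class `coverage_table` with columns `taxon`,
#'   `subtaxon`, `n_structures`, `structure_share`, `n_publications`,
#'   `n_organisms`, `n_nmr`; the last row (`subtaxon = "(cumulative)"`)
#'   holds the distinct-count totals.
#' @export
#' @examples
#' coll <- generate_collection(simulation_spec(seed = 1))
#' coverage_table(coll, "phylum", "Phylum01")
coverage_table <- function(collection, rank, taxa, year_range = NULL,
                           structure_type = NULL) {
  check_rank(rank)
  if (rank == "strain") rlang::abort("no rank below strain to distribute to")
  if (!is.null(year_range)) {
    if (length(year_range) != 2L || any(is.na(year_range)) ||
        year_range[1] > year_range[2])
      rlang::abort("year_range must be c(from, to) with from <= to")
  }
  if (!is.null(structure_type) && !(structure_type %in% STRUCTURE_TYPES))
    rlang::abort(paste0("unknown structure_type '", structure_type, "'"))
  subrank <- TAXON_RANKS[match(rank, TAXON_RANKS) + 1L]

  keep_ids <- collection$structures$structure_id
  if (!is.null(structure_type))
    keep_ids <- keep_ids[collection$structures$structure_type ==
                           structure_type]
  pubs <- collection$publications
  if (!is.null(year_range))
    pubs <- dplyr::filter(pubs, .data$year >= year_range[1],
                          .data$year <= year_range[2])
  keep_ids <- intersect(keep_ids, unique(pubs$structure_id))

  asg <- collection$assignments |>
    dplyr::filter(.data$structure_id %in% keep_ids,
                  .data[[rank]] %in% taxa, !is.na(.data[[subrank]]))

  empty <- tibble::tibble(taxon = character(), subtaxon = character(),
                          n_structures = integer(),
                          structure_share = numeric(),
                          n_publications = integer(),
                          n_organisms = integer(), n_nmr = integer())
  measure <- function(a) {
    ids <- unique(a$structure_id)
    orgs <- dplyr::distinct(a, dplyr::across(dplyr::all_of(TAXON_RANKS)))
    tibble::tibble(
      n_structures = length(ids),
      n_publications = dplyr::n_distinct(
        pubs$publication_id[pubs$structure_id %in% ids]),
      n_organisms = nrow(orgs),
      n_nmr = sum(collection$structures$nmr_count[
        collection$structures$structure_id %in% ids]))
  }

  if (!nrow(asg)) {
    out <- empty
    total <- 0L
  } else {
    total <- dplyr::n_distinct(asg$structure_id)
    out <- asg |>
      dplyr::group_by(taxon = .data[[rank]], subtaxon = .data[[subrank]]) |>
      dplyr::group_modify(~ measure(.x)) |>
      dplyr::ungroup() |>
      dplyr::mutate(structure_share =
                      round_half_up(.data$n_structures / total * 100),
                    .after = "n_structures") |>
      dplyr::arrange(.data$taxon, .data$subtaxon)
  }
  cum <- if (nrow(asg)) {
    dplyr::bind_cols(tibble::tibble(taxon = "(all)",
                                    subtaxon = "(cumulative)"),
                     measure(asg),
                     tibble::tibble(structure_share = 100)) |>
      dplyr::select(dplyr::all_of(names(empty)))
  } else {
    tibble::tibble(taxon = "(all)", subtaxon = "(cumulative)",
                   n_structures = 0L, structure_share = 0,
                   n_publications = 0L, n_organisms = 0L, n_nmr = 0L)
  }
  res <- dplyr::bind_rows(out, cum)
  class(res) <- c("coverage_table", class(res))
  res
}
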