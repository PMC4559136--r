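# round half up to `digits` (percentages are reported half-up, not banker's)
round_half_up <- function(x, digits = 2) {
  pow <- 10^digits
  floor(x * pow + 0.5) / pow
}

fragments_of_structure <- function(collection, structure_id, arity, opts) {
  i <- match(structure_id, collection$structures$structure_id)
  enumerate_fragments(collection$structures$graph[[i]], arity = arity,
                      opts = opts)
}

# tibble(structure_id, fragment), one row per fragment instance; memoized
# per (structure, arity, option set) in the collection's cache environment
fragment_instances <- function(collection, structure_ids, arity, opts) {
  sig <- paste0("a", arity, ":",
                paste(vapply(opts, as.integer, integer(1)), collapse = ""))
  cache <- collection$cache
  frags <- lapply(structure_ids, function(sid) {
    key <- paste0(sid, "|", sig)
    hit <- cache[[key]]
    if (is.null(hit)) {
      hit <- fragments_of_structure(collection, sid, arity, opts)$fragment
      cache[[key]] <- hit
    }
    hit
  })
  lens <- lengths(frags)
  tibble::tibble(structure_id = rep(structure_ids, lens),
                 fragment = as.character(unlist(frags)))
}

#' Per-taxon fragment abundance table
#'
#' Computes the abundance of monomeric or dimeric fragments in structures
#' assigned to the selected taxa: absolute abundance (instances across
#' matching structures), the ids of structures containing the fragment,
#' relative abundance within the selection (percent of all fragment
#' instances), and the share of selected taxa whose structures contain the
#' fragment (structure-level presence). With a single selected taxon the
#' share is 100 for every row.
#'
#' @param collection A `glycan_collection`.
#' @param rank Rank of the selected taxa.
#' @param taxa Character vector of taxon names at `rank`.
#' @param arity 1 (monomers) or 2 (dimers).
#' @param opts A [filter_options()] object.
#' @return A tibble of class `abundance_table` with columns `fragment`,
#'   `absolute`, `structure_ids` (list), `relative_in_selection`,
#'   `share_of_taxa`, sorted by decreasing abundance then fragment; summary
#'   counts (`n_fragments`, `n_structures`, `n_organisms`) are attached as
#'   attributes and available via [glance()].
#' @export
#' @examples
#' coll <- generate_collection(simulation_spec(seed = 1))
#' tab <- fragment_abundance(coll, "genus", "Genus01_01")
#' head(tab, 3)
fragment_abundance <- function(collection, rank, taxa, arity = 2L,
                               opts = filter_options()) {
  check_rank(rank)
  if (!length(taxa)) rlang::abort("no taxa selected")
  known <- taxa_at_rank(collection, rank)
  bad <- setdiff(taxa, known)
  if (length(bad))
    rlang::abort(paste0("unknown taxa at rank ", rank, ": ",
                        paste(bad, collapse = ", ")))
  by_taxon <- lapply(taxa, function(t) structures_in_taxon(collection, rank, t))
  names(by_taxon) <- taxa
  all_ids <- sort(unique(unlist(by_taxon)))
  inst <- fragment_instances(collection, all_ids, arity, opts)

  if (!nrow(inst)) {
    out <- tibble::tibble(fragment = character(), absolute = integer(),
                          structure_ids = list(),
                          relative_in_selection = numeric(),
                          share_of_taxa = numeric())
  } else {
    total <- nrow(inst)
    out <- inst |>
      dplyr::group_by(.data$fragment) |>
      dplyr::summarise(absolute = dplyr::n(),
                       structure_ids = list(sort(unique(.data$structure_id))),
                       .groups = "drop")
    presence <- vapply(seq_len(nrow(out)), function(k) {
      ids <- out$structure_ids[[k]]
      sum(vapply(by_taxon, function(s) any(ids %in% s), logical(1)))
    }, numeric(1))
    out$relative_in_selection <- round_half_up(out$absolute / total * 100)
    out$share_of_taxa <- round_half_up(presence / length(taxa) * 100)
    out <- dplyr::arrange(out, dplyr::desc(.data$absolute), .data$fragment)
  }
  organisms <- collection$assignments |>
    dplyr::filter(.data$structure_id %in% all_ids) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(TAXON_RANKS)))
  attr(out, "summary") <- tibble::tibble(n_fragments = nrow(out),
                                         n_structures = length(all_ids),
                                         n_organisms = nrow(organisms))
  class(out) <- c("abundance_table", class(out))
  out
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
glance.abundance_table <- function(x, ...) attr(x, "summary")

#' @export
tidy.abundance_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "abundance_table")
  attr(out, "summary") <- NULL
  out
}

#' Fragments unique to a taxon within a scope
#'
#' Fragments occurring at least once in the taxon's structures and never in
#' the rest of the scope: all loaded structures (`all_biota`; note this
#' covers only the domains populated in the collection), or the taxon's
#' kingdom or phylum. Widening the scope can only shrink the result.
#'
#' @inheritParams fragment_abundance
#' @param taxon A single taxon name at `rank`.
#' @param scope `"all_biota"`, `"kingdom"` or `"phylum"`.
#' @return Tibble with columns `fragment` and `absolute` (occurrences inside
#'   the taxon).
#' @export
unique_fragments <- function(collection, rank, taxon,
                             scope = c("all_biota", "kingdom", "phylum"),
                             arity = 2L, opts = filter_options()) {
  scope <- match.arg(scope)
  check_rank(rank)
  inside_ids <- structures_in_taxon(collection, rank, taxon)
  if (!length(inside_ids))
    return(tibble::tibble(fragment = character(), absolute = integer()))
  if (scope == "all_biota") {
    scope_ids <- sort(unique(collection$assignments$structure_id))
  } else {
    if (match(scope, TAXON_RANKS) >= match(rank, TAXON_RANKS))
      rlang::abort(paste0("scope rank '", scope,
                          "' is not above taxon rank '", rank, "'"))
    anc <- collection$assignments |>
      dplyr::filter(.data[[rank]] == taxon) |>
      dplyr::pull(dplyr::all_of(scope)) |>
      unique() |>
      stats::na.omit()
    if (!length(anc))
      rlang::abort(paste0("taxon '", taxon, "' has no ", scope,
                          " in its lineage"))
    scope_ids <- sort(unique(unlist(
      lapply(anc, function(a) structures_in_taxon(collection, scope, a)))))
  }
  inside <- fragment_instances(collection, inside_ids, arity, opts)
  outside <- fragment_instances(collection, setdiff(scope_ids, inside_ids),
                                arity, opts)
  inside |>
    dplyr::count(.data$fragment, name = "absolute") |>
    dplyr::filter(!(.data$fragment %in% outside$fragment)) |>
    dplyr::arrange(dplyr::desc(.data$absolute), .data$fragment)
}

#' Frequency of a fragment within a taxonomic domain
#'
#' Total occurrences of the fragment in structures assigned to the domain,
#' normalized by the number of structures in the domain.
#'
#' @inheritParams fragment_abundance
#' @param fragment A fragment key as produced by [enumerate_fragments()]
#'   under the same `opts`.
#' @param domain Domain name.
#' @return A single ratio (occurrences per structure).
#' @export
domain_frequency <- function(collection, fragment, domain, arity = 2L,
                             opts = filter_options()) {
  ids <- structures_in_taxon(collection, "domain", domain)
  if (!length(ids))
    rlang::abort(paste0("domain '", domain, "' is not populated"))
  inst <- fragment_instances(collection, ids, arity, opts)
  sum(inst$fragment == fragment) / length(ids)
}
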