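#' @keywords internal
TAXON_RANKS <- c("domain", "kingdom", "phylum", "class", "genus", "species",
                 "strain")

#' @keywords internal
STRUCTURE_TYPES <- c("mono_oligomer", "polymer", "mono_homopolymer", "cyclic",
                     "biological_repeat")

#' Default grouping of taxonomic domains into database partitions
#'
#' Stands in for the bacterial vs plant-and-fungal split of the source
#' collections: relative population thresholds and "database" denominators
#' are computed within the group holding the taxon's domain. Domains not
#' listed form singleton groups.
#'
#' @return Named list of character vectors of domain names.
#' @export
default_domain_groups <- function() {
  list(bacterial = c("Bacteria", "Archaea", "Protista"),
       plant_fungal = c("Plants", "Fungi", "Algae"))
}

new_collection <- function(structures, assignments, publications,
                           domain_groups = default_domain_groups()) {
  structure(list(structures = structures, assignments = assignments,
                 publications = publications, domain_groups = domain_groups,
                 cache = new.env(parent = emptyenv())),
            class = "glycan_collection")
}

#' @export
print.glycan_collection <- function(x, ...) {
  cat(sprintf(paste0("<glycan_collection: %d structures, %d taxon ",
                     "assignments, %d publication links>\n"),
              nrow(x$structures), nrow(x$assignments), nrow(x$publications)))
  doms <- unique(x$assignments$domain)
  cat("  domains:", paste(doms, collapse = ", "), "\n")
  invisible(x)
}

parse_lineage <- function(lineage, row = NA_integer_) {
  out <- stats::setNames(rep(NA_character_, length(TAXON_RANKS)), TAXON_RANKS)
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  for (p in parts) {
    p <- trimws(p)
    if (!nchar(p)) next
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L || !(trimws(kv[1]) %in% TAXON_RANKS))
      rlang::abort(sprintf("malformed lineage entry '%s' (row %s)", p, row),
                   class = "glycotaxa_dump_error")
    out[[trimws(kv[1])]] <- trimws(kv[2])
  }
  if (is.na(out[["domain"]]))
    rlang::abort(sprintf("lineage without domain (row %s)", row),
                 class = "glycotaxa_dump_error")
  out
}

#' Read a structure-collection dump
#'
#' Reads the package's tab-separated dump format: one row per (structure,
#' organism, publication) with header columns `structure_id`, `notation`,
#' `lineage` (semicolon-separated `rank=name` pairs), `year`, `nmr_count`,
#' `structure_type`, and optionally `publication_id`. Rows sharing a
#' `structure_id` merge into one record; when `publication_id` is absent a
#' publication is derived per (structure, year). Notations are parsed once
#' per structure; malformed rows raise an error naming the row.
#'
#' @param path Path to a TSV file.
#' @param vocab Residue vocabulary passed to [parse_csdb()].
#' @param domain_groups See [default_domain_groups()].
#' @return A `glycan_collection`.
#' @export
read_dump <- function(path, vocab = csdb_vocabulary(),
                      domain_groups = default_domain_groups()) {
  if (!file.exists(path))
    rlang::abort(paste0("dump file not found: ", path),
                 class = "glycotaxa_missing_input")
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("structure_id", "notation", "lineage", "year", "nmr_count",
                "structure_type")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    rlang::abort(paste0("dump is missing columns: ",
                        paste(missing_cols, collapse = ", ")),
                 class = "glycotaxa_dump_error")
  if (!"publication_id" %in% names(raw))
    raw$publication_id <- paste0(raw$structure_id, "@", raw$year)
  build_collection_from_rows(raw, vocab, domain_groups)
}

build_collection_from_rows <- function(raw, vocab = csdb_vocabulary(),
                                       domain_groups = default_domain_groups()) {
  raw$year <- suppressWarnings(as.integer(raw$year))
  raw$nmr_count <- suppressWarnings(as.integer(raw$nmr_count))
  for (i in seq_len(nrow(raw))) {
    if (is.na(raw$year[i]) || raw$year[i] < 1900 || raw$year[i] > 2100)
      rlang::abort(sprintf("invalid year (row %d)", i),
                   class = "glycotaxa_dump_error")
    if (is.na(raw$nmr_count[i]) || raw$nmr_count[i] < 0)
      rlang::abort(sprintf("invalid nmr_count (row %d)", i),
                   class = "glycotaxa_dump_error")
    if (!(raw$structure_type[i] %in% STRUCTURE_TYPES))
      rlang::abort(sprintf("unknown structure_type '%s' (row %d)",
                           raw$structure_type[i], i),
                   class = "glycotaxa_dump_error")
  }
  consistent <- raw |>
    dplyr::distinct(.data$structure_id, .data$notation,
                    .data$structure_type, .data$nmr_count) |>
    dplyr::count(.data$structure_id)
  if (any(consistent$n > 1L))
    rlang::abort(paste0("conflicting notation/type/nmr_count for structure ",
                        consistent$structure_id[consistent$n > 1L][1]),
                 class = "glycotaxa_dump_error")

  structures <- raw |>
    dplyr::distinct(.data$structure_id, .data$notation, .data$structure_type,
                    .data$nmr_count) |>
    dplyr::arrange(.data$structure_id)
  graphs <- vector("list", nrow(structures))
  notation_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(structures))) {
    key <- structures$notation[i]
    if (is.null(notation_cache[[key]])) {
      row_of <- which(raw$structure_id == structures$structure_id[i])[1]
      notation_cache[[key]] <- tryCatch(
        parse_csdb(key, vocab = vocab),
        error = function(e) rlang::abort(
          sprintf("cannot parse notation of structure %s (row %d): %s",
                  structures$structure_id[i], row_of, conditionMessage(e)),
          class = "glycotaxa_dump_error"))
    }
    graphs[[i]] <- notation_cache[[key]]
  }
  structures$graph <- graphs

  lineages <- purrr::map2_dfr(raw$lineage, seq_len(nrow(raw)), function(l, i) {
    tibble::as_tibble_row(parse_lineage(l, row = i))
  })
  if (!nrow(lineages))
    lineages <- tibble::as_tibble(stats::setNames(
      rep(list(character()), length(TAXON_RANKS)), TAXON_RANKS))
  assignments <- dplyr::bind_cols(
    tibble::tibble(structure_id = raw$structure_id), lineages) |>
    dplyr::distinct() |>
    dplyr::arrange(dplyr::across(dplyr::everything()))
  publications <- raw |>
    dplyr::distinct(.data$structure_id, publication_id = .data$publication_id,
                    .data$year) |>
    dplyr::arrange(.data$structure_id, .data$publication_id)

  new_collection(structures, assignments, publications, domain_groups)
}

#' Write a structure-collection dump
#'
#' Inverse of [read_dump()]: expands the collection back to one row per
#' (structure, organism, publication) in a deterministic order, so that
#' identical collections produce byte-identical dumps and
#' `read_dump(write_dump(x))` equals `x`.
#'
#' @param collection A `glycan_collection`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dump <- function(collection, path) {
  stopifnot(inherits(collection, "glycan_collection"))
  asg <- collection$assignments
  lineage <- vapply(seq_len(nrow(asg)), function(i) {
    vals <- unlist(asg[i, TAXON_RANKS])
    keep <- !is.na(vals)
    paste(paste0(TAXON_RANKS[keep], "=", vals[keep]), collapse = ";")
  }, character(1))
  rows <- tibble::tibble(structure_id = asg$structure_id, lineage = lineage) |>
    dplyr::inner_join(collection$publications, by = "structure_id",
                      relationship = "many-to-many") |>
    dplyr::inner_join(
      dplyr::select(collection$structures, "structure_id", "notation",
                    "structure_type", "nmr_count"),
      by = "structure_id") |>
    dplyr::select("structure_id", "notation", "lineage", "year", "nmr_count",
                  "structure_type", "publication_id") |>
    dplyr::arrange(.data$structure_id, .data$lineage, .data$publication_id)
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

check_rank <- function(rank) {
  if (!(rank %in% TAXON_RANKS))
    rlang::abort(paste0("unknown rank '", rank, "'; expected one of ",
                        paste(TAXON_RANKS, collapse = ", ")))
  rank
}

#' Taxa present in a collection at a rank
#'
#' @param collection A `glycan_collection`.
#' @param rank A taxonomic rank (`domain` ... `strain`).
#' @return Sorted character vector of taxon names populated at that rank.
#' @export
taxa_at_rank <- function(collection, rank) {
  check_rank(rank)
  sort(unique(stats::na.omit(collection$assignments[[rank]])))
}

#' Structure ids assigned to a taxon (or any subtaxon)
#'
#' @inheritParams taxa_at_rank
#' @param taxon Taxon name at `rank`.
#' @return Character vector of distinct structure ids.
#' @export
structures_in_taxon <- function(collection, rank, taxon) {
  check_rank(rank)
  hits <- collection$assignments[[rank]] == taxon
  sort(unique(collection$assignments$structure_id[!is.na(hits) & hits]))
}

#' Population of a taxon
#'
#' The number of distinct structures assigned to organisms belonging to the
#' taxon or its subtaxa. A structure assigned to several organisms within
#' the taxon counts once (set semantics).
#'
#' @inheritParams structures_in_taxon
#' @return Integer count.
#' @export
population <- function(collection, rank, taxon) {
  check_rank(rank)
  if (!(taxon %in% taxa_at_rank(collection, rank)))
    rlang::abort(paste0("unknown taxon '", taxon, "' at rank ", rank))
  length(structures_in_taxon(collection, rank, taxon))
}

# database-partition group of a domain name
domain_group_of <- function(collection, domain) {
  for (g in names(collection$domain_groups)) {
    if (domain %in% collection$domain_groups[[g]]) return(g)
  }
  domain
}

# distinct structure ids in the database partition holding `domain`
structures_in_domain_group <- function(collection, domain) {
  grp <- domain_group_of(collection, domain)
  doms <- vapply(collection$assignments$domain, domain_group_of,
                 character(1), collection = collection)
  sort(unique(collection$assignments$structure_id[doms == grp]))
}

#' Compare two collections for equality of content
#'
#' @param a,b `glycan_collection` objects.
#' @return `TRUE` or `FALSE`.
#' @export
collections_equal <- function(a, b) {
  strip <- function(x) {
    s <- dplyr::select(x$structures, -"graph")
    list(structures = s[order(s$structure_id), ],
         assignments = dplyr::arrange(x$assignments,
                                      dplyr::across(dplyr::everything())),
         publications = dplyr::arrange(x$publications,
                                       dplyr::across(dplyr::everything())))
  }
  isTRUE(all.equal(strip(a), strip(b), check.attributes = FALSE))
}
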