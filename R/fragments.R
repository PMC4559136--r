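#' Residue filter options for fragment enumeration
#'
#' Controls which residues enter fragment statistics and how residue
#' identities are canonicalized. These mirror the residue filters of the
#' fragment-abundance and clustering tools: anomer combining, handling of
#' underdetermined residues (spellings carrying `?`), monovalent
#' substituents, aglycons, aliases/superclasses, and optional annotation of
#' fragments with their position class and branching degree.
#'
#' `only_saccharides = TRUE` restricts fragments to monosaccharide residues
#' and therefore forces `include_monovalent = FALSE`; asking for both is an
#' error (the two filters are interdependent). `include_undefined_configs`
#' and `exclude_underdetermined` are the same filter seen from the two tools'
#' opposite defaults; a residue with an explicit `?` is dropped when either
#' requests it. `strict_comparison` is always on: `?DGalp` never matches
#' `bDGalp`.
#'
#' @param combine_anomers Treat anomeric forms of a residue as one entity
#'   (`aDGlcp` and `bDGlcp` both become `DGlcp`).
#' @param include_undefined_configs Keep residues with explicit unknown
#'   configurations (`?Kdop`, `b?Fucp`, `?DGal?`).
#' @param only_saccharides Keep monosaccharide residues only.
#' @param include_monovalent Keep monovalent substituents (Ac, Me, P, S, ...).
#' @param include_aglycons Keep aglycon residues.
#' @param include_aliases Keep alias (`Subst...`) and superclass (`LIP`,
#'   `HEX`, ...) residues.
#' @param explain_subst Replace alias residues by their declared explanation
#'   (`Subst1` becomes e.g. `2,5-diaminopentanoic acid`); otherwise aliases
#'   are pooled by their alias name.
#' @param distinguish_position Annotate fragments with the position class of
#'   the residue (terminal / inline / reducing; for dimers, of the acceptor).
#' @param distinguish_branching Annotate fragments with the branching degree.
#' @param count_monovalent_in_branching Count monovalent substituents when
#'   computing branching degrees.
#' @param exclude_underdetermined Drop residues with explicit unknown
#'   configurations.
#' @param exclude_superclasses Drop alias and superclass residues.
#' @param strict_comparison Always `TRUE`; configurations compare strictly.
#'
#' @return A list of class `filter_options`.
#' @export
#' @examples
#' filter_options(only_saccharides = TRUE)
filter_options <- function(combine_anomers = FALSE,
                           include_undefined_configs = TRUE,
                           only_saccharides = FALSE,
                           include_monovalent = TRUE,
                           include_aglycons = TRUE,
                           include_aliases = TRUE,
                           explain_subst = FALSE,
                           distinguish_position = FALSE,
                           distinguish_branching = FALSE,
                           count_monovalent_in_branching = TRUE,
                           exclude_underdetermined = FALSE,
                           exclude_superclasses = FALSE,
                           strict_comparison = TRUE) {
  if (!strict_comparison)
    rlang::abort("strict_comparison is always enabled")
  if (only_saccharides && !missing(include_monovalent) && include_monovalent)
    rlang::abort(paste0("only_saccharides and include_monovalent are ",
                        "mutually exclusive"))
  if (only_saccharides) include_monovalent <- FALSE
  opts <- list(combine_anomers = combine_anomers,
               include_undefined_configs = include_undefined_configs,
               only_saccharides = only_saccharides,
               include_monovalent = include_monovalent,
               include_aglycons = include_aglycons,
               include_aliases = include_aliases,
               explain_subst = explain_subst,
               distinguish_position = distinguish_position,
               distinguish_branching = distinguish_branching,
               count_monovalent_in_branching = count_monovalent_in_branching,
               exclude_underdetermined = exclude_underdetermined,
               exclude_superclasses = exclude_superclasses,
               strict_comparison = TRUE)
  stopifnot(all(vapply(opts, is.logical, logical(1))))
  structure(opts, class = "filter_options")
}

#' Canonical residue key under filter options
#'
#' Maps a residue of a parsed graph to its canonical text identity, or to
#' `NA` when the active filters exclude it: monovalent residues when
#' excluded, aglycons when excluded, aliases/superclasses when excluded, and
#' monosaccharides with an explicit `?` when underdetermined residues are
#' excluded. With `combine_anomers` the anomeric prefix is dropped; with
#' `explain_subst` a declared alias is replaced by its explanation.
#'
#' @param graph A `glycan_graph`.
#' @param node Residue index in `graph$residues`.
#' @param opts A [filter_options()] object.
#' @return A character key, or `NA_character_` when the residue is excluded.
#' @export
residue_key <- function(graph, node, opts = filter_options()) {
  residue_keys(graph, opts)[node]
}

# vectorized residue keys for all nodes of a graph (NA = excluded)
residue_keys <- function(graph, opts) {
  r <- graph$residues
  cls <- r$residue_class
  key <- r$token
  # aliases may be renamed before exclusion checks
  if (opts$explain_subst) {
    ren <- cls == "alias" & !is.na(r$alias_value)
    key[ren] <- r$alias_value[ren]
  }
  # anomer combining for monosaccharides
  comb <- opts$combine_anomers & cls == "monosaccharide" & nchar(r$anomer) > 0
  key[comb] <- substr(r$token[comb], 2, nchar(r$token[comb]))
  drop <- rep(FALSE, nrow(r))
  drop[cls == "monovalent" & (!opts$include_monovalent ||
                                opts$only_saccharides)] <- TRUE
  drop[cls == "aglycon" & (!opts$include_aglycons ||
                             opts$only_saccharides)] <- TRUE
  drop[cls %in% c("alias", "superclass") &
         (!opts$include_aliases || opts$exclude_superclasses ||
            opts$only_saccharides)] <- TRUE
  underdetermined <- cls == "monosaccharide" & grepl("?", key, fixed = TRUE)
  drop[underdetermined & (opts$exclude_underdetermined ||
                            !opts$include_undefined_configs)] <- TRUE
  key[drop] <- NA_character_
  key
}

#' Branching degree of a residue
#'
#' The number of substituents of a residue, excluding its own acceptor
#' linkage at the anomeric (or default) center; monovalent substituents are
#' counted or not according to `count_monovalent`. In
#' `Gal(1-3)GlcNAc(1-2)Man` the `GlcN` residue is di-branched (2) with
#' monovalent residues counted and linear (1) without.
#'
#' @param graph A `glycan_graph`.
#' @param node Residue index.
#' @param count_monovalent Count monovalent substituents?
#' @return Non-negative integer.
#' @export
branching_degree <- function(graph, node, count_monovalent = TRUE) {
  inc <- incoming_edges(graph, node)
  if (!count_monovalent) {
    keep <- graph$residues$residue_class[inc$donor] != "monovalent"
    inc <- inc[keep, , drop = FALSE]
  }
  nrow(inc)
}

#' Position class of a residue
#'
#' `reducing` for the root residue (reducing end or aglycon side), `terminal`
#' for a residue carrying no non-monovalent substituents, `inline` otherwise.
#' In a polymer repeating unit the endpoints of the wrap-around linkage are
#' classified `inline` by convention.
#'
#' @inheritParams branching_degree
#' @return One of `"terminal"`, `"inline"`, `"reducing"`.
#' @export
position_class <- function(graph, node) {
  if (graph$topology_kind == "polymer_repeat") {
    wrap <- dplyr::filter(graph$edges, .data$wrap)
    if (node %in% c(wrap$donor, wrap$acceptor)) return("inline")
  }
  if (node == graph$root) return("reducing")
  if (branching_degree(graph, node, count_monovalent = FALSE) == 0L)
    return("terminal")
  "inline"
}

annotate_key <- function(key, graph, node, opts) {
  if (opts$distinguish_position)
    key <- paste0(key, "|", position_class(graph, node))
  if (opts$distinguish_branching)
    key <- paste0(key, "|br", branching_degree(
      graph, node, count_monovalent = opts$count_monovalent_in_branching))
  key
}

#' Enumerate monomeric fragments of a structure
#'
#' One fragment per residue surviving the active filters, with multiplicity
#' preserved (one row per instance). When position or branching annotation is
#' requested the annotation is folded into the fragment key.
#'
#' @param graph A `glycan_graph`.
#' @param opts A [filter_options()] object.
#' @return A tibble with columns `fragment`, `arity` (1), `donor`, `linkage`
#'   (`NA`), `acceptor` (`NA`), one row per fragment instance.
#' @export
#' @examples
#' g <- parse_csdb("Gal(1-3)GlcNAc(1-2)Man")
#' enumerate_monomers(g, filter_options(only_saccharides = TRUE))$fragment
enumerate_monomers <- function(graph, opts = filter_options()) {
  keys <- residue_keys(graph, opts)
  keep <- which(!is.na(keys))
  frag <- keys[keep]
  if (opts$distinguish_position || opts$distinguish_branching) {
    frag <- vapply(seq_along(keep), function(k)
      annotate_key(frag[k], graph, keep[k], opts), character(1))
  }
  tibble::tibble(fragment = frag, arity = rep(1L, length(keep)),
                 donor = keys[keep],
                 linkage = rep(NA_character_, length(keep)),
                 acceptor = rep(NA_character_, length(keep)))
}

#' Enumerate dimeric fragments of a structure
#'
#' One fragment per linkage whose donor and acceptor both survive the active
#' filters; the wrap-around linkage of a polymer repeating unit is counted
#' once. Fragments render as CSDB dimer text `donor(d-a)acceptor` (or
#' `donor-a)acceptor` for single-attachment-center donors). Position class
#' annotation, when requested, is taken from the acceptor residue.
#'
#' @inheritParams enumerate_monomers
#' @return A tibble with columns `fragment`, `arity` (2), `donor`, `linkage`,
#'   `acceptor`, one row per fragment instance.
#' @export
#' @examples
#' g <- parse_csdb("Gal(1-3)GlcNAc(1-2)Man")
#' enumerate_dimers(g, filter_options(only_saccharides = TRUE))$fragment
enumerate_dimers <- function(graph, opts = filter_options()) {
  keys <- residue_keys(graph, opts)
  e <- graph$edges
  dk <- keys[e$donor]
  ak <- keys[e$acceptor]
  keep <- which(!is.na(dk) & !is.na(ak))
  lk <- ifelse(is.na(e$donor_pos[keep]),
               paste0("-", e$acceptor_pos[keep], ")"),
               paste0("(", e$donor_pos[keep], "-", e$acceptor_pos[keep],
                      ")"))
  lk <- as.character(lk)
  frag <- paste0(dk[keep], lk, ak[keep])
  if (opts$distinguish_position)
    frag <- paste0(frag, "|", vapply(e$acceptor[keep], function(n)
      position_class(graph, n), character(1)))
  if (opts$distinguish_branching)
    frag <- paste0(frag, "|br", vapply(e$acceptor[keep], function(n)
      branching_degree(graph, n,
                       count_monovalent = opts$count_monovalent_in_branching),
      integer(1)))
  tibble::tibble(fragment = frag, arity = rep(2L, length(keep)),
                 donor = dk[keep], linkage = lk, acceptor = ak[keep])
}

#' Enumerate fragments of either arity
#'
#' @inheritParams enumerate_monomers
#' @param arity 1 for monomers, 2 for dimers.
#' @return See [enumerate_monomers()] / [enumerate_dimers()].
#' @export
enumerate_fragments <- function(graph, arity = 2L, opts = filter_options()) {
  arity <- as.integer(arity)
  stopifnot(arity %in% c(1L, 2L))
  if (arity == 1L) enumerate_monomers(graph, opts)
  else enumerate_dimers(graph, opts)
}
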