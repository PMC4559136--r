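#' Thresholds for the taxon/fragment pools and occurrence codes
#'
#' Bundles the tunable parameters of the glycome clustering pipeline. The
#' defaults are the values used for the package's reference analyses: a
#' fragment must occur at least 120 times (`fragment_min_instances`) in at
#' least 100 structures (`fragment_min_structures`) to enter the fragment
#' pool; a fragment is qualified as present in a taxon when it occurs at
#' least `presence_threshold = 2` times in the taxon's structures; the
#' species-level taxon pool uses an absolute population minimum of 20
#' structures and the genus-level pool a relative minimum of 1.2% of the
#' taxon's database partition. Since a structure may contain several
#' identical fragments, `fragment_min_instances` should not be lower than
#' `fragment_min_structures` (equality triggers a warning).
#'
#' @param population_abs_min Minimal number of structures assigned to a
#'   taxon (used when `use_abs`).
#' @param population_rel_min Minimal population as a fraction of all
#'   structures in the taxon's database partition (used when `use_rel`).
#' @param use_abs,use_rel Which population thresholds to apply (both may be
#'   used simultaneously).
#' @param fragment_min_structures Minimal number of structures containing a
#'   fragment.
#' @param fragment_min_instances Minimal number of fragment instances over
#'   all structures.
#' @param presence_threshold Minimal occurrences of a fragment within a
#'   taxon to set its profile bit.
#' @param fragment_arity 1 (monomers) or 2 (dimers).
#' @param structure_scope `"any"`, `"only_polymers"`, `"only_oligomers"` or
#'   `"optimized"` (polymers for bacteria, fungi and archaea; oligomers for
#'   other domains).
#' @return A list of class `pool_thresholds`.
#' @export
pool_thresholds <- function(population_abs_min = 20L,
                            population_rel_min = 0.012,
                            use_abs = TRUE,
                            use_rel = FALSE,
                            fragment_min_structures = 100L,
                            fragment_min_instances = 120L,
                            presence_threshold = 2L,
                            fragment_arity = 2L,
                            structure_scope = c("any", "only_polymers",
                                                "only_oligomers",
                                                "optimized")) {
  structure_scope <- match.arg(structure_scope)
  stopifnot(population_abs_min >= 0, population_rel_min >= 0,
            population_rel_min <= 1, fragment_min_structures >= 1,
            fragment_min_instances >= 1, presence_threshold >= 1,
            fragment_arity %in% c(1L, 2L))
  if (fragment_min_instances < fragment_min_structures)
    rlang::abort(paste0("fragment_min_instances must be >= ",
                        "fragment_min_structures"))
  if (fragment_min_instances == fragment_min_structures)
    rlang::warn(paste0("fragment_min_instances equals ",
                       "fragment_min_structures; the instance threshold is ",
                       "usually set higher"))
  structure(list(population_abs_min = as.integer(population_abs_min),
                 population_rel_min = population_rel_min,
                 use_abs = use_abs, use_rel = use_rel,
                 fragment_min_structures = as.integer(fragment_min_structures),
                 fragment_min_instances = as.integer(fragment_min_instances),
                 presence_threshold = as.integer(presence_threshold),
                 fragment_arity = as.integer(fragment_arity),
                 structure_scope = structure_scope),
            class = "pool_thresholds")
}

empty_pool_error <- function(msg) {
  rlang::abort(msg, class = "glycotaxa_empty_pool")
}

# structure ids surviving the structure-type scope
scoped_structure_ids <- function(collection, structure_scope) {
  st <- collection$structures
  polymer_types <- c("polymer", "mono_homopolymer", "cyclic",
                     "biological_repeat")
  if (structure_scope == "any") return(st$structure_id)
  if (structure_scope == "only_polymers")
    return(st$structure_id[st$structure_type %in% polymer_types])
  if (structure_scope == "only_oligomers")
    return(st$structure_id[st$structure_type == "mono_oligomer"])
  # optimized: polymers from bacteria, fungi and archaea; oligomers otherwise
  poly_domains <- c("Bacteria", "Fungi", "Archaea")
  doms <- collection$assignments |>
    dplyr::distinct(.data$structure_id, .data$domain)
  wants_poly <- doms$structure_id[doms$domain %in% poly_domains]
  is_poly <- st$structure_id[st$structure_type %in% polymer_types]
  is_olig <- st$structure_id[st$structure_type == "mono_oligomer"]
  union(intersect(wants_poly, is_poly),
        intersect(setdiff(st$structure_id, wants_poly), is_olig))
}

#' Build the taxon pool
#'
#' Taxa at the given rank (optionally within a scope taxon) whose population
#' passes the active thresholds. The relative threshold divides the
#' population by the number of structures in the database partition holding
#' the taxon's domain. An explicit list bypasses the thresholds.
#'
#' @param collection A `glycan_collection`.
#' @param rank Rank of the compared taxa.
#' @param thresholds A [pool_thresholds()] object.
#' @param scope Optional `list(rank =, taxon =)` restricting candidates to
#'   one higher-rank taxon.
#' @param explicit_list Optional character vector of taxon names to use
#'   as-is.
#' @return Tibble with columns `taxon` and `n_structures`, sorted by taxon.
#' @export
build_taxon_pool <- function(collection, rank, thresholds = pool_thresholds(),
                             scope = NULL, explicit_list = NULL) {
  check_rank(rank)
  candidates <- taxa_at_rank(collection, rank)
  if (!is.null(scope)) {
    asg <- dplyr::filter(collection$assignments,
                         .data[[scope$rank]] == scope$taxon)
    candidates <- intersect(candidates,
                            unique(stats::na.omit(asg[[rank]])))
  }
  if (!is.null(explicit_list)) {
    missing_taxa <- setdiff(explicit_list, candidates)
    if (length(missing_taxa))
      rlang::abort(paste0("taxa not in collection: ",
                          paste(missing_taxa, collapse = ", ")))
    candidates <- explicit_list
  }
  pool <- tibble::tibble(
    taxon = candidates,
    n_structures = vapply(candidates, function(t)
      population(collection, rank, t), integer(1)))
  if (is.null(explicit_list)) {
    if (thresholds$use_abs)
      pool <- dplyr::filter(pool,
                            .data$n_structures >= thresholds$population_abs_min)
    if (thresholds$use_rel) {
      denom <- vapply(pool$taxon, function(t) {
        dom <- collection$assignments |>
          dplyr::filter(.data[[rank]] == t) |>
          dplyr::pull("domain")
        length(structures_in_domain_group(collection, dom[1]))
      }, numeric(1))
      pool <- dplyr::filter(pool,
                            .data$n_structures / denom >=
                              thresholds$population_rel_min)
    }
  }
  if (!nrow(pool))
    empty_pool_error(paste0("empty taxon pool at rank ", rank,
                            "; lower the population thresholds"))
  dplyr::arrange(pool, .data$taxon)
}

#' Build the fragment pool
#'
#' All fragments observed in the scoped structures that occur in at least
#' `fragment_min_structures` structures with at least
#' `fragment_min_instances` instances in total, in a deterministic
#' (lexicographic, C-locale) order.
#'
#' @inheritParams build_taxon_pool
#' @param opts A [filter_options()] object controlling residue filtering.
#' @return Tibble with columns `fragment`, `n_structures`, `n_instances`.
#' @export
build_fragment_pool <- function(collection, thresholds = pool_thresholds(),
                                opts = filter_options()) {
  ids <- scoped_structure_ids(collection, thresholds$structure_scope)
  inst <- fragment_instances(collection, ids, thresholds$fragment_arity, opts)
  if (!nrow(inst)) empty_pool_error("no fragments observed in scope")
  pool <- inst |>
    dplyr::group_by(.data$fragment) |>
    dplyr::summarise(n_structures = dplyr::n_distinct(.data$structure_id),
                     n_instances = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_structures >= thresholds$fragment_min_structures,
                  .data$n_instances >= thresholds$fragment_min_instances)
  if (!nrow(pool))
    empty_pool_error("empty fragment pool; lower the abundance thresholds")
  pool[order(pool$fragment, method = "radix"), ]
}

#' Binary occurrence code (glycoprofile) of a taxon
#'
#' For every fragment of the pool, the profile bit is 1 exactly when the
#' fragment occurs at least `presence_threshold` times across the taxon's
#' scoped structures. These binary profiles follow the phylogenetic-profile
#' idea: each fragment owns one bit position shared by all taxa.
#'
#' @inheritParams build_taxon_pool
#' @param taxon A taxon name at `rank`.
#' @param fragment_pool Tibble from [build_fragment_pool()] (or any tibble
#'   with a `fragment` column defining the bit order).
#' @param opts The [filter_options()] used to build the pool.
#' @return An object of class `occurrence_profile`: list with `taxon`,
#'   `rank`, `bits` (named 0/1 integer vector over the pool) and
#'   `n_structures` (number of scoped structures profiled).
#' @export
occurrence_code <- function(collection, rank, taxon, fragment_pool,
                            thresholds = pool_thresholds(),
                            opts = filter_options()) {
  if (!nrow(fragment_pool)) empty_pool_error("empty fragment pool")
  ids <- intersect(structures_in_taxon(collection, rank, taxon),
                   scoped_structure_ids(collection,
                                        thresholds$structure_scope))
  inst <- fragment_instances(collection, ids, thresholds$fragment_arity, opts)
  counts <- table(factor(inst$fragment, levels = fragment_pool$fragment))
  bits <- as.integer(counts >= thresholds$presence_threshold)
  names(bits) <- fragment_pool$fragment
  structure(list(taxon = taxon, rank = rank, bits = bits,
                 n_structures = length(ids)),
            class = "occurrence_profile")
}

#' @export
print.occurrence_profile <- function(x, ...) {
  cat(sprintf("<occurrence_profile %s [%s]: %d/%d bits set, %d structures>\n",
              x$taxon, x$rank, sum(x$bits), length(x$bits), x$n_structures))
  invisible(x)
}

#' Hamming distance between two occurrence profiles
#'
#' The number of bit inversions required to convert one profile into the
#' other.
#'
#' @param a,b `occurrence_profile` objects (or plain 0/1 vectors) of equal
#'   length.
#' @return Integer count of differing positions.
#' @export
hamming <- function(a, b) {
  xa <- if (inherits(a, "occurrence_profile")) a$bits else a
  xb <- if (inherits(b, "occurrence_profile")) b$bits else b
  if (length(xa) != length(xb))
    rlang::abort("occurrence codes have different lengths")
  sum(xa != xb)
}

#' Normalized taxon dissimilarity matrix
#'
#' Pairwise Hamming distances between occurrence codes, each cell divided by
#' the total number of structures assigned to the two taxa of that cell (to
#' remove study-degree bias), then the whole matrix rescaled so its maximum
#' equals 100 (for compatibility with clustering software). If all profiles
#' are identical the matrix is returned unscaled with a warning.
#'
#' @param profiles List of `occurrence_profile` objects (equal bit lengths).
#' @return A symmetric numeric matrix of class `glyco_dissimilarity` with
#'   taxon labels, zero diagonal and attributes `scaled` (logical) and
#'   `n_structures` (named per-taxon counts).
#' @export
dissimilarity_matrix <- function(profiles) {
  if (length(profiles) < 2L)
    rlang::abort("need at least two profiles")
  labels <- vapply(profiles, function(p) p$taxon, character(1))
  if (anyDuplicated(labels))
    rlang::abort("duplicated taxon labels in profiles")
  n <- length(profiles)
  ns <- vapply(profiles, function(p) p$n_structures, numeric(1))
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      h <- hamming(profiles[[i]], profiles[[j]])
      d <- if (h == 0) 0 else h / (ns[i] + ns[j])
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  mx <- max(m)
  scaled <- mx > 0
  if (scaled) {
    m <- m * (100 / mx)
  } else {
    rlang::warn("all profiles identical; matrix left unscaled")
  }
  structure(m, scaled = scaled,
            n_structures = stats::setNames(ns, labels),
            class = c("glyco_dissimilarity", "matrix", "array"))
}

#' @export
print.glyco_dissimilarity <- function(x, ...) {
  cat(sprintf("<glyco_dissimilarity: %d taxa, %s>\n", nrow(x),
              if (isTRUE(attr(x, "scaled"))) "scaled to max 100"
              else "unscaled"))
  print(round(unclass(x)[, , drop = FALSE], 2), ...)
  invisible(x)
}

#' @export
tidy.glyco_dissimilarity <- function(x, ...) {
  m <- unclass(x)
  labels <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(taxon1 = labels[idx[, 1]], taxon2 = labels[idx[, 2]],
                 distance = m[idx])
}

as_dist <- function(D) {
  stats::as.dist(unclass(D))
}

#' Hierarchical (rooted) cluster tree from a dissimilarity matrix
#'
#' Agglomerative clustering with average linkage (UPGMA), complete linkage,
#' or Ward's minimum-variance criterion on squared dissimilarities
#' (`ward_d2`, the `ward.D2` variant). UPGMA trees are ultrametric.
#'
#' @param D A `glyco_dissimilarity` (or plain symmetric matrix).
#' @param method `"upgma"`, `"complete"` or `"ward_d2"`.
#' @return A rooted `phylo` tree (with the underlying `hclust` object in
#'   attribute `"hclust"` for cluster cutting).
#' @export
hierarchical_tree <- function(D, method = c("upgma", "complete", "ward_d2")) {
  method <- match.arg(method)
  if (nrow(as.matrix(unclass(D))) < 2L)
    rlang::abort("need at least two taxa")
  hc <- stats::hclust(as_dist(D),
                      method = c(upgma = "average", complete = "complete",
                                 ward_d2 = "ward.D2")[[method]])
  tree <- ape::as.phylo(hc)
  attr(tree, "hclust") <- hc
  tree
}

#' Cut a hierarchical tree into k clusters
#'
#' @param tree A tree returned by [hierarchical_tree()].
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_tree_clusters <- function(tree, k) {
  hc <- attr(tree, "hclust")
  if (is.null(hc))
    rlang::abort("tree was not produced by hierarchical_tree()")
  stats::cutree(hc, k = k)
}

#' Neighbor-joining tree from a dissimilarity matrix
#'
#' Classical neighbor joining or its variance-aware BIONJ variant, which at
#' every agglomeration step chooses the reduction minimizing the variance of
#' the new distance matrix. On additive matrices both reconstruct the
#' generating tree exactly (path lengths to within 1e-9); branch lengths may
#' be negative. The BIONJ agglomeration is computed in double precision with
#' a deterministic tie-break (first minimal pair in row-major order).
#'
#' @inheritParams hierarchical_tree
#' @param variant `"nj"` or `"bionj"`.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(D, variant = c("nj", "bionj")) {
  variant <- match.arg(variant)
  m <- as.matrix(unclass(D))
  if (nrow(m) < 3L) rlang::abort("neighbor joining needs at least 3 taxa")
  if (variant == "nj") ape::nj(as_dist(D)) else bionj_impl(m)
}

# BIONJ agglomeration (variance-weighted neighbor joining) in double
# precision; builds the Newick text with full-precision branch lengths
bionj_impl <- function(D) {
  labels <- rownames(D)
  n <- nrow(D)
  frag <- labels                      # newick fragment per active node
  V <- D                              # variance matrix, initialized to D
  active <- seq_len(n)
  num <- function(x) sprintf("%.17g", x)
  while (length(active) > 3L) {
    r <- length(active)
    Da <- D[active, active]
    S <- rowSums(Da)
    Q <- (r - 2) * Da - outer(S, S, `+`)
    diag(Q) <- Inf
    k <- which(Q == min(Q), arr.ind = TRUE)
    k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]   # deterministic tie-break
    i <- active[k[1]]; j <- active[k[2]]
    bi <- Da[k[1], k[2]] / 2 + (S[k[1]] - S[k[2]]) / (2 * (r - 2))
    bj <- Da[k[1], k[2]] - bi
    others <- setdiff(active, c(i, j))
    vij <- V[i, j]
    lambda <- if (vij > 0) {
      0.5 + sum(V[j, others] - V[i, others]) / (2 * (r - 2) * vij)
    } else 0.5
    lambda <- min(1, max(0, lambda))
    # reduce: new node u replaces i; distances and variances to the rest
    Du <- lambda * (D[i, others] - bi) + (1 - lambda) * (D[j, others] - bj)
    Vu <- lambda * V[i, others] + (1 - lambda) * V[j, others] -
      lambda * (1 - lambda) * vij
    frag[i] <- paste0("(", frag[i], ":", num(bi), ",", frag[j], ":",
                      num(bj), ")")
    D[i, others] <- Du; D[others, i] <- Du; D[i, i] <- 0
    V[i, others] <- Vu; V[others, i] <- Vu; V[i, i] <- 0
    active <- setdiff(active, j)
  }
  a <- active[1]; b <- active[2]; c_ <- active[3]
  xa <- (D[a, b] + D[a, c_] - D[b, c_]) / 2
  xb <- (D[a, b] + D[b, c_] - D[a, c_]) / 2
  xc <- (D[a, c_] + D[b, c_] - D[a, b]) / 2
  txt <- paste0("(", frag[a], ":", num(xa), ",", frag[b], ":", num(xb),
                ",", frag[c_], ":", num(xc), ");")
  ape::read.tree(text = txt)
}

#' Minimum-evolution tree from a dissimilarity matrix
#'
#' Fast minimum-evolution tree search (NNI from a BIONJ start) under the
#' ordinary least-squares or the balanced branch-length scheme, in which
#' sibling subtrees receive equal weights.
#'
#' @inheritParams hierarchical_tree
#' @param scheme `"ols"` or `"balanced"`.
#' @return An unrooted `phylo` tree.
#' @export
minimum_evolution_tree <- function(D, scheme = c("ols", "balanced")) {
  scheme <- match.arg(scheme)
  m <- as.matrix(unclass(D))
  if (nrow(m) < 3L) rlang::abort("minimum evolution needs at least 3 taxa")
  if (scheme == "ols") ape::fastme.ols(as_dist(D), nni = TRUE)
  else ape::fastme.bal(as_dist(D), nni = TRUE, spr = FALSE, tbr = FALSE)
}

#' Run the full glycome clustering pipeline
#'
#' Builds the taxon pool, the fragment pool, the per-taxon occurrence codes
#' and the normalized dissimilarity matrix, then the requested tree.
#'
#' @inheritParams build_taxon_pool
#' @param opts A [filter_options()] object.
#' @param method Tree method: `upgma`, `complete`, `ward_d2`, `nj`, `bionj`,
#'   `me_ols` or `me_balanced`.
#' @return An object of class `glyco_clustering`: list with `taxon_pool`,
#'   `fragment_pool`, `profiles`, `matrix`, `tree`, `method`, `params`.
#' @export
#' @examples
#' coll <- generate_collection(simulation_spec(seed = 1))
#' th <- pool_thresholds(population_abs_min = 1, fragment_min_structures = 2,
#'                       fragment_min_instances = 3)
#' res <- clusterize(coll, "genus", thresholds = th, method = "upgma")
#' glance(res)
clusterize <- function(collection, rank, thresholds = pool_thresholds(),
                       opts = filter_options(), scope = NULL,
                       explicit_list = NULL,
                       method = c("upgma", "complete", "ward_d2", "nj",
                                  "bionj", "me_ols", "me_balanced")) {
  method <- match.arg(method)
  taxon_pool <- build_taxon_pool(collection, rank, thresholds, scope,
                                 explicit_list)
  fragment_pool <- build_fragment_pool(collection, thresholds, opts)
  profiles <- lapply(taxon_pool$taxon, function(t)
    occurrence_code(collection, rank, t, fragment_pool, thresholds, opts))
  D <- dissimilarity_matrix(profiles)
  tree <- switch(method,
                 upgma = ,
                 complete = ,
                 ward_d2 = hierarchical_tree(D, method),
                 nj = nj_tree(D, "nj"),
                 bionj = nj_tree(D, "bionj"),
                 me_ols = minimum_evolution_tree(D, "ols"),
                 me_balanced = minimum_evolution_tree(D, "balanced"))
  structure(list(taxon_pool = taxon_pool, fragment_pool = fragment_pool,
                 profiles = profiles, matrix = D, tree = tree,
                 method = method,
                 params = list(rank = rank, thresholds = thresholds,
                               opts = opts, scope = scope,
                               explicit_list = explicit_list)),
            class = "glyco_clustering")
}

#' @export
print.glyco_clustering <- function(x, ...) {
  cat(sprintf(paste0("<glyco_clustering: %d taxa x %d fragments, method ",
                     "%s>\n"),
              nrow(x$taxon_pool), nrow(x$fragment_pool), x$method))
  invisible(x)
}

#' @export
glance.glyco_clustering <- function(x, ...) {
  tibble::tibble(n_taxa = nrow(x$taxon_pool),
                 n_fragments = nrow(x$fragment_pool),
                 max_distance = max(unclass(x$matrix)),
                 scaled = isTRUE(attr(x$matrix, "scaled")),
                 method = x$method)
}

#' @export
tidy.glyco_clustering <- function(x, ...) tidy(x$matrix)
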