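# non-trivial bipartitions of an unrooted leaf-labelled tree: one logical
# vector (over sorted tip labels) per internal edge, TRUE = tip below edge
tree_bipartitions <- function(tree, labels) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  tip_idx <- match(tree$tip.label, labels)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(node) {
    if (node <= ntip) return(tip_idx[node])
    unlist(lapply(children[[as.character(node)]], below))
  }
  internal <- which(tree$edge[, 2] > ntip)
  parts <- lapply(internal, function(k) {
    side <- rep(FALSE, length(labels))
    side[below(tree$edge[k, 2])] <- TRUE
    side
  })
  keep <- vapply(parts, function(p) sum(p) >= 2 && sum(!p) >= 2, logical(1))
  parts[keep]
}

jaccard <- function(a, b) {
  u <- sum(a | b)
  if (!u) return(1)
  sum(a & b) / u
}

# score of one branch pair: best of the two side alignments, each the mean
# of the two Jaccard indices between aligned sides
branch_pair_score <- function(p, q) {
  max((jaccard(p, q) + jaccard(!p, !q)) / 2,
      (jaccard(p, !q) + jaccard(!p, q)) / 2)
}

#' Topological similarity score between two trees
#'
#' Compares two leaf-labelled trees on the same leaf set by their internal
#' branches: every internal branch induces a bipartition of the leaves; each
#' branch pair is scored by the best side alignment (mean of the two Jaccard
#' indices between aligned sides); an optimal one-to-one assignment of
#' branches maximizes the total score; the result is the mean matched score
#' as a percent. Identical topologies score 100. Rooted inputs are unrooted
#' first. When the trees have different numbers of internal branches the
#' unmatched branches count as zero; two star trees (no internal branches)
#' score 100 by convention, with a warning.
#'
#' @param t1,t2 `phylo` trees with identical tip label sets.
#' @return A percent in `[0, 100]`.
#' @export
#' @examples
#' t <- ape::read.tree(text = "((A,B),(C,D));")
#' topological_score(t, t)
topological_score <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  labels <- sort(t1$tip.label)
  if (!identical(labels, sort(t2$tip.label)))
    rlang::abort("trees have different leaf label sets")
  p1 <- tree_bipartitions(t1, labels)
  p2 <- tree_bipartitions(t2, labels)
  if (!length(p1) && !length(p2)) {
    rlang::warn("both trees are stars (no internal branches); score is 100 by convention")
    return(100)
  }
  if (!length(p1) || !length(p2)) return(0)
  S <- matrix(0, length(p1), length(p2))
  for (i in seq_along(p1)) {
    for (j in seq_along(p2)) {
      S[i, j] <- branch_pair_score(p1[[i]], p2[[j]])
    }
  }
  total <- sum_optimal_assignment(S)
  100 * total / max(length(p1), length(p2))
}

# maximal total of a one-to-one assignment on a (possibly rectangular)
# score matrix, solved optimally
sum_optimal_assignment <- function(S) {
  if (nrow(S) > ncol(S)) S <- t(S)
  sol <- clue::solve_LSAP(S, maximum = TRUE)
  sum(S[cbind(seq_len(nrow(S)), sol)])
}

#' Read a Newick tree file
#'
#' @param path Path to a Newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path))
    rlang::abort(paste0("tree file not found: ", path),
                 class = "glycotaxa_missing_input")
  ape::read.tree(path)
}
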