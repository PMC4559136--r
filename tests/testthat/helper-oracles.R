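# Independent oracles and fixture builders shared across the suite.

# ---- fixture notations -------------------------------------------------------

fixture_notations <- function() {
  c("aDManp",
    "Gal(1-3)GlcNAc(1-2)Man",
    "Subst1(1-3)aDGlcp(1-1)LIP // Subst1 = 2,5-diaminopentanoic acid",
    "-4)[Ac(1-2)]aDGlcpN(1-",
    "aDManp(1-3)[aDManp(1-6)]bDManp(1-4)bDGlcpN",
    "P-6)aLDmanHepp",
    "Glc-1OMe",
    "-3)aLRhap(1-4)[bDGlcp(1-2)]aDGalp(1-",
    "bDXylp(1-2)aDManp(1-6)[aDGalf(1-2)]aDManp",
    "?DGal?(1-4)b?Fucp(1-3)aDGlcp")
}

# write a dump TSV from a tibble of rows (characters throughout)
write_fixture_dump <- function(rows, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(rows, path, progress = FALSE)
  path
}

dump_row <- function(id, notation, lineage, year = 2000, nmr = 0,
                     type = "mono_oligomer", pub = NULL) {
  tibble::tibble(structure_id = id, notation = notation, lineage = lineage,
                 year = as.character(year), nmr_count = as.character(nmr),
                 structure_type = type,
                 publication_id = if (is.null(pub)) paste0(id, "@", year)
                 else pub)
}

# a small hand-built collection: two phyla, three genera, five structures,
# one structure shared between two species of one genus
fixture_collection <- function() {
  lin <- function(ph, cl, gen, sp)
    paste0("domain=Bacteria;kingdom=Bacteria;phylum=", ph, ";class=", cl,
           ";genus=", gen, ";species=", sp)
  rows <- dplyr::bind_rows(
    dump_row("S1", "aDGlcp(1-4)bDGalp", lin("PhyA", "ClaA", "GenA", "GenA one"),
             year = 2001, nmr = 2, pub = "P1"),
    dump_row("S2", "aDGlcp(1-4)bDGalp(1-3)aDManp",
             lin("PhyA", "ClaA", "GenA", "GenA one"), year = 2002, nmr = 1,
             pub = "P2"),
    dump_row("S3", "aLRhap(1-2)aDManp", lin("PhyA", "ClaA", "GenB", "GenB one"),
             year = 2003, nmr = 0, pub = "P3"),
    # S4 assigned to two species of GenB (two rows, same id)
    dump_row("S4", "bDXylp(1-2)aDManp", lin("PhyA", "ClaA", "GenB", "GenB one"),
             year = 2004, nmr = 3, pub = "P4"),
    dump_row("S4", "bDXylp(1-2)aDManp", lin("PhyA", "ClaA", "GenB", "GenB two"),
             year = 2004, nmr = 3, pub = "P4"),
    dump_row("S5", "aKdop(2-6)bDGlcpN", lin("PhyB", "ClaB", "GenC", "GenC one"),
             year = 2005, nmr = 1, pub = "P5", type = "polymer"))
  read_dump(write_fixture_dump(rows))
}

# ---- independent fragment enumeration ----------------------------------------

# Brute-force fragment counting over the adjacency list with its own residue
# filtering, kept deliberately separate from residue_key(): supports the
# option combinations exercised in tests.
oracle_fragments <- function(graph, arity, only_saccharides = FALSE,
                             combine_anomers = FALSE) {
  key_of <- function(i) {
    r <- graph$residues[i, ]
    if (only_saccharides && r$residue_class != "monosaccharide")
      return(NA_character_)
    k <- r$token
    if (combine_anomers && r$residue_class == "monosaccharide" &&
        substr(k, 1, 1) %in% c("a", "b", "?") &&
        grepl("^[A-Z?]", substr(k, 2, nchar(k))))
      k <- substr(k, 2, nchar(k))
    k
  }
  if (arity == 1) {
    keys <- vapply(seq_len(nrow(graph$residues)), key_of, character(1))
    return(sort(keys[!is.na(keys)]))
  }
  out <- character()
  for (k in seq_len(nrow(graph$edges))) {
    e <- graph$edges[k, ]
    dk <- key_of(e$donor)
    ak <- key_of(e$acceptor)
    if (is.na(dk) || is.na(ak)) next
    lt <- if (is.na(e$donor_pos)) paste0("-", e$acceptor_pos, ")")
    else paste0("(", e$donor_pos, "-", e$acceptor_pos, ")")
    out <- c(out, paste0(dk, lt, ak))
  }
  sort(out)
}

# ---- tree oracles ------------------------------------------------------------

# edge ids on the path between two tips of an unrooted phylo tree
path_edges <- function(tree, from, to) {
  adj <- list()
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]
    adj[[as.character(a)]] <- rbind(adj[[as.character(a)]], c(b, k))
    adj[[as.character(b)]] <- rbind(adj[[as.character(b)]], c(a, k))
  }
  # DFS
  stack <- list(list(node = from, edges = integer()))
  seen <- from
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (cur$node == to) return(cur$edges)
    nb <- adj[[as.character(cur$node)]]
    for (r in seq_len(nrow(nb))) {
      if (!(nb[r, 1] %in% seen)) {
        seen <- c(seen, nb[r, 1])
        stack[[length(stack) + 1L]] <- list(node = nb[r, 1],
                                            edges = c(cur$edges, nb[r, 2]))
      }
    }
  }
  stop("tips not connected")
}

# OLS total tree length of a topology fitted to distance matrix D
oracle_ols_length <- function(topology, D) {
  labels <- topology$tip.label
  pairs <- utils::combn(length(labels), 2)
  A <- matrix(0, ncol(pairs), nrow(topology$edge))
  d <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    A[p, path_edges(topology, i, j)] <- 1
    d[p] <- D[labels[i], labels[j]]
  }
  l <- solve(crossprod(A), crossprod(A, d))
  sum(l)
}

# balanced (Pauplin) total tree length of a topology given D
oracle_balanced_length <- function(topology, D) {
  labels <- topology$tip.label
  pairs <- utils::combn(length(labels), 2)
  total <- 0
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    pij <- length(path_edges(topology, i, j))
    total <- total + 2^(1 - pij) * D[labels[i], labels[j]]
  }
  total
}

# exhaustive minimum-evolution topology search over all unrooted topologies
oracle_me_topology <- function(D, criterion = c("ols", "balanced")) {
  criterion <- match.arg(criterion)
  labels <- rownames(D)
  tops <- phangorn::allTrees(length(labels), rooted = FALSE,
                             tip.label = labels)
  lens <- vapply(tops, function(tp) {
    if (criterion == "ols") oracle_ols_length(tp, D)
    else oracle_balanced_length(tp, D)
  }, numeric(1))
  tops[[which.min(lens)]]
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2), method = "PH85") == 0
}

# random additive matrix from a random tree with its generating tree
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.5, 2))
  list(tree = tr, D = stats::cophenetic(tr))
}

random_ultrametric <- function(n, seed) {
  set.seed(seed)
  stats::cophenetic(ape::rcoal(n))
}

# exhaustive maximal assignment total over permutations (n <= 7)
oracle_assignment <- function(S) {
  if (nrow(S) > ncol(S)) S <- t(S)
  best <- -Inf
  for (perm in asplit(gtools_permutations(ncol(S), nrow(S)), 1)) {
    best <- max(best, sum(S[cbind(seq_len(nrow(S)), perm)]))
  }
  best
}

# all permutations of k items out of n (rows), base R
gtools_permutations <- function(n, k) {
  if (k == 0) return(matrix(integer(), 1, 0))
  out <- NULL
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) {
      out <<- rbind(out, prefix)
      return()
    }
    for (x in remaining) rec(c(prefix, x), setdiff(remaining, x))
  }
  rec(integer(), seq_len(n))
  out
}

# partitions equal up to label permutation
same_partition <- function(a, b) {
  stopifnot(identical(sort(names(a)), sort(names(b))))
  b <- b[names(a)]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
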