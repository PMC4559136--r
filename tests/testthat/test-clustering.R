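quiet_thresholds <- function(...) suppressWarnings(pool_thresholds(...))

test_that("taxon pool thresholds match brute-force population counts", {
  coll <- generate_collection(simulation_spec(n_groups = 2,
                                              taxa_per_group = 5,
                                              structures_per_taxon = 8,
                                              seed = 21))
  th <- pool_thresholds(population_abs_min = 8,
                        fragment_min_structures = 1,
                        fragment_min_instances = 2)
  pool <- build_taxon_pool(coll, "genus", th)
  genera <- taxa_at_rank(coll, "genus")
  oracle <- genera[vapply(genera, function(t)
    population(coll, "genus", t), integer(1)) >= 8]
  expect_equal(pool$taxon, sort(oracle))
  # no absolute threshold keeps every taxon at the rank
  all_pool <- build_taxon_pool(coll, "genus",
                               pool_thresholds(population_abs_min = 0,
                                               fragment_min_structures = 1,
                                               fragment_min_instances = 2))
  expect_equal(all_pool$taxon, sort(genera))
  # an explicit list bypasses thresholds
  pick <- sort(genera)[1:3]
  expect_equal(build_taxon_pool(coll, "genus", th,
                                explicit_list = pick)$taxon, pick)
  # impossible threshold gives the empty-pool error
  expect_error(build_taxon_pool(coll, "genus",
                                pool_thresholds(population_abs_min = 10000,
                                                fragment_min_structures = 1,
                                                fragment_min_instances = 2)),
               class = "glycotaxa_empty_pool")
})

test_that("relative population thresholds divide by the database partition", {
  coll <- fixture_collection()   # 5 bacterial structures
  th <- pool_thresholds(use_abs = FALSE, use_rel = TRUE,
                        population_rel_min = 0.3,
                        fragment_min_structures = 1,
                        fragment_min_instances = 2)
  pool <- build_taxon_pool(coll, "genus", th)
  # GenA: 2/5 = 0.4, GenB: 2/5 = 0.4, GenC: 1/5 = 0.2
  expect_equal(pool$taxon, c("GenA", "GenB"))
})

test_that("fragment pool thresholds filter by structures and instances", {
  coll <- fixture_collection()
  th1 <- quiet_thresholds(fragment_min_structures = 1,
                          fragment_min_instances = 1)
  pool1 <- build_fragment_pool(coll, th1)
  # every observed dimer passes at (1, 1): brute-force union over structures
  oracle <- sort(unique(unlist(lapply(coll$structures$graph, function(g)
    oracle_fragments(g, 2)))))
  expect_equal(pool1$fragment, oracle)
  # fragment in fewer structures than the threshold is excluded
  th2 <- quiet_thresholds(fragment_min_structures = 2,
                          fragment_min_instances = 2)
  pool2 <- build_fragment_pool(coll, th2)
  counts <- table(unlist(lapply(coll$structures$graph, function(g)
    unique(oracle_fragments(g, 2)))))
  expect_equal(pool2$fragment, sort(names(counts[counts >= 2])))
  expect_equal(pool2$fragment, "aDGlcp(1-4)bDGalp")
})

test_that("occurrence codes apply the presence threshold per taxon", {
  coll <- fixture_collection()
  th <- quiet_thresholds(fragment_min_structures = 1,
                         fragment_min_instances = 1,
                         presence_threshold = 2)
  pool <- build_fragment_pool(coll, th)
  prof <- occurrence_code(coll, "genus", "GenA", pool, th)
  # aDGlcp(1-4)bDGalp occurs twice in GenA (S1, S2): bit set at threshold 2
  expect_equal(unname(prof$bits[["aDGlcp(1-4)bDGalp"]]), 1)
  # bDGalp(1-3)aDManp occurs once: bit cleared at threshold 2
  expect_equal(unname(prof$bits[["bDGalp(1-3)aDManp"]]), 0)
  th1 <- quiet_thresholds(fragment_min_structures = 1,
                          fragment_min_instances = 1,
                          presence_threshold = 1)
  prof1 <- occurrence_code(coll, "genus", "GenA", pool, th1)
  expect_equal(unname(prof1$bits[["bDGalp(1-3)aDManp"]]), 1)
  # a taxon without scoped structures gets an all-zero code
  th_poly <- quiet_thresholds(fragment_min_structures = 1,
                              fragment_min_instances = 1,
                              structure_scope = "only_polymers")
  prof0 <- occurrence_code(coll, "genus", "GenA", pool, th_poly)
  expect_true(all(prof0$bits == 0))
  expect_equal(prof0$n_structures, 0)
})

test_that("hamming distance counts differing bits", {
  expect_equal(hamming(c(1L, 0L, 1L, 0L), c(0L, 0L, 1L, 1L)), 2)
  x <- c(1L, 1L, 0L)
  expect_equal(hamming(x, x), 0)
  expect_equal(hamming(c(1L, 0L, 1L), c(0L, 1L, 0L)), 3)
  expect_error(hamming(c(1L, 0L), c(1L, 0L, 1L)), "different lengths")
})

make_profile <- function(taxon, bits, n) {
  structure(list(taxon = taxon, rank = "genus", bits = as.integer(bits),
                 n_structures = n), class = "occurrence_profile")
}

test_that("dissimilarity normalization divides by paired structure counts then rescales to 100", {
  # H = 4 over 8 bits, N_i = 10, N_j = 30: raw 0.1; single positive value
  # is its own maximum, so it becomes 100 after rescaling
  a <- make_profile("A", c(1, 1, 1, 1, 0, 0, 0, 0), 10)
  b <- make_profile("B", c(0, 0, 0, 0, 1, 1, 1, 1, 0)[1:8], 30)
  D <- dissimilarity_matrix(list(a, b))
  expect_equal(unclass(D)["A", "B"], 100)
  expect_true(attr(D, "scaled"))
  # three profiles: ratios between cells are preserved by the rescaling
  c_ <- make_profile("C", c(1, 1, 1, 1, 0, 0, 0, 0), 10)
  D3 <- dissimilarity_matrix(list(a, b, c_))
  m <- unclass(D3)
  expect_equal(m["A", "C"], 0)           # identical profiles
  expect_equal(max(m), 100)
  # raw: AB = 8/40 = 0.2, BC = 8/40 = 0.2, AC = 0 -> AB and BC both 100
  expect_equal(m["B", "C"], 100)
  expect_equal(diag(m), c(A = 0, B = 0, C = 0))
  expect_equal(m, t(m))
  # identical profiles everywhere: unscaled with a warning
  expect_warning(D0 <- dissimilarity_matrix(list(a, c_)), "unscaled")
  expect_false(attr(D0, "scaled"))
  expect_error(dissimilarity_matrix(list(a)), "at least two")
})

test_that("UPGMA agglomeration matches the hand oracle", {
  # two taxa at distance 100: single join, each leaf branch 50
  m2 <- matrix(c(0, 100, 100, 0), 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  t2 <- hierarchical_tree(m2, "upgma")
  expect_equal(sort(t2$edge.length), c(50, 50))
  # D(AB) = 2, D(AC) = D(BC) = 8: join A,B at height 1, then C at height 4
  m3 <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- hierarchical_tree(m3, "upgma")
  hc <- attr(t3, "hclust")
  expect_equal(hc$height, c(2, 8))
  cop <- as.matrix(stats::cophenetic(hc))
  expect_equal(cop["A", "B"], 2)
  expect_equal(cop["A", "C"], 8)
  expect_error(hierarchical_tree(matrix(0, 1, 1,
                                        dimnames = list("A", "A"))),
               "at least two")
})

test_that("UPGMA trees are ultrametric and exact on ultrametric input", {
  for (seed in 1:5) {
    D <- random_ultrametric(8, seed)
    tr <- hierarchical_tree(D, "upgma")
    # equal root-to-leaf path lengths
    depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
    expect_lt(diff(range(depths)), 1e-9)
    # cophenetic distances reproduce the input exactly
    cop <- as.matrix(stats::cophenetic(attr(tr, "hclust")))
    expect_equal(cop[rownames(D), colnames(D)], D, tolerance = 1e-9)
  }
})

test_that("ward_d2 and complete linkage produce valid rooted dendrograms", {
  coll <- generate_collection(simulation_spec(seed = 9))
  th <- quiet_thresholds(population_abs_min = 1,
                         fragment_min_structures = 2,
                         fragment_min_instances = 2)
  res_w <- clusterize(coll, "genus", th, method = "ward_d2")
  res_c <- clusterize(coll, "genus", th, method = "complete")
  for (res in list(res_w, res_c)) {
    expect_s3_class(res$tree, "phylo")
    expect_true(ape::is.rooted(res$tree))
    expect_setequal(res$tree$tip.label, res$taxon_pool$taxon)
  }
})

test_that("NJ and BIONJ reproduce additive matrices exactly", {
  for (seed in 1:5) {
    gen <- random_additive(7, seed)
    for (variant in c("nj", "bionj")) {
      tr <- nj_tree(gen$D, variant)
      path <- stats::cophenetic(tr)
      expect_equal(path[rownames(gen$D), colnames(gen$D)], gen$D,
                   tolerance = 1e-9)
      expect_true(same_topology(tr, gen$tree))
    }
  }
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("A", "B"),
                                                       c("A", "B")))),
               "at least 3")
})

test_that("the BIONJ agglomeration agrees with the reference implementation", {
  for (seed in 1:4) {
    gen <- random_additive(8, seed + 50)
    ours <- nj_tree(gen$D, "bionj")
    ref <- ape::bionj(stats::as.dist(gen$D))
    expect_true(same_topology(ours, ref))
    expect_setequal(ours$tip.label, rownames(gen$D))
  }
  # three taxa: closed-form branch lengths solve the pairwise equations
  m <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(m, "bionj")
  path <- stats::cophenetic(tr)
  expect_equal(path[rownames(m), colnames(m)], m, tolerance = 1e-12)
})

test_that("minimum-evolution trees match the exhaustive topology oracle", {
  for (n in c(5, 6)) {
    for (seed in 1:3) {
      gen <- random_additive(n, seed + 100 * n)
      for (scheme in c("ols", "balanced")) {
        tr <- minimum_evolution_tree(gen$D, scheme)
        oracle <- oracle_me_topology(gen$D, if (scheme == "ols") "ols"
                                     else "balanced")
        expect_true(same_topology(tr, oracle),
                    label = sprintf("n=%d seed=%d scheme=%s", n, seed,
                                    scheme))
        # on additive data both schemes recover the generating topology
        expect_true(same_topology(tr, gen$tree))
      }
    }
  }
})

test_that("a noisy matrix still matches the exhaustive ME oracle", {
  # perturbed additive matrix: the oracle argmin is no longer the generator
  gen <- random_additive(5, 77)
  set.seed(78)
  E <- matrix(stats::runif(25, 0, 0.35), 5)
  E <- (E + t(E)) / 2
  diag(E) <- 0
  D <- gen$D + E
  for (scheme in c("ols", "balanced")) {
    tr <- minimum_evolution_tree(D, scheme)
    oracle <- oracle_me_topology(D, if (scheme == "ols") "ols" else "balanced")
    expect_true(same_topology(tr, oracle), label = scheme)
  }
})

test_that("matrix exports follow the declared formats", {
  m <- matrix(c(0, 100, 100, 0), 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  phy <- export_matrix(m, "phylip")
  lines <- strsplit(phy, "\n")[[1]]
  expect_length(lines, 3)
  expect_equal(lines[1], "2")
  expect_match(lines[2], "^A {9} 0\\.0 100\\.0$")
  tsv <- strsplit(export_matrix(m, "tsv"), "\n")[[1]]
  expect_equal(tsv[1], "taxon\tA\tB")
  expect_equal(tsv[2], "A\t0.0\t100.0")
  # r format reads back with dget
  f <- tempfile()
  writeLines(export_matrix(m, "r"), f, sep = "")
  expect_equal(dget(f), m)
  # truncation collisions are an error
  long <- matrix(0, 2, 2, dimnames = list(c("Pseudomonas_one",
                                            "Pseudomonas_two"),
                                          c("Pseudomonas_one",
                                            "Pseudomonas_two")))
  expect_error(export_matrix(long, "phylip"), "collide")
})

test_that("tree exports round trip through Newick and parse as Nexus", {
  gen <- random_additive(6, 3)
  tr <- nj_tree(gen$D)
  nwk <- export_tree(tr, "newick")
  tr2 <- ape::read.tree(text = nwk)
  expect_true(same_topology(tr, tr2))
  expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
  nex <- export_tree(tr, "nexus")
  f <- tempfile(fileext = ".nex")
  writeLines(nex, f, sep = "")
  tr3 <- ape::read.nexus(f)
  expect_true(same_topology(tr, tr3))
})

test_that("the whole pipeline is deterministic from dump to exports", {
  spec <- simulation_spec(n_groups = 2, taxa_per_group = 3,
                          structures_per_taxon = 10, seed = 31)
  dump <- tempfile(fileext = ".tsv")
  generate_dump(spec, dump)
  run_once <- function(outdir) {
    coll <- read_dump(dump)
    th <- quiet_thresholds(population_abs_min = 1,
                           fragment_min_structures = 2,
                           fragment_min_instances = 3)
    res <- clusterize(coll, "genus", th, method = "upgma")
    write_clustering(res, outdir, matrix_format = "phylip",
                     tree_format = "both")
  }
  d1 <- tempfile(); d2 <- tempfile()
  run_once(d1); run_once(d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("structure scopes select the right structures", {
  coll <- fixture_collection()   # S5 is a polymer, the rest oligomers
  ids_any <- glycotaxa:::scoped_structure_ids(coll, "any")
  expect_length(ids_any, 5)
  expect_equal(glycotaxa:::scoped_structure_ids(coll, "only_polymers"), "S5")
  expect_setequal(glycotaxa:::scoped_structure_ids(coll, "only_oligomers"),
                  setdiff(ids_any, "S5"))
  # optimized: all domains here are Bacteria, so polymers only
  expect_equal(glycotaxa:::scoped_structure_ids(coll, "optimized"), "S5")
})
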