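test_that("residue keys honor anomer combining, exclusion and aliases", {
  g <- parse_csdb("aDGlcp")
  expect_equal(residue_key(g, 1, filter_options(combine_anomers = TRUE)),
               "DGlcp")
  expect_equal(residue_key(g, 1, filter_options()), "aDGlcp")

  gu <- parse_csdb("?DGal?")
  expect_equal(residue_key(gu, 1,
                           filter_options(include_undefined_configs = FALSE)),
               NA_character_)
  expect_equal(residue_key(gu, 1,
                           filter_options(exclude_underdetermined = TRUE)),
               NA_character_)
  expect_equal(residue_key(gu, 1, filter_options()), "?DGal?")

  ga <- parse_csdb("Subst1(1-3)aDGlcp // Subst1 = 2,5-diaminopentanoic acid")
  i <- which(ga$residues$token == "Subst1")
  expect_equal(residue_key(ga, i, filter_options(explain_subst = TRUE)),
               "2,5-diaminopentanoic acid")
  expect_equal(residue_key(ga, i, filter_options()), "Subst1")
  expect_equal(residue_key(ga, i, filter_options(include_aliases = FALSE)),
               NA_character_)
  expect_equal(residue_key(ga, i, filter_options(exclude_superclasses = TRUE)),
               NA_character_)
})

test_that("interdependent filters are rejected", {
  expect_error(filter_options(only_saccharides = TRUE,
                              include_monovalent = TRUE),
               "mutually exclusive")
  expect_false(filter_options(only_saccharides = TRUE)$include_monovalent)
  expect_error(filter_options(strict_comparison = FALSE))
})

test_that("alias worked example yields three monomers and two dimers", {
  g <- parse_csdb(paste0("Subst1(1-3)aDGlcp(1-1)LIP // ",
                         "Subst1 = 2,5-diaminopentanoic acid"))
  opts <- filter_options(include_aliases = TRUE)
  expect_equal(nrow(enumerate_monomers(g, opts)), 3)
  dim <- enumerate_dimers(g, opts)
  expect_setequal(dim$fragment, c("Subst1(1-3)aDGlcp", "aDGlcp(1-1)LIP"))
  # explained aliases rename the dimer
  dim2 <- enumerate_dimers(g, filter_options(explain_subst = TRUE))
  expect_true("2,5-diaminopentanoic acid(1-3)aDGlcp" %in% dim2$fragment)
})

test_that("saccharide-only filtering drops monovalent dimers but keeps sugar ones", {
  g <- parse_csdb("Gal(1-3)GlcNAc(1-2)Man")
  opts <- filter_options(only_saccharides = TRUE)
  mono <- enumerate_monomers(g, opts)
  expect_setequal(mono$fragment, c("Gal", "GlcN", "Man"))
  dim <- enumerate_dimers(g, opts)
  expect_true("Gal(1-3)GlcN" %in% dim$fragment)
  expect_false("Ac(1-2)GlcN" %in% dim$fragment)
  # with monovalent residues included the acetyl dimer is an ordinary dimer
  dim_all <- enumerate_dimers(g, filter_options())
  expect_true("Ac(1-2)GlcN" %in% dim_all$fragment)
})

test_that("branching degree counts substituents with or without monovalent residues", {
  g <- parse_csdb("Gal(1-3)GlcNAc(1-2)Man")
  glcn <- which(g$residues$token == "GlcN")
  expect_equal(branching_degree(g, glcn, count_monovalent = TRUE), 2)
  expect_equal(branching_degree(g, glcn, count_monovalent = FALSE), 1)
  gal <- which(g$residues$token == "Gal")
  expect_equal(branching_degree(g, gal), 0)
})

test_that("position classes follow root/leaf/interior roles", {
  g <- parse_csdb("Gal(1-3)GlcNAc(1-2)Man")
  tok <- g$residues$token
  expect_equal(position_class(g, which(tok == "Man")), "reducing")
  expect_equal(position_class(g, which(tok == "Gal")), "terminal")
  expect_equal(position_class(g, which(tok == "GlcN")), "inline")
  # a residue whose only substituent is monovalent is still terminal
  g2 <- parse_csdb("GlcNAc(1-2)Man")
  expect_equal(position_class(g2, which(g2$residues$token == "GlcN")),
               "terminal")
  # wrap-around members of a repeating unit are inline by convention
  gp <- parse_csdb("-4)aDGlcpN(1-")
  expect_equal(position_class(gp, gp$root), "inline")
})

test_that("position/branching annotations fold into fragment keys", {
  g <- parse_csdb("Gal(1-3)GlcNAc(1-2)Man")
  opts <- filter_options(distinguish_position = TRUE,
                         distinguish_branching = TRUE)
  mono <- enumerate_monomers(g, opts)
  expect_true("GlcN|inline|br2" %in% mono$fragment)
  opts2 <- filter_options(distinguish_position = TRUE,
                          distinguish_branching = TRUE,
                          count_monovalent_in_branching = FALSE)
  expect_true("GlcN|inline|br1" %in%
                enumerate_monomers(g, opts2)$fragment)
})

test_that("permissive options conserve node and edge counts", {
  opts <- filter_options()
  for (s in fixture_notations()) {
    g <- parse_csdb(s)
    expect_equal(nrow(enumerate_monomers(g, opts)), nrow(g$residues),
                 info = s)
    expect_equal(nrow(enumerate_dimers(g, opts)), nrow(g$edges), info = s)
  }
})

test_that("tightening any single filter never increases fragment counts", {
  tighter <- list(filter_options(include_monovalent = FALSE),
                  filter_options(include_aglycons = FALSE),
                  filter_options(include_aliases = FALSE),
                  filter_options(exclude_underdetermined = TRUE),
                  filter_options(exclude_superclasses = TRUE),
                  filter_options(only_saccharides = TRUE))
  base <- filter_options()
  for (s in fixture_notations()) {
    g <- parse_csdb(s)
    for (arity in 1:2) {
      n0 <- nrow(enumerate_fragments(g, arity, base))
      for (opt in tighter) {
        expect_lte(nrow(enumerate_fragments(g, arity, opt)), n0,
                   label = paste(s, "arity", arity))
      }
    }
  }
})

test_that("enumeration is deterministic and matches the brute-force oracle", {
  for (s in fixture_notations()) {
    g <- parse_csdb(s)
    for (arity in 1:2) {
      a <- sort(enumerate_fragments(g, arity, filter_options())$fragment)
      b <- sort(enumerate_fragments(g, arity, filter_options())$fragment)
      expect_identical(a, b)
      expect_identical(a, oracle_fragments(g, arity))
      sac <- filter_options(only_saccharides = TRUE)
      expect_identical(
        sort(enumerate_fragments(g, arity, sac)$fragment),
        oracle_fragments(g, arity, only_saccharides = TRUE), info = s)
      comb <- filter_options(combine_anomers = TRUE)
      expect_identical(
        sort(enumerate_fragments(g, arity, comb)$fragment),
        oracle_fragments(g, arity, combine_anomers = TRUE), info = s)
    }
  }
})

test_that("the wrap-around linkage of a repeat contributes exactly one dimer", {
  g <- parse_csdb("-3)aLRhap(1-4)[bDGlcp(1-2)]aDGalp(1-")
  dim <- enumerate_dimers(g, filter_options())
  expect_equal(sum(dim$fragment == "aDGalp(1-3)aLRhap"), 1)
  expect_equal(nrow(dim), 3)
})
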