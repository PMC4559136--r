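---
title: "Glycome statistics and taxon clustering: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glycome statistics and taxon clustering: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotaxa)
```

## The problem

Carbohydrate structures — oligomers and polymer repeating units built of
monosaccharides, monovalent substituents (acetyl, methyl, phosphate,
sulfate), aglycons and placeholder residues — are deposited in curated
collections annotated with the taxonomy of the organisms they were isolated
from. Because the repertoire of glycans an organism can make is determined
by its carbohydrate-active enzymes, two taxa with similar disaccharide
repertoires are expected to carry enzymes with similar activities. glycotaxa
implements the statistics that make this comparable across taxa: fragment
abundance tables, database-coverage tables, and a clustering pipeline that
turns per-taxon fragment repertoires into distance-based phenetic trees.

## Structures and fragments

A structure is parsed from CSDB linear notation into a rooted
residue/linkage graph (`parse_csdb()`). Every entity attached through an
ester, ether or amide linkage is a distinct residue, so shortcut spellings
are expanded: `GlcNAc` is `GlcN` with `Ac` at position 2, `Glc-1OMe` is the
dimer `Glc(1-1)Me`. The rightmost main-chain residue is the root (reducing
end or aglycon); a repeating unit `-4)...(1-` closes with a single
wrap-around linkage, counted once per repeat when fragments are extracted
(the alternative, once per polymer chain, is unobservable from a repeating
unit, so we document the convention rather than guess a multiplier).

Monomeric fragments are residues; dimeric fragments are linked residue
pairs rendered as `donor(d-a)acceptor`. Larger fragments are deliberately
out of scope: dimers already capture the biosynthesized linkage, which is
what glycosyltransferase activities map onto. Which residues count is
controlled by `filter_options()`:

* `combine_anomers` merges α/β spellings (`aDGlcp`, `bDGlcp` → `DGlcp`);
* underdetermined residues are spellings carrying an explicit `?`
  (`?Kdop`, `b?Fucp`, `?DGal?`); spellings that simply omit a
  configuration are not treated as unknown, matching how the notation is
  written in practice;
* `only_saccharides` restricts to monosaccharides and therefore forces
  monovalent residues out (the two filters are interdependent);
* aliases (`Subst1 = ...` declarations) can be pooled by alias name or
  replaced by their explanations (`explain_subst`);
* position class (terminal / inline / reducing) and branching degree can be
  folded into fragment identities. Both are defined per residue; a dimer
  inherits them from its acceptor, which carries the reducing-end
  semantics. Branching degrees count substituents excluding the residue's
  own acceptor linkage, with monovalent substituents counted or not.

Comparison of fragment identities is always strict: `?DGalp` never equals
`bDGalp`. Treating known configurations as a subset of unknown ones would
make fragment identity non-transitive, so the relaxed mode is not offered.

## The clustering model

The pipeline (`clusterize()`) follows four stages:

1. **Taxon pool.** Taxa at the chosen rank whose population (distinct
   structures assigned to the taxon or its subtaxa) passes an absolute
   threshold and/or a relative threshold, the latter normalized by the
   number of structures in the taxon's database partition (bacterial vs
   plant–fungal by default, `default_domain_groups()`). Defaults follow the
   package's reference analyses: 20 structures for species-level runs,
   1.2% of the partition for genus-level runs. An explicit taxon list
   bypasses the thresholds.
2. **Fragment pool.** Fragments present in at least `fragment_min_structures`
   structures with at least `fragment_min_instances` instances (defaults
   100 and 120). Since one structure can contain several identical
   fragments, the instance threshold should not be below the structure
   threshold; the constructor enforces `>=` and warns on equality.
3. **Occurrence codes.** One bit per pooled fragment and taxon: set when
   the fragment occurs at least `presence_threshold` times (default 2) in
   the taxon's structures. The threshold of 2 suppresses single analytical
   artifacts and one-off exotic fragments. These binary glycoprofiles
   follow the phylogenetic-profile idea: each fragment owns a fixed bit
   position shared by all taxa.
4. **Dissimilarity matrix.** Pairwise Hamming distances between profiles,
   each cell divided by the summed structure counts of its two taxa —
   intensively studied taxa accumulate rare fragments, and without this
   normalization study effort masquerades as biological distance. The
   normalizer is read as the *sum* `N_i + N_j` of the two populations; of
   the combinations consistent with "the total number of structures
   assigned to both taxa" this is the simplest and keeps the matrix
   symmetric. Finally the whole matrix is rescaled so its maximum is 100,
   for compatibility with external clustering software. If all profiles
   are identical the matrix cannot be rescaled and is returned unscaled
   with a warning.

### Trees

Seven tree methods are exposed, the set commonly applied to distance data
in phenetics: UPGMA, complete linkage and Ward's `ward.D2` variant
(`stats::hclust`, rooted dendrograms; `ward_d2` squares the
dissimilarities in the Lance–Williams update), classical neighbor joining
(`ape::nj`), BIONJ, and OLS/balanced minimum evolution
(`ape::fastme.ols`/`ape::fastme.bal`, NNI search from a BIONJ start).
Other linkage schemes and minimum-variance-reduction are excluded: the
former fit biological phylogenetics poorly, the latter targets incomplete
matrices, which cannot arise here.

BIONJ is implemented in the package itself rather than delegated: the
reference C implementation underlying `ape::bionj` accumulates in single
precision, and its path lengths deviate from additive input at the 1e-7
level, while this package promises (and tests) exact reconstruction of
additive matrices to 1e-9. The in-package agglomeration uses the
variance-weighted reduction in double precision with a deterministic
tie-break (first minimal pair in row-major order); tests cross-check its
topologies against `ape::bionj`. Minimum-evolution results are verified in
the test suite against an exhaustive search over all unrooted topologies
(OLS fitted lengths; Pauplin's formula for the balanced criterion) for up
to six taxa.

Trees compare through `topological_score()`: each internal branch induces
a leaf bipartition; a branch pair scores the better of its two side
alignments, each the mean of the two Jaccard indices between aligned
sides; branches are then matched one-to-one by an optimal assignment
(solved exactly — greedy matching can misalign equally good branches) and
the mean matched score is reported as a percent. The per-branch formula of
the published topological-scoring approach is declared here rather than
claimed identical to its reference, and validated against an exhaustive
assignment oracle. Two star trees score 100 by convention (nothing
distinguishes them topologically); when branch counts differ, unmatched
branches count zero. Rooted inputs are unrooted first.

## The synthetic generator

Real collections are not redistributable, so validation runs on seeded
synthetic collections (`generate_collection()`). The taxonomy has
`n_groups` phyla with `taxa_per_group` genera each and
`structures_per_taxon` linear oligomers per genus. Each group owns a dimer
pool built from a group-specific successor permutation of a 12-residue
alphabet of common pyranoses combined with a group-specific acceptor
position, which makes pools disjoint across groups by construction. A
chain step draws from the group pool with probability `1 - noise_rate` and
from a global pool otherwise.

Defaults — 2 groups, 4 genera per group, 25 structures per genus, mean
chain length 6, noise 0.02 — are sized like a modestly covered genus-level
analysis: tens of structures per taxon, chain lengths typical of repeating
units and oligomers, and a few percent of linkages that do not follow the
group's preferences. What the generator does *not* emulate: branched
structures (exercised by hand-written fixtures instead), polymer repeats,
monovalent decoration, skewed frequency spectra of real residues, or
shared fragments between groups. Passing the planted-recovery tests
therefore shows that the pipeline machinery is correct, not that real
glycomes separate this cleanly; on real data group pools overlap and the
trees are correspondingly noisier.

Generation uses one RNG stream seeded once, with a fixed order (groups,
then taxa, then structures), so a seed fully determines the dump byte for
byte.

## Numerical and interface choices

* Percentages are reported half-up to 2 decimals; counts are exact
  integers.
* Fragment pools are ordered lexicographically in the C locale, so bit
  positions are stable across platforms.
* All exports are deterministic; the Nexus writer emits a minimal
  TAXA + TREES block itself because timestamped headers would break
  byte-identical reproducibility.
* Phylip matrix labels are truncated to 10 characters; collisions are an
  error rather than a silent rename.
* "All biota" uniqueness scopes cover only the domains actually loaded in
  the collection; the kingdom scope is the more meaningful default, and
  the coverage caveat is printed by the CLI.
* Degenerate inputs: identical profiles give an unscaled matrix with a
  warning; an all-zero profile is legitimate (an unpopulated taxon); empty
  taxon or fragment pools raise a classed error that the CLI maps to exit
  code 3.
* Alditol/reducing-end artifacts (e.g. d-mannitol) are not auto-detected;
  exclusion is the caller's choice via the filter surface, since artifact
  status is an annotation, not a property of the notation.

## Problem sizes used in validation

The test suite and the acceptance script run on synthetic collections of
2–4 groups × 4 genera × 25 structures (200–400 structures), fragment-pool
thresholds scaled to that size (5 structures / 6 instances), and exhaustive
tree oracles at 5–6 taxa; these sizes exercise every code path while
keeping the suite quick to run. The statistical defaults
(`pool_thresholds()`) remain the reference-analysis values and are used
unchanged wherever population permits.

## Known limitations

* The notation grammar covers the documented subset (residues, linkages,
  branches, one repeating unit, aliases, shortcut suffixes); repetition
  counts, side-chain polymers and multiple structures per line are
  rejected explicitly rather than guessed.
* Residue classification is vocabulary-driven (`csdb_vocabulary()`);
  unknown names default to monosaccharides, so non-sugar aglycons spelled
  without an alias declaration need a vocabulary entry.
* Ring-size extraction from spellings is best-effort (the ring letter is
  embedded mid-name); filters depend only on the anomeric prefix and
  explicit `?` marks, which are extracted exactly.
* Trees are data structures here; publication-quality dendrogram graphics
  beyond the shipped ggplot2 helpers are out of scope.
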