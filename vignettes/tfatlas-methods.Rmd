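---
title: "Models and methods behind tfatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tfatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfatlas)
```

# The scientific problem

Mammalian genomes encode anywhere from roughly 1300 to 2000 transcription
factors (TFs), and the size of individual TF families varies widely even
between close relatives. `tfatlas` implements an analysis chain for asking
where that variation comes from and what it does to regulatory networks:

1. a **TF census** from profile-HMM domain hits (a TF is a protein carrying
   a recognizable DNA-binding domain, DBD);
2. a **duplication–loss atlas**: each TF family's gene tree is reconciled
   with the species tree to place gain (duplication) and loss events on
   species-tree branches and measure per-lineage turnover;
3. an **isolated-TF classification**: in the TF-to-TF interaction
   subnetwork, TFs outside the single largest connected component — tiny
   components and TFs whose only partners are non-TFs — form a distinct,
   evolutionarily labile class;
4. **functional cartography**: within-module degree z-scores and
   participation coefficients place every gene in one of eight network
   roles;
5. **expression contrasts**: negative-binomial regression compares mean
   expression across five classes of genes defined by the orthology of
   their TF partners;
6. **GO overlap curves**: per GO term, how much the TF sets of two species
   overlap, as a smoothed function of set size.

Real inputs (genome-wide domain scans, interaction databases, organ
expression panels) are large downloads; the package therefore ships a
synthetic-data generator whose ground truth is recorded, so every stage can
be validated end to end offline.

# Duplication–loss reconciliation

Gene-tree leaves are labeled `gene_id@species`. `lca_map()` computes the
standard last-common-ancestor mapping `M`: each gene-tree node maps to the
species-tree MRCA of the species below it. Events are read off the mapping:

* a gene node `v` is a **duplication** when `M(v) = M(c)` for one of its
  children `c`; the event is assigned to the species-tree branch above
  `M(v)`;
* on a gene-tree edge `(u, v)` spanning `d` species-tree edges, `d − 1`
  **losses** occur when `u` is a speciation and `d` when `u` is a
  duplication; each loss is assigned to the branch of the bypassed sibling
  subtree, which is exactly the lineage that went missing.

The LCA mapping minimizes the duplication count over all reconciliations;
the test suite confirms this against an exhaustive enumeration of every
ancestry-consistent mapping on small trees. We deliberately do not
re-implement bootstrap-guided rearrangement of weakly supported gene-tree
branches: gene trees are taken as given, because rearrangement is an
optimizer-specific heuristic while the event-counting layer is the analysis
itself.

## Turnover definitions

The published quantities "fraction of a species' TFs gained / lost since the
common ancestor" do not come with printed denominators, so the package fixes
explicit, configurable ones. For species X, pooling families:

* `gained_fraction(X)` = extant copies of X whose *origin* duplication maps
  strictly below the species root, over all extant copies of X
  (`gained_denominator = "extant"`, the default; `"lineage-total"` instead
  divides path gains by root copies + path gains);
* `lost_fraction(X)` = loss events on the root-to-X path over the copies
  that ever existed on that lineage (root copies + gains on the path).

A copy's origin uses a deterministic convention: at each duplication the
first child continues the ancestral copy and the second child is the new
copy. The synthetic generator uses the same convention, so loss-free
simulations round-trip exactly.

# The synthetic generator as study conditions

The generator's defaults are fixed once and treated as the conditions under
which the pipeline is exercised, not as free dials:

* **Species tree**: 16 species, coalescent topology rescaled to unit height.
  Gene families (48, matching the number of small families an analyst can
  build trees for) evolve by a linear birth–death process along the tree
  with duplication rate 0.3 and loss rate 0.1 per copy per unit height —
  enough events that most branches see turnover without families routinely
  going extinct. Every event is recorded against the species branch where it
  occurred, which makes the truth exactly the quantity reconciliation
  estimates.
* **Interactome**: a stochastic block model with 900 genes, 4 modules,
  `p_in = 0.15`, `p_out = 0.02`, 300 TFs spread evenly over modules, and one
  third of TFs planted as isolated (the observed share in the human
  TF-to-TF network). Planted-isolated TFs have all TF–TF edges suppressed
  and keep at least one TF-to-non-TF edge, so they are networked but outside
  the TF-to-TF largest component. Lethality and ortholog-absence flags are
  drawn at 48.8%/3.8% for connected TFs and 5.0%/36.7% for isolated ones —
  the contrast the real annotation join exhibits. Scores are integers
  400–999 on the database's 0–1000 confidence scale.
* **Expression**: negative-binomial counts with log mean `α + β_k`,
  `α = log 50`, `β = (0, 0.5, 1.0, −0.5, 0.25)` across the five
  TF-interaction gene types, dispersion `θ = 2`, 2000 genes per type, five
  organs, two species.
* **GO terms**: 1000 terms with log-uniform set sizes in [5, 400]; the
  expected cross-species overlap proportion decays as `size^−γ` with `γ`
  calibrated so the expectation is 0.5 at size 100 (the qualitative pattern
  seen in real annotations: small terms are regulated by mostly orthologous
  TFs, large terms much less so).

What the generator does **not** emulate: sequence-level realism (domain-hit
tables are emitted directly, because the census logic rather than HMM
scoring is the computation under test), correlated family sizes, degree
heterogeneity beyond the block model, organ- or species-specific expression
shifts, and GO-term hierarchy. Passing tests therefore demonstrate
correctness of the algorithms under these statistical assumptions, not
robustness to every artifact of real data.

# Census conventions

* The E-value filter is **inclusive** at the threshold (default `1e-4`),
  matching common profile-HMM tool semantics; the boundary convention is
  asserted in tests.
* Isoforms collapse per (gene, species, family) to the highest bit score,
  ties broken by the lexicographically smallest protein id. When a hit
  lacks a gene name the protein id stands in for the gene — a stated
  convention, since isoform-to-gene grouping is upstream annotation.
* A gene carrying DBDs of several families counts once in each family.
  This deliberately reproduces the inflation of cross-family correlations
  caused by shared-DBD genes.
* Counts are standardized per family to a cross-species mean of 1.
  Pearson correlation is computed on the matrix as given; because
  standardization is a per-column scaling it leaves r unchanged, so raw or
  standardized input is equally valid. Zero-variance families are excluded
  from both the numerator and denominator of the weak-pair fraction.

# Network and cartography choices

* Edge threshold inclusive at 0.4 (medium confidence); integer 0–1000
  scores are auto-rescaled, and a file mixing scales is an error rather
  than a guess.
* "Isolated" follows the component definition (everything networked but
  outside the largest TF-to-TF component), which subsumes small TF-TF
  components as well as TFs with only non-TF partners. TFs with no
  interactions at all are excluded from both classes and reported
  separately, since their isolation is indistinguishable from lack of
  study. A tie for the largest component is an error that demands an
  explicit `tie_break` rather than a silent arbitrary choice.
* Module detection uses deterministic greedy modularity optimization (the
  original cartography protocol used simulated annealing, which is
  stochastic and slow); reproducibility is preferred to fidelity to an
  unspecified optimizer, and precomputed assignments are accepted wherever
  modules are consumed. As a guard for degenerate tiny graphs, a greedy
  partition is never accepted if plain connected components score higher
  modularity.
* `z` uses the **population** standard deviation of within-module degree,
  as in the cartography literature; a module whose members all have equal
  within-module degree gives `z = 0` (no ranking signal, no division by
  zero). In the z formula κ counts links to the node's own module; in the
  participation coefficient k is total degree — two different quantities
  that share a symbol in the original notation.
* The printed definition of kinless hubs (class 8) lacks a z condition and
  would overlap the non-hub classes; the package requires `z ≥ 2.5` so
  classes 2–8 partition cleanly. The completion is recorded in the result's
  `class8_rule` attribute.

# Expression model

Gene types derive from TF-partner profiles across the two networks:
reference (no TF partners), all-orthologous partners, species-specific
partners in both species, or in one species only, with precedence
both > one > orthologous for mixed profiles (the precedence is a package
convention; mixed profiles are not resolved in the original description).
Genes present in the ortholog table but absent from both networks fall to
the reference type with a logged note.

The contrast `log E[expression | type = k] = α + β_k` is fit with
`MASS::glm.nb` (maximum-likelihood dispersion), reference first, so `β_k`
is the log mean of type k relative to genes without TF interactions. TPM
values are continuous; by default they are rounded to the nearest integer
for the count likelihood (`nb_input = "rounded"`), and `"raw-counts"`
disables rounding for genuine counts. No cross-species rescaling beyond TPM
is applied. Identifiability is verified by a relabeling test: changing the
reference shifts all β by a constant while α compensates.

# GO overlap

Per term, `q = |A ∩ B| / ((|A| + |B|) / 2)`, algebraically the
Sørensen–Dice coefficient (asserted as a cross-check in tests). Orthology
between the two species' TF namespaces is an input table; unmapped TFs
count toward set sizes but never toward the intersection — a conservative
choice that can only lower q. Smoothing is a degree-2 loess of q on log
average size with `surface = "direct"` (deterministic, order-invariant),
span 0.75 by default (no span is published), predictions clipped to [0, 1].
GO-hierarchy propagation is out of scope; annotations are compared as
given.

# Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
package's own validation design: exhaustive reconciliation oracles on gene
trees of up to 6 leaves, 200 birth–death families for copy-number
conservation, 20-seed planted-partition recovery at 900 genes, 10-seed NB
recovery at 2000 genes per type, and 1000-term GO curves. Dispersion
estimation follows `glm.nb` defaults; loess failures on sparse inputs are
reported with a suggestion to enlarge the span; standardization tolerances
are 1e-12 (exact arithmetic identities) and 1e-9 (module-wise z
standardization).

# Known limitations

* LCA parsimony undercounts duplications whose descendants were later
  erased by losses; the round-trip equality with simulator truth therefore
  holds exactly only in the loss-free regime, and as an inequality
  (`estimated ≤ true`) otherwise.
* The greedy module detector is a convention, not the optimum; role classes
  near the z and p cut-points can shift with the module partition.
* The isolated/connected annotation contrasts in the generator are marginal
  probabilities; the package does not model correlation between lethality
  and ortholog absence.
* Single-copy families that dwindle to fewer than two surviving genes have
  no gene tree to reconcile and are skipped by the atlas (their event lists
  remain available from the generator).
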