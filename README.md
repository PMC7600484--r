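# tfatlas

Tools for studying how mammalian transcription-factor (TF) repertoires
evolve and what that evolution does to regulatory networks.

TF counts vary widely across mammals (roughly 1300–2000 per genome), and in
the human TF-to-TF interaction network about a third of TFs are *isolated*:
they interact with non-TF genes but sit outside the largest connected
component of the TF-to-TF subnetwork. These isolated TFs are less often
lethal when mutated, far more often absent in other species, and plausibly
act as evolutionary switches that tune target-gene expression between
species. `tfatlas` packages the full analysis chain behind that picture,
for computational biologists who want to run it on their own species sets
or audit each stage against synthetic ground truth:

* **TF census** (`filter_hits`, `dedup_isoforms`, `count_families`,
  `standardize_counts`, `family_correlations`) — per-species TF catalogs
  from profile-HMM domain-hit tables (hmmscan per-domain format or a plain
  6-column TSV), family count matrices standardized to a cross-species mean
  of 1, and the fraction of weakly correlated family pairs.
* **Duplication–loss atlas** (`lca_map`, `reconcile`, `branch_atlas`,
  `lineage_turnover`) — LCA (parsimony) reconciliation of TF-family gene
  trees with a species tree. A gene node is a duplication iff it maps to the
  same species node as one of its children; a gene edge spanning *d* species
  branches implies *d − 1* losses after a speciation and *d* after a
  duplication. Events accumulate per species-tree branch, and per-lineage
  turnover (fraction of a species' TFs gained / lost since the common
  ancestor) is reported.
* **Isolated-TF classification** (`load_edges`, `classify_tf_components`,
  `summarize_classes`, `relative_difference`) — score-thresholded
  interaction networks (confidence ≥ 0.4), the largest-component definition
  of isolation, and Table-style class summaries.
* **Functional cartography** (`detect_modules`, `within_module_z`,
  `participation_coefficient`, `classify_roles`) — within-module degree
  z-score `z_i = (κ_i − mean κ) / sd κ` (population sd) and participation
  coefficient `p_i = 1 − Σ_s (k_is / k_i)²`, with the eight role classes
  (ultra-peripheral … kinless hub).
* **Expression contrasts** (`assign_gene_types`, `fit_nb_contrast`,
  `contrast_profile`) — negative-binomial regression
  `log E[expr | type = k] = α + β_k` over the five TF-interaction gene
  types, per organ and species.
* **GO overlap** (`overlap_proportion`, `go_overlap_table`,
  `smooth_overlap`) — per-GO-term TF-set overlap
  `q = |A ∩ B| / ((|A| + |B|)/2)` between two species, loess-smoothed
  against set size.
* **Synthetic data** (`simulate_species_tree`, `simulate_gene_family`,
  `simulate_ppi_network`, `simulate_expression`, `simulate_go_annotations`,
  `simulate_domain_hits`) — generators with recorded ground truth for every
  stage: birth–death gene families on a known species tree, planted-
  partition interactomes with a planted isolated-TF subset, NB expression
  with known contrasts, and GO sets with a calibrated overlap decay.

## Worked example

Simulate 48 TF families on an 8-species tree, reconcile each gene tree, and
summarize the gain/loss atlas and lineage turnover:

```r
library(tfatlas)

st   <- simulate_species_tree(8, seed = 42)
fams <- lapply(1:48, function(i) simulate_gene_family(st, 0.3, 0.1, seed = i))
fams <- Filter(function(f) length(f$leaves) >= 2, fams)
recs <- lapply(fams, function(f) reconcile(f$tree, st))

head(branch_atlas(recs, st), 4)
#>   node label parent gains losses events      share
#> 1    1  sp04     15     0      0      0 0.00000000
#> 2    2  sp05     15     0      0      0 0.00000000
#> 3    3  sp07     14     1      0      1 0.02127660
#> 4    4  sp06     12     1      1      2 0.04255319

tv <- lineage_turnover(recs, st)
sprintf("gained %.1f%%  lost %.1f%%", tv$mean_gained_pct, tv$mean_lost_pct)
#> "gained 25.2%  lost 1.4%"
```

Each atlas row is a species-tree branch (keyed by its child node): `gains`
counts duplications assigned to that branch over all families, `losses`
counts lost copies, `share` is the branch's fraction of all events. The
turnover means say that, under these simulation conditions, on average a
quarter of an extant species' TF copies arose after the common ancestor and
1.4% of the copies its lineage ever carried were lost.

Classify TFs in a planted-partition interactome and join annotations:

```r
net <- simulate_ppi_network(sim_config(seed = 7))
cl  <- classify_tf_components(load_edges(net$edges, 0.4),
                              net$nodes$gene[net$nodes$is_tf])
cl
#> TF-to-TF network classification
#>   large component: 200
#>   isolated:        100
#>   no interactions: 0

summarize_classes(cl, data.frame(gene = net$nodes$gene,
                                 lethal = net$nodes$lethal,
                                 absent_in_other = net$nodes$absent_in_other))
#>             class   n lethal_n lethal_pct absent_n absent_pct degree_mean degree_sd
#> 1 large_component 200       93       46.5        7        3.5      42.375  6.028773
#> 2        isolated 100        2        2.0       34       34.0      30.860  4.907261
```

The 100 planted isolated TFs are recovered exactly, and the class summary
shows the planted annotation contrast: isolated TFs are rarely lethal but
often absent in the comparator species.

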