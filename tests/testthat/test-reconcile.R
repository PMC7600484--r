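test_that("LCA mapping matches the forced small cases", {
  st2 <- ape::read.tree(text = "(A,B);")
  gt2 <- ape::read.tree(text = "(a1@A,b1@B);")
  M <- lca_map(gt2, st2)
  expect_equal(unname(M[3]), 3)  # gene root -> species root

  st <- toy_species()
  gt <- ape::read.tree(text = "((a1@A,a2@A),b1@B);")
  M <- lca_map(gt, st)
  inner <- ape::getMRCA(gt, c("a1@A", "a2@A"))
  expect_equal(unname(M[inner]), match("A", st$tip.label))
  # species under the gene root are {A, B}: maps to their ancestor
  expect_equal(unname(M[ape::Ntip(gt) + 1L]), ape::getMRCA(st, c("A", "B")))

  bad <- ape::read.tree(text = "(a1@A,zz@NOPE);")
  expect_error(lca_map(bad, st), "zz@NOPE")
})

test_that("LCA mapping equals the recursive clade-MRCA oracle on congruent trees", {
  for (seed in 1:40) {
    st <- simulate_species_tree(sample(4:10, 1), seed = seed)
    fam <- simulate_gene_family(st, 0, 0, seed = seed + 100)
    M <- lca_map(fam$tree, st)
    expect_equal(unname(M), oracle_lca_map(fam$tree, st))
  }
})

test_that("mapping respects ancestry along every gene-tree edge", {
  for (seed in 1:20) {
    st <- simulate_species_tree(6, seed = seed)
    gt <- random_gene_tree(8, st$tip.label, seed = seed + 7)
    r <- reconcile(gt, st)
    par <- oracle_parents(st)
    for (i in seq_len(nrow(gt$edge))) {
      u <- gt$edge[i, 1]
      v <- gt$edge[i, 2]
      expect_true(oracle_is_anc(r$mapping[u], r$mapping[v], par))
    }
  }
})

test_that("reconciliation of the 4-leaf worked case gives 1 duplication, 1 loss", {
  st <- toy_species()
  gt <- ape::read.tree(text = "((a1@A,(a2@A,b1@B)),c1@C);")
  r <- reconcile(gt, st)
  expect_equal(r$n_dup, 1)
  expect_equal(r$n_loss, 1)
  # the duplication sits on the branch above the A-B ancestor,
  # the loss on the B branch
  ab <- ape::getMRCA(st, c("A", "B"))
  expect_equal(r$branches$gains[ab], 1)
  expect_equal(r$branches$losses[match("B", st$tip.label)], 1)
  # exhaustive enumeration confirms 1 duplication is the minimum
  expect_equal(oracle_min_dups(gt, st), 1)
})

test_that("congruent gene trees reconcile with zero events", {
  st <- simulate_species_tree(9, seed = 2)
  fam <- simulate_gene_family(st, 0, 0, seed = 3)
  r <- reconcile(fam$tree, st)
  expect_equal(r$n_dup, 0)
  expect_equal(r$n_loss, 0)
  expect_true(all(r$origins$ancestral))
})

test_that("polytomies error unless a resolution seed is supplied", {
  st <- toy_species()
  gt <- ape::read.tree(text = "(a1@A,b1@B,c1@C);")
  expect_error(reconcile(gt, st), "polytomies")
  r <- reconcile(gt, st, resolve_polytomies = 1)
  expect_s3_class(r, "reconciliation")
})

test_that("atlas is additive across families and zero for no families", {
  st <- simulate_species_tree(6, seed = 4)
  f1 <- simulate_gene_family(st, 0.4, 0, seed = 5)
  f2 <- simulate_gene_family(st, 0.4, 0, seed = 6)
  r1 <- reconcile(f1$tree, st)
  r2 <- reconcile(f2$tree, st)
  a1 <- branch_atlas(list(r1), st)
  a2 <- branch_atlas(list(r2), st)
  both <- branch_atlas(list(r1, r2), st)
  expect_equal(both$gains, a1$gains + a2$gains)
  expect_equal(both$losses, a1$losses + a2$losses)

  zero <- branch_atlas(list(), st)
  expect_true(all(zero$events == 0))
  expect_true(all(is.na(zero$share)))

  other <- simulate_species_tree(6, seed = 99)
  expect_error(branch_atlas(list(r1), other), "same species tree")
})

test_that("a single duplication lands in exactly one atlas cell", {
  st <- toy_species()
  gt <- ape::read.tree(text = "(((a1@A,a2@A),b1@B),c1@C);")
  r <- reconcile(gt, st)
  a <- branch_atlas(list(r), st)
  expect_equal(sum(a$gains > 0), 1)
  expect_equal(a$gains[match("A", st$tip.label)], 1)
  expect_equal(sum(a$losses), 0)
})

test_that("turnover is zero without events and 1/2 for one terminal duplication", {
  st <- simulate_species_tree(5, seed = 7)
  fam <- simulate_gene_family(st, 0, 0, seed = 8)
  tv <- lineage_turnover(list(reconcile(fam$tree, st)), st)
  expect_true(all(tv$per_species$gained_fraction == 0))
  expect_true(all(tv$per_species$lost_fraction == 0))

  st3 <- toy_species()
  gt <- ape::read.tree(text = "(((a1@A,a2@A),b1@B),c1@C);")
  tv2 <- lineage_turnover(list(reconcile(gt, st3)), st3)
  per <- tv2$per_species
  expect_equal(per$gained_fraction[per$species == "A"], 1 / 2)
  expect_equal(per$gained_fraction[per$species == "B"], 0)
  expect_true(all(per$lost_fraction == 0))
})

test_that("turnover on loss-free simulations matches ground truth exactly", {
  st <- simulate_species_tree(8, seed = 10)
  fams <- lapply(1:50, function(s) simulate_gene_family(st, 0.3, 0, seed = s))
  recs <- lapply(fams, function(f) reconcile(f$tree, st))
  tv <- lineage_turnover(recs, st)

  dups <- rowSums(sapply(fams, function(f) {
    truth_path_events(st, f$events)["dups", ]
  }))
  extant <- rowSums(sapply(fams, function(f) {
    table(factor(leaf_species(f$leaves), levels = st$tip.label))
  }))
  expect_equal(tv$per_species$gained_fraction, unname(dups / extant))
  expect_equal(tv$per_species$path_gains, unname(dups))
  expect_true(all(tv$per_species$lost_fraction == 0))
})

test_that("reconciliation recovers true duplication counts when no subtree was lost", {
  st <- simulate_species_tree(8, seed = 55)
  exact <- 0
  for (seed in 1:80) {
    fam <- simulate_gene_family(st, 0.3, 0.1, seed = seed)
    if (length(fam$leaves) < 2) next
    r <- reconcile(fam$tree, st)
    true_dups <- sum(fam$events$type == "duplication")
    # parsimony can never demand more duplications than truly happened
    expect_lte(r$n_dup, true_dups)
    if (!any(fam$events$type == "loss")) {
      expect_equal(r$n_dup, true_dups)
      exact <- exact + 1
    }
  }
  expect_gt(exact, 5)  # the loss-free subset is non-trivial
})
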