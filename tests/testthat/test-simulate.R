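test_that("species-tree simulation is valid, minimal and deterministic", {
  t2 <- simulate_species_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_equal(t2$Nnode, 1)

  t8a <- simulate_species_tree(8, seed = 7)
  t8b <- simulate_species_tree(8, seed = 7)
  expect_identical(ape::write.tree(t8a), ape::write.tree(t8b))
  expect_equal(t8a$Nnode, 7)  # rooted binary: n - 1 internals
  expect_true(ape::is.binary(t8a))
  expect_true(ape::is.ultrametric(t8a, tol = 1e-8))
  expect_equal(anyDuplicated(t8a$tip.label), 0L)

  expect_error(simulate_species_tree(1, seed = 1), "at least 2")
})

test_that("gene families with no events are congruent with the species tree", {
  st <- simulate_species_tree(8, seed = 3)
  fam <- simulate_gene_family(st, 0, 0, seed = 9)
  expect_equal(nrow(fam$events), 0)
  expect_equal(length(fam$leaves), 8)
  gt <- fam$tree
  gt$tip.label <- leaf_species(gt$tip.label)
  expect_equal(ape::dist.topo(ape::unroot(gt), ape::unroot(st)), 0,
               ignore_attr = TRUE)
})

test_that("without losses, copy number equals 1 + path duplications", {
  st <- simulate_species_tree(10, seed = 5)
  for (seed in 1:25) {
    fam <- simulate_gene_family(st, 0.4, 0, seed = seed)
    truth <- truth_path_events(st, fam$events)
    per_sp <- table(factor(leaf_species(fam$leaves), levels = st$tip.label))
    expect_equal(as.numeric(per_sp), 1 + truth["dups", ],
                 ignore_attr = TRUE)
  }
})

test_that("simulated event lists reference existing species branches", {
  st <- simulate_species_tree(6, seed = 2)
  fam <- simulate_gene_family(st, 0.5, 0.3, seed = 13)
  n_nodes <- ape::Ntip(st) + st$Nnode
  expect_true(all(fam$events$node >= 1 & fam$events$node <= n_nodes))
  # events never land on the root itself: copies enter at the root node
  expect_false((ape::Ntip(st) + 1L) %in% fam$events$node)
})

test_that("planted isolated TFs have no TF-TF edges but stay networked", {
  cfg <- sim_config(seed = 21, n_genes = 300, n_tfs = 90, n_modules = 3)
  net <- simulate_ppi_network(cfg)
  tfs <- net$nodes$gene[net$nodes$is_tf]
  iso <- net$truth
  tftf <- net$edges$node_a %in% tfs & net$edges$node_b %in% tfs
  expect_false(any(net$edges$node_a[tftf] %in% iso |
                   net$edges$node_b[tftf] %in% iso))
  networked <- unique(c(net$edges$node_a, net$edges$node_b))
  expect_true(all(iso %in% networked))
})

test_that("network simulation is deterministic and blocks match components at p_out = 0", {
  cfg <- sim_config(seed = 8, n_genes = 200, n_tfs = 60, n_modules = 4,
                    p_in = 0.3, p_out = 0)
  a <- simulate_ppi_network(cfg)
  b <- simulate_ppi_network(cfg)
  expect_identical(a$edges, b$edges)
  expect_identical(a$nodes, b$nodes)

  g <- igraph::graph_from_data_frame(a$edges[, 1:2], directed = FALSE)
  comp <- igraph::components(g)$membership
  mod <- a$nodes$module[match(names(comp), a$nodes$gene)]
  # block-diagonal limit: no component spans two modules
  expect_true(all(tapply(mod, comp, function(x) length(unique(x))) == 1))
})

test_that("expression simulator hits the Poisson limit at large theta", {
  cfg <- sim_config(seed = 4, theta = 1e6, n_genes_per_type = 4000,
                    beta = c(ref = 0), organs = "liver")
  sim <- simulate_expression(cfg)
  y <- sim$expression$expression[sim$expression$species == "human"]
  expect_lt(abs(stats::var(y) / mean(y) - 1), 0.1)
})

test_that("expression simulator rejects non-positive dispersion", {
  expect_error(sim_config(theta = 0), "theta")
})

test_that("GO simulator limits: zero decay gives full overlap", {
  cfg <- sim_config(seed = 6, go_n_terms = 50, go_decay = 0)
  g <- simulate_go_annotations(cfg)
  tab <- go_overlap_table(g$annotations_a, g$annotations_b,
                          map = g$ortholog_map)
  expect_true(all(tab$q == 1))
})

test_that("disjoint GO sets give zero overlap", {
  ann_a <- data.frame(term = rep("t1", 3), tf = c("a1", "a2", "a3"))
  ann_b <- data.frame(term = rep("t1", 3), tf = c("b1", "b2", "b3"))
  map <- data.frame(tf_a = "a9", tf_b = "b9")
  tab <- go_overlap_table(ann_a, ann_b, map = map)
  expect_equal(tab$q, 0)
})

test_that("domain-hit simulator round-trips through the census exactly", {
  sim <- simulate_domain_hits(n_species = 5, seed = 17)
  counts <- count_families(build_tf_catalog(dedup_isoforms(
    filter_hits(sim$hits, 1e-4))))
  expect_equal(counts[rownames(sim$truth_counts), colnames(sim$truth_counts)],
               sim$truth_counts)
})

test_that("a simulation bundle writes and reads back", {
  dir <- withr::local_tempdir()
  st <- simulate_species_tree(5, seed = 1)
  fam <- simulate_gene_family(st, 0.3, 0, seed = 2)
  net <- simulate_ppi_network(sim_config(seed = 3, n_genes = 100, n_tfs = 30,
                                         n_modules = 2))
  write_sim_bundle(dir, species_tree = st, families = list(fam),
                   network = net)
  expect_true(file.exists(file.path(dir, "species_tree.nwk")))
  st2 <- ape::read.tree(file.path(dir, "species_tree.nwk"))
  expect_identical(st2$tip.label, st$tip.label)
  edges2 <- utils::read.table(file.path(dir, "edges.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(edges2), nrow(net$edges))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_equal(unlist(truth$planted_isolated), net$truth,
               ignore_attr = TRUE)
})
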