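two_cliques <- function(k = 5) {
  a <- t(combn(paste0("a", 1:k), 2))
  b <- t(combn(paste0("b", 1:k), 2))
  data.frame(node_a = c(a[, 1], b[, 1], "a1"),
             node_b = c(a[, 2], b[, 2], "b1"), score = 1)
}

test_that("greedy module detection separates two bridged cliques", {
  mod <- detect_modules(two_cliques())
  expect_equal(mod$n_modules, 2)
  mem <- mod$membership
  expect_equal(length(unique(mem[paste0("a", 1:5)])), 1)
  expect_equal(length(unique(mem[paste0("b", 1:5)])), 1)

  single <- detect_modules(data.frame(node_a = "x", node_b = "y", score = 1))
  expect_equal(single$n_modules, 1)
})

test_that("block-model modules are recovered at p_out near zero", {
  agree <- vapply(1:20, function(seed) {
    cfg <- sim_config(seed = seed, n_genes = 200, n_tfs = 40, n_modules = 3,
                      p_in = 0.25, p_out = 0.005)
    net <- simulate_ppi_network(cfg)
    mod <- detect_modules(net$edges, seed = seed)
    truth <- net$nodes$module[match(names(mod$membership), net$nodes$gene)]
    igraph::compare(as.integer(mod$membership), truth, method = "nmi")
  }, numeric(1))
  expect_true(mean(agree >= 0.95) >= 0.95)
})

test_that("within-module z matches the star closed form and the sd=0 convention", {
  star <- data.frame(node_a = "hub", node_b = paste0("leaf", 1:10), score = 1)
  asg <- stats::setNames(rep(1, 11), c("hub", paste0("leaf", 1:10)))
  z <- within_module_z(star, asg)
  # kappa = (10, 1 x10), population sd: hub z = sqrt(10)
  expect_equal(unname(z["hub"]), sqrt(10), tolerance = 1e-12)
  expect_equal(unname(z["leaf1"]), -1 / sqrt(10), tolerance = 1e-12)

  # all-equal within-module degree: z = 0 everywhere
  ring <- data.frame(node_a = c("r1", "r2", "r3"),
                     node_b = c("r2", "r3", "r1"), score = 1)
  z0 <- within_module_z(ring, stats::setNames(rep(1, 3), paste0("r", 1:3)))
  expect_true(all(z0 == 0))
})

test_that("each module's z-scores have mean 0 and population sd 1", {
  cfg <- sim_config(seed = 41, n_genes = 300, n_tfs = 60, n_modules = 4,
                    p_in = 0.2, p_out = 0.02)
  net <- simulate_ppi_network(cfg)
  mod <- detect_modules(net$edges)
  z <- within_module_z(net$edges, mod)
  for (m in unique(mod$membership)) {
    zm <- z[names(mod$membership)[mod$membership == m]]
    if (stats::sd(zm) > 0) {
      expect_lt(abs(mean(zm)), 1e-9)
      expect_lt(abs(sqrt(mean((zm - mean(zm))^2)) - 1), 1e-9)
    }
  }
})

test_that("participation coefficient matches its closed forms", {
  # all links in one module -> 0
  e1 <- data.frame(node_a = c("n", "n"), node_b = c("m1", "m2"), score = 1)
  a1 <- stats::setNames(c(1, 1, 1), c("n", "m1", "m2"))
  expect_equal(unname(participation_coefficient(e1, a1)["n"]), 0)

  # degree 4 split evenly over 4 modules -> 1 - 1/4
  e2 <- data.frame(node_a = rep("n", 4), node_b = paste0("m", 1:4), score = 1)
  a2 <- stats::setNames(c(1, 1:4), c("n", paste0("m", 1:4)))
  expect_equal(unname(participation_coefficient(e2, a2)["n"]), 0.75)

  # k_is = (3, 1): p = 1 - (9 + 1)/16
  e3 <- data.frame(node_a = rep("n", 4),
                   node_b = c("x1", "x2", "x3", "y1"), score = 1)
  a3 <- stats::setNames(c(1, 1, 1, 1, 2), c("n", "x1", "x2", "x3", "y1"))
  expect_equal(unname(participation_coefficient(e3, a3)["n"]), 0.375)
})

test_that("k_is sums to the total degree and p stays within [0, 1 - 1/N_M]", {
  cfg <- sim_config(seed = 5, n_genes = 250, n_tfs = 50, n_modules = 5,
                    p_in = 0.15, p_out = 0.03)
  net <- simulate_ppi_network(cfg)
  carto <- cartography(net$edges, seed = 1)
  g <- igraph::simplify(igraph::graph_from_data_frame(net$edges[, 1:2],
                                                      directed = FALSE))
  deg <- igraph::degree(g)[carto$node]
  expect_equal(carto$degree, unname(deg))
  n_m <- length(unique(carto$module))
  expect_true(all(carto$p >= 0 - 1e-12))
  expect_true(all(carto$p <= 1 - 1 / n_m + 1e-12))
})

test_that("role classification reproduces the printed cut-points and partitions", {
  expect_equal(as.integer(classify_roles(3, 0.1)), 6L)    # provincial hub
  expect_equal(as.integer(classify_roles(0, 0)), 2L)      # ultra-peripheral
  expect_equal(as.integer(classify_roles(2.5, 0.75)), 8L) # inclusive boundaries
  expect_equal(as.integer(classify_roles(0, 0.05)), 3L)
  expect_equal(as.integer(classify_roles(0, 0.7)), 4L)
  expect_equal(as.integer(classify_roles(0, 0.9)), 5L)
  expect_equal(as.integer(classify_roles(3, 0.5)), 7L)
  expect_equal(as.integer(classify_roles(0, 0, has_interactions = FALSE)), 1L)

  # classes 2-8 partition every (z, p) combination with interactions
  set.seed(1)
  z <- stats::runif(500, -3, 5)
  p <- stats::runif(500, 0, 1)
  roles <- classify_roles(z, p)
  expect_true(all(roles %in% 2:8))
})
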