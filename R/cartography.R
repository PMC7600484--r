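# normalize a module assignment to a named integer vector with
# contiguous labels 1..N_M
.as_assignment <- function(assignment) {
  if (is.data.frame(assignment)) {
    v <- assignment[[2]]
    names(v) <- assignment[[1]]
    assignment <- v
  }
  lab <- as.integer(factor(assignment))
  names(lab) <- names(assignment)
  lab
}

#' Detect network modules by greedy modularity optimization
#'
#' Deterministic greedy (agglomerative) modularity maximization. A
#' precomputed assignment can be supplied to bypass detection, e.g. one
#' produced by a slower stochastic optimizer.
#'
#' @param edges Edge data.frame (`node_a`, `node_b`, ...).
#' @param seed Integer seed, set before detection so any stochastic
#'   detector swapped in later stays reproducible; the default greedy
#'   algorithm is deterministic.
#' @param assignment Optional precomputed assignment: a data.frame
#'   (node, module) or a named vector; must cover every networked node.
#' @return List of class `"module_assignment"`: `membership` (named integer
#'   vector, labels 1..n_modules) and `n_modules`.
#' @export
detect_modules <- function(edges, seed = 1L, assignment = NULL) {
  g <- .graph_from_edges(edges)
  if (igraph::vcount(g) == 0) stop("empty network")
  if (is.null(assignment)) {
    set.seed(as.integer(seed))
    cl <- igraph::cluster_fast_greedy(g)
    mem <- as.integer(igraph::membership(cl))
    # never accept a partition worse than plain connected components
    # (guards tiny graphs where the greedy merge sequence stops early)
    comp <- as.integer(igraph::components(g)$membership)
    if (igraph::modularity(g, comp) > igraph::modularity(g, mem)) mem <- comp
    membership <- mem
    names(membership) <- igraph::V(g)$name
  } else {
    membership <- .as_assignment(assignment)
    miss <- setdiff(igraph::V(g)$name, names(membership))
    if (length(miss) > 0) {
      stop("assignment does not cover node(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    membership <- membership[igraph::V(g)$name]
  }
  structure(list(membership = membership,
                 n_modules = length(unique(membership))),
            class = "module_assignment")
}

# per-node degree into each module: list(kappa = links to own module,
# degree = total, k_by_module = node x module matrix)
.module_link_counts <- function(edges, membership) {
  g <- .graph_from_edges(edges)
  nodes <- igraph::V(g)$name
  miss <- setdiff(nodes, names(membership))
  if (length(miss) > 0) {
    stop("assignment does not cover node(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  mods <- sort(unique(membership[nodes]))
  k_is <- matrix(0L, length(nodes), length(mods),
                 dimnames = list(nodes, as.character(mods)))
  if (nrow(el) > 0) {
    ends <- c(el[, 1], el[, 2])
    mod_other <- membership[c(el[, 2], el[, 1])]
    tab <- table(factor(ends, levels = nodes),
                 factor(mod_other, levels = mods))
    k_is[] <- as.integer(tab)
  }
  kappa <- k_is[cbind(nodes, as.character(membership[nodes]))]
  names(kappa) <- nodes
  list(nodes = nodes, kappa = kappa, degree = rowSums(k_is),
       k_by_module = k_is, membership = membership[nodes])
}

#' Within-module degree z-score
#'
#' Standardizes each node's number of links to its own module against the
#' distribution of that count over the module's members:
#' `z_i = (kappa_i - mean(kappa in module)) / sd(kappa in module)`, with the
#' population standard deviation. A module whose members all have the same
#' within-module degree carries no ranking signal, so its nodes get `z = 0`.
#'
#' @param edges Edge data.frame.
#' @param assignment A [detect_modules()] result, named vector, or
#'   (node, module) data.frame covering all networked nodes.
#' @return Named numeric vector of z-scores.
#' @export
within_module_z <- function(edges, assignment) {
  membership <- if (inherits(assignment, "module_assignment")) {
    assignment$membership
  } else {
    .as_assignment(assignment)
  }
  lc <- .module_link_counts(edges, membership)
  z <- numeric(length(lc$nodes))
  names(z) <- lc$nodes
  for (m in unique(lc$membership)) {
    sel <- lc$membership == m
    k <- lc$kappa[sel]
    mu <- mean(k)
    sdev <- sqrt(mean((k - mu)^2))  # population sd
    z[sel] <- if (sdev > 0) (k - mu) / sdev else 0
  }
  z
}

#' Participation coefficient
#'
#' `p_i = 1 - sum_s (k_is / k_i)^2`, where `k_is` counts node i's links into
#' module s and `k_i` is its total degree: 0 when all links stay in one
#' module, approaching `1 - 1/N_M` when links spread evenly over all
#' modules. Degree-0 nodes have no defined participation and return NA with
#' a logged count.
#'
#' @inheritParams within_module_z
#' @return Named numeric vector of participation coefficients.
#' @export
participation_coefficient <- function(edges, assignment) {
  membership <- if (inherits(assignment, "module_assignment")) {
    assignment$membership
  } else {
    .as_assignment(assignment)
  }
  lc <- .module_link_counts(edges, membership)
  p <- 1 - rowSums((lc$k_by_module / pmax(lc$degree, 1))^2)
  zero <- lc$degree == 0
  if (any(zero)) {
    message(sum(zero), " degree-0 node(s): participation undefined (NA)")
    p[zero] <- NA_real_
  }
  names(p) <- lc$nodes
  p
}

#' Role-class labels
#' @return Character vector of the eight role-class names, indexed 1-8.
#' @export
role_labels <- function() {
  c("no_interactions", "ultra_peripheral", "peripheral",
    "non_hub_connector", "non_hub_kinless", "provincial_hub",
    "connector_hub", "kinless_hub")
}

#' Classify nodes into the eight cartographic roles
#'
#' Class 1 is reserved for genes with no experimental interactions. Nodes
#' with interactions split on the hub threshold `z >= 2.5`: non-hubs are
#' ultra-peripheral (`p < 0.05`), peripheral (`0.05 <= p < 0.625`), non-hub
#' connectors (`0.625 <= p < 0.8`) or non-hub kinless (`p >= 0.8`); hubs are
#' provincial (`p < 0.3`), connector (`0.3 <= p < 0.75`) or kinless
#' (`p >= 0.75`). Lower bounds are inclusive. Kinless hubs (class 8) require
#' both `z >= 2.5` and `p >= 0.75`, completing the published cut-points into
#' a clean partition (recorded in the result's `class8_rule` attribute).
#'
#' @param z,p Numeric vectors (within-module degree z, participation).
#' @param has_interactions Logical vector; `FALSE` forces class 1.
#' @return Integer vector of classes 1-8, with a `labels` attribute from
#'   [role_labels()] and attribute `class8_rule = "z>=2.5 & p>=0.75"`.
#' @export
classify_roles <- function(z, p, has_interactions = rep(TRUE, length(z))) {
  stopifnot(length(z) == length(p), length(z) == length(has_interactions))
  role <- integer(length(z))
  for (i in seq_along(z)) {
    if (!has_interactions[i] || is.na(z[i]) || is.na(p[i])) {
      role[i] <- 1L
    } else if (z[i] < 2.5) {
      role[i] <- if (p[i] < 0.05) 2L else if (p[i] < 0.625) 3L
        else if (p[i] < 0.8) 4L else 5L
    } else {
      role[i] <- if (p[i] < 0.3) 6L else if (p[i] < 0.75) 7L else 8L
    }
  }
  names(role) <- names(z)
  attr(role, "labels") <- role_labels()
  attr(role, "class8_rule") <- "z>=2.5 & p>=0.75"
  role
}

#' Functional cartography of a network
#'
#' Convenience wrapper: detects (or accepts) modules, computes each node's
#' within-module degree, z-score, participation coefficient and role class.
#'
#' @param edges Edge data.frame.
#' @param assignment Optional precomputed module assignment.
#' @param seed Seed passed to [detect_modules()].
#' @return data.frame: `node`, `module`, `kappa`, `degree`, `z`, `p`,
#'   `role`, `role_label`.
#' @export
cartography <- function(edges, assignment = NULL, seed = 1L) {
  mod <- if (inherits(assignment, "module_assignment")) assignment
         else detect_modules(edges, seed = seed, assignment = assignment)
  lc <- .module_link_counts(edges, mod$membership)
  z <- within_module_z(edges, mod)
  p <- participation_coefficient(edges, mod)
  role <- classify_roles(z, p, has_interactions = lc$degree > 0)
  data.frame(
    node = lc$nodes,
    module = as.integer(lc$membership),
    kappa = as.integer(lc$kappa),
    degree = as.integer(lc$degree),
    z = as.numeric(z),
    p = as.numeric(p),
    role = as.integer(role),
    role_label = role_labels()[role],
    row.names = NULL, stringsAsFactors = FALSE
  )
}
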