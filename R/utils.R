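#' One-decimal percentage
#'
#' Percentage of `n` out of `d`, rounded to one decimal place. This is the
#' formatting convention used throughout the class summaries and the family
#' correlation report.
#'
#' @param n Numerator (count).
#' @param d Denominator (count), must be > 0.
#' @return Numeric percentage rounded to one decimal.
#' @examples
#' pct(507, 1040)  # 48.8
#' @export
pct <- function(n, d) {
  stopifnot(is.numeric(n), is.numeric(d), all(d > 0))
  round(100 * n / d, 1)
}

# ---- internal rooted-tree helpers (ape 'phylo' objects) ----

# parent vector indexed by node id (0 for the root)
.parent_vec <- function(tree) {
  nnode <- ape::Ntip(tree) + tree$Nnode
  par <- integer(nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

# list of children per node id (integer(0) for tips)
.children_list <- function(tree) {
  nnode <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", nnode)
  for (i in seq_len(nnode)) ch[[i]] <- integer(0)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1]
    ch[[a]] <- c(ch[[a]], tree$edge[i, 2])
  }
  ch
}

# depth (edges from root) per node id
.depth_vec <- function(tree, parent = .parent_vec(tree)) {
  root <- ape::Ntip(tree) + 1L
  nnode <- length(parent)
  dep <- rep(NA_integer_, nnode)
  dep[root] <- 0L
  # nodes in tree$edge are ordered parent-before-child under cladewise order
  ord <- tree$edge[, 2][order(tree$edge[, 1])]
  repeat {
    done <- TRUE
    for (v in seq_len(nnode)) {
      if (is.na(dep[v]) && v != root && !is.na(dep[parent[v]])) {
        dep[v] <- dep[parent[v]] + 1L
        done <- FALSE
      }
    }
    if (done) break
  }
  dep
}

# LCA of two node ids via parent walks
.lca2 <- function(a, b, parent, depth) {
  while (depth[a] > depth[b]) a <- parent[a]
  while (depth[b] > depth[a]) b <- parent[b]
  while (a != b) {
    a <- parent[a]
    b <- parent[b]
  }
  a
}

# path of node ids from ancestor `top` down to `bottom` (inclusive)
.path_down <- function(top, bottom, parent) {
  p <- bottom
  out <- bottom
  while (p != top) {
    p <- parent[p]
    if (p == 0L) stop("'top' is not an ancestor of 'bottom'")
    out <- c(p, out)
  }
  out
}

# is `anc` an ancestor-or-equal of `node`?
.is_anc <- function(anc, node, parent, depth) {
  while (depth[node] > depth[anc]) node <- parent[node]
  node == anc
}

# postorder of node ids (children before parents)
.postorder_nodes <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  unique(c(tr$edge[, 2], tr$edge[, 1]))
}

# human-readable node labels: tip label for tips, "node<k>" for internals
.node_labels <- function(tree) {
  ntip <- ape::Ntip(tree)
  lab <- character(ntip + tree$Nnode)
  lab[seq_len(ntip)] <- tree$tip.label
  inner <- if (!is.null(tree$node.label) && all(nzchar(tree$node.label))) {
    tree$node.label
  } else {
    paste0("node", seq_len(tree$Nnode) + ntip)
  }
  lab[ntip + seq_len(tree$Nnode)] <- inner
  lab
}
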