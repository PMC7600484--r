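# Independent oracles and small fixture builders. Everything here is written
# against ape primitives only, separate from the package's own tree code.

toy_species <- function() ape::read.tree(text = "((A,B),C);")

# parent vector from the raw edge matrix
oracle_parents <- function(tree) {
  par <- integer(ape::Ntip(tree) + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

oracle_is_anc <- function(anc, node, par) {
  while (node != 0L) {
    if (node == anc) return(TRUE)
    node <- par[node]
  }
  FALSE
}

# recursive LCA-map oracle: map each gene clade to the MRCA of its species
oracle_lca_map <- function(gene_tree, species_tree, sep = "@") {
  ngt <- ape::Ntip(gene_tree)
  M <- integer(ngt + gene_tree$Nnode)
  for (v in seq_len(ngt)) {
    sp <- sub(paste0("^.*", sep), "", gene_tree$tip.label[v])
    M[v] <- match(sp, species_tree$tip.label)
  }
  for (v in (ngt + 1L):(ngt + gene_tree$Nnode)) {
    tips <- ape::extract.clade(gene_tree, v)$tip.label
    sp <- unique(sub(paste0("^.*", sep), "", tips))
    M[v] <- if (length(sp) == 1) match(sp, species_tree$tip.label)
            else ape::getMRCA(species_tree, sp)
  }
  M
}

# exhaustive minimum-duplication oracle: enumerate every map of the gene
# tree's internal nodes to species nodes consistent with ancestry and return
# the smallest duplication count over all of them
oracle_min_dups <- function(gene_tree, species_tree, sep = "@") {
  sp_par <- oracle_parents(species_tree)
  sp_kids <- split(species_tree$edge[, 2], species_tree$edge[, 1])
  n_sp <- ape::Ntip(species_tree) + species_tree$Nnode
  ngt <- ape::Ntip(gene_tree)
  g_par <- oracle_parents(gene_tree)
  g_kids <- split(gene_tree$edge[, 2], gene_tree$edge[, 1])

  leaf_map <- integer(ngt)
  for (v in seq_len(ngt)) {
    sp <- sub(paste0("^.*", sep), "", gene_tree$tip.label[v])
    leaf_map[v] <- match(sp, species_tree$tip.label)
  }
  # postorder list of internal nodes
  tr <- ape::reorder.phylo(gene_tree, "postorder")
  internals <- unique(c(tr$edge[, 2], tr$edge[, 1]))
  internals <- internals[internals > ngt]

  is_dup <- function(m, m1, m2) {
    kk <- sp_kids[[as.character(m)]]
    if (is.null(kk)) return(TRUE)  # mapped to a species tip: must be a dup
    sep_ok <- (oracle_is_anc(kk[1], m1, sp_par) &&
               oracle_is_anc(kk[2], m2, sp_par)) ||
              (oracle_is_anc(kk[2], m1, sp_par) &&
               oracle_is_anc(kk[1], m2, sp_par))
    !sep_ok
  }

  best <- Inf
  assign_next <- function(i, M, dups) {
    if (dups >= best) return(invisible(NULL))
    if (i > length(internals)) {
      best <<- min(best, dups)
      return(invisible(NULL))
    }
    v <- internals[i]
    kids <- g_kids[[as.character(v)]]
    m1 <- M[kids[1]]
    m2 <- M[kids[2]]
    for (m in seq_len(n_sp)) {
      if (!oracle_is_anc(m, m1, sp_par) || !oracle_is_anc(m, m2, sp_par)) next
      M[v] <- m
      assign_next(i + 1L, M, dups + is_dup(m, m1, m2))
    }
    invisible(NULL)
  }
  M0 <- c(leaf_map, rep(0L, gene_tree$Nnode))
  assign_next(1L, M0, 0L)
  best
}

# random gene tree with leaves assigned to random species
random_gene_tree <- function(n_leaves, species, seed) {
  set.seed(seed)
  gt <- ape::rtree(n_leaves, rooted = TRUE)
  sp <- sample(species, n_leaves, replace = TRUE)
  gt$tip.label <- paste0("g", seq_len(n_leaves), "@", sp)
  gt
}

# true per-species quantities from a simulated family's event list:
# duplications/losses on the root-to-tip path of each species
truth_path_events <- function(species_tree, events) {
  par <- oracle_parents(species_tree)
  root <- ape::Ntip(species_tree) + 1L
  sapply(seq_len(ape::Ntip(species_tree)), function(tip) {
    path <- tip
    v <- tip
    while (par[v] != 0L) {
      v <- par[v]
      path <- c(path, v)
    }
    path <- setdiff(path, root)  # branch keys = child-end nodes
    c(dups = sum(events$type == "duplication" & events$node %in% path),
      losses = sum(events$type == "loss" & events$node %in% path))
  })
}
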