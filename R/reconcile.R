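#' Species label of gene-tree leaves
#'
#' Gene-tree tips follow the `gene_id@species` convention; the species is
#' everything after the last separator.
#'
#' @param labels Character vector of gene-tree tip labels.
#' @param sep Separator between gene id and species name (default `"@"`).
#' @return Character vector of species names.
#' @export
leaf_species <- function(labels, sep = "@") {
  sub(paste0("^.*", sep), "", labels)
}

#' LCA mapping of a gene tree onto a species tree
#'
#' Maps every gene-tree node to the most recent common ancestor, in the
#' species tree, of the species found below it. This is the standard
#' parsimony (duplication-minimizing) reconciliation mapping, computed
#' bottom-up.
#'
#' @param gene_tree Rooted `phylo`; tips labeled `gene_id@species`.
#' @param species_tree Rooted `phylo` with unique species tip labels.
#' @param sep Separator in gene tip labels (default `"@"`).
#' @return Integer vector indexed by gene-tree node id, giving the mapped
#'   species-tree node id. Names are the gene-tree node labels.
#' @export
lca_map <- function(gene_tree, species_tree, sep = "@") {
  stopifnot(inherits(gene_tree, "phylo"), inherits(species_tree, "phylo"))
  sp_par <- .parent_vec(species_tree)
  sp_dep <- .depth_vec(species_tree, sp_par)
  sp <- leaf_species(gene_tree$tip.label, sep)
  tip_map <- match(sp, species_tree$tip.label)
  if (anyNA(tip_map)) {
    bad <- gene_tree$tip.label[which(is.na(tip_map))[1]]
    stop("gene-tree leaf '", bad, "' names a species absent from the species tree")
  }
  ng <- ape::Ntip(gene_tree) + gene_tree$Nnode
  M <- integer(ng)
  M[seq_len(ape::Ntip(gene_tree))] <- tip_map
  ch <- .children_list(gene_tree)
  for (v in .postorder_nodes(gene_tree)) {
    kids <- ch[[v]]
    if (length(kids) == 0) next
    m <- M[kids[1]]
    for (k in kids[-1]) m <- .lca2(m, M[k], sp_par, sp_dep)
    M[v] <- m
  }
  names(M) <- .node_labels(gene_tree)
  M
}

#' Duplication-loss reconciliation of a gene tree with a species tree
#'
#' Embeds the gene tree into the species tree by LCA mapping and reads off
#' duplication and loss events. A gene-tree node is a duplication when it
#' maps to the same species node as one of its children; duplications are
#' assigned to the species-tree branch above the mapped node. On a gene-tree
#' edge (u, v) spanning d species-tree edges, d - 1 copies are lost when u is
#' a speciation and d when u is a duplication; each loss is assigned to the
#' branch of the bypassed sibling. The duplication total is the minimum over
#' all reconciliations of the two trees.
#'
#' Per-leaf origins are also recorded: at each duplication the first child
#' continues the ancestral copy and the second child starts a new copy, so a
#' leaf's origin is the mapped species node of the lowest ancestral
#' duplication from which it descends as the new copy (or the root when the
#' leaf is an unduplicated ancestral copy). Origins feed
#' [lineage_turnover()].
#'
#' @param gene_tree Rooted binary `phylo`; tips `gene_id@species`.
#' @param species_tree Rooted binary `phylo`.
#' @param sep Gene-leaf label separator.
#' @param resolve_polytomies Optional integer seed; when given, polytomies in
#'   the gene tree are resolved at random (recorded in the result). By
#'   default a non-binary gene tree is an error.
#' @return An object of class `"reconciliation"`: a list with `mapping`
#'   (node id -> species node id), `event` (per gene node:
#'   `"leaf"`/`"speciation"`/`"duplication"`), `branches` (data.frame keyed
#'   by the child-end species node of each branch, with `gains` and `losses`;
#'   the row for the species root counts duplications predating the first
#'   speciation), `n_dup`, `n_loss`, `origins` (per gene leaf: its species
#'   tip and origin species node), and the species tree used.
#' @export
reconcile <- function(gene_tree, species_tree, sep = "@",
                      resolve_polytomies = NULL) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(species_tree, "phylo"))
  if (!ape::is.rooted(species_tree) || !ape::is.binary(species_tree)) {
    stop("species tree must be rooted and binary")
  }
  if (!ape::is.rooted(gene_tree) || !ape::is.binary(gene_tree)) {
    if (is.null(resolve_polytomies)) {
      stop("gene tree has polytomies; pass 'resolve_polytomies = <seed>' to resolve them at random")
    }
    set.seed(as.integer(resolve_polytomies))
    gene_tree <- ape::multi2di(gene_tree, random = TRUE)
  }
  M <- lca_map(gene_tree, species_tree, sep)

  sp_par <- .parent_vec(species_tree)
  sp_dep <- .depth_vec(species_tree, sp_par)
  sp_ch <- .children_list(species_tree)
  sp_root <- ape::Ntip(species_tree) + 1L
  nsp <- length(sp_par)

  g_ch <- .children_list(gene_tree)
  g_par <- .parent_vec(gene_tree)
  ntip_g <- ape::Ntip(gene_tree)
  ng <- ntip_g + gene_tree$Nnode

  event <- rep("leaf", ng)
  for (v in (ntip_g + 1L):ng) {
    kids <- g_ch[[v]]
    event[v] <- if (any(M[kids] == M[v])) "duplication" else "speciation"
  }
  names(event) <- names(M)

  gains <- integer(nsp)
  losses <- integer(nsp)
  for (v in which(event == "duplication")) gains[M[v]] <- gains[M[v]] + 1L

  # losses along every gene-tree edge (u, v)
  for (i in seq_len(nrow(gene_tree$edge))) {
    u <- gene_tree$edge[i, 1]
    v <- gene_tree$edge[i, 2]
    if (M[u] == M[v]) next
    path <- .path_down(M[u], M[v], sp_par)  # M[u] = w0, ..., wd = M[v]
    d <- length(path) - 1L
    # passing through an intermediate species node drops a copy in the
    # sibling subtree; a duplication at M[u] additionally passes M[u] itself
    start <- if (event[u] == "duplication") 1L else 2L
    if (d >= start) {
      for (j in start:d) {
        w <- path[j]           # species node being passed through
        taken <- path[j + 1L]  # child on the path
        sib <- setdiff(sp_ch[[w]], taken)
        losses[sib] <- losses[sib] + 1L
      }
    }
  }

  # per-leaf origin: lowest ancestral duplication from which the leaf
  # descends as the second (new) child
  origin <- rep(sp_root, ntip_g)
  ancestral <- rep(TRUE, ntip_g)
  for (leaf in seq_len(ntip_g)) {
    v <- leaf
    while (g_par[v] != 0L) {
      u <- g_par[v]
      if (event[u] == "duplication" && v == g_ch[[u]][2]) {
        origin[leaf] <- M[u]
        ancestral[leaf] <- FALSE
        break
      }
      v <- u
    }
  }

  sp_lab <- .node_labels(species_tree)
  branches <- data.frame(
    node = seq_len(nsp),
    label = sp_lab,
    parent = sp_par,
    gains = gains,
    losses = losses,
    stringsAsFactors = FALSE
  )
  res <- list(
    mapping = M,
    event = event,
    branches = branches,
    n_dup = sum(gains),
    n_loss = sum(losses),
    origins = data.frame(
      leaf = gene_tree$tip.label,
      species = leaf_species(gene_tree$tip.label, sep),
      origin_node = origin,
      ancestral = ancestral,
      stringsAsFactors = FALSE
    ),
    species_tree = species_tree
  )
  class(res) <- "reconciliation"
  res
}

#' @export
print.reconciliation <- function(x, ...) {
  cat("Duplication-loss reconciliation\n")
  cat("  gene leaves:  ", nrow(x$origins), "\n")
  cat("  duplications: ", x$n_dup, "\n")
  cat("  losses:       ", x$n_loss, "\n")
  invisible(x)
}

#' Per-branch gain/loss atlas over a set of reconciled families
#'
#' Sums duplication (gain) and loss events per species-tree branch across
#' families and reports each branch's share of the tree-wide event total.
#'
#' @param results List of `"reconciliation"` objects, all against the same
#'   species tree.
#' @param species_tree The common species tree.
#' @return data.frame keyed by the child-end node of each branch: `gains`,
#'   `losses`, `events`, and `share` (fraction of all events tree-wide; NA
#'   when there are no events).
#' @export
branch_atlas <- function(results, species_tree) {
  stopifnot(inherits(species_tree, "phylo"))
  sp_par <- .parent_vec(species_tree)
  nsp <- length(sp_par)
  ref <- ape::write.tree(species_tree)
  gains <- integer(nsp)
  losses <- integer(nsp)
  for (r in results) {
    stopifnot(inherits(r, "reconciliation"))
    if (!identical(ape::write.tree(r$species_tree), ref)) {
      stop("all reconciliations must use the same species tree")
    }
    gains <- gains + r$branches$gains
    losses <- losses + r$branches$losses
  }
  total <- sum(gains) + sum(losses)
  data.frame(
    node = seq_len(nsp),
    label = .node_labels(species_tree),
    parent = sp_par,
    gains = gains,
    losses = losses,
    events = gains + losses,
    share = if (total > 0) (gains + losses) / total else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Lineage turnover: fraction of a species' TFs gained and lost
#'
#' For each extant species X, the gained fraction is the share of its extant
#' TF copies whose origin (the duplication that created the copy) maps
#' strictly below the species root — copies that arose during the lineage's
#' own evolution rather than being inherited from the common ancestor. The
#' lost fraction is the number of loss events on the root-to-X path divided
#' by the number of copies that ever existed on that lineage (root copies
#' plus gains on the path). Families are pooled per species; cross-species
#' averages are reported as percentages.
#'
#' @param results List of `"reconciliation"` objects on a common species tree.
#' @param species_tree The species tree.
#' @param gained_denominator `"extant"` (default): gained copies over extant
#'   copies; `"lineage-total"`: gains on the path over root copies + gains,
#'   the same denominator the lost fraction uses.
#' @return List with `per_species` (data.frame: species, extant, gained,
#'   gained_fraction, root_copies, path_gains, path_losses, lost_fraction)
#'   and `mean_gained_pct` / `mean_lost_pct`, the cross-species averages as
#'   percentages. Species with no extant copies are excluded with a warning.
#' @export
lineage_turnover <- function(results, species_tree,
                             gained_denominator = c("extant", "lineage-total")) {
  gained_denominator <- match.arg(gained_denominator)
  stopifnot(inherits(species_tree, "phylo"))
  sp_par <- .parent_vec(species_tree)
  sp_root <- ape::Ntip(species_tree) + 1L
  ntip <- ape::Ntip(species_tree)
  species <- species_tree$tip.label

  extant <- gained <- path_gains <- path_losses <- root_copies <-
    stats::setNames(numeric(ntip), species)
  # branches (child-end node ids) on the root-to-tip path, per tip
  paths <- lapply(seq_len(ntip), function(tip) {
    setdiff(.path_down(sp_root, tip, sp_par), sp_root)
  })

  for (r in results) {
    stopifnot(inherits(r, "reconciliation"))
    tab <- table(factor(r$origins$species, levels = species))
    extant <- extant + as.numeric(tab)
    gtab <- table(factor(
      r$origins$species[!r$origins$ancestral & r$origins$origin_node != sp_root],
      levels = species
    ))
    gained <- gained + as.numeric(gtab)
    fam_root <- 1L + r$branches$gains[sp_root]
    for (tip in seq_len(ntip)) {
      b <- paths[[tip]]
      path_gains[tip] <- path_gains[tip] + sum(r$branches$gains[b])
      path_losses[tip] <- path_losses[tip] + sum(r$branches$losses[b])
      root_copies[tip] <- root_copies[tip] + fam_root
    }
  }

  keep <- extant > 0
  if (any(!keep)) {
    warning(sum(!keep), " species with zero extant TF copies excluded: ",
            paste(species[!keep], collapse = ", "))
  }
  gden <- switch(gained_denominator,
    "extant" = extant,
    "lineage-total" = root_copies + path_gains
  )
  gnum <- switch(gained_denominator,
    "extant" = gained,
    "lineage-total" = path_gains
  )
  per <- data.frame(
    species = species,
    extant = extant,
    gained = gained,
    gained_fraction = ifelse(gden > 0, gnum / gden, NA_real_),
    root_copies = root_copies,
    path_gains = path_gains,
    path_losses = path_losses,
    lost_fraction = ifelse(root_copies + path_gains > 0,
                           path_losses / (root_copies + path_gains), NA_real_),
    row.names = NULL,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  list(
    per_species = per,
    mean_gained_pct = 100 * mean(per$gained_fraction),
    mean_lost_pct = 100 * mean(per$lost_fraction)
  )
}
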