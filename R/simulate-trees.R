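#' Simulate an ultrametric species tree
#'
#' Draws a rooted, binary, ultrametric tree (coalescent topology and branch
#' times) with labeled tips, standing in for a dated mammalian species tree.
#' Depth is rescaled to `depth` time units so duplication/loss rates have a
#' fixed meaning across tree sizes.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed; fixed seed gives a byte-identical tree.
#' @param depth Total root-to-tip height (default 1).
#' @return A rooted binary ultrametric `phylo` with tips `sp01, sp02, ...`.
#' @export
simulate_species_tree <- function(n_species, seed, depth = 1) {
  if (!is.numeric(n_species) || n_species < 2) {
    stop("'n_species' must be at least 2")
  }
  n_species <- as.integer(n_species)
  set.seed(as.integer(seed))
  tr <- ape::rcoal(n_species,
                   tip.label = sprintf("sp%02d", seq_len(n_species)))
  tr$edge.length <- tr$edge.length * depth / max(ape::node.depth.edgelength(tr))
  tr
}

#' Simulate a gene family by birth-death evolution along a species tree
#'
#' A single ancestral copy enters the species tree at its root and evolves
#' down every branch: duplications (rate `dup_rate` per copy per time unit)
#' split a copy in two, losses (rate `loss_rate`) kill it; every surviving
#' copy speciates at each internal species node. Each true event is recorded
#' against the species-tree branch (child-end node id) where it occurred, so
#' the simulator's truth is exactly the quantity duplication-loss
#' reconciliation estimates.
#'
#' At each duplication the first child of the created gene-tree node carries
#' the ancestral copy and the second the new copy, matching the origin
#' convention of [reconcile()].
#'
#' @param species_tree Rooted binary `phylo` with branch lengths.
#' @param dup_rate,loss_rate Non-negative event rates per copy per unit time.
#' @param seed Integer seed.
#' @return List with `tree` (rooted `phylo`, tips `g<k>@<species>`; `NULL`
#'   when fewer than two copies survive), `leaves` (character vector of
#'   surviving copy labels), `events` (data.frame: `node` = species branch
#'   child-end id, `type` = `"duplication"`/`"loss"`), and `extinct` flag.
#' @export
simulate_gene_family <- function(species_tree, dup_rate, loss_rate, seed) {
  stopifnot(inherits(species_tree, "phylo"))
  if (!ape::is.binary(species_tree)) stop("species tree must be binary")
  if (dup_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  if (is.null(species_tree$edge.length)) stop("species tree needs branch lengths")
  set.seed(as.integer(seed))

  ch <- .children_list(species_tree)
  ntip <- ape::Ntip(species_tree)
  root <- ntip + 1L
  elen <- numeric(ntip + species_tree$Nnode)
  elen[species_tree$edge[, 2]] <- species_tree$edge.length

  env <- new.env()
  env$counter <- 0L
  env$ev_node <- integer(0)
  env$ev_type <- character(0)
  record <- function(node, type) {
    env$ev_node <- c(env$ev_node, node)
    env$ev_type <- c(env$ev_type, type)
  }

  # one copy entering the branch above species node `v`, `remaining` time
  # units from the branch end; returns a Newick fragment or NULL if the
  # copy leaves no surviving descendants
  down_branch <- function(v, remaining) {
    total <- dup_rate + loss_rate
    while (TRUE) {
      wait <- if (total > 0) stats::rexp(1, total) else Inf
      if (wait >= remaining) return(at_node(v))
      remaining <- remaining - wait
      if (stats::runif(1) < dup_rate / total) {
        record(v, "duplication")
        a <- down_branch(v, remaining)  # ancestral copy
        b <- down_branch(v, remaining)  # new copy
        if (is.null(a) && is.null(b)) return(NULL)
        if (is.null(a)) return(b)
        if (is.null(b)) return(a)
        return(paste0("(", a, ",", b, ")"))
      } else {
        record(v, "loss")
        return(NULL)
      }
    }
  }

  at_node <- function(v) {
    if (v <= ntip) {
      env$counter <- env$counter + 1L
      return(paste0("g", env$counter, "@", species_tree$tip.label[v]))
    }
    kids <- ch[[v]]
    a <- down_branch(kids[1], elen[kids[1]])
    b <- down_branch(kids[2], elen[kids[2]])
    if (is.null(a) && is.null(b)) return(NULL)
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    paste0("(", a, ",", b, ")")
  }

  nwk <- at_node(root)
  events <- data.frame(node = env$ev_node, type = env$ev_type,
                       stringsAsFactors = FALSE)
  leaves <- if (is.null(nwk)) {
    character(0)
  } else {
    regmatches(nwk, gregexpr("g[0-9]+@[A-Za-z0-9_.]+", nwk))[[1]]
  }
  tree <- if (length(leaves) >= 2) ape::read.tree(text = paste0(nwk, ";")) else NULL
  list(tree = tree, leaves = leaves, events = events,
       extinct = length(leaves) == 0)
}
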