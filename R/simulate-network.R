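#' Simulation configuration
#'
#' Bundles, with validation, every tunable the synthetic-data generators
#' use. The defaults are the study conditions the pipeline is exercised
#' under: a mid-sized modular interactome with one third of TFs planted as
#' isolated, lethality and ortholog-absence probabilities matching the
#' contrast observed between connected and isolated TFs (48.8% vs 5.0%
#' lethal; 3.8% vs 36.7% absent in the comparator species), five organs of
#' negative-binomial expression, and GO-term TF sets whose cross-species
#' overlap decays with set size.
#'
#' @param seed Integer seed.
#' @param n_species,dup_rate,loss_rate,n_families Birth-death gene-family
#'   settings (rates are events per copy per unit tree height).
#' @param n_genes,n_tfs,n_modules,p_in,p_out,isolated_frac Stochastic
#'   block-model interactome settings; `isolated_frac` is the fraction of
#'   TFs planted as isolated (no TF-TF edges).
#' @param p_lethal_connected,p_lethal_isolated,p_absent_connected,p_absent_isolated
#'   Annotation-flag probabilities for connected vs planted-isolated TFs.
#' @param alpha Log mean expression of the reference gene type.
#' @param beta Named or ordered numeric of log-mean offsets for the five
#'   TF-interaction gene types (first entry, the reference, must be 0).
#' @param theta NB dispersion (size) parameter, > 0.
#' @param n_genes_per_type Genes per expression type.
#' @param organs Organ panel.
#' @param go_n_terms,go_size_range,go_decay GO simulator settings: number of
#'   terms, TF-set size range (log-uniform), and the power-law rate at which
#'   the expected cross-species overlap proportion decays with set size
#'   (expected proportion = size^-go_decay).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_species = 16, dup_rate = 0.3, loss_rate = 0.1,
                       n_families = 48,
                       n_genes = 900, n_tfs = 300, n_modules = 4,
                       p_in = 0.15, p_out = 0.02, isolated_frac = 1 / 3,
                       p_lethal_connected = 0.488, p_lethal_isolated = 0.050,
                       p_absent_connected = 0.038, p_absent_isolated = 0.367,
                       alpha = log(50),
                       beta = c(no_TF_interaction = 0, orth_TF = 0.5,
                                spec_TF_HM = 1.0, spec_TF_H = -0.5,
                                spec_TF_M = 0.25),
                       theta = 2, n_genes_per_type = 2000,
                       organs = c("cerebellum", "heart", "kidney", "liver",
                                  "testis"),
                       go_n_terms = 1000, go_size_range = c(5, 400),
                       go_decay = log(2) / log(100)) {
  probs <- c(p_in = p_in, p_out = p_out, isolated_frac = isolated_frac,
             p_lethal_connected = p_lethal_connected,
             p_lethal_isolated = p_lethal_isolated,
             p_absent_connected = p_absent_connected,
             p_absent_isolated = p_absent_isolated)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  }
  if (dup_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  if (theta <= 0) stop("'theta' must be > 0")
  if (n_tfs > n_genes) stop("'n_tfs' cannot exceed 'n_genes'")
  if (n_modules > n_genes) stop("'n_modules' cannot exceed 'n_genes'")
  if (beta[1] != 0) stop("the first (reference) beta must be 0")
  if (any(!is.finite(beta))) stop("beta offsets must be finite")
  cfg <- list(seed = as.integer(seed), n_species = n_species,
              dup_rate = dup_rate, loss_rate = loss_rate,
              n_families = n_families, n_genes = n_genes, n_tfs = n_tfs,
              n_modules = n_modules, p_in = p_in, p_out = p_out,
              isolated_frac = isolated_frac,
              p_lethal_connected = p_lethal_connected,
              p_lethal_isolated = p_lethal_isolated,
              p_absent_connected = p_absent_connected,
              p_absent_isolated = p_absent_isolated,
              alpha = alpha, beta = beta, theta = theta,
              n_genes_per_type = n_genes_per_type, organs = organs,
              go_n_terms = go_n_terms, go_size_range = go_size_range,
              go_decay = go_decay)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a modular interactome with a planted isolated-TF subset
#'
#' Draws a stochastic block-model graph over `n_genes` genes split into
#' `n_modules` blocks (edge probability `p_in` within, `p_out` between),
#' marks `n_tfs` of the genes as TFs spread evenly over the blocks, and
#' plants a fraction of the TFs as isolated: all their TF-TF edges are
#' removed and each is guaranteed at least one TF-to-non-TF edge, so they
#' stay networked but fall outside the TF-to-TF largest component.
#' Lethality and comparator-species-absence flags are drawn with distinct
#' probabilities for connected and planted-isolated TFs. Edge confidence is
#' emitted on the integer 0-1000 scale used by interaction databases.
#'
#' @param cfg A [sim_config()].
#' @return List: `edges` (data.frame `node_a`, `node_b`, `combined_score`),
#'   `nodes` (data.frame `gene`, `module`, `is_tf`, `planted_isolated`,
#'   `lethal`, `absent_in_other`), and `truth` (planted isolated gene ids).
#' @export
simulate_ppi_network <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  m <- cfg$n_modules
  block_sizes <- diff(round(seq(0, n, length.out = m + 1)))
  module <- rep(seq_len(m), times = block_sizes)
  gene <- sprintf("gene%04d", seq_len(n))

  # TFs spread evenly over blocks
  per_block <- diff(round(seq(0, cfg$n_tfs, length.out = m + 1)))
  is_tf <- logical(n)
  for (b in seq_len(m)) {
    idx <- which(module == b)
    is_tf[idx[seq_len(min(per_block[b], length(idx)))]] <- TRUE
  }
  tf_idx <- which(is_tf)
  n_iso <- round(cfg$isolated_frac * length(tf_idx))
  iso_idx <- sort(sample(tf_idx, n_iso))
  planted <- logical(n)
  planted[iso_idx] <- TRUE

  pref <- matrix(cfg$p_out, m, m)
  diag(pref) <- cfg$p_in
  g <- igraph::sample_sbm(n, pref.matrix = pref, block.sizes = block_sizes)
  el <- igraph::as_edgelist(g, names = FALSE)

  # suppress every TF-TF edge touching a planted-isolated TF
  drop <- (el[, 1] %in% iso_idx & is_tf[el[, 2]]) |
          (el[, 2] %in% iso_idx & is_tf[el[, 1]])
  el <- el[!drop, , drop = FALSE]

  # guarantee each planted-isolated TF one TF-to-non-TF edge
  nontf_idx <- which(!is_tf)
  if (length(nontf_idx) == 0) stop("network has no non-TF genes to anchor isolated TFs")
  deg_nontf <- tabulate(c(el[, 1], el[, 2]), nbins = n)
  for (v in iso_idx) {
    nb <- c(el[el[, 1] == v, 2], el[el[, 2] == v, 1])
    if (!any(!is_tf[nb])) {
      same <- nontf_idx[module[nontf_idx] == module[v]]
      anchor <- if (length(same) > 0) sample(same, 1) else sample(nontf_idx, 1)
      el <- rbind(el, c(v, anchor))
    }
  }

  score <- sample(400:999, nrow(el), replace = TRUE)
  edges <- data.frame(node_a = gene[el[, 1]], node_b = gene[el[, 2]],
                      combined_score = score, stringsAsFactors = FALSE)

  lethal <- absent <- rep(NA, n)
  conn <- setdiff(tf_idx, iso_idx)
  lethal[conn] <- stats::rbinom(length(conn), 1, cfg$p_lethal_connected) == 1
  lethal[iso_idx] <- stats::rbinom(length(iso_idx), 1, cfg$p_lethal_isolated) == 1
  absent[conn] <- stats::rbinom(length(conn), 1, cfg$p_absent_connected) == 1
  absent[iso_idx] <- stats::rbinom(length(iso_idx), 1, cfg$p_absent_isolated) == 1

  nodes <- data.frame(gene = gene, module = module, is_tf = is_tf,
                      planted_isolated = planted, lethal = lethal,
                      absent_in_other = absent, stringsAsFactors = FALSE)
  list(edges = edges, nodes = nodes, truth = gene[iso_idx])
}

#' Simulate negative-binomial expression by TF-interaction gene type
#'
#' For each species and organ, draws NB counts with log mean
#' `alpha + beta[k]` for gene type `k`; the first type is the reference
#' (genes without TF interactions, `beta = 0`).
#'
#' @param cfg A [sim_config()].
#' @return List: `expression` (long data.frame: `gene`, `species`, `organ`,
#'   `type`, `expression`) and `truth` (`alpha`, `beta`, `theta`).
#' @export
simulate_expression <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$theta <= 0) stop("'theta' must be > 0")
  set.seed(cfg$seed)
  types <- names(cfg$beta)
  if (is.null(types)) types <- paste0("type", seq_along(cfg$beta))
  ng <- cfg$n_genes_per_type
  gene <- unlist(lapply(types, function(t) sprintf("%s_g%05d", t, seq_len(ng))))
  type <- rep(types, each = ng)
  species <- c("human", "mouse")
  out <- expand.grid(gene = gene, species = species, organ = cfg$organs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$type <- rep(type, times = length(species) * length(cfg$organs))
  mu <- exp(cfg$alpha + cfg$beta[match(out$type, types)])
  out$expression <- stats::rnbinom(nrow(out), size = cfg$theta, mu = mu)
  list(expression = out,
       truth = list(alpha = cfg$alpha, beta = cfg$beta, theta = cfg$theta))
}

#' Simulate paired-species GO-term TF annotations with decaying overlap
#'
#' For each term, draws a target TF-set size `s` (log-uniform over
#' `go_size_range`) and an expected cross-species overlap proportion
#' `q = s^-go_decay`; the realized number of shared TFs is Binomial(s, q),
#' drawn from an orthologous TF pool, and the remainder from
#' species-specific pools. With `go_decay = 0` both sets are identical;
#' the default calibrates the expected proportion to 0.5 at size 100.
#'
#' @param cfg A [sim_config()].
#' @return List: `annotations_a` / `annotations_b` (data.frames `term`,
#'   `tf`), `ortholog_map` (data.frame `tf_a`, `tf_b`), and `truth`
#'   (per-term data.frame: `term`, `size`, `q_expected`, `q_realized`).
#' @export
simulate_go_annotations <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$go_n_terms < 1) stop("'go_n_terms' must be >= 1")
  set.seed(cfg$seed)
  smin <- cfg$go_size_range[1]
  smax <- cfg$go_size_range[2]
  pool_n <- 2 * smax
  orth_a <- sprintf("hsTF%04d", seq_len(pool_n))
  orth_b <- sprintf("mmTF%04d", seq_len(pool_n))
  spec_a <- sprintf("hsSPEC%04d", seq_len(pool_n))
  spec_b <- sprintf("mmSPEC%04d", seq_len(pool_n))

  terms <- sprintf("GO:%07d", seq_len(cfg$go_n_terms))
  size <- round(exp(stats::runif(cfg$go_n_terms, log(smin), log(smax))))
  q <- size^(-cfg$go_decay)
  shared_n <- stats::rbinom(cfg$go_n_terms, size, q)

  rows_a <- vector("list", cfg$go_n_terms)
  rows_b <- vector("list", cfg$go_n_terms)
  for (i in seq_len(cfg$go_n_terms)) {
    sh <- sample.int(pool_n, shared_n[i])
    extra <- size[i] - shared_n[i]
    sa <- if (extra > 0) spec_a[sample.int(pool_n, extra)] else character(0)
    sb <- if (extra > 0) spec_b[sample.int(pool_n, extra)] else character(0)
    rows_a[[i]] <- data.frame(term = terms[i], tf = c(orth_a[sh], sa),
                              stringsAsFactors = FALSE)
    rows_b[[i]] <- data.frame(term = terms[i], tf = c(orth_b[sh], sb),
                              stringsAsFactors = FALSE)
  }
  list(
    annotations_a = do.call(rbind, rows_a),
    annotations_b = do.call(rbind, rows_b),
    ortholog_map = data.frame(tf_a = orth_a, tf_b = orth_b,
                              stringsAsFactors = FALSE),
    truth = data.frame(term = terms, size = size, q_expected = q,
                       q_realized = shared_n / size, stringsAsFactors = FALSE)
  )
}

#' Simulate a profile-HMM domain-hit table with known family counts
#'
#' Emits the hit table a domain scan would produce — several isoforms per
#' gene with varying bit scores, sub-threshold decoy hits, genes carrying
#' DNA-binding domains of two families — together with the true
#' (species, family) gene counts, so the census stage can be validated by
#' round trip.
#'
#' @param n_species Number of species.
#' @param families Character vector of family names.
#' @param mean_count Poisson mean of true TF genes per (species, family).
#' @param multi_dbd_frac Fraction of TF genes carrying a second family's
#'   domain.
#' @param decoy_frac Decoy (above-threshold E-value) hits added per true
#'   gene, as a fraction.
#' @param seed Integer seed.
#' @return List: `hits` (data.frame `protein_id`, `gene_name`, `species`,
#'   `family`, `e_value`, `bit_score`) and `truth_counts` (species x family
#'   matrix of distinct (gene, family) memberships).
#' @export
simulate_domain_hits <- function(n_species = 6,
                                 families = paste0("fam", sprintf("%02d", 1:10)),
                                 mean_count = 20, multi_dbd_frac = 0.1,
                                 decoy_frac = 0.2, seed = 1L) {
  set.seed(as.integer(seed))
  species <- sprintf("sp%02d", seq_len(n_species))
  truth <- matrix(0L, n_species, length(families),
                  dimnames = list(species, families))
  rows <- list()
  for (s in seq_len(n_species)) {
    n_gene <- stats::rpois(1, mean_count * length(families))
    fam1 <- sample(families, n_gene, replace = TRUE)
    fam2 <- ifelse(stats::runif(n_gene) < multi_dbd_frac,
                   vapply(fam1, function(f) sample(setdiff(families, f), 1), ""),
                   NA_character_)
    for (g in seq_len(n_gene)) {
      gname <- sprintf("%s_g%04d", species[s], g)
      fams <- c(fam1[g], if (!is.na(fam2[g])) fam2[g])
      for (f in fams) {
        truth[s, f] <- truth[s, f] + 1L
        n_iso <- 1L + stats::rpois(1, 0.7)
        sc <- sort(stats::runif(n_iso, 30, 200), decreasing = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = sprintf("%s_p%d", gname, seq_len(n_iso)),
          gene_name = gname, species = species[s], family = f,
          e_value = 10^stats::runif(n_iso, -20, -5), bit_score = sc,
          stringsAsFactors = FALSE
        )
      }
    }
    # decoys: hits that fail the E-value filter
    n_decoy <- round(decoy_frac * n_gene)
    if (n_decoy > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = sprintf("%s_decoy%04d_p1", species[s], seq_len(n_decoy)),
        gene_name = sprintf("%s_decoy%04d", species[s], seq_len(n_decoy)),
        species = species[s],
        family = sample(families, n_decoy, replace = TRUE),
        e_value = 10^stats::runif(n_decoy, -3.5, -1),
        bit_score = stats::runif(n_decoy, 5, 25),
        stringsAsFactors = FALSE
      )
    }
  }
  list(hits = do.call(rbind, rows), truth_counts = truth)
}
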