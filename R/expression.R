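#' The five TF-interaction gene types
#'
#' Reference first: genes without TF interactions, then genes whose TF
#' partners are all orthologous, genes with both human- and mouse-specific
#' TF partners, genes with human-specific partners only, and genes with
#' mouse-specific partners only.
#'
#' @return Character vector of the five type names, reference first.
#' @export
gene_type_levels <- function() {
  c("no_TF_interaction", "orth_TF", "spec_TF_HM", "spec_TF_H", "spec_TF_M")
}

#' Assign orthologous genes to TF-interaction types
#'
#' Looks up each gene's TF partners in the two species' networks and maps
#' the partner profile to a type: no TF partner in either network gives the
#' reference type; species-specific partners (TFs with no ortholog in the
#' other species) in both networks give `spec_TF_HM`; in one network only,
#' `spec_TF_H` or `spec_TF_M`; otherwise (all partners orthologous)
#' `orth_TF`. Mixed profiles resolve with precedence HM > H/M > orth.
#'
#' @param edges_a,edges_b Edge data.frames for species A (human) and B
#'   (mouse).
#' @param tf_orthology data.frame with columns `tf_a`, `tf_b`: one row per
#'   TF, the id in each species' namespace, NA where the TF has no ortholog
#'   (species-specific).
#' @param genes Character vector of orthologous gene ids (shared namespace);
#'   defaults to all non-TF nodes seen in either network. Genes absent from
#'   both networks are assigned the reference type with a logged note.
#' @return data.frame `gene`, `type` (factor with levels
#'   [gene_type_levels()]).
#' @export
assign_gene_types <- function(edges_a, edges_b, tf_orthology, genes = NULL) {
  stopifnot(all(c("tf_a", "tf_b") %in% names(tf_orthology)))
  tfs_a <- tf_orthology$tf_a[!is.na(tf_orthology$tf_a)]
  tfs_b <- tf_orthology$tf_b[!is.na(tf_orthology$tf_b)]
  spec_a <- tf_orthology$tf_a[!is.na(tf_orthology$tf_a) & is.na(tf_orthology$tf_b)]
  spec_b <- tf_orthology$tf_b[!is.na(tf_orthology$tf_b) & is.na(tf_orthology$tf_a)]

  nbr <- function(edges, tfs) {
    # gene -> TF partner list, from both edge directions
    a_tf <- edges$node_b %in% tfs
    b_tf <- edges$node_a %in% tfs
    g <- c(edges$node_a[a_tf], edges$node_b[b_tf])
    t <- c(edges$node_b[a_tf], edges$node_a[b_tf])
    split(t, g)
  }
  part_a <- nbr(edges_a, tfs_a)
  part_b <- nbr(edges_b, tfs_b)

  if (is.null(genes)) {
    all_nodes <- unique(c(edges_a$node_a, edges_a$node_b,
                          edges_b$node_a, edges_b$node_b))
    genes <- sort(setdiff(all_nodes, c(tfs_a, tfs_b)))
  }
  absent <- !(genes %in% c(edges_a$node_a, edges_a$node_b)) &
            !(genes %in% c(edges_b$node_a, edges_b$node_b))
  if (any(absent)) {
    message(sum(absent), " gene(s) absent from both networks: reference type")
  }
  type <- vapply(genes, function(g) {
    pa <- part_a[[g]]
    pb <- part_b[[g]]
    if (length(pa) == 0 && length(pb) == 0) return("no_TF_interaction")
    has_a <- any(pa %in% spec_a)
    has_b <- any(pb %in% spec_b)
    if (has_a && has_b) "spec_TF_HM"
    else if (has_a) "spec_TF_H"
    else if (has_b) "spec_TF_M"
    else "orth_TF"
  }, character(1))
  data.frame(gene = genes,
             type = factor(type, levels = gene_type_levels()),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' TPM standardization
#'
#' Rescales each sample (column) so its values sum to one million, the
#' transcripts-per-million convention.
#'
#' @param mat Non-negative gene x sample matrix (already length-normalized).
#' @return Matrix with column sums equal to 1e6.
#' @export
tpm_standardize <- function(mat) {
  stopifnot(is.matrix(mat), all(mat >= 0))
  cs <- colSums(mat)
  if (any(cs == 0)) stop("sample(s) with zero total signal")
  sweep(mat, 2, cs, "/") * 1e6
}

#' Negative-binomial expression contrast across gene types
#'
#' Fits an NB GLM with log link, `expression ~ type`, the reference being
#' the first type level (genes without TF interactions), so each coefficient
#' `beta_k` is the log mean expression of type k relative to the reference
#' and `alpha` is the reference log mean. Dispersion is estimated by maximum
#' likelihood (via `MASS::glm.nb`). TPM values are continuous; by default
#' they are rounded to the nearest integer for the count likelihood.
#'
#' @param expr Long data.frame with columns `gene`, `organ`, `species`,
#'   `type`, `expression`.
#' @param organ,species Optional filters; kept in the returned fit.
#' @param nb_input `"rounded"` (default; round TPM to integers) or
#'   `"raw-counts"` (values are already integer counts).
#' @return Object of class `"nb_contrast_fit"`: `alpha`, `alpha_se`, `beta`
#'   (named, 0 for the reference), `se`, `theta`, `organ`, `species`,
#'   `model` (the `glm.nb`/`glm` fit).
#' @export
fit_nb_contrast <- function(expr, organ = NULL, species = NULL,
                            nb_input = c("rounded", "raw-counts")) {
  nb_input <- match.arg(nb_input)
  stopifnot(all(c("type", "expression") %in% names(expr)))
  if (!is.null(organ)) expr <- expr[expr$organ %in% organ, , drop = FALSE]
  if (!is.null(species)) expr <- expr[expr$species %in% species, , drop = FALSE]
  if (nrow(expr) == 0) stop("no expression rows after filtering")
  y <- expr$expression
  if (nb_input == "rounded") y <- round(y)
  if (any(y < 0)) stop("expression values must be non-negative")

  type <- if (is.factor(expr$type)) {
    droplevels(expr$type)
  } else {
    lev <- unique(as.character(expr$type))
    canon <- intersect(gene_type_levels(), lev)
    factor(expr$type, levels = c(canon, setdiff(lev, canon)))
  }
  counts <- table(type)
  if (length(counts) > 1 && any(counts < 2)) {
    stop("singular design: type(s) with fewer than 2 observations: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  }
  dat <- data.frame(y = y, type = type)
  fit <- if (nlevels(type) == 1) {
    MASS::glm.nb(y ~ 1, data = dat)
  } else {
    MASS::glm.nb(y ~ type, data = dat)
  }
  cf <- summary(fit)$coefficients
  alpha <- cf["(Intercept)", "Estimate"]
  lev <- levels(type)
  beta <- stats::setNames(numeric(length(lev)), lev)
  se <- stats::setNames(rep(NA_real_, length(lev)), lev)
  se[1] <- 0
  if (length(lev) > 1) {
    for (k in lev[-1]) {
      row <- paste0("type", k)
      beta[k] <- cf[row, "Estimate"]
      se[k] <- cf[row, "Std. Error"]
    }
  }
  structure(list(alpha = alpha, alpha_se = cf["(Intercept)", "Std. Error"],
                 beta = beta, se = se, theta = fit$theta,
                 organ = if (is.null(organ)) NA_character_ else organ,
                 species = if (is.null(species)) NA_character_ else species,
                 model = fit),
            class = "nb_contrast_fit")
}

#' @export
print.nb_contrast_fit <- function(x, ...) {
  cat("NB expression contrast (", x$species, ", ", x$organ, ")\n", sep = "")
  cat("  alpha =", format(x$alpha, digits = 4),
      " theta =", format(x$theta, digits = 4), "\n")
  print(round(rbind(beta = x$beta, se = x$se), 4))
  invisible(x)
}

#' Fit NB contrasts for every organ x species combination
#'
#' @param expr Long expression data.frame (`gene`, `organ`, `species`,
#'   `type`, `expression`).
#' @param ... Passed to [fit_nb_contrast()].
#' @return Named list of `"nb_contrast_fit"` objects
#'   (`"<organ>.<species>"`).
#' @export
fit_nb_contrasts <- function(expr, ...) {
  combos <- unique(expr[, c("organ", "species")])
  fits <- list()
  for (i in seq_len(nrow(combos))) {
    o <- combos$organ[i]
    s <- combos$species[i]
    fits[[paste(o, s, sep = ".")]] <-
      fit_nb_contrast(expr, organ = o, species = s, ...)
  }
  fits
}

#' Tidy table of fitted contrasts
#'
#' @param fits List of `"nb_contrast_fit"` objects (e.g. from
#'   [fit_nb_contrasts()]).
#' @param include_reference Include reference rows (`beta = 0`)?
#' @return Long data.frame: `organ`, `species`, `type`, `beta`, `se` —
#'   the input for a grouped-bar rendering of the contrast profile.
#' @export
contrast_profile <- function(fits, include_reference = FALSE) {
  if (inherits(fits, "nb_contrast_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    keep <- if (include_reference) seq_along(f$beta) else -1L
    data.frame(organ = f$organ, species = f$species,
               type = names(f$beta)[keep], beta = unname(f$beta[keep]),
               se = unname(f$se[keep]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
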