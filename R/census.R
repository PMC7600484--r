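#' Filter domain hits by E-value
#'
#' Keeps hits at or below the E-value threshold (inclusive, matching common
#' profile-HMM tool semantics at the boundary). Input row order is preserved.
#'
#' @param hits data.frame with at least an `e_value` column.
#' @param e_threshold Positive E-value cutoff (default 1e-4).
#' @return The retained rows of `hits`.
#' @export
filter_hits <- function(hits, e_threshold = 1e-4) {
  stopifnot(is.data.frame(hits), "e_value" %in% names(hits))
  if (!is.numeric(e_threshold) || e_threshold <= 0) {
    stop("'e_threshold' must be > 0")
  }
  hits[hits$e_value <= e_threshold, , drop = FALSE]
}

#' Collapse protein isoforms to one hit per gene, species and family
#'
#' For every (gene, species, family) combination, keeps the isoform with the
#' highest bit score; ties go to the lexicographically smallest protein id.
#' Hits with a missing gene name are reported and kept keyed by their
#' protein id (each treated as its own gene).
#'
#' @param hits data.frame with `protein_id`, `gene_name`, `species`,
#'   `family`, `bit_score`.
#' @return data.frame with one row per (gene, species, family).
#' @export
dedup_isoforms <- function(hits) {
  stopifnot(is.data.frame(hits),
            all(c("protein_id", "gene_name", "species", "family",
                  "bit_score") %in% names(hits)))
  if (nrow(hits) == 0) return(hits)
  missing_gene <- is.na(hits$gene_name) | hits$gene_name == ""
  if (any(missing_gene)) {
    message(sum(missing_gene),
            " hit(s) lack a gene name; keyed by protein id instead")
    hits$gene_name[missing_gene] <- hits$protein_id[missing_gene]
  }
  ord <- order(hits$gene_name, hits$species, hits$family,
               -hits$bit_score, hits$protein_id)
  h <- hits[ord, , drop = FALSE]
  key <- paste(h$gene_name, h$species, h$family, sep = "\r")
  h[!duplicated(key), , drop = FALSE]
}

#' Build a TF catalog from filtered, deduplicated domain hits
#'
#' The catalog records each distinct (species, gene, family) membership; a
#' gene carrying DNA-binding domains of several families appears once per
#' family.
#'
#' @param hits Filtered, deduplicated hits.
#' @return data.frame of class `"tf_catalog"` with columns `species`,
#'   `gene_name`, `family`.
#' @export
build_tf_catalog <- function(hits) {
  stopifnot(is.data.frame(hits),
            all(c("gene_name", "species", "family") %in% names(hits)))
  cat_df <- unique(hits[, c("species", "gene_name", "family")])
  rownames(cat_df) <- NULL
  class(cat_df) <- c("tf_catalog", "data.frame")
  cat_df
}

#' Species-by-family TF counts
#'
#' @param catalog A [build_tf_catalog()] result (or any data.frame with
#'   `species`, `gene_name`, `family`). The total over all cells equals the
#'   number of distinct (gene, family) memberships.
#' @return Integer matrix, species rows x family columns.
#' @export
count_families <- function(catalog) {
  stopifnot(is.data.frame(catalog), nrow(catalog) > 0)
  tab <- table(catalog$species, catalog$family)
  matrix(as.integer(tab), nrow = nrow(tab),
         dimnames = list(rownames(tab), colnames(tab)))
}

#' Standardize family counts to a cross-species mean of 1
#'
#' Divides each cell by its family column's mean over species, so every
#' family column has mean exactly 1 and species can be compared on a common
#' scale. Families absent everywhere (all-zero columns) are dropped with a
#' warning.
#'
#' @param mat Species x family count (or ratio) matrix.
#' @return Matrix of the same shape (minus dropped columns) with unit column
#'   means. Idempotent.
#' @export
standardize_counts <- function(mat) {
  stopifnot(is.matrix(mat))
  means <- colMeans(mat)
  zero <- means == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero family column(s) dropped: ",
            paste(colnames(mat)[zero], collapse = ", "))
    mat <- mat[, !zero, drop = FALSE]
    means <- means[!zero]
  }
  sweep(mat, 2, means, "/")
}

#' Cross-family correlation of TF counts and the weak-pair fraction
#'
#' Pearson correlation over species for each unordered family pair, plus the
#' fraction of pairs whose correlation falls below `r_threshold` (the share
#' of family pairs whose size variation is effectively independent).
#' Standardizing first does not change the result: per-column scaling leaves
#' Pearson r invariant, so raw or standardized input is acceptable.
#'
#' @param mat Species x family matrix (>= 3 species rows).
#' @param r_threshold Correlation threshold in (0, 1); default 0.5.
#' @return List: `correlations` (family x family matrix), `n_pairs` (number
#'   of unordered pairs with defined correlation), `n_below`, and
#'   `fraction_pct` (one-decimal percentage of pairs below threshold).
#'   Zero-variance families are excluded from the pair count with a message.
#' @export
family_correlations <- function(mat, r_threshold = 0.5) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 3) stop("need at least 3 species rows")
  if (r_threshold <= 0 || r_threshold >= 1) stop("'r_threshold' must be in (0, 1)")
  sds <- apply(mat, 2, stats::sd)
  degen <- sds == 0
  if (any(degen)) {
    message(sum(degen), " zero-variance family column(s) excluded from the ",
            "pair fraction: ", paste(colnames(mat)[degen], collapse = ", "))
  }
  cors <- suppressWarnings(stats::cor(mat))
  ok <- which(!degen)
  rvals <- cors[ok, ok, drop = FALSE][upper.tri(diag(length(ok)))]
  n_pairs <- length(rvals)
  n_below <- sum(rvals < r_threshold)
  list(correlations = cors, n_pairs = n_pairs, n_below = n_below,
       fraction_pct = if (n_pairs > 0) pct(n_below, n_pairs) else NA_real_)
}
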