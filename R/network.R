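# shared: igraph from a node_a/node_b data.frame
.graph_from_edges <- function(edges) {
  igraph::simplify(
    igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE),
    remove.multiple = TRUE, remove.loops = TRUE
  )
}

#' Load a score-thresholded interaction network
#'
#' Reads an edge list (STRING links dialect or 3-column TSV), keeps edges
#' with confidence at or above `min_score` (inclusive; 0.4 is the
#' medium-confidence cutoff), drops self-loops, and collapses duplicate
#' undirected pairs to one edge keeping the highest score.
#'
#' @param path File path, or a data.frame already holding `node_a`,
#'   `node_b`, `score` columns (scores in [0, 1] or integers 0-1000).
#' @param min_score Threshold in [0, 1]; default 0.4.
#' @return data.frame `node_a`, `node_b`, `score` with scores in [0, 1].
#' @export
load_edges <- function(path, min_score = 0.4) {
  if (min_score < 0 || min_score > 1) stop("'min_score' must be in [0, 1]")
  e <- if (is.character(path)) read_string_edges(path) else {
    stopifnot(is.data.frame(path), ncol(path) >= 3)
    out <- path[, 1:3]
    names(out) <- c("node_a", "node_b", "score")
    if (nrow(out) > 0 && any(out$score > 1)) {
      if (all(out$score == round(out$score)) && all(out$score <= 1000)) {
        out$score <- out$score / 1000
      } else {
        stop("cannot determine score scale")
      }
    }
    out
  }
  e <- e[e$score >= min_score, , drop = FALSE]
  loops <- e$node_a == e$node_b
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    e <- e[!loops, , drop = FALSE]
  }
  if (nrow(e) == 0) {
    warning("no edges pass the score threshold")
    return(e)
  }
  a <- pmin(e$node_a, e$node_b)
  b <- pmax(e$node_a, e$node_b)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -e$score)
  e <- data.frame(node_a = a[ord], node_b = b[ord], score = e$score[ord],
                  stringsAsFactors = FALSE)
  e <- e[!duplicated(paste(e$node_a, e$node_b, sep = "\r")), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Classify TFs as large-component vs isolated in the TF-to-TF network
#'
#' Induces the TF-to-TF subgraph on the supplied TF list, finds its
#' connected components, and labels TFs inside the single largest component
#' `large_component`; every other networked TF — members of small TF-TF
#' components and TFs whose only interactions are with non-TF genes — is
#' `isolated`. TFs with no interactions of any kind are excluded from both
#' classes and returned separately.
#'
#' @param edges Global edge data.frame (`node_a`, `node_b`, ...), already
#'   thresholded.
#' @param tf_list Character vector of TF gene ids.
#' @param tie_break Optional TF id; when two or more TF-TF components tie
#'   for largest (an ambiguous "largest component"), the component containing
#'   this TF is taken. Without it a tie is an error.
#' @return List of class `"tf_classification"`: `classification`
#'   (data.frame: `tf`, `class`, `component`, `degree_tftf`,
#'   `degree_global`), `no_interaction` (TF ids absent from the network),
#'   and counts `n_large`, `n_isolated`, `n_no_interaction`.
#' @export
classify_tf_components <- function(edges, tf_list, tie_break = NULL) {
  stopifnot(length(tf_list) > 0)
  tf_list <- unique(tf_list)
  g <- .graph_from_edges(edges)
  nodes <- igraph::V(g)$name
  networked <- intersect(tf_list, nodes)
  no_int <- setdiff(tf_list, networked)

  if (length(networked) == 0) {
    return(structure(list(
      classification = data.frame(tf = character(0), class = character(0),
                                  component = integer(0),
                                  degree_tftf = integer(0),
                                  degree_global = integer(0)),
      no_interaction = no_int, n_large = 0L, n_isolated = 0L,
      n_no_interaction = length(no_int)
    ), class = "tf_classification"))
  }

  sub <- igraph::induced_subgraph(g, networked)
  comp <- igraph::components(sub)
  sizes <- comp$csize
  big <- which(sizes == max(sizes))
  if (length(big) > 1) {
    if (is.null(tie_break)) {
      stop(length(big), " TF-TF components tie for largest (size ",
           max(sizes), "); pass 'tie_break' with a TF inside the intended ",
           "large component")
    }
    if (!tie_break %in% igraph::V(sub)$name) {
      stop("'tie_break' TF not in the TF-TF network")
    }
    big <- comp$membership[tie_break]
  }
  member <- comp$membership[igraph::V(sub)$name]
  cls <- ifelse(member == big, "large_component", "isolated")
  deg_tf <- igraph::degree(sub)[igraph::V(sub)$name]
  deg_glob <- igraph::degree(g)[igraph::V(sub)$name]
  res <- data.frame(tf = igraph::V(sub)$name, class = cls,
                    component = as.integer(member),
                    degree_tftf = as.integer(deg_tf),
                    degree_global = as.integer(deg_glob),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    classification = res, no_interaction = no_int,
    n_large = sum(cls == "large_component"),
    n_isolated = sum(cls == "isolated"),
    n_no_interaction = length(no_int)
  ), class = "tf_classification")
}

#' @export
print.tf_classification <- function(x, ...) {
  cat("TF-to-TF network classification\n")
  cat("  large component:", x$n_large, "\n")
  cat("  isolated:       ", x$n_isolated, "\n")
  cat("  no interactions:", x$n_no_interaction, "\n")
  invisible(x)
}

#' Summarize TF classes against annotations
#'
#' Per class: member count, lethal-phenotype count and percentage,
#' absent-in-comparator count and percentage (unknown flags excluded from
#' both numerator and denominator, with a logged count), and the mean +/- sd
#' of the degree. Percentages are rounded to one decimal.
#'
#' @param classification A [classify_tf_components()] result.
#' @param annotations data.frame with `gene`, `lethal`, `absent_in_other`
#'   (logical, NA = unknown).
#' @param degree Which degree to summarize: `"global"` (whole gene
#'   interaction network, default — the Table-style convention) or `"tftf"`
#'   (TF-to-TF subnetwork).
#' @return data.frame with one row per class.
#' @export
summarize_classes <- function(classification, annotations,
                              degree = c("global", "tftf")) {
  stopifnot(inherits(classification, "tf_classification"))
  degree <- match.arg(degree)
  df <- classification$classification
  ann <- annotations[match(df$tf, annotations$gene), ]
  degcol <- if (degree == "tftf") df$degree_tftf else df$degree_global
  n_unknown <- sum(is.na(ann$lethal)) + sum(is.na(ann$absent_in_other))
  if (n_unknown > 0) message(n_unknown, " unknown annotation flag(s) excluded")
  rows <- lapply(c("large_component", "isolated"), function(cl) {
    sel <- df$class == cl
    n <- sum(sel)
    if (n == 0) {
      return(data.frame(class = cl, n = 0L, lethal_n = NA_integer_,
                        lethal_pct = NA_real_, absent_n = NA_integer_,
                        absent_pct = NA_real_, degree_mean = NA_real_,
                        degree_sd = NA_real_, stringsAsFactors = FALSE))
    }
    let <- ann$lethal[sel]
    abs_ <- ann$absent_in_other[sel]
    data.frame(
      class = cl, n = n,
      lethal_n = sum(let, na.rm = TRUE),
      lethal_pct = if (sum(!is.na(let)) > 0)
        pct(sum(let, na.rm = TRUE), sum(!is.na(let))) else NA_real_,
      absent_n = sum(abs_, na.rm = TRUE),
      absent_pct = if (sum(!is.na(abs_)) > 0)
        pct(sum(abs_, na.rm = TRUE), sum(!is.na(abs_))) else NA_real_,
      degree_mean = mean(degcol[sel]),
      degree_sd = stats::sd(degcol[sel]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Relative difference between paired counts
#'
#' `100 * |a - b| / ((a + b) / 2)`, the symmetric percent difference used to
#' compare orthologous TF interacting-gene counts between species; ranges
#' from 0 (equal) to 200 (one count zero). Pairs with both counts zero are
#' excluded with a logged count.
#'
#' @param count_a,count_b Non-negative numeric vectors of equal length.
#' @return List: `values` (per pair, NA where both counts are zero), `mean`,
#'   `sd`, `n_excluded`.
#' @export
relative_difference <- function(count_a, count_b) {
  stopifnot(length(count_a) == length(count_b),
            all(count_a >= 0), all(count_b >= 0))
  both_zero <- count_a + count_b == 0
  if (any(both_zero)) message(sum(both_zero), " all-zero pair(s) excluded")
  rd <- ifelse(both_zero, NA_real_,
               100 * abs(count_a - count_b) / ((count_a + count_b) / 2))
  list(values = rd, mean = mean(rd, na.rm = TRUE),
       sd = stats::sd(rd, na.rm = TRUE), n_excluded = sum(both_zero))
}
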