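#' Read a 6-column domain-hit TSV
#'
#' The portable hit-table dialect: tab-separated columns `protein_id`,
#' `gene_name`, `species`, `family`, `e_value`, `bit_score`, with a header.
#'
#' @param path File path.
#' @return data.frame of hits.
#' @export
read_hits_tsv <- function(path) {
  h <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "",
                         comment.char = "")
  need <- c("protein_id", "gene_name", "species", "family", "e_value",
            "bit_score")
  miss <- setdiff(need, names(h))
  if (length(miss) > 0) {
    stop("hit table lacks column(s): ", paste(miss, collapse = ", "))
  }
  h
}

#' Read hmmscan per-domain tabular output (domtblout)
#'
#' Parses the whitespace-delimited per-domain table of HMMER 3's `hmmscan
#' --domtblout`. The target (model) name is taken as the family, the query
#' as the protein; the full-sequence E-value and bit score are used. Gene
#' and species are recovered from the query name with a configurable
#' convention `gene|species|protein` unless a `splitter` function is given.
#'
#' @param path File path.
#' @param splitter Optional function mapping the query-name vector to a
#'   data.frame with columns `protein_id`, `gene_name`, `species`. The
#'   default splits on `"|"` as `gene|species|protein`; queries that do not
#'   match keep the full name as protein id with gene and species `NA`.
#' @return data.frame with the 6 canonical hit columns.
#' @export
read_domtblout <- function(path, splitter = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(protein_id = character(0), gene_name = character(0),
                      species = character(0), family = character(0),
                      e_value = numeric(0), bit_score = numeric(0)))
  }
  fields <- strsplit(lines, "[ \t]+")
  short <- which(vapply(fields, length, 1L) < 23)
  if (length(short) > 0) {
    stop("malformed domtblout line (fewer than 23 fields): line ", short[1])
  }
  target <- vapply(fields, `[[`, "", 1)   # model = family
  query <- vapply(fields, `[[`, "", 4)    # protein sequence
  evalue <- as.numeric(vapply(fields, `[[`, "", 7))  # full-sequence E-value
  score <- as.numeric(vapply(fields, `[[`, "", 8))   # full-sequence bit score
  if (is.null(splitter)) {
    splitter <- function(q) {
      parts <- strsplit(q, "|", fixed = TRUE)
      ok <- vapply(parts, length, 1L) == 3
      data.frame(
        protein_id = ifelse(ok, vapply(parts, function(p) p[3], ""), q),
        gene_name = ifelse(ok, vapply(parts, function(p) p[1], ""),
                           NA_character_),
        species = ifelse(ok, vapply(parts, function(p) p[2], ""),
                         NA_character_),
        stringsAsFactors = FALSE
      )
    }
  }
  ids <- splitter(query)
  data.frame(ids, family = target, e_value = evalue, bit_score = score,
             stringsAsFactors = FALSE)
}

#' Read an interaction edge list in the STRING links dialect
#'
#' Accepts space- or tab-separated files with columns
#' `protein1 protein2 combined_score` (header optional). Scores on the
#' integer 0-1000 scale are rescaled to [0, 1]; fractional scores are kept
#' as-is. A file mixing the two scales is an error.
#'
#' @param path File path.
#' @return data.frame `node_a`, `node_b`, `score` (score in [0, 1]).
#' @export
read_string_edges <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty edge file: ", path)
    return(data.frame(node_a = character(0), node_b = character(0),
                      score = numeric(0)))
  }
  first <- strsplit(lines[1], "[ \t]+")[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[3])))
  if (has_header) lines <- lines[-1]
  if (length(lines) == 0) {
    warning("edge file has a header but no data rows: ", path)
    return(data.frame(node_a = character(0), node_b = character(0),
                      score = numeric(0)))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3)) {
    stop("malformed edge line (fewer than 3 fields): line ",
         which(nf < 3)[1] + has_header)
  }
  a <- vapply(fields, `[[`, "", 1)
  b <- vapply(fields, `[[`, "", 2)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  if (anyNA(s)) {
    stop("non-numeric score: line ", which(is.na(s))[1] + has_header)
  }
  if (all(s <= 1)) {
    # already on [0, 1]
  } else if (all(s == round(s)) && all(s >= 0 & s <= 1000)) {
    s <- s / 1000
  } else {
    stop("cannot determine score scale: scores are neither all in [0, 1] ",
         "nor all integers in [0, 1000]")
  }
  data.frame(node_a = a, node_b = b, score = s, stringsAsFactors = FALSE)
}

#' Write a simulated dataset bundle to disk
#'
#' Serializes whichever simulated pieces are supplied: Newick trees, TSV
#' edge/node/expression/GO tables, and a JSON ground-truth sidecar.
#'
#' @param dir Output directory (created if needed).
#' @param species_tree Optional `phylo`.
#' @param families Optional list of [simulate_gene_family()] results.
#' @param network Optional [simulate_ppi_network()] result.
#' @param expression Optional [simulate_expression()] result.
#' @param go Optional [simulate_go_annotations()] result.
#' @return Invisibly, the paths written.
#' @export
write_sim_bundle <- function(dir, species_tree = NULL, families = NULL,
                             network = NULL, expression = NULL, go = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  truth <- list()
  w_tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(species_tree)) {
    p <- file.path(dir, "species_tree.nwk")
    ape::write.tree(species_tree, file = p)
    paths <- c(paths, p)
  }
  if (!is.null(families)) {
    fam_dir <- file.path(dir, "gene_trees")
    dir.create(fam_dir, showWarnings = FALSE)
    for (i in seq_along(families)) {
      if (!is.null(families[[i]]$tree)) {
        p <- file.path(fam_dir, sprintf("family%03d.nwk", i))
        ape::write.tree(families[[i]]$tree, file = p)
        paths <- c(paths, p)
      }
    }
    truth$family_events <- lapply(families, `[[`, "events")
  }
  if (!is.null(network)) {
    w_tsv(network$edges, "edges.tsv")
    w_tsv(network$nodes, "nodes.tsv")
    truth$planted_isolated <- network$truth
  }
  if (!is.null(expression)) {
    w_tsv(expression$expression, "expression.tsv")
    truth$expression <- expression$truth
  }
  if (!is.null(go)) {
    w_tsv(go$annotations_a, "go_species_a.tsv")
    w_tsv(go$annotations_b, "go_species_b.tsv")
    w_tsv(go$ortholog_map, "go_ortholog_map.tsv")
    truth$go <- go$truth
  }
  if (length(truth) > 0) {
    p <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
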