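#' Overlap proportion of two TF sets
#'
#' The number of shared TFs divided by the average set size,
#' `q = |A ∩ B| / ((|A| + |B|) / 2)` — algebraically the Sørensen–Dice
#' coefficient, symmetric in the two species and in [0, 1]. When an ortholog
#' map is supplied the intersection is taken through it; unmapped TFs count
#' toward set sizes but never toward the intersection.
#'
#' @param set_a,set_b Character vectors of TF ids (species A / B namespaces).
#' @param map Optional data.frame `tf_a`, `tf_b` of orthologous id pairs;
#'   without it the two sets share a namespace.
#' @return List: `size_a`, `size_b`, `avg_size`, `n_common`, `q`.
#' @export
overlap_proportion <- function(set_a, set_b, map = NULL) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  avg <- (length(set_a) + length(set_b)) / 2
  if (avg == 0) stop("both sets are empty")
  n_common <- if (is.null(map)) {
    length(intersect(set_a, set_b))
  } else {
    m <- map[!is.na(map$tf_a) & !is.na(map$tf_b), ]
    sum(m$tf_a %in% set_a & m$tf_b %in% set_b)
  }
  list(size_a = length(set_a), size_b = length(set_b), avg_size = avg,
       n_common = n_common, q = n_common / avg)
}

#' Per-term overlap table for two species' GO annotations
#'
#' @param ann_a,ann_b data.frames `term`, `tf` for species A and B.
#' @param map Optional ortholog map (`tf_a`, `tf_b`).
#' @return data.frame: `term`, `size_a`, `size_b`, `avg_size`, `n_common`,
#'   `q`. Terms annotated in neither species are skipped with a logged count.
#' @export
go_overlap_table <- function(ann_a, ann_b, map = NULL) {
  stopifnot(all(c("term", "tf") %in% names(ann_a)),
            all(c("term", "tf") %in% names(ann_b)))
  terms <- sort(unique(c(ann_a$term, ann_b$term)))
  sa <- split(ann_a$tf, ann_a$term)
  sb <- split(ann_b$tf, ann_b$term)
  empty <- vapply(terms, function(t) {
    length(sa[[t]]) == 0 && length(sb[[t]]) == 0
  }, logical(1))
  if (any(empty)) {
    message(sum(empty), " term(s) with both sets empty skipped")
    terms <- terms[!empty]
  }
  rows <- lapply(terms, function(t) {
    o <- overlap_proportion(sa[[t]], sb[[t]], map = map)
    data.frame(term = t, size_a = o$size_a, size_b = o$size_b,
               avg_size = o$avg_size, n_common = o$n_common, q = o$q,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Smooth the overlap proportion against set size
#'
#' Local polynomial (degree-2 loess) regression of the per-term overlap
#' proportion on log average set size; fitted values are clipped to [0, 1].
#' The direct-surface fit is deterministic and invariant to term ordering.
#'
#' @param points data.frame with `avg_size` and `q` columns (>= 10 terms).
#' @param span Loess span in (0, 1]; default 0.75.
#' @return Object of class `"overlap_curve"`: `points` (input plus `qhat`),
#'   `model` (the loess fit on `log(avg_size)`), `span`.
#' @export
smooth_overlap <- function(points, span = 0.75) {
  stopifnot(all(c("avg_size", "q") %in% names(points)))
  if (nrow(points) < 10) stop("need at least 10 terms to smooth")
  if (span <= 0 || span > 1) stop("'span' must be in (0, 1]")
  pts <- points[order(points$avg_size), , drop = FALSE]
  dat <- data.frame(log_size = log(pts$avg_size), q = pts$q)
  model <- tryCatch(
    stats::loess(q ~ log_size, data = dat, span = span, degree = 2,
                 family = "gaussian", surface = "direct"),
    error = function(e) {
      stop("loess fit failed (", conditionMessage(e),
           "); try a larger span", call. = FALSE)
    }
  )
  pts$qhat <- pmin(pmax(stats::predict(model, dat), 0), 1)
  structure(list(points = pts, model = model, span = span),
            class = "overlap_curve")
}

#' Predict the smoothed overlap proportion at given set sizes
#'
#' @param object An `"overlap_curve"`.
#' @param sizes Average set sizes at which to evaluate the curve.
#' @param ... Unused.
#' @return Numeric vector of predictions, clipped to [0, 1].
#' @export
predict.overlap_curve <- function(object, sizes, ...) {
  pred <- stats::predict(object$model,
                         data.frame(log_size = log(sizes)))
  unname(pmin(pmax(pred, 0), 1))
}

#' Per-term set-size comparison between species
#'
#' The scatter input for comparing how many TFs regulate each GO term in the
#' two species, with the identity line as reference.
#'
#' @param ann_a,ann_b data.frames `term`, `tf`.
#' @return data.frame `term`, `size_a`, `size_b` (one row per term annotated
#'   in at least one species).
#' @export
count_comparison <- function(ann_a, ann_b) {
  terms <- sort(unique(c(ann_a$term, ann_b$term)))
  if (length(terms) == 0) {
    return(data.frame(term = character(0), size_a = integer(0),
                      size_b = integer(0)))
  }
  sa <- split(ann_a$tf, ann_a$term)
  sb <- split(ann_b$tf, ann_b$term)
  data.frame(
    term = terms,
    size_a = vapply(terms, function(t) length(unique(sa[[t]])), 1L),
    size_b = vapply(terms, function(t) length(unique(sb[[t]])), 1L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
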