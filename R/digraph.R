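#' Directed degree sequences
#'
#' A directed degree sequence prescribes an out-degree and an in-degree per
#' vertex (simple digraphs: no loops, no parallel arcs, antiparallel arcs
#' allowed).
#'
#' @param labels character vertex identifiers, duplicate-free.
#' @param out_degree,in_degree non-negative integers, unnamed (label order)
#'   or named by label.
#' @return class `redese_dds`.
#' @export
directed_degree_sequence <- function(labels, out_degree, in_degree) {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    redese_stop("REJECT_SCHEMA", "duplicate vertex labels")
  structure(list(
    labels = labels,
    out_degree = if (length(labels)) normalize_degrees(out_degree, labels, "out") else stats::setNames(integer(), character()),
    in_degree = if (length(labels)) normalize_degrees(in_degree, labels, "in") else stats::setNames(integer(), character())
  ), class = "redese_dds")
}

#' Bipartite representation of a directed degree sequence
#'
#' The classical split representation: class `U` holds one copy of every
#' vertex with positive out-degree (carrying the out-degree), class `W` one
#' copy of every vertex with positive in-degree (carrying the in-degree);
#' the arc `x -> y` corresponds to the bipartite edge `(u_x, w_y)`. Loops
#' are excluded by forbidding every diagonal pair `(u_x, w_x)` where both
#' copies exist -- a matching, so the resulting problem is 1F1S with an
#' empty star. Zero-degree copies are deleted.
#'
#' @param dds a [directed_degree_sequence()].
#' @return list with `problem` (the bipartite problem), `map` (data frame
#'   `label`, `u_label`, `w_label`, `NA` where a copy was deleted) and
#'   `out_half_regular` (are the retained out-degrees equal except at most
#'   one vertex -- the condition under which the sampling chain's rapid
#'   mixing guarantee applies to digraphs).
#' @export
directed_to_bipartite <- function(dds) {
  stopifnot(inherits(dds, "redese_dds"))
  keep_u <- dds$labels[dds$out_degree > 0L]
  keep_w <- dds$labels[dds$in_degree > 0L]
  if (length(keep_u) == 0L || length(keep_w) == 0L)
    redese_stop("REJECT_SCHEMA", "no vertex with positive out-degree and in-degree; empty bipartite problem")
  u_labels <- paste0(keep_u, "__out")
  w_labels <- paste0(keep_w, "__in")
  both <- intersect(keep_u, keep_w)
  fb <- if (length(both)) cbind(paste0(both, "__out"), paste0(both, "__in")) else NULL
  problem <- validate_problem(u_labels, w_labels,
                              unname(dds$out_degree[keep_u]),
                              unname(dds$in_degree[keep_w]), fb)
  outs <- unname(dds$out_degree[keep_u])
  tab <- table(outs)
  out_half_regular <- length(tab) <= 1L || (length(tab) == 2L && min(tab) == 1L)
  map <- data.frame(label = dds$labels,
                    u_label = ifelse(dds$labels %in% keep_u, paste0(dds$labels, "__out"), NA),
                    w_label = ifelse(dds$labels %in% keep_w, paste0(dds$labels, "__in"), NA),
                    stringsAsFactors = FALSE)
  list(problem = problem, map = map, out_half_regular = out_half_regular)
}

#' Arcs of a directed graph from a bipartite realization
#'
#' Inverse of the split representation: each bipartite edge `(u_x, w_y)`
#' becomes the arc `x -> y`. The forbidden diagonal matching guarantees the
#' result is loop-free, and per-vertex out/in arc counts equal the directed
#' prescription.
#'
#' @param realization a realization of a problem produced by
#'   [directed_to_bipartite()].
#' @param map the label map returned alongside it.
#' @return two-column character matrix of arcs (`from`, `to`).
#' @export
realization_to_digraph <- function(realization, map) {
  e <- realization$edges
  from <- map$label[match(e[, 1L], map$u_label)]
  to <- map$label[match(e[, 2L], map$w_label)]
  if (anyNA(from) || anyNA(to))
    redese_stop("MAP_MISMATCH", "realization edge not covered by the label map")
  arcs <- cbind(from = from, to = to)
  if (any(arcs[, 1L] == arcs[, 2L]))
    redese_stop("MAP_MISMATCH", "loop produced; the problem does not forbid the diagonal")
  arcs
}
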