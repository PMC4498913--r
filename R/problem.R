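#' Validate a bipartite restricted degree sequence problem
#'
#' Builds the central problem object: a bipartite degree prescription on two
#' vertex classes `U` and `W` together with a set of forbidden `(u, w)` pairs.
#' The forbidden set must decompose as a (partial) 1-factor -- a matching --
#' plus a star whose center lies in `U` (the "1F1S" restriction). This is the
#' restriction under which the swap chain, the greedy construction and the
#' self-reduction counter of this package operate; it covers in particular the
#' bipartite representation of loop-free directed graphs, where the forbidden
#' set is the diagonal matching and the star is empty.
#'
#' The star center is inferred: a `U` vertex carrying two or more forbidden
#' incidences is the unique possible center; if every `U` vertex carries at
#' most one, the center may still be forced by a `W` vertex carrying two (the
#' star must absorb one of them), and otherwise the star is empty and the
#' center is left unset, to be designated on demand (first `U` label in input
#' order) by operations that need one.
#'
#' @param u_labels,w_labels character vectors of vertex identifiers; the two
#'   sets must be disjoint and duplicate-free. Input order is meaningful: it
#'   is the tie-break order used by every deterministic operation.
#' @param u_degrees,w_degrees non-negative integer degree prescriptions,
#'   either unnamed (in label order) or named by label.
#' @param forbidden forbidden pairs: a two-column matrix/data.frame
#'   (`u` label, `w` label), or a list of length-2 vectors, or `NULL`.
#' @param star_center optional `U` label to force as star center; validation
#'   fails if the remainder of the forbidden set is not a matching.
#'
#' @return An object of class `redese_problem` with fields `u`, `w`,
#'   `du`, `dw` (named integer vectors), `forbidden` (two-column character
#'   matrix), `star_center` (label or `NA`), `half_regular` (all `U` degrees
#'   equal except possibly at the center), and `degree_sum_ok` (class degree
#'   sums match; a mismatch is recorded, not fatal, so that counting can
#'   return 0 cleanly).
#'
#' @section Errors: `REJECT_SCHEMA` for malformed input, `REJECT_NOT_1F1S`
#'   when no star center decomposition exists.
#'
#' @examples
#' # the directed-triangle instance: all degrees 1, forbidden diagonal matching
#' p <- validate_problem(c("u1", "u2", "u3"), c("w1", "w2", "w3"),
#'                       c(1, 1, 1), c(1, 1, 1),
#'                       rbind(c("u1", "w1"), c("u2", "w2"), c("u3", "w3")))
#' p$half_regular
#' @export
validate_problem <- function(u_labels, w_labels, u_degrees, w_degrees,
                             forbidden = NULL, star_center = NULL) {
  u_labels <- as.character(u_labels)
  w_labels <- as.character(w_labels)
  if (length(u_labels) == 0L || length(w_labels) == 0L)
    redese_stop("REJECT_SCHEMA", "both vertex classes must be non-empty")
  if (anyDuplicated(u_labels) || anyDuplicated(w_labels))
    redese_stop("REJECT_SCHEMA", "duplicate vertex labels within a class")
  if (length(intersect(u_labels, w_labels)))
    redese_stop("REJECT_SCHEMA", "U and W labels must be disjoint")

  du <- normalize_degrees(u_degrees, u_labels, "u")
  dw <- normalize_degrees(w_degrees, w_labels, "w")
  fb <- normalize_pairs(forbidden)
  if (nrow(fb)) {
    bad <- !(fb[, 1L] %in% u_labels) | !(fb[, 2L] %in% w_labels)
    if (any(bad))
      redese_stop("REJECT_SCHEMA", sprintf(
        "forbidden pair (%s, %s) references unknown labels",
        fb[which(bad)[1L], 1L], fb[which(bad)[1L], 2L]))
    if (anyDuplicated(paste(fb[, 1L], fb[, 2L], sep = "\t")))
      redese_stop("REJECT_SCHEMA", "duplicate forbidden pairs")
  }

  s <- find_star_center(u_labels, fb, star_center)

  du_rest <- if (is.na(s)) du else du[setdiff(u_labels, s)]
  half_regular <- length(unique(unname(du_rest))) <= 1L

  structure(list(
    u = u_labels, w = w_labels, du = du, dw = dw,
    forbidden = fb,
    star_center = s,
    half_regular = half_regular,
    degree_sum_ok = sum(du) == sum(dw)
  ), class = "redese_problem")
}

normalize_degrees <- function(d, labels, side) {
  if (!is.null(names(d))) {
    if (!setequal(names(d), labels) || anyDuplicated(names(d)))
      redese_stop("REJECT_SCHEMA",
                  sprintf("%s_degrees names do not cover the %s labels exactly", side, side))
    d <- d[labels]
  } else if (length(d) != length(labels)) {
    redese_stop("REJECT_SCHEMA",
                sprintf("%s_degrees has length %d, expected %d", side, length(d), length(labels)))
  }
  d <- unname(d)
  if (any(is.na(d)) || any(d < 0) || any(d != round(d)))
    redese_stop("REJECT_SCHEMA", sprintf("%s_degrees must be non-negative integers", side))
  stats::setNames(as.integer(d), labels)
}

normalize_pairs <- function(x) {
  if (is.null(x) || (is.list(x) && !is.data.frame(x) && length(x) == 0L))
    return(matrix(character(), 0L, 2L))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.list(x)) {
    if (any(lengths(x) != 2L))
      redese_stop("REJECT_SCHEMA", "pairs must have exactly two elements")
    x <- do.call(rbind, lapply(x, as.character))
  }
  if (is.null(dim(x)) && length(x) == 2L) x <- matrix(x, 1L, 2L)
  if (!is.matrix(x) || ncol(x) != 2L)
    redese_stop("REJECT_SCHEMA", "pairs must form a two-column structure")
  if (nrow(x) == 0L) return(matrix(character(), 0L, 2L))
  matrix(as.character(x), nrow(x), 2L, dimnames = NULL)
}

# Star-center decomposition under condition (Psi): forbidden = matching + star
# with center in U. Returns the center label or NA (empty star), or raises
# REJECT_NOT_1F1S.
find_star_center <- function(u_labels, fb, supplied = NULL) {
  if (nrow(fb) == 0L) {
    if (!is.null(supplied)) {
      if (!supplied %in% u_labels)
        redese_stop("REJECT_SCHEMA", "star_center is not a U label")
      return(as.character(supplied))
    }
    return(NA_character_)
  }
  cnt_u <- table(factor(fb[, 1L], levels = u_labels))
  rest_is_matching <- function(s) {
    keep <- fb[, 1L] != s
    rest <- fb[keep, , drop = FALSE]
    !anyDuplicated(rest[, 1L]) && !anyDuplicated(rest[, 2L])
  }
  if (!is.null(supplied)) {
    supplied <- as.character(supplied)
    if (!supplied %in% u_labels)
      redese_stop("REJECT_SCHEMA", "star_center is not a U label")
    if (!rest_is_matching(supplied))
      redese_stop("REJECT_NOT_1F1S",
                  "forbidden set minus the supplied star is not a matching")
    return(supplied)
  }
  heavy <- names(cnt_u)[cnt_u >= 2L]
  if (length(heavy) >= 2L)
    redese_stop("REJECT_NOT_1F1S",
                "two U vertices carry >= 2 forbidden incidences; no single star center")
  if (length(heavy) == 1L) {
    if (!rest_is_matching(heavy))
      redese_stop("REJECT_NOT_1F1S",
                  "forbidden set minus the forced star is not a matching")
    return(heavy)
  }
  # every u has <= 1 incidence; a w with 2 incidences still forces a star edge
  cnt_w <- table(fb[, 2L])
  if (any(cnt_w >= 3L))
    redese_stop("REJECT_NOT_1F1S",
                "a W vertex carries >= 3 forbidden incidences; the star (centered in U) cannot absorb them")
  heavy_w <- names(cnt_w)[cnt_w == 2L]
  if (length(heavy_w) == 0L) return(NA_character_)  # plain matching, empty star
  cand <- fb[fb[, 2L] == heavy_w[1L], 1L]
  for (hw in heavy_w[-1L]) cand <- intersect(cand, fb[fb[, 2L] == hw, 1L])
  cand <- u_labels[u_labels %in% cand]  # input order
  for (s in cand) if (rest_is_matching(s)) return(s)
  redese_stop("REJECT_NOT_1F1S", "no star center decomposition of the forbidden set exists")
}

#' @export
print.redese_problem <- function(x, ...) {
  cat(sprintf("Bipartite 1F1S degree sequence problem: |U| = %d, |W| = %d\n",
              length(x$u), length(x$w)))
  cat(sprintf("  degree sums: U = %d, W = %d%s\n", sum(x$du), sum(x$dw),
              if (x$degree_sum_ok) "" else "  (MISMATCH: non-graphical)"))
  cat(sprintf("  forbidden pairs: %d (star center: %s)\n", nrow(x$forbidden),
              if (is.na(x$star_center)) "none/unset" else x$star_center))
  cat(sprintf("  half-regular in U: %s\n", x$half_regular))
  invisible(x)
}

# --- internal index-based views -------------------------------------------

# logical |U| x |W| forbidden matrix, dimnames by label
forbidden_matrix <- function(p) {
  f <- matrix(FALSE, length(p$u), length(p$w), dimnames = list(p$u, p$w))
  if (nrow(p$forbidden)) f[p$forbidden] <- TRUE
  f
}

edge_keys <- function(edges) if (nrow(edges)) paste(edges[, 1L], edges[, 2L], sep = "\t") else character()

# Designated operative star center: the validated one, else first U label.
operative_center <- function(p) if (!is.na(p$star_center)) p$star_center else p$u[[1L]]

same_problem <- function(a, b) {
  identical(a$u, b$u) && identical(a$w, b$w) &&
    identical(unname(a$du), unname(b$du)) && identical(unname(a$dw), unname(b$dw)) &&
    identical(a$forbidden[order(a$forbidden[, 1L], a$forbidden[, 2L]), , drop = FALSE],
              b$forbidden[order(b$forbidden[, 1L], b$forbidden[, 2L]), , drop = FALSE])
}

#' Construct a realization of a problem
#'
#' A realization is a simple bipartite graph whose per-vertex degrees equal
#' the prescription and whose edge set avoids the forbidden pairs.
#'
#' @param problem a [validate_problem()] object.
#' @param edges two-column structure of `(u, w)` pairs (matrix, data.frame or
#'   list of pairs).
#' @param validate check all realization invariants (`INVALID_REALIZATION` on
#'   violation). Internal callers that construct provably valid edge sets may
#'   skip it.
#' @return An object of class `redese_realization` with the canonically
#'   ordered edge matrix in `$edges`.
#' @export
new_realization <- function(problem, edges, validate = TRUE) {
  stopifnot(inherits(problem, "redese_problem"))
  e <- normalize_pairs(edges)
  ord <- order(match(e[, 1L], problem$u), match(e[, 2L], problem$w))
  e <- e[ord, , drop = FALSE]
  r <- structure(list(problem = problem, edges = e), class = "redese_realization")
  if (validate) validate_realization(r)
  r
}

validate_realization <- function(r) {
  p <- r$problem
  e <- r$edges
  if (nrow(e)) {
    if (any(!(e[, 1L] %in% p$u)) || any(!(e[, 2L] %in% p$w)))
      redese_stop("INVALID_REALIZATION", "edge references an unknown label")
    k <- edge_keys(e)
    if (anyDuplicated(k))
      redese_stop("INVALID_REALIZATION",
                  sprintf("duplicate edge (%s)", k[duplicated(k)][1L]))
    bad <- k %in% edge_keys(p$forbidden)
    if (any(bad))
      redese_stop("INVALID_REALIZATION",
                  sprintf("forbidden pair used as edge (%s)", k[bad][1L]))
  }
  tu <- table(factor(e[, 1L], levels = p$u))
  tw <- table(factor(e[, 2L], levels = p$w))
  if (any(tu != p$du))
    redese_stop("INVALID_REALIZATION", sprintf(
      "degree mismatch at U vertex %s: %d edges, prescribed %d",
      p$u[which(tu != p$du)[1L]], tu[which(tu != p$du)[1L]], p$du[which(tu != p$du)[1L]]))
  if (any(tw != p$dw))
    redese_stop("INVALID_REALIZATION", sprintf(
      "degree mismatch at W vertex %s: %d edges, prescribed %d",
      p$w[which(tw != p$dw)[1L]], tw[which(tw != p$dw)[1L]], p$dw[which(tw != p$dw)[1L]]))
  invisible(r)
}

#' Biadjacency matrix of a realization
#'
#' Rows are `U` in input order, columns `W` in input order (conventional
#' row-major orientation).
#' @param r a realization.
#' @return a 0/1 integer matrix with dimnames.
#' @export
biadjacency <- function(r) {
  p <- r$problem
  m <- matrix(0L, length(p$u), length(p$w), dimnames = list(p$u, p$w))
  if (nrow(r$edges)) m[r$edges] <- 1L
  m
}

# logical variant used by the fast internal engines
realization_matrix <- function(r) biadjacency(r) > 0L

matrix_to_realization <- function(p, M, validate = FALSE) {
  idx <- which(M, arr.ind = TRUE)
  e <- cbind(p$u[idx[, 1L]], p$w[idx[, 2L]])
  new_realization(p, e, validate = validate)
}

# canonical string key (state identity for enumeration / chain diagnostics)
realization_key <- function(r) paste(edge_keys(r$edges), collapse = ";")

#' @export
print.redese_realization <- function(x, ...) {
  cat(sprintf("Realization with %d edges of a %dx%d problem\n",
              nrow(x$edges), length(x$problem$u), length(x$problem$w)))
  if (nrow(x$edges)) {
    shown <- utils::head(seq_len(nrow(x$edges)), 10L)
    cat(paste0("  ", x$edges[shown, 1L], " -- ", x$edges[shown, 2L], collapse = "\n"), "\n")
    if (nrow(x$edges) > 10L) cat(sprintf("  ... and %d more\n", nrow(x$edges) - 10L))
  }
  invisible(x)
}
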