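#' Chord-circuits
#'
#' A chord-circuit is a cyclic vertex sequence `x1, ..., x2i` alternating
#' between the two classes such that every consecutive cyclic pair is a chord
#' (an allowed vertex pair: opposite classes and not forbidden) and the `2i`
#' chords are pairwise distinct. It is *elementary* when no vertex occurs more
#' than twice and repeated vertices lie at odd cyclic distance; in the
#' bipartite setting repeated vertices always sit at even distance (the
#' sequence alternates classes), so elementary circuits are exactly the
#' vertex-distinct alternating cycles.
#'
#' @param problem a [validate_problem()] object.
#' @param vertices character vector of vertex labels, cyclic order, even
#'   length.
#' @return class `redese_circuit`: the label vector with the problem attached
#'   as an attribute.
#' @export
chord_circuit <- function(problem, vertices) {
  v <- as.character(vertices)
  n <- length(v)
  if (n < 4L || n %% 2L != 0L)
    redese_stop("REJECT_SCHEMA", "a chord-circuit needs even length >= 4")
  in_u <- v %in% problem$u
  in_w <- v %in% problem$w
  if (any(!in_u & !in_w))
    redese_stop("REJECT_SCHEMA", "circuit vertex not in the problem")
  if (any(in_u == in_u[c(2:n, 1L)]))
    redese_stop("REJECT_SCHEMA", "circuit must alternate between the classes (D1)")
  ch <- circuit_chords(v, in_u)
  k <- edge_keys(ch)
  if (anyDuplicated(k))
    redese_stop("REJECT_SCHEMA", "circuit chords must be pairwise distinct (D2)")
  if (any(k %in% edge_keys(problem$forbidden)))
    redese_stop("REJECT_SCHEMA", "circuit traverses a forbidden pair (not a chord, D1)")
  structure(v, problem = problem, class = "redese_circuit")
}

# the 2i chords as a (u, w) matrix in traversal order
circuit_chords <- function(v, in_u = NULL) {
  n <- length(v)
  if (is.null(in_u)) in_u <- v %in% attr(v, "problem")$u
  a <- v
  b <- v[c(2:n, 1L)]
  ua <- in_u
  cbind(ifelse(ua, a, b), ifelse(ua, b, a))
}

#' Is a chord-circuit elementary?
#'
#' Checks D3 (no vertex more than twice) and D4 (repeats at odd cyclic
#' distance). For bipartite circuits D4 can never hold for a repeat, so this
#' is equivalent to all vertices being distinct.
#' @param circuit a [chord_circuit()] (or plain label vector).
#' @export
is_elementary <- function(circuit) {
  v <- as.character(circuit)
  n <- length(v)
  tab <- table(v)
  if (any(tab > 2L)) return(FALSE)
  for (lab in names(tab)[tab == 2L]) {
    pos <- which(v == lab)
    d <- min(pos[2L] - pos[1L], n - (pos[2L] - pos[1L]))
    if (d %% 2L == 0L) return(FALSE)
  }
  TRUE
}

#' PV-pairs of a chord-circuit
#'
#' Two distinct vertices of the circuit form a PV-pair when their cyclic
#' distance (number of chords between them, taking the shorter arc) is odd and
#' greater than 1. A circular swap along the circuit is compatible with the
#' forbidden set exactly when every PV-pair is a non-chord (forbidden); C4
#' circuits have no PV-pairs, so every C4 swap is compatible, and a C6 has
#' exactly its three opposite pairs.
#'
#' @param circuit a [chord_circuit()] or plain label vector (even length,
#'   alternating classes).
#' @return a two-column character matrix of unordered pairs, the vertex of
#'   class `U` first when a problem is attached, otherwise the vertex at the
#'   earlier position.
#' @export
pv_pairs <- function(circuit) {
  v <- as.character(circuit)
  pos <- pv_positions(length(v))
  if (nrow(pos) == 0L) return(matrix(character(), 0L, 2L))
  a <- v[pos[, 1L]]
  b <- v[pos[, 2L]]
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  p <- attr(circuit, "problem")
  if (!is.null(p)) {
    swap <- b %in% p$u
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  pr <- unique(cbind(a, b), MARGIN = 1L)
  dimnames(pr) <- NULL
  pr[order(pr[, 1L], pr[, 2L]), , drop = FALSE]
}

# index pairs (p < q) at odd min-arc distance > 1
pv_positions <- function(n) {
  out <- which(outer(seq_len(n), seq_len(n), function(p, q) {
    d <- abs(q - p); d <- pmin(d, n - d)
    q > p & d %% 2L == 1L & d > 1L
  }), arr.ind = TRUE)
  colnames(out) <- NULL
  out
}

#' Does a chord-circuit alternate in a realization?
#'
#' True when consecutive chords along the circuit are alternately edges and
#' non-edges of the realization (either phase).
#' @param realization a [new_realization()] object.
#' @param circuit a [chord_circuit()] or label vector.
#' @export
is_alternating <- function(realization, circuit) {
  st <- circuit_status(realization, circuit)
  n <- length(st)
  all(st != st[c(2:n, 1L)])
}

# logical vector: chord j of the circuit is an edge of the realization
circuit_status <- function(realization, circuit) {
  v <- as.character(circuit)
  ch <- circuit_chords(v, v %in% realization$problem$u)
  edge_keys(ch) %in% edge_keys(realization$edges)
}

# all PV-pairs forbidden (given the attached/supplied problem)?
is_f_compatible <- function(circuit, problem = attr(circuit, "problem")) {
  pr <- pv_pairs(circuit)
  if (nrow(pr) == 0L) return(TRUE)
  all(edge_keys(pr) %in% edge_keys(problem$forbidden))
}
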