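#' Colored symmetric difference of two realizations
#'
#' Partitions the symmetric difference of the edge sets by origin. At every
#' vertex the number of incident `x_edges` equals the number of incident
#' `y_edges`, which is what allows the difference to be decomposed into
#' alternating circuits.
#'
#' @param X,Y realizations of the same problem.
#' @return class `redese_coldiff`: list with `x_edges`, `y_edges` (two-column
#'   matrices) and the problem.
#' @export
symmetric_difference <- function(X, Y) {
  if (!same_problem(X$problem, Y$problem))
    redese_stop("PROBLEM_MISMATCH", "realizations belong to different problems")
  kx <- edge_keys(X$edges)
  ky <- edge_keys(Y$edges)
  structure(list(
    x_edges = X$edges[!(kx %in% ky), , drop = FALSE],
    y_edges = Y$edges[!(ky %in% kx), , drop = FALSE],
    problem = X$problem
  ), class = "redese_coldiff")
}

#' Decompose a symmetric difference into elementary alternating circuits
#'
#' Walks the two-colored difference graph into closed walks whose edges
#' alternate between the two origins, then splits any walk that repeats a
#' vertex (repeats necessarily sit at even cyclic distance in a bipartite
#' alternating circuit) until every circuit is an elementary alternating
#' cycle. The extraction is deterministic: it starts from the first
#' unsaturated vertex in input order (`U` before `W`) and always follows the
#' first unused edge of the required color in input order.
#'
#' @param X,Y realizations of the same problem.
#' @return list of [chord_circuit()] objects, alternating in `X` (and in
#'   `Y`); empty when `X == Y`. Their chords partition the symmetric
#'   difference.
#' @export
decompose_to_elementary_circuits <- function(X, Y) {
  cd <- symmetric_difference(X, Y)
  p <- cd$problem
  ex <- cd$x_edges
  ey <- cd$y_edges
  if (nrow(ex) == 0L) return(list())

  vorder <- c(p$u, p$w)
  # adjacency: per vertex, incident edge ids per color, input order
  eid_x <- seq_len(nrow(ex))
  eid_y <- seq_len(nrow(ey))
  used_x <- rep(FALSE, nrow(ex))
  used_y <- rep(FALSE, nrow(ey))
  other_end <- function(edge, v) if (edge[[1L]] == v) edge[[2L]] else edge[[1L]]
  next_edge <- function(v, color) {
    if (color == "x") {
      cand <- eid_x[!used_x & (ex[, 1L] == v | ex[, 2L] == v)]
    } else {
      cand <- eid_y[!used_y & (ey[, 1L] == v | ey[, 2L] == v)]
    }
    if (length(cand)) cand[[1L]] else NA_integer_
  }
  circuits <- list()
  repeat {
    touched <- unique(c(ex[!used_x, ], ey[!used_y, ]))
    if (length(touched) == 0L) break
    v0 <- vorder[vorder %in% touched][[1L]]
    v <- v0
    color <- "x"
    verts <- character()
    repeat {
      verts <- c(verts, v)
      id <- next_edge(v, color)
      if (is.na(id))
        redese_stop("INVARIANT_VIOLATION", "difference graph not balanced; corrupt input")
      if (color == "x") { used_x[id] <- TRUE; e <- ex[id, ] }
      else { used_y[id] <- TRUE; e <- ey[id, ] }
      v <- other_end(e, v)
      color <- if (color == "x") "y" else "x"
      if (v == v0 && color == "x") break  # closed, alternation complete
    }
    circuits <- c(circuits, split_to_cycles(verts))
  }
  lapply(circuits, function(vs) chord_circuit(p, vs))
}

# split a cyclic vertex sequence at repeated vertices until vertex-distinct;
# alternation is preserved because repeats sit at even cyclic distance
split_to_cycles <- function(verts) {
  n <- length(verts)
  dup <- which(duplicated(verts))
  if (length(dup) == 0L) return(list(verts))
  q <- dup[[1L]]
  p_ <- which(verts == verts[[q]])[[1L]]
  part1 <- verts[p_:(q - 1L)]
  part2 <- verts[c(seq_len(p_ - 1L), q:n)]
  c(split_to_cycles(part1), split_to_cycles(part2))
}

#' Process an alternating circuit into compatible swaps
#'
#' Carries out the circular swap along an alternating elementary circuit as a
#' sequence of forbidden-set-compatible C4/C6 swaps of total weight
#' `length/2 - 1`. If every PV-pair of the circuit is a non-chord the
#' circular swap is emitted directly (necessarily a C4 or C6 under the 1F1S
#' restriction); otherwise the circuit is split at the first PV-pair that is
#' a chord, the currently-alternating half is processed first (flipping the
#' chord's status), then the complementary half (flipping it back).
#'
#' @param realization a realization in which the circuit alternates.
#' @param circuit a [chord_circuit()] or label vector.
#' @return list with `realization` and `moves`; the final realization
#'   differs from the input exactly on the circuit's chords.
#' @section Errors: `NOT_ALTERNATING`, `NOT_ELEMENTARY`.
#' @export
process_circuit <- function(realization, circuit) {
  p <- realization$problem
  v <- as.character(circuit)
  if (is.null(attr(circuit, "problem"))) circuit <- chord_circuit(p, v)
  if (!is_alternating(realization, circuit))
    redese_stop("NOT_ALTERNATING", "circuit does not alternate in the realization")
  if (!is_elementary(circuit)) {
    # not expected for 1F1S inputs coming from the decomposition; re-split
    parts <- split_to_cycles(v)
    if (length(parts) == 1L)
      redese_stop("NOT_ELEMENTARY", "circuit is not elementary and cannot be split")
    moves <- list()
    for (pt in parts) {
      res <- process_circuit(realization, chord_circuit(p, pt))
      realization <- res$realization
      moves <- c(moves, res$moves)
    }
    return(list(realization = realization, moves = moves))
  }
  process_cycle_rec(realization, v)
}

# recursion on vertex-distinct alternating cycles
process_cycle_rec <- function(realization, v) {
  p <- realization$problem
  n <- length(v)
  fbk <- edge_keys(p$forbidden)
  ek <- edge_keys(realization$edges)
  pos <- pv_positions(n)
  chordal <- integer(0)
  if (nrow(pos)) {
    in_u <- v[pos[, 1L]] %in% p$u
    pk <- ifelse(in_u,
                 paste(v[pos[, 1L]], v[pos[, 2L]], sep = "\t"),
                 paste(v[pos[, 2L]], v[pos[, 1L]], sep = "\t"))
    chordal <- which(!(pk %in% fbk))
  }
  if (length(chordal) == 0L) {
    if (n > 6L)
      redese_stop("INVARIANT_VIOLATION",
                  "compatible circular swap longer than C6; impossible under 1F1S")
    ch <- circuit_chords(v, v %in% p$u)
    st <- edge_keys(ch) %in% ek
    mv <- new_swap_move(if (n == 4L) "C4" else "C6",
                        removed = ch[st, , drop = FALSE],
                        added = ch[!st, , drop = FALSE],
                        u = sort(unique(v[v %in% p$u])),
                        w = sort(unique(v[v %in% p$w])))
    return(list(realization = apply_move(realization, mv), moves = list(mv)))
  }
  sp <- pos[chordal[[1L]], ]
  a <- sp[[1L]]; b <- sp[[2L]]
  half1 <- v[a:b]                      # closed by the chord (v[a], v[b])
  half2 <- c(v[b:n], v[seq_len(a)])    # the complement, closed by the same chord
  # exactly one half alternates given the chord's current status
  first <- if (is_alternating_vec(realization, half1)) half1 else half2
  second <- if (identical(first, half1)) half2 else half1
  res1 <- process_cycle_rec(realization, first)
  res2 <- process_cycle_rec(res1$realization, second)
  list(realization = res2$realization, moves = c(res1$moves, res2$moves))
}

is_alternating_vec <- function(realization, v) {
  is_alternating(realization, chord_circuit(realization$problem, v))
}

#' Swap path between two realizations
#'
#' Constructive connectivity of the realization space: decomposes the
#' symmetric difference of `X` and `Y` into elementary alternating circuits
#' and processes each with compatible swaps. Applying the returned moves in
#' order to `X` yields `Y`, through valid realizations only, with total
#' weight `sum(|C_k|/2 - 1)` over the decomposition's circuits.
#'
#' @param X,Y realizations of the same validated 1F1S problem.
#' @return list of swap moves (empty when `X == Y`).
#' @export
swap_path <- function(X, Y) {
  circuits <- decompose_to_elementary_circuits(X, Y)
  moves <- list()
  cur <- X
  for (cc in circuits) {
    res <- process_circuit(cur, cc)
    cur <- res$realization
    moves <- c(moves, res$moves)
  }
  if (!identical(realization_key(cur), realization_key(Y)))
    redese_stop("INVARIANT_VIOLATION", "swap path did not reproduce the target realization")
  moves
}

#' Total weight of a move sequence
#' @param moves list of swap moves.
#' @export
path_weight <- function(moves) sum(vapply(moves, function(m) m$weight, integer(1L)))
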