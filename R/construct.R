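#' Forbidden partner of a W vertex
#'
#' For the operative vertex `u` (the star center, or an arbitrary `U` vertex
#' when the star is empty) and a chord-neighbor `y` of `u`, there is at most
#' one other `U` vertex whose pair with `y` is forbidden; distinct neighbors
#' with defined partners have distinct partners. This uniqueness is what the
#' good order and the greedy construction rest on.
#'
#' @param problem a validated problem.
#' @param y a `W` label forming a chord with `u`.
#' @param u the operative `U` label.
#' @return the partner's `U` label, or `NULL` when none exists.
#' @section Errors: `INVARIANT_VIOLATION` if two partners exist (the
#'   forbidden set then cannot be a 1-factor plus a star at `u`);
#'   `PRECONDITION_VIOLATION` if `(u, y)` is not a chord.
#' @export
forbidden_partner <- function(problem, y, u) {
  y <- as.character(y); u <- as.character(u)
  fb <- problem$forbidden
  if (nrow(fb) && any(fb[, 1L] == u & fb[, 2L] == y))
    redese_stop("PRECONDITION_VIOLATION", sprintf("(%s, %s) is not a chord", u, y))
  partners <- fb[fb[, 2L] == y & fb[, 1L] != u, 1L]
  if (length(partners) >= 2L)
    redese_stop("INVARIANT_VIOLATION", sprintf(
      "W vertex %s has two forbidden partners besides %s; not 1F1S relative to %s",
      y, u, u))
  if (length(partners) == 0L) NULL else partners
}

#' Good order on the chord-neighborhood of a vertex
#'
#' Orders the chord-neighbors of `u` by decreasing (residual) degree; among
#' equal degrees, by decreasing degree of the forbidden partner, a
#' partner-free vertex ranking last (a vertex without forbidden partner can
#' always be exchanged in later, while a neighbor whose partner carries
#' demand must be served first -- see the methods vignette for why this
#' completion of the ordering rule is forced); remaining ties by input label
#' order. The function is pure: residual degrees are passed in, the problem
#' is not mutated.
#'
#' @param problem a validated problem.
#' @param u the pivot `U` label.
#' @param residual_w_degrees named integer vector of current `W` degrees;
#'   defaults to the prescription.
#' @param residual_u_degrees named integer vector of current `U` degrees
#'   (used to rank forbidden partners); defaults to the prescription.
#' @param candidates optional subset of `W` labels to order (defaults to all
#'   chord-neighbors of `u` with positive residual degree).
#' @return class `redese_good_order`: list with `u` and `ordered_w`.
#' @export
good_order <- function(problem, u, residual_w_degrees = problem$dw,
                       residual_u_degrees = problem$du, candidates = NULL) {
  u <- as.character(u)
  fb <- problem$forbidden
  forb_w <- fb[fb[, 1L] == u, 2L]
  if (is.null(candidates)) {
    candidates <- problem$w[!(problem$w %in% forb_w) & residual_w_degrees[problem$w] > 0L]
  } else {
    candidates <- as.character(candidates)
  }
  # partners are looked up among the *remaining* U vertices (those named in
  # residual_u_degrees): forbidden incidences of processed vertices are gone
  alive <- names(residual_u_degrees)
  key_partner <- vapply(candidates, function(y) {
    pf <- fb[fb[, 2L] == y & fb[, 1L] != u & fb[, 1L] %in% alive, 1L]
    if (length(pf) >= 2L)
      redese_stop("INVARIANT_VIOLATION", sprintf(
        "W vertex %s has two forbidden partners among the remaining U vertices", y))
    if (length(pf) == 0L) -Inf else as.numeric(residual_u_degrees[[pf]])
  }, numeric(1L))
  ord <- order(-as.numeric(residual_w_degrees[candidates]),
               -key_partner,
               match(candidates, problem$w))
  structure(list(u = u, ordered_w = unname(candidates[ord])),
            class = "redese_good_order")
}

#' @export
print.redese_good_order <- function(x, ...) {
  cat(sprintf("Good order at %s: %s\n", x$u, paste(x$ordered_w, collapse = " > ")))
  invisible(x)
}

#' Greedy construction of a realization (generalized Havel)
#'
#' Repeatedly pins down the neighborhood of one `U` vertex: the star center
#' while the star is non-empty, otherwise the first remaining `U` label.
#' The pivot is connected to its first `d(u)` chord-neighbors in good order
#' (among `W` vertices with positive residual degree); the pivot and its
#' forbidden incidences are then removed. The instance is graphical if and
#' only if this greedy run completes -- which makes the run a polynomial
#' decision procedure as well as a constructor.
#'
#' @param problem a validated 1F1S problem.
#' @return a realization.
#' @section Errors: `INFEASIBLE` when `d(u)` exceeds the available
#'   chord-neighbors at any step, or upfront on a degree-sum mismatch.
#' @seealso [is_graphical()] for the boolean wrapper.
#' @export
greedy_realize <- function(problem) {
  p <- problem
  if (!p$degree_sum_ok)
    redese_stop("INFEASIBLE", "class degree sums differ; no realization exists")
  rem_u <- p$u
  du <- p$du
  dw <- p$dw
  fb <- p$forbidden
  star <- p$star_center
  edges <- matrix(character(), 0L, 2L)
  while (length(rem_u)) {
    star_alive <- !is.na(star) && star %in% rem_u && any(fb[, 1L] == star)
    u <- if (star_alive) star else rem_u[[1L]]
    forb_w <- fb[fb[, 1L] == u, 2L]
    nb <- p$w[!(p$w %in% forb_w) & dw[p$w] > 0L]
    if (du[[u]] > length(nb))
      redese_stop("INFEASIBLE", sprintf(
        "vertex %s needs %d neighbors but only %d chords with residual capacity remain",
        u, du[[u]], length(nb)))
    if (du[[u]] > 0L) {
      go <- good_order(p, u, residual_w_degrees = dw,
                       residual_u_degrees = du[rem_u], candidates = nb)
      pick <- go$ordered_w[seq_len(du[[u]])]
      edges <- rbind(edges, cbind(u, pick))
      dw[pick] <- dw[pick] - 1L
    }
    rem_u <- setdiff(rem_u, u)
    fb <- fb[fb[, 1L] != u, , drop = FALSE]
  }
  new_realization(p, edges, validate = TRUE)
}

#' Is a 1F1S instance graphical?
#'
#' Boolean wrapper around [greedy_realize()].
#' @param problem a validated problem.
#' @export
is_graphical <- function(problem) {
  tryCatch({ greedy_realize(problem); TRUE }, INFEASIBLE = function(e) FALSE)
}

#' Neighborhood exchange along a short alternating cycle
#'
#' Given `(u, z)` an edge and `(u, y)` a non-edge chord with `y` preceding
#' `z` in a good order at `u`, finds an alternating chord-cycle of length at
#' most 6 through `y, u, z` and processes it with compatible swaps, so that
#' the new realization has `Gamma(u) = Gamma(u) - {z} + {y}` and every
#' intermediate state is valid. The result is a single C4; or a single
#' compatible C6; or two C4s when the C6's middle pair happens to be a chord
#' (the cycle is then processed recursively).
#'
#' @param realization a realization.
#' @param u a `U` label; `y`, `z` chord-neighbors of `u`.
#' @param y,z `W` labels with `(u,y)` a non-edge and `(u,z)` an edge.
#' @return list with `realization` (the result) and `moves` (the swap
#'   sequence applied).
#' @export
neighbor_exchange <- function(realization, u, y, z) {
  p <- realization$problem
  u <- as.character(u); y <- as.character(y); z <- as.character(z)
  M <- realization_matrix(realization)
  Fm <- forbidden_matrix(p)
  iu <- match(u, p$u); iy <- match(y, p$w); iz <- match(z, p$w)
  if (anyNA(c(iu, iy, iz)) || y == z)
    redese_stop("PRECONDITION_VIOLATION", "u, y, z must name distinct problem vertices")
  if (Fm[iu, iy] || Fm[iu, iz])
    redese_stop("PRECONDITION_VIOLATION", "y and z must form chords with u")
  if (!M[iu, iz] || M[iu, iy])
    redese_stop("PRECONDITION_VIOLATION", "(u,z) must be an edge and (u,y) a non-edge")
  keyd <- function(iwv) {
    pf <- forbidden_partner(p, p$w[iwv], u)
    if (is.null(pf)) -Inf else as.numeric(p$du[[pf]])
  }
  dy <- p$dw[[y]]; dz <- p$dw[[z]]
  if (!(dy > dz || (dy == dz && keyd(iy) >= keyd(iz))))
    redese_stop("PRECONDITION_VIOLATION", "y does not precede z in any good order at u")

  # C4: some mu != u with (mu,y) an edge, (mu,z) a non-edge chord
  for (imu in setdiff(seq_along(p$u), iu)) {
    if (M[imu, iy] && !M[imu, iz] && !Fm[imu, iz]) {
      mv <- c4_move_idx(M, Fm, p, sort(c(iu, imu)), sort(c(iy, iz)))
      return(list(realization = apply_move(realization, mv), moves = list(mv)))
    }
  }
  # C6 (y, u, z, x1, w1, x2): (z,x1) non-edge chord, (x1,w1) edge,
  # (w1,x2) non-edge chord, (x2,y) edge; processed recursively if the middle
  # pair (u,w1) is a chord.
  for (ix1 in setdiff(seq_along(p$u), iu)) {
    if (M[ix1, iz] || Fm[ix1, iz]) next
    for (iw1 in setdiff(seq_along(p$w), c(iy, iz))) {
      if (!M[ix1, iw1]) next
      for (ix2 in setdiff(seq_along(p$u), c(iu, ix1))) {
        if (!M[ix2, iy] || M[ix2, iw1] || Fm[ix2, iw1]) next
        circ <- chord_circuit(p, c(y, u, z, p$u[ix1], p$w[iw1], p$u[ix2]))
        res <- process_circuit(realization, circ)
        return(res)
      }
    }
  }
  redese_stop("INVARIANT_VIOLATION",
              "no alternating chord-cycle of length <= 6 realizes the exchange; preconditions violated upstream")
}
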