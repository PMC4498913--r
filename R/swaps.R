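#' Swap moves
#'
#' A swap move exchanges the edges and non-edges along an alternating chord
#' circuit of length 4 (the classical Havel-type swap, weight 1) or length 6
#' (the triangular swap needed e.g. for directed degree sequences, weight 2;
#' its three opposite vertex pairs must all be forbidden). These are the only
#' two move types compatible with a 1-factor + star forbidden set.
#'
#' @name swap_move
NULL

new_swap_move <- function(kind, removed, added, u, w) {
  structure(list(kind = kind,
                 removed = removed, added = added,
                 u = u, w = w,
                 weight = if (kind == "C4") 1L else 2L),
            class = "redese_swap_move")
}

#' @export
print.redese_swap_move <- function(x, ...) {
  cat(sprintf("%s swap (weight %d): - {%s}  + {%s}\n", x$kind, x$weight,
              paste(x$removed[, 1L], x$removed[, 2L], sep = "~", collapse = ", "),
              paste(x$added[, 1L], x$added[, 2L], sep = "~", collapse = ", ")))
  invisible(x)
}

#' Propose a C4 swap on two U and two W vertices
#'
#' Returns the unique valid Havel-type swap on the four vertices if one of
#' the two perfect matchings between them consists of edges and the
#' complementary matching of non-forbidden non-edges; otherwise `NULL`
#' (the chain then holds). At most one orientation can be valid.
#'
#' @param realization a realization.
#' @param u_pair,w_pair two distinct `U` labels / `W` labels.
#' @return a swap move or `NULL`.
#' @export
propose_c4 <- function(realization, u_pair, w_pair) {
  p <- realization$problem
  iu <- match(as.character(u_pair), p$u)
  iw <- match(as.character(w_pair), p$w)
  if (length(iu) != 2L || length(iw) != 2L || anyNA(iu) || anyNA(iw) ||
      iu[1L] == iu[2L] || iw[1L] == iw[2L])
    redese_stop("REJECT_SCHEMA", "propose_c4 needs two distinct labels per class")
  M <- realization_matrix(realization)
  Fm <- forbidden_matrix(p)
  c4_move_idx(M, Fm, p, sort(iu), sort(iw))
}

# index-level C4 proposal; iu, iw sorted
c4_move_idx <- function(M, Fm, p, iu, iw) {
  e11 <- M[iu[1L], iw[1L]]; e12 <- M[iu[1L], iw[2L]]
  e21 <- M[iu[2L], iw[1L]]; e22 <- M[iu[2L], iw[2L]]
  if (e11 && e22 && !e12 && !e21 && !Fm[iu[1L], iw[2L]] && !Fm[iu[2L], iw[1L]]) {
    removed <- cbind(p$u[iu], p$w[iw])            # (u1,w1),(u2,w2)
    added <- cbind(p$u[iu], p$w[rev(iw)])         # (u1,w2),(u2,w1)
  } else if (e12 && e21 && !e11 && !e22 && !Fm[iu[1L], iw[1L]] && !Fm[iu[2L], iw[2L]]) {
    removed <- cbind(p$u[iu], p$w[rev(iw)])
    added <- cbind(p$u[iu], p$w[iw])
  } else return(NULL)
  new_swap_move("C4", removed, added, p$u[iu], p$w[iw])
}

#' Propose a C6 swap on three U and three W vertices
#'
#' The six vertices must admit a perfect pairing by forbidden pairs (unique
#' when it exists, since every non-center `U` vertex has at most one
#' forbidden incidence). The hexagon placing each `U` vertex opposite its
#' forbidden partner is then checked: all six cyclic pairs must be chords and
#' strictly alternate edge/non-edge in the realization. Returns the move
#' (weight 2) or `NULL`.
#'
#' @param realization a realization.
#' @param u_triple,w_triple three distinct `U` labels / `W` labels.
#' @return a swap move or `NULL`.
#' @export
propose_c6 <- function(realization, u_triple, w_triple) {
  p <- realization$problem
  iu <- match(as.character(u_triple), p$u)
  iw <- match(as.character(w_triple), p$w)
  if (length(iu) != 3L || length(iw) != 3L || anyNA(iu) || anyNA(iw) ||
      anyDuplicated(iu) || anyDuplicated(iw))
    redese_stop("REJECT_SCHEMA", "propose_c6 needs three distinct labels per class")
  M <- realization_matrix(realization)
  Fm <- forbidden_matrix(p)
  c6_move_idx(M, Fm, p, sort(iu), sort(iw))
}

# permutations of 1:3, fixed order
.PERM3 <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

# index-level C6 proposal; iu, iw sorted (canonical hexagon up to
# rotation/reflection, under which validity and the move are invariant)
c6_move_idx <- function(M, Fm, p, iu, iw) {
  Fs <- Fm[iu, iw, drop = FALSE]
  sigma <- NULL
  for (k in seq_len(nrow(.PERM3))) {
    pm <- .PERM3[k, ]
    if (Fs[1L, pm[1L]] && Fs[2L, pm[2L]] && Fs[3L, pm[3L]]) { sigma <- pm; break }
  }
  if (is.null(sigma)) return(NULL)
  # hexagon (a1,b1,a2,b2,a3,b3) with each a_k opposite its forbidden partner:
  # b2 = partner(a1), b3 = partner(a2), b1 = partner(a3)
  j1 <- iw[sigma[3L]]; j2 <- iw[sigma[1L]]; j3 <- iw[sigma[2L]]
  i1 <- iu[1L]; i2 <- iu[2L]; i3 <- iu[3L]
  cyc_u <- c(i1, i2, i2, i3, i3, i1)
  cyc_w <- c(j1, j1, j2, j2, j3, j3)
  if (any(Fm[cbind(cyc_u, cyc_w)])) return(NULL)    # every cyclic pair must be a chord
  st <- M[cbind(cyc_u, cyc_w)]
  if (!all(st == c(st[1L], !st[1L], st[1L], !st[1L], st[1L], !st[1L]))) return(NULL)
  removed <- cbind(p$u[cyc_u[st]], p$w[cyc_w[st]])
  added <- cbind(p$u[cyc_u[!st]], p$w[cyc_w[!st]])
  new_swap_move("C6", removed, added, p$u[c(i1, i2, i3)], p$w[sort(c(j1, j2, j3))])
}

#' Apply a swap move to a realization
#'
#' The realization space is closed under compatible swaps: the result is
#' again a valid realization, and applying the reversed move (removed and
#' added exchanged) restores the input exactly.
#'
#' @param realization a realization.
#' @param move a swap move valid for it.
#' @return the new realization.
#' @export
apply_move <- function(realization, move) {
  stopifnot(inherits(move, "redese_swap_move"))
  ek <- edge_keys(realization$edges)
  rk <- edge_keys(move$removed)
  ak <- edge_keys(move$added)
  if (!all(rk %in% ek))
    redese_stop("INVALID_MOVE", "move removes a chord that is not an edge")
  if (any(ak %in% ek))
    redese_stop("INVALID_MOVE", "move adds a chord that is already an edge")
  if (any(ak %in% edge_keys(realization$problem$forbidden)))
    redese_stop("INVALID_MOVE", "move adds a forbidden pair")
  e <- rbind(realization$edges[!(ek %in% rk), , drop = FALSE], move$added)
  new_realization(realization$problem, e, validate = TRUE)
}

reverse_move <- function(move) {
  new_swap_move(move$kind, move$added, move$removed, move$u, move$w)
}

#' Enumerate all valid swap moves from a realization
#'
#' All valid C4 moves over every choice of two `U` and two `W` vertices, then
#' all valid C6 moves over every choice of triples; deterministic
#' lexicographic order by vertex indices. This is the neighborhood structure
#' of the Markov chain's state graph.
#'
#' @param realization a realization.
#' @return list of swap moves.
#' @export
enumerate_moves <- function(realization) {
  p <- realization$problem
  M <- realization_matrix(realization)
  Fm <- forbidden_matrix(p)
  nu <- length(p$u); nw <- length(p$w)
  out <- list()
  if (nu >= 2L && nw >= 2L) {
    cu <- utils::combn(nu, 2L)
    cw <- utils::combn(nw, 2L)
    for (a in seq_len(ncol(cu))) for (b in seq_len(ncol(cw))) {
      mv <- c4_move_idx(M, Fm, p, cu[, a], cw[, b])
      if (!is.null(mv)) out[[length(out) + 1L]] <- mv
    }
  }
  if (nu >= 3L && nw >= 3L) {
    cu <- utils::combn(nu, 3L)
    cw <- utils::combn(nw, 3L)
    for (a in seq_len(ncol(cu))) for (b in seq_len(ncol(cw))) {
      mv <- c6_move_idx(M, Fm, p, cu[, a], cw[, b])
      if (!is.null(mv)) out[[length(out) + 1L]] <- mv
    }
  }
  out
}
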