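#' Canonical small instances
#'
#' Four desk-scale instances used throughout the documentation and tests:
#'
#' * `fixture_t3()` -- the "directed triangle": three vertices each with one
#'   in- and one out-arc, in bipartite representation. All degrees 1, the
#'   forbidden set is the diagonal matching. Exactly two realizations (the
#'   two cyclic orientations), which differ in six chords: no C4 swap
#'   connects them, a C6 swap is necessary.
#' * `fixture_b2()` -- 2x2, all degrees 1, nothing forbidden; two
#'   realizations one C4 swap apart.
#' * `fixture_s3()` -- 3x3 with degrees (1,2,2)/(1,2,2) and a size-2 star at
#'   `s` plus one matching edge; a unique realization.
#' * `fixture_r33()` -- 3x3, all degrees 2, nothing forbidden; six
#'   realizations (complements of the 3x3 permutation matrices).
#'
#' @return a validated problem.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
fixture_t3 <- function() {
  validate_problem(c("u1", "u2", "u3"), c("w1", "w2", "w3"),
                   c(1, 1, 1), c(1, 1, 1),
                   rbind(c("u1", "w1"), c("u2", "w2"), c("u3", "w3")))
}

#' @rdname fixtures
#' @export
fixture_b2 <- function() {
  validate_problem(c("u1", "u2"), c("w1", "w2"), c(1, 1), c(1, 1))
}

#' @rdname fixtures
#' @export
fixture_s3 <- function() {
  validate_problem(c("s", "u2", "u3"), c("w1", "w2", "w3"),
                   c(1, 2, 2), c(1, 2, 2),
                   rbind(c("s", "w1"), c("s", "w2"), c("u2", "w1")))
}

#' @rdname fixtures
#' @export
fixture_r33 <- function() {
  validate_problem(c("u1", "u2", "u3"), c("w1", "w2", "w3"), c(2, 2, 2), c(2, 2, 2))
}

#' Generate a feasible half-regular 1F1S instance with a known realization
#'
#' Builds an `r`-regular witness on `U` by round-robin
#' (`u_i -> w_{(i+j) mod n_w}`, `j < r`), randomizes it with valid C4 swaps,
#' derives the `W` degrees from the witness, and then draws the forbidden
#' set among the witness's *non-edges*: a star of `star_size` at a randomly
#' chosen center plus a vertex-disjoint matching of `matching_size` avoiding
#' the center. The witness is therefore a realization of the emitted problem
#' by construction, and the problem is half-regular 1F1S.
#'
#' @param n_u,n_w class sizes.
#' @param degree common `U` degree `r` (`<= n_w`).
#' @param star_size,matching_size forbidden-set sizes.
#' @param shuffle_swaps number of successful randomizing C4 swaps to apply.
#' @param seed optional integer seed.
#' @return list with `problem` and `witness` (a realization of it).
#' @section Errors: `FIXTURE_INFEASIBLE` when the requested forbidden sizes
#'   exceed the available non-edges.
#' @export
generate_fixture <- function(n_u, n_w, degree, star_size = 0L, matching_size = 0L,
                             shuffle_swaps = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (degree > n_w)
    redese_stop("REJECT_SCHEMA", "degree must not exceed n_w")
  if (matching_size > min(n_u - 1L, n_w))
    redese_stop("FIXTURE_INFEASIBLE", "matching_size exceeds min(n_u - 1, n_w)")
  u <- sprintf("u%d", seq_len(n_u))
  w <- sprintf("w%d", seq_len(n_w))
  M <- matrix(FALSE, n_u, n_w, dimnames = list(u, w))
  for (i in seq_len(n_u)) for (j in seq_len(degree))
    M[i, ((i + j - 2L) %% n_w) + 1L] <- TRUE
  # randomize with valid C4 swaps (no forbidden pairs yet)
  done <- 0L; attempts <- 0L
  while (done < shuffle_swaps && attempts < 100L * max(1L, shuffle_swaps)) {
    attempts <- attempts + 1L
    if (n_u < 2L || n_w < 2L) break
    i <- sample.int(n_u, 2L); j <- sample.int(n_w, 2L)
    if (M[i[1L], j[1L]] && M[i[2L], j[2L]] && !M[i[1L], j[2L]] && !M[i[2L], j[1L]]) {
      M[i[1L], j[1L]] <- FALSE; M[i[2L], j[2L]] <- FALSE
      M[i[1L], j[2L]] <- TRUE;  M[i[2L], j[1L]] <- TRUE
      done <- done + 1L
    }
  }
  # forbidden pairs among non-edges of the witness
  s_idx <- if (star_size > 0L) sample.int(n_u, 1L) else NA_integer_
  fb <- NULL
  if (star_size > 0L) {
    free_w <- which(!M[s_idx, ])
    if (length(free_w) < star_size)
      redese_stop("FIXTURE_INFEASIBLE", "not enough non-edges at the star center")
    pick <- if (length(free_w) == 1L) free_w else sample(free_w, star_size)
    fb <- cbind(u[s_idx], w[pick])
  }
  if (matching_size > 0L) {
    cand_u <- setdiff(seq_len(n_u), s_idx)
    cand_u <- if (length(cand_u) > 1L) sample(cand_u) else cand_u
    used_w <- integer()
    got <- 0L
    for (i in cand_u) {
      if (got == matching_size) break
      free_w <- setdiff(which(!M[i, ]), used_w)
      if (length(free_w) == 0L) next
      j <- if (length(free_w) == 1L) free_w else sample(free_w, 1L)
      fb <- rbind(fb, c(u[i], w[j]))
      used_w <- c(used_w, j)
      got <- got + 1L
    }
    if (got < matching_size)
      redese_stop("FIXTURE_INFEASIBLE", "not enough disjoint non-edges for the matching")
  }
  problem <- validate_problem(u, w, rep(degree, n_u), unname(colSums(M)), fb,
                              star_center = if (star_size > 0L) u[s_idx])
  list(problem = problem, witness = matrix_to_realization(problem, M, validate = TRUE))
}
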