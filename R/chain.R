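#' Chain configuration
#'
#' Parameters of a sampling run. The chain is lazy: it holds with probability
#' 1/2, proposes a uniformly chosen C4 swap with probability 1/4 and a
#' uniformly chosen C6 swap with probability 1/4 (holding whenever the
#' proposal is invalid), so its transition matrix is symmetric, its diagonal
#' is at least 1/2, and the uniform distribution is stationary.
#'
#' @param steps total chain steps.
#' @param burn_in steps discarded before the first recorded state; defaults
#'   to `10 * |U| * |W|` (resolved at run time).
#' @param thin spacing between recorded states; defaults to `|U| * |W|`.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @param start optional starting realization; defaults to
#'   [greedy_realize()].
#' @return class `redese_chain_config`.
#' @export
chain_config <- function(steps, burn_in = NULL, thin = NULL, seed = NULL,
                         start = NULL) {
  if (!is.null(thin) && thin < 1L) redese_stop("REJECT_SCHEMA", "thin must be >= 1")
  if (!is.null(burn_in) && burn_in < 0L) redese_stop("REJECT_SCHEMA", "burn_in must be >= 0")
  structure(list(steps = as.integer(steps), burn_in = burn_in, thin = thin,
                 seed = seed, start = start),
            class = "redese_chain_config")
}

# one step of the lazy chain on the logical biadjacency matrix M.
# nu/nw/Fm are cached by the caller; returns the (possibly unchanged) matrix.
chain_step_matrix <- function(M, Fm, nu, nw) {
  r <- stats::runif(1L)
  if (r < 0.5) return(M)
  if (r < 0.75) {
    if (nu < 2L || nw < 2L) return(M)          # degenerate class: forced hold
    i <- sample.int(nu, 2L)
    j <- sample.int(nw, 2L)
    e11 <- M[i[1L], j[1L]]; e12 <- M[i[1L], j[2L]]
    e21 <- M[i[2L], j[1L]]; e22 <- M[i[2L], j[2L]]
    if (e11 && e22 && !e12 && !e21) {
      if (!Fm[i[1L], j[2L]] && !Fm[i[2L], j[1L]]) {
        M[i[1L], j[1L]] <- FALSE; M[i[2L], j[2L]] <- FALSE
        M[i[1L], j[2L]] <- TRUE;  M[i[2L], j[1L]] <- TRUE
      }
    } else if (e12 && e21 && !e11 && !e22) {
      if (!Fm[i[1L], j[1L]] && !Fm[i[2L], j[2L]]) {
        M[i[1L], j[2L]] <- FALSE; M[i[2L], j[1L]] <- FALSE
        M[i[1L], j[1L]] <- TRUE;  M[i[2L], j[2L]] <- TRUE
      }
    }
    return(M)
  }
  if (nu < 3L || nw < 3L) return(M)            # degenerate class: forced hold
  i <- sort(sample.int(nu, 3L))
  j <- sort(sample.int(nw, 3L))
  Fs <- Fm[i, j]
  sigma <- NULL
  for (k in 1:6) {
    pm <- .PERM3[k, ]
    if (Fs[1L, pm[1L]] && Fs[2L, pm[2L]] && Fs[3L, pm[3L]]) { sigma <- pm; break }
  }
  if (is.null(sigma)) return(M)                # no forbidden perfect pairing
  cyc_u <- c(i[1L], i[2L], i[2L], i[3L], i[3L], i[1L])
  cyc_w <- c(j[sigma[3L]], j[sigma[3L]], j[sigma[1L]], j[sigma[1L]], j[sigma[2L]], j[sigma[2L]])
  idx <- cbind(cyc_u, cyc_w)
  if (any(Fm[idx])) return(M)
  st <- M[idx]
  if (st[1L] == st[2L] || st[2L] == st[3L] || st[3L] == st[4L] ||
      st[4L] == st[5L] || st[5L] == st[6L]) return(M)
  M[idx] <- !st
  M
}

#' One step of the lazy swap chain
#'
#' Advances the chain by a single proposal using the current RNG stream
#' (seed it with `set.seed()` for reproducibility). With probability 1/2 the
#' state is returned unchanged; with probability 1/4 an unordered pair of
#' `U` vertices and of `W` vertices is drawn uniformly and the C4 swap is
#' applied if valid; with probability 1/4 triples are drawn and the C6 swap
#' is applied if the six vertices pair up by forbidden chords and the
#' hexagon alternates. A class smaller than the proposal size makes the
#' corresponding branch a forced hold.
#'
#' The per-neighbor jump probability is `1/4 / (choose(|U|,2) choose(|W|,2))`
#' for C4 neighbors and `1/4 / (choose(|U|,3) choose(|W|,3))` for C6
#' neighbors.
#'
#' @param realization the current state.
#' @return the next state (possibly identical).
#' @export
chain_step <- function(realization) {
  p <- realization$problem
  M <- chain_step_matrix(realization_matrix(realization), forbidden_matrix(p),
                         length(p$u), length(p$w))
  matrix_to_realization(p, M)
}

# internal engine: runs the chain on matrices, calling record(M) at the
# sampling indices burn_in, burn_in + thin, ...
chain_engine <- function(p, M0, steps, burn_in, thin, record) {
  Fm <- forbidden_matrix(p)
  nu <- length(p$u); nw <- length(p$w)
  M <- M0
  for (t in seq_len(steps)) {
    M <- chain_step_matrix(M, Fm, nu, nw)
    if (t > burn_in && (t - burn_in - 1L) %% thin == 0L) record(M, t)
  }
  invisible(M)
}

#' Run the sampling chain
#'
#' Runs the lazy swap chain from a start state ([greedy_realize()] unless
#' given) and returns the states at indices `burn_in`, `burn_in + thin`, ...
#' The run is deterministic given the seed. Rapid mixing is guaranteed for
#' half-regular instances (all `U` degrees equal except possibly the star
#' center); on other validated instances the chain is still symmetric with
#' uniform stationary distribution and is run after a warning.
#'
#' @param problem a validated problem.
#' @param config a [chain_config()].
#' @return list of realizations.
#' @export
run_chain <- function(problem, config) {
  stopifnot(inherits(config, "redese_chain_config"))
  nu <- length(problem$u); nw <- length(problem$w)
  burn_in <- config$burn_in %||% (10L * nu * nw)
  thin <- config$thin %||% (nu * nw)
  if (burn_in >= config$steps)
    redese_stop("REJECT_SCHEMA", "burn_in must be smaller than steps")
  if (!problem$half_regular)
    redese_warn("NOT_HALF_REGULAR",
                "instance is not half-regular in U: sampling is still uniform-stationary, but rapid mixing is not guaranteed")
  if (!is.null(config$seed)) set.seed(config$seed)
  start <- config$start %||% greedy_realize(problem)
  if (!same_problem(start$problem, problem))
    redese_stop("PROBLEM_MISMATCH", "start state belongs to a different problem")
  out <- list()
  chain_engine(problem, realization_matrix(start), config$steps, burn_in, thin,
               function(M, t) out[[length(out) + 1L]] <<- matrix_to_realization(problem, M))
  out
}

#' Exact transition matrix over the enumerated state space
#'
#' Enumerates all realizations and assembles the chain's transition matrix:
#' row-stochastic, symmetric, diagonal entries at least 1/2, off-diagonal
#' entries equal to the C4/C6 jumping probabilities. Its stationary vector is
#' uniform. Intended for small-instance verification.
#'
#' @param problem a validated problem.
#' @param max_states enumeration budget (`STATE_SPACE_TOO_LARGE` beyond it).
#' @return matrix with states as dimnames (canonical edge-list keys), with
#'   the list of realizations attached as attribute `states`.
#' @export
transition_matrix <- function(problem, max_states = 1000L) {
  states <- exact_enumerate(problem, limit = max_states)
  n <- length(states)
  if (n == 0L)
    redese_stop("INFEASIBLE", "no realizations; empty state space")
  keys <- vapply(states, realization_key, character(1L))
  nu <- length(problem$u); nw <- length(problem$w)
  p4 <- if (nu >= 2L && nw >= 2L) 0.25 / (choose(nu, 2L) * choose(nw, 2L)) else 0
  p6 <- if (nu >= 3L && nw >= 3L) 0.25 / (choose(nu, 3L) * choose(nw, 3L)) else 0
  P <- matrix(0, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n)) {
    for (mv in enumerate_moves(states[[i]])) {
      j <- match(realization_key(apply_move(states[[i]], mv)), keys)
      P[i, j] <- P[i, j] + if (mv$kind == "C4") p4 else p6
    }
  }
  diag(P) <- 1 - rowSums(P)
  attr(P, "states") <- states
  P
}
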