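#' Exact enumeration of all realizations
#'
#' Backtracking over the `U` vertices in input order, assigning each its
#' neighbor subset among chords with positive residual degree, with a cheap
#' residual-capacity prune. Works for arbitrary forbidden sets (not only
#' 1F1S), which makes it the brute-force oracle for every other module.
#'
#' @param problem a validated problem.
#' @param limit abort with `STATE_SPACE_TOO_LARGE` when more than this many
#'   realizations are found.
#' @param first_only stop after the first realization (a pure backtracking
#'   graphicality decision, independent of the greedy construction).
#' @return list of realizations in deterministic order.
#' @export
exact_enumerate <- function(problem, limit = 100000L, first_only = FALSE) {
  p <- problem
  if (!p$degree_sum_ok) return(list())
  nu <- length(p$u); nw <- length(p$w)
  Fm <- forbidden_matrix(p)
  out <- list()
  rows <- vector("list", nu)
  recurse <- function(i, dw) {
    if (first_only && length(out)) return()
    if (i > nu) {
      if (all(dw == 0L)) {
        e <- do.call(rbind, lapply(seq_len(nu), function(k)
          if (length(rows[[k]])) cbind(p$u[[k]], p$w[rows[[k]]]) else NULL))
        out[[length(out) + 1L]] <<- new_realization(p, e %||% matrix(character(), 0L, 2L),
                                                    validate = FALSE)
        if (length(out) > limit)
          redese_stop("STATE_SPACE_TOO_LARGE",
                      sprintf("more than %d realizations", limit))
      }
      return()
    }
    d <- p$du[[i]]
    nb <- which(!Fm[i, ] & dw > 0L)
    if (d > length(nb)) return()
    # prune: every remaining w must still be servable by remaining u's with
    # positive degree (each can serve a w at most once)
    active <- seq_len(nu) >= i & unname(p$du) > 0L
    slack <- colSums(!Fm[active, , drop = FALSE])
    if (any(dw > slack)) return()
    choices <- if (d == 0L) list(integer(0)) else
      if (d == length(nb)) list(nb) else
        utils::combn(nb, d, simplify = FALSE)
    for (ch in choices) {
      rows[[i]] <<- ch
      dw2 <- dw; dw2[ch] <- dw2[ch] - 1L
      recurse(i + 1L, dw2)
      if (first_only && length(out)) return()
    }
    rows[[i]] <<- integer(0)
  }
  recurse(1L, unname(p$dw))
  out
}

#' Fix one chord of the star center (self-reduction step)
#'
#' The counting recursion conditions on the presence of the chord `(s, v)`,
#' where `s` is the operative star center (the validated center, or the
#' first `U` label when the star is empty) and `v` the first `W` label in
#' input order forming a chord with `s`. Both branches add `(s, v)` to the
#' forbidden set (growing the star); the presence branch also decrements
#' `d(s)` and `d(v)`. The reduced instance is again 1F1S and remains
#' half-regular in `U` except possibly at `s`. When `d(s)` reaches zero the
#' vertex `s` is eliminated together with its remaining forbidden
#' incidences, and the next `U` label becomes the operative center.
#'
#' @param problem a validated 1F1S problem.
#' @param v the `W` label to fix; defaults to the first chord of `s` in
#'   input order.
#' @param present condition on the chord being an edge (`TRUE`) or a
#'   non-edge (`FALSE`).
#' @return the reduced, revalidated problem.
#' @section Errors: `NEGATIVE_DEGREE` when the presence branch would drive
#'   `d(s)` or `d(v)` below zero (the branch is infeasible); `REJECT_SCHEMA`
#'   when `(s, v)` is not a chord.
#' @export
reduce_problem <- function(problem, v = NULL, present) {
  p <- problem
  s <- operative_center(p)
  forb_w <- p$forbidden[p$forbidden[, 1L] == s, 2L]
  chords <- p$w[!(p$w %in% forb_w)]
  if (is.null(v)) {
    if (length(chords) == 0L)
      redese_stop("REJECT_SCHEMA", sprintf("star center %s has no chords left", s))
    v <- chords[[1L]]
  }
  v <- as.character(v)
  if (!(v %in% chords))
    redese_stop("REJECT_SCHEMA", sprintf("(%s, %s) is not a chord", s, v))
  du <- p$du; dw <- p$dw
  if (present) {
    if (du[[s]] == 0L || dw[[v]] == 0L)
      redese_stop("NEGATIVE_DEGREE",
                  sprintf("presence branch would drive d(%s) or d(%s) negative",
                          if (du[[s]] == 0L) s else v, v))
    du[[s]] <- du[[s]] - 1L
    dw[[v]] <- dw[[v]] - 1L
  }
  fb <- rbind(p$forbidden, c(s, v))
  keep <- p$u != s
  if (du[[s]] == 0L && any(keep)) {
    validate_problem(p$u[keep], p$w, du[p$u[keep]], dw, fb[fb[, 1L] != s, , drop = FALSE])
  } else {
    validate_problem(p$u, p$w, du, dw, fb, star_center = s)
  }
}

# drop zero-degree operative centers (they constrain nothing; a degree-0
# vertex has no edges in any solution); returns the possibly reduced problem
drop_exhausted_center <- function(p) {
  while (sum(p$du) > 0L && p$du[[operative_center(p)]] == 0L) {
    s <- operative_center(p)
    keep <- p$u != s
    p <- validate_problem(p$u[keep], p$w, p$du[p$u[keep]], p$dw,
                          p$forbidden[p$forbidden[, 1L] != s, , drop = FALSE])
  }
  p
}

#' Approximate counting by self-reduction
#'
#' Estimates the number of realizations by recursively conditioning on one
#' chord of the star center at a time (see [reduce_problem()]): at each
#' level the chain ([run_chain()]) samples `level_samples` realizations of
#' the current instance, the fraction containing the fixed chord is
#' estimated, the majority branch (estimated fraction >= 1/2) is followed,
#' and the reciprocal of its fraction multiplies the running estimate. A
#' branch whose reduced instance is non-graphical (decided exactly by the
#' greedy construction) forces the other branch with multiplier 1. A sampled
#' state consistent with the chosen branch seeds the next level's chain.
#' The recursion ends at the all-degrees-zero instance (count 1); an
#' infeasible or degree-sum-mismatched input yields estimate 0.
#'
#' @param problem a validated 1F1S problem.
#' @param level_samples samples drawn per level (default 100).
#' @param burn_in,thin per-level chain parameters; the defaults are
#'   `10 * |U| * |W|` and `3 * |U| * |W|` of the current level's instance
#'   (the fraction estimator wants near-independent draws, hence the more
#'   conservative spacing than [run_chain()]'s generic default).
#' @param seed optional integer seed for the whole run.
#' @param max_retries times a level is re-run with doubled samples when the
#'   estimated fraction is 0 or 1 although both branches are feasible.
#' @return class `redese_count_estimate`: list with `estimate`, `levels`
#'   (data frame: chord, branch, fraction, samples), `seed`,
#'   `level_samples`.
#' @export
approx_count <- function(problem, level_samples = 100L, burn_in = NULL,
                         thin = NULL, seed = NULL, max_retries = 3L) {
  if (!is.null(seed)) set.seed(seed)
  levels <- data.frame(chord = character(), branch = character(),
                       fraction = numeric(), samples = integer(),
                       stringsAsFactors = FALSE)
  finish <- function(estimate) {
    structure(list(estimate = estimate, levels = levels, seed = seed,
                   level_samples = level_samples),
              class = "redese_count_estimate")
  }
  p <- problem
  if (!p$degree_sum_ok) return(finish(0))
  if (!is_graphical(p)) return(finish(0))
  witness <- realization_matrix(greedy_realize(p))
  estimate <- 1
  repeat {
    p <- drop_exhausted_center(p)
    witness <- witness[p$u, , drop = FALSE]          # keep rows in sync
    if (sum(p$du) == 0L) break                       # unique empty continuation
    s <- operative_center(p)
    forb_w <- p$forbidden[p$forbidden[, 1L] == s, 2L]
    chords <- p$w[!(p$w %in% forb_w)]
    if (length(chords) == 0L)
      redese_stop("INVARIANT_VIOLATION",
                  "feasible instance with an unservable star center")  # greedy would have failed
    v <- chords[[1L]]
    pres <- tryCatch(reduce_problem(p, v, present = TRUE), NEGATIVE_DEGREE = function(e) NULL)
    abs_ <- reduce_problem(p, v, present = FALSE)
    feas_p <- !is.null(pres) && is_graphical(pres)
    feas_a <- is_graphical(abs_)
    iu <- match(s, p$u); iw <- match(v, p$w)
    if (!feas_p && !feas_a)
      redese_stop("INVARIANT_VIOLATION", "both branches infeasible on a feasible instance")
    if (feas_p && feas_a) {
      m <- as.integer(level_samples)
      attempt <- 0L
      repeat {
        samp <- sample_fraction(p, witness, iu, iw, m, burn_in, thin)
        phat <- samp$fraction
        if ((phat > 0 && phat < 1) || attempt >= max_retries) break
        attempt <- attempt + 1L
        redese_warn("SAMPLER_FAILURE", sprintf(
          "level fraction estimate hit %g although both branches are feasible; re-running with %d samples",
          phat, 2L * m))
        m <- 2L * m
      }
      if (phat >= 0.5) {
        branch <- "present"; fraction <- phat
        wit <- samp$with %||% witness   # witness containing the chord
      } else {
        branch <- "absent"; fraction <- 1 - phat
        wit <- samp$without %||% witness
      }
    } else {
      m <- 0L
      if (feas_p) { branch <- "present"; fraction <- 1 }
      else { branch <- "absent"; fraction <- 1 }
      wit <- NULL
    }
    estimate <- estimate / fraction
    levels <- rbind(levels, data.frame(chord = paste(s, v, sep = "~"),
                                       branch = branch, fraction = fraction,
                                       samples = m, stringsAsFactors = FALSE))
    p_next <- if (branch == "present") pres else abs_
    # carry a start state into the reduced instance (a near-uniform draw from
    # the chosen branch is a near-uniform start for the reduced state space)
    if (!is.null(wit)) {
      if (branch == "present") wit[iu, iw] <- FALSE
      witness <- wit
    } else {
      witness <- realization_matrix(greedy_realize(p_next))
    }
    p <- p_next
  }
  finish(estimate)
}

# run the chain from witness and estimate the fraction of samples containing
# the chord (iu, iw); also capture one witness per branch (the last seen)
sample_fraction <- function(p, witness, iu, iw, m, burn_in, thin) {
  nu <- length(p$u); nw <- length(p$w)
  b <- burn_in %||% (10L * nu * nw)
  # the fraction estimator assumes near-independent draws; thin at three
  # times the generic spacing to keep residual autocorrelation small
  th <- thin %||% (3L * nu * nw)
  steps <- b + (m - 1L) * th + 1L
  hits <- 0L
  with_w <- NULL
  without_w <- NULL
  chain_engine(p, witness, steps, b, th, function(M, t) {
    if (M[iu, iw]) { hits <<- hits + 1L; with_w <<- M }
    else without_w <<- M
  })
  list(fraction = hits / m, with = with_w, without = without_w)
}

#' @export
print.redese_count_estimate <- function(x, ...) {
  cat(sprintf("Approximate realization count: %.4g (%d levels, %s)\n",
              x$estimate, nrow(x$levels),
              if (is.null(x$seed)) "no seed" else paste("seed", x$seed)))
  if (nrow(x$levels)) {
    shown <- utils::head(x$levels, 12L)
    for (i in seq_len(nrow(shown)))
      cat(sprintf("  %-12s %-7s fraction %.3f (%d samples)\n",
                  shown$chord[i], shown$branch[i], shown$fraction[i], shown$samples[i]))
    if (nrow(x$levels) > 12L) cat(sprintf("  ... and %d more levels\n", nrow(x$levels) - 12L))
  }
  invisible(x)
}
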