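# Shared helpers: fixtures are built in code, oracles are kept independent of
# the code paths they check.

edge_key <- function(m) if (nrow(m)) paste(m[, 1L], m[, 2L], sep = "\t") else character()
state_key <- function(r) paste(sort(edge_key(r$edges)), collapse = ";")

t3_states <- function() exact_enumerate(fixture_t3())

# random feasible half-regular 1F1S instance; retries infeasible forbidden draws
rand_fixture <- function(nu = sample(3:5, 1), nw = sample(3:6, 1),
                         degree = sample(1:3, 1),
                         star = sample(0:2, 1), matching = sample(0:2, 1)) {
  for (k in 1:20) {
    fx <- tryCatch(
      generate_fixture(nu, nw, min(degree, nw), star_size = star,
                       matching_size = min(matching, nu - 1L, nw),
                       shuffle_swaps = 10L),
      FIXTURE_INFEASIBLE = function(e) NULL)
    if (!is.null(fx)) return(fx)
    star <- max(0L, star - 1L); matching <- max(0L, matching - 1L)
  }
  stop("could not draw a feasible fixture")
}

# a battery of fixtures whose full state space has between lo and hi states
state_battery <- function(n, lo = 2L, hi = 200L, seed = 42L) {
  set.seed(seed)
  out <- list()
  while (length(out) < n) {
    fx <- rand_fixture()
    states <- tryCatch(exact_enumerate(fx$problem, limit = hi),
                       STATE_SPACE_TOO_LARGE = function(e) NULL)
    if (is.null(states) || length(states) < lo) next
    out[[length(out) + 1L]] <- list(problem = fx$problem, states = states)
  }
  out
}

# adjacency (by state index) of the move graph, from enumerate_moves
move_graph <- function(states) {
  keys <- vapply(states, state_key, character(1L))
  lapply(states, function(s) {
    unique(vapply(enumerate_moves(s), function(mv)
      match(state_key(apply_move(s, mv)), keys), integer(1L)))
  })
}

# independent breadth-first reachability over an adjacency list
bfs_component <- function(adj, start = 1L) {
  seen <- rep(FALSE, length(adj))
  queue <- start
  seen[start] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (x in adj[[v]]) if (!seen[x]) { seen[x] <- TRUE; queue <- c(queue, x) }
  }
  which(seen)
}

# deterministic sampler over the exhaustive small-instance family used by the
# graphicality-equivalence suite: |U|,|W| <= 4, degrees <= 3, 1F1S forbidden
# sets of up to 4 pairs
sample_small_instance <- function() {
  nu <- sample(1:4, 1L); nw <- sample(1:4, 1L)
  du <- sample(0:min(3L, nw), nu, replace = TRUE)
  dw <- sample(0:min(3L, nu), nw, replace = TRUE)
  if (stats::runif(1) < 0.75 && sum(du) <= nw * min(3L, nu)) {
    # rebalance dw so the class sums match (the interesting cases)
    for (k in 1:200) {
      if (sum(dw) == sum(du)) break
      j <- sample.int(nw, 1L)
      if (sum(dw) < sum(du) && dw[j] < min(3L, nu)) dw[j] <- dw[j] + 1L
      if (sum(dw) > sum(du) && dw[j] > 0L) dw[j] <- dw[j] - 1L
    }
  }
  u <- sprintf("u%d", seq_len(nu)); w <- sprintf("w%d", seq_len(nw))
  fb <- NULL
  sc <- NULL
  star <- sample(0:min(2L, nw), 1L)
  if (star > 0L) {
    sc <- sample(u, 1L)
    fb <- cbind(sc, sample(w, star))
  }
  m_max <- min(nu - (star > 0L), nw, 4L - star)
  msize <- if (m_max > 0L) sample(0:m_max, 1L) else 0L
  if (msize > 0L) {
    mu <- sample(setdiff(u, sc), msize)
    mw <- sample(w, msize)
    fb <- rbind(fb, cbind(mu, mw))
  }
  fb <- unique(fb)
  validate_problem(u, w, du, dw, fb, star_center = sc)
}
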