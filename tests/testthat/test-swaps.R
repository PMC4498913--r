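test_that("C4 proposals accept exactly the valid alternating rectangles", {
  b2 <- fixture_b2()
  rb <- new_realization(b2, rbind(c("u1", "w1"), c("u2", "w2")))
  mv <- propose_c4(rb, c("u1", "u2"), c("w1", "w2"))
  expect_identical(mv$kind, "C4")
  expect_identical(mv$weight, 1L)
  expect_setequal(edge_key(mv$removed), c("u1\tw1", "u2\tw2"))
  expect_setequal(edge_key(mv$added), c("u1\tw2", "u2\tw1"))

  # every C4 proposal on the directed-triangle instance is blocked by a
  # forbidden pair or broken alternation
  t3 <- fixture_t3()
  r <- new_realization(t3, rbind(c("u1", "w2"), c("u2", "w3"), c("u3", "w1")))
  for (us in utils::combn(t3$u, 2, simplify = FALSE))
    for (ws in utils::combn(t3$w, 2, simplify = FALSE))
      expect_null(propose_c4(r, us, ws))

  # complementary matching hitting a forbidden pair blocks the move
  p <- validate_problem(c("u1", "u2"), c("w1", "w2"), c(1, 1), c(1, 1),
                        rbind(c("u1", "w2")))
  rp <- new_realization(p, rbind(c("u1", "w1"), c("u2", "w2")))
  expect_null(propose_c4(rp, c("u1", "u2"), c("w1", "w2")))
})

test_that("C6 proposals require the forbidden pairing and alternation", {
  t3 <- fixture_t3()
  r <- new_realization(t3, rbind(c("u1", "w2"), c("u2", "w3"), c("u3", "w1")))
  mv <- propose_c6(r, t3$u, t3$w)
  expect_identical(mv$kind, "C6")
  expect_identical(mv$weight, 2L)
  expect_setequal(edge_key(mv$removed), c("u1\tw2", "u2\tw3", "u3\tw1"))
  expect_setequal(edge_key(mv$added), c("u1\tw3", "u2\tw1", "u3\tw2"))

  # no forbidden pairing at all
  r33 <- fixture_r33()
  rr <- greedy_realize(r33)
  expect_null(propose_c6(rr, r33$u, r33$w))

  # pairing exists but the hexagon does not alternate: 4x4 with a diagonal
  # matching forbidden and an edge pattern equal on the triple
  p4 <- validate_problem(paste0("u", 1:4), paste0("w", 1:4),
                         c(2, 2, 2, 2), c(2, 2, 2, 2),
                         cbind(paste0("u", 1:3), paste0("w", 1:3)))
  r4 <- new_realization(p4, rbind(
    c("u1", "w2"), c("u1", "w4"), c("u2", "w3"), c("u2", "w4"),
    c("u3", "w1"), c("u3", "w2"), c("u4", "w1"), c("u4", "w3")))
  expect_null(propose_c6(r4, c("u1", "u2", "u3"), c("w1", "w2", "w3")))
})

test_that("applying a move conserves degrees and reversing restores the state", {
  b2 <- fixture_b2()
  rb <- new_realization(b2, rbind(c("u1", "w1"), c("u2", "w2")))
  mv <- propose_c4(rb, c("u1", "u2"), c("w1", "w2"))
  r2 <- apply_move(rb, mv)
  back <- apply_move(r2, redese:::reverse_move(mv))
  expect_identical(state_key(back), state_key(rb))

  t3 <- fixture_t3()
  st <- t3_states()
  mv6 <- propose_c6(st[[1]], t3$u, t3$w)
  expect_identical(state_key(apply_move(st[[1]], mv6)), state_key(st[[2]]))

  expect_error(apply_move(r2, mv), class = "INVALID_MOVE")
})

test_that("a C4 changes 4 biadjacency entries and a C6 changes 6", {
  b2 <- fixture_b2()
  rb <- new_realization(b2, rbind(c("u1", "w1"), c("u2", "w2")))
  mv <- propose_c4(rb, c("u1", "u2"), c("w1", "w2"))
  expect_identical(sum(biadjacency(rb) != biadjacency(apply_move(rb, mv))), 4L)

  st <- t3_states()
  mv6 <- propose_c6(st[[1]], fixture_t3()$u, fixture_t3()$w)
  expect_identical(sum(biadjacency(st[[1]]) != biadjacency(apply_move(st[[1]], mv6))), 6L)

  set.seed(5)
  for (k in 1:10) {
    fx <- rand_fixture()
    for (mv in utils::head(enumerate_moves(fx$witness), 5)) {
      d <- sum(biadjacency(fx$witness) != biadjacency(apply_move(fx$witness, mv)))
      expect_identical(d, if (mv$kind == "C4") 4L else 6L)
    }
  }
})

test_that("move enumeration matches the known neighborhoods", {
  st <- t3_states()
  for (s in st) {
    mv <- enumerate_moves(s)
    expect_length(mv, 1L)
    expect_identical(mv[[1]]$kind, "C6")
  }
  b2 <- fixture_b2()
  for (s in exact_enumerate(b2)) {
    mv <- enumerate_moves(s)
    expect_length(mv, 1L)
    expect_identical(mv[[1]]$kind, "C4")
  }
  for (s in exact_enumerate(fixture_r33())) {
    mv <- enumerate_moves(s)
    expect_gte(length(mv), 1L)
    expect_true(all(vapply(mv, function(m) m$kind, "") == "C4"))
  }
})

test_that("the move graph is symmetric", {
  set.seed(9)
  for (k in 1:5) {
    fx <- rand_fixture(nu = 3, nw = sample(3:4, 1), degree = sample(1:2, 1))
    states <- tryCatch(exact_enumerate(fx$problem, limit = 120),
                       STATE_SPACE_TOO_LARGE = function(e) NULL)
    if (is.null(states) || length(states) < 2) next
    adj <- move_graph(states)
    for (i in seq_along(adj)) for (j in adj[[i]])
      expect_true(i %in% adj[[j]])
  }
})

test_that("no compatible circular swap longer than C6 exists under 1F1S", {
  # exhaustive search for alternating chord-cycles of length 8 whose four
  # PV-pairs at distance 3 are all forbidden, on random small instances
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(rest) c(v[i], rest))))
  }
  p4 <- perms(1:4)
  p4_fix1 <- Filter(function(x) x[1] == 1L, p4)
  set.seed(13)
  for (k in 1:8) {
    fx <- rand_fixture(nu = sample(4:5, 1), nw = sample(4:5, 1))
    p <- fx$problem
    r <- fx$witness
    fbk <- edge_key(p$forbidden)
    found <- FALSE
    for (us in utils::combn(p$u, 4, simplify = FALSE))
      for (ws in utils::combn(p$w, 4, simplify = FALSE))
        for (pw in p4_fix1)
          for (pu in p4) {
            v <- as.vector(rbind(us[pu], ws[pw]))
            circ <- tryCatch(chord_circuit(p, v), REJECT_SCHEMA = function(e) NULL)
            if (is.null(circ)) next
            if (!is_elementary(circ)) next
            if (!is_alternating(r, circ)) next
            if (all(edge_key(pv_pairs(circ)) %in% fbk)) found <- TRUE
          }
    expect_false(found)
  }
})
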