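test_that("the symmetric difference is balanced and correctly colored", {
  st <- t3_states()
  cd <- symmetric_difference(st[[1]], st[[2]])
  expect_identical(nrow(cd$x_edges), 3L)
  expect_identical(nrow(cd$y_edges), 3L)
  # X = Y -> empty
  cd0 <- symmetric_difference(st[[1]], st[[1]])
  expect_identical(nrow(cd0$x_edges) + nrow(cd0$y_edges), 0L)
  # B2: 4 chords
  sb <- exact_enumerate(fixture_b2())
  cdb <- symmetric_difference(sb[[1]], sb[[2]])
  expect_identical(nrow(cdb$x_edges) + nrow(cdb$y_edges), 4L)
  # per-vertex balance on random pairs
  set.seed(55)
  for (k in 1:10) {
    fx <- rand_fixture()
    states <- tryCatch(exact_enumerate(fx$problem, limit = 150),
                       STATE_SPACE_TOO_LARGE = function(e) NULL)
    if (is.null(states) || length(states) < 2) next
    i <- sample(length(states), 2)
    cd <- symmetric_difference(states[[i[1]]], states[[i[2]]])
    verts <- unique(c(cd$x_edges, cd$y_edges))
    for (v in verts)
      expect_identical(sum(cd$x_edges == v), sum(cd$y_edges == v))
  }
  p2 <- fixture_b2()
  expect_error(symmetric_difference(st[[1]], exact_enumerate(p2)[[1]]),
               class = "PROBLEM_MISMATCH")
})

test_that("decomposition yields elementary alternating circuits partitioning the difference", {
  st <- t3_states()
  cc <- decompose_to_elementary_circuits(st[[1]], st[[2]])
  expect_length(cc, 1L)
  expect_length(cc[[1]], 6L)

  sb <- exact_enumerate(fixture_b2())
  ccb <- decompose_to_elementary_circuits(sb[[1]], sb[[2]])
  expect_length(ccb, 1L)
  expect_length(ccb[[1]], 4L)

  expect_length(decompose_to_elementary_circuits(st[[1]], st[[1]]), 0L)

  # constructed 4x4 pair whose difference is two disjoint 4-cycles
  p4 <- validate_problem(paste0("u", 1:4), paste0("w", 1:4), rep(1, 4), rep(1, 4))
  X <- new_realization(p4, cbind(paste0("u", 1:4), paste0("w", 1:4)))
  Y <- new_realization(p4, cbind(paste0("u", 1:4), paste0("w", c(2, 1, 4, 3))))
  cc2 <- decompose_to_elementary_circuits(X, Y)
  expect_identical(sort(lengths(cc2)), c(4L, 4L))

  # circuits are elementary, alternate in X, and partition the difference
  set.seed(66)
  for (k in 1:10) {
    fx <- rand_fixture()
    states <- tryCatch(exact_enumerate(fx$problem, limit = 150),
                       STATE_SPACE_TOO_LARGE = function(e) NULL)
    if (is.null(states) || length(states) < 2) next
    i <- sample(length(states), 2)
    X <- states[[i[1]]]; Y <- states[[i[2]]]
    cc <- decompose_to_elementary_circuits(X, Y)
    all_chords <- unlist(lapply(cc, function(circ)
      edge_key(redese:::circuit_chords(as.character(circ),
                                       as.character(circ) %in% fx$problem$u))))
    cd <- symmetric_difference(X, Y)
    expect_setequal(all_chords, c(edge_key(cd$x_edges), edge_key(cd$y_edges)))
    expect_identical(anyDuplicated(all_chords), 0L)
    for (circ in cc) {
      expect_true(is_elementary(circ))
      expect_true(is_alternating(X, circ))
    }
  }
})

test_that("processing a circuit emits compatible swaps of total weight len/2 - 1", {
  st <- t3_states()
  cc <- decompose_to_elementary_circuits(st[[1]], st[[2]])
  res <- process_circuit(st[[1]], cc[[1]])
  expect_length(res$moves, 1L)
  expect_identical(res$moves[[1]]$kind, "C6")
  expect_identical(path_weight(res$moves), 2L)
  expect_identical(state_key(res$realization), state_key(st[[2]]))

  # any length-4 circuit: one C4, weight 1
  sb <- exact_enumerate(fixture_b2())
  ccb <- decompose_to_elementary_circuits(sb[[1]], sb[[2]])
  resb <- process_circuit(sb[[1]], ccb[[1]])
  expect_identical(path_weight(resb$moves), 1L)

  # a length-8 alternating cycle with a chordal PV-pair: weight 3 in >= 2 moves
  p4 <- validate_problem(paste0("u", 1:4), paste0("w", 1:4), rep(1, 4), rep(1, 4))
  X <- new_realization(p4, cbind(paste0("u", 1:4), paste0("w", 1:4)))
  circ <- chord_circuit(p4, as.vector(rbind(paste0("u", 1:4), paste0("w", c(1, 2, 3, 4)))))
  res8 <- process_circuit(X, circ)
  expect_identical(path_weight(res8$moves), 3L)
  expect_gte(length(res8$moves), 2L)
  # the final state differs from X exactly on the circuit's chords
  expect_identical(sum(biadjacency(res8$realization) != biadjacency(X)), 8L)

  r33 <- fixture_r33()
  rr <- new_realization(r33, rbind(c("u1", "w1"), c("u1", "w2"), c("u2", "w2"),
                                   c("u2", "w3"), c("u3", "w3"), c("u3", "w1")))
  expect_error(process_circuit(rr, chord_circuit(r33, c("u1", "w2", "u2", "w3"))),
               class = "NOT_ALTERNATING")
})

test_that("swap paths replay exactly with the decomposition weight identity", {
  st <- t3_states()
  sp <- swap_path(st[[1]], st[[2]])
  expect_length(sp, 1L)
  expect_identical(path_weight(sp), 2L)
  expect_length(swap_path(st[[1]], st[[1]]), 0L)
  sb <- exact_enumerate(fixture_b2())
  expect_identical(path_weight(swap_path(sb[[1]], sb[[2]])), 1L)

  set.seed(88)
  done <- 0L
  for (k in 1:60) {
    if (done >= 25L) break
    fx <- rand_fixture()
    states <- tryCatch(exact_enumerate(fx$problem, limit = 150),
                       STATE_SPACE_TOO_LARGE = function(e) NULL)
    if (is.null(states) || length(states) < 2) next
    i <- sample(length(states), 2)
    X <- states[[i[1]]]; Y <- states[[i[2]]]
    moves <- swap_path(X, Y)
    cur <- X
    for (mv in moves) cur <- apply_move(cur, mv)   # every intermediate validated
    expect_identical(state_key(cur), state_key(Y))
    cc <- decompose_to_elementary_circuits(X, Y)
    expect_identical(path_weight(moves), as.integer(sum(lengths(cc) / 2 - 1)))
    done <- done + 1L
  }
  expect_gte(done, 10L)
})
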