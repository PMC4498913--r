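test_that("validate_problem accepts the canonical instances and infers the star", {
  t3 <- fixture_t3()
  expect_true(is.na(t3$star_center))      # perfect matching, empty star
  expect_true(t3$half_regular)
  expect_true(t3$degree_sum_ok)

  b2 <- fixture_b2()
  expect_true(is.na(b2$star_center))
  expect_identical(nrow(b2$forbidden), 0L)

  s3 <- fixture_s3()
  expect_identical(s3$star_center, "s")   # forced: s carries two incidences
  expect_true(s3$half_regular)            # (2, 2) outside the center
})

test_that("validation is idempotent and stable under an explicit center", {
  s3 <- fixture_s3()
  again <- validate_problem(s3$u, s3$w, s3$du, s3$dw, s3$forbidden,
                            star_center = s3$star_center)
  expect_identical(again$star_center, s3$star_center)
  expect_identical(again$du, s3$du)
})

test_that("non-1F1S forbidden sets are rejected", {
  # complete 2x2 forbidden block: every candidate center leaves two pairs
  # sharing an endpoint, so no decomposition exists
  expect_error(
    validate_problem(c("u1", "u2"), c("w1", "w2"), c(1, 1), c(1, 1),
                     rbind(c("u1", "w1"), c("u1", "w2"),
                           c("u2", "w1"), c("u2", "w2"))),
    class = "REJECT_NOT_1F1S")
  # two U vertices with >= 2 incidences: two stars would be needed
  expect_error(
    validate_problem(paste0("u", 1:2), paste0("w", 1:4), c(1, 1), rep(1, 4),
                     rbind(c("u1", "w1"), c("u1", "w2"),
                           c("u2", "w3"), c("u2", "w4"))),
    class = "REJECT_NOT_1F1S")
  # a W vertex with three incidences cannot be absorbed by a U-centered star
  expect_error(
    validate_problem(paste0("u", 1:3), "w1", c(1, 1, 1), 3,
                     rbind(c("u1", "w1"), c("u2", "w1"), c("u3", "w1"))),
    class = "REJECT_NOT_1F1S")
})

test_that("a doubly covered W vertex forces a size-one star", {
  p <- validate_problem(paste0("u", 1:3), paste0("w", 1:3),
                        c(1, 1, 1), c(1, 1, 1),
                        rbind(c("u1", "w1"), c("u2", "w1")))
  expect_identical(p$star_center, "u1")   # first forced candidate in input order
})

test_that("schema violations and degree-sum mismatches are classified", {
  expect_error(validate_problem(c("u1", "u1"), "w1", c(1, 1), 2),
               class = "REJECT_SCHEMA")
  expect_error(validate_problem("u1", "w1", -1, 1), class = "REJECT_SCHEMA")
  expect_error(validate_problem("u1", "w1", 1, 1, rbind(c("u9", "w1"))),
               class = "REJECT_SCHEMA")
  expect_error(validate_problem("u1", "w1", 1, 1,
                                rbind(c("u1", "w1"), c("u1", "w1"))),
               class = "REJECT_SCHEMA")
  # mismatched sums are recorded, not fatal
  pm <- validate_problem(c("u1", "u2"), "w1", c(1, 1), 1)
  expect_false(pm$degree_sum_ok)
})

test_that("realization invariants are enforced", {
  t3 <- fixture_t3()
  good <- new_realization(t3, rbind(c("u1", "w2"), c("u2", "w3"), c("u3", "w1")))
  expect_s3_class(good, "redese_realization")
  expect_error(new_realization(t3, rbind(c("u1", "w1"), c("u2", "w3"), c("u3", "w2"))),
               class = "INVALID_REALIZATION")   # forbidden pair
  expect_error(new_realization(t3, rbind(c("u1", "w2"), c("u1", "w3"), c("u3", "w1"))),
               class = "INVALID_REALIZATION")   # degree violation
})

test_that("pv_pairs: none on C4, opposite pairs on C6, distance-3 pairs on C8", {
  t3 <- fixture_t3()
  b2 <- fixture_b2()
  expect_identical(nrow(pv_pairs(chord_circuit(b2, c("u1", "w1", "u2", "w2")))), 0L)

  c6 <- chord_circuit(fixture_r33(), c("u1", "w1", "u2", "w2", "u3", "w3"))
  got <- pv_pairs(c6)
  expect_identical(got, rbind(c("u1", "w2"), c("u2", "w3"), c("u3", "w1")))

  # oracle: brute force over all index pairs of a generic length-8 circuit
  p4 <- validate_problem(paste0("u", 1:4), paste0("w", 1:4), rep(1, 4), rep(1, 4))
  v8 <- as.vector(rbind(paste0("u", 1:4), paste0("w", 1:4)))
  oracle <- do.call(rbind, Filter(Negate(is.null), unlist(lapply(1:8, function(p_) lapply(1:8, function(q) {
    if (q <= p_) return(NULL)
    d <- min(q - p_, 8 - (q - p_))
    if (d %% 2 == 1 && d > 1) sort(c(v8[p_], v8[q]))
  })), recursive = FALSE)))
  oracle <- unique(oracle)
  got8 <- pv_pairs(chord_circuit(p4, v8))
  expect_identical(nrow(got8), 8L)
  expect_setequal(paste(got8[, 1], got8[, 2]), paste(oracle[, 1], oracle[, 2]))
})

test_that("is_alternating detects both phases and rejects broken alternation", {
  t3 <- fixture_t3()
  r <- new_realization(t3, rbind(c("u1", "w2"), c("u2", "w3"), c("u3", "w1")))
  expect_true(is_alternating(r, chord_circuit(t3, c("u1", "w3", "u2", "w1", "u3", "w2"))))
  b2 <- fixture_b2()
  rb <- new_realization(b2, rbind(c("u1", "w1"), c("u2", "w2")))
  expect_true(is_alternating(rb, chord_circuit(b2, c("u1", "w1", "u2", "w2"))))
  # two consecutive realization edges: alternation violated
  r33 <- fixture_r33()
  rr <- new_realization(r33, rbind(c("u1", "w1"), c("u1", "w2"), c("u2", "w2"),
                                   c("u2", "w3"), c("u3", "w3"), c("u3", "w1")))
  expect_false(is_alternating(rr, chord_circuit(r33, c("u1", "w2", "u2", "w3"))))
})

test_that("1F1S incidence structure holds on random fixtures", {
  set.seed(101)
  for (k in 1:25) {
    p <- rand_fixture()$problem
    s <- p$star_center
    fb <- p$forbidden
    for (u in setdiff(p$u, s))
      expect_lte(sum(fb[, 1] == u), 1L)
    for (w in p$w) {
      expect_lte(sum(fb[, 2] == w), 2L)
      if (!is.na(s)) expect_lte(sum(fb[, 2] == w & fb[, 1] != s), 1L)
    }
  }
})
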