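test_that("local transition matrices count consecutive id pairs", {
  # constant id sequence over tau = 5 snapshots: all raw mass on one cell
  const <- data.frame(from = rep(3, 4), to = rep(3, 4))
  tm <- local_transition_matrix(const, k = 3)
  expect_equal(tm$counts[4, 4], 4)
  expect_equal(sum(tm$counts), 4)
  expect_equal(tm$n_transitions, 4L)

  # k = 2 id sequence 0,1,1,0
  seq2 <- data.frame(from = c(0, 1, 1), to = c(1, 1, 0))
  tm2 <- local_transition_matrix(seq2, k = 2)
  expect_equal(tm2$counts, rbind(c(0, 1), c(1, 1)))

  # pseudo-count adds 1/|A_3| = 1/8 to every cell
  tm3 <- local_transition_matrix(seq2[0, ], k = 3, pseudocount = TRUE)
  expect_true(all(tm3$counts == 1 / 8))

  expect_error(local_transition_matrix(data.frame(from = 9, to = 0), k = 2),
               "out of range")
})

test_that("raw count total of a local matrix equals tau - 1", {
  set.seed(8)
  g <- generate_random_dynamic_graph(9, 10, 4, 50, seed = 8)
  tl <- transition_list(g, c(2, 5, 8))
  for (pc in c(FALSE, TRUE)) {
    tm <- local_transition_matrix(tl, k = 3, pseudocount = pc)
    expect_equal(sum(tm$counts - tm$pseudocount), g$tau - 1)
  }
})

test_that("assemble_tensor collects all anchored tuples with row totals", {
  g <- snapshots_to_batches(
    list(rbind(c(1, 2)), rbind(c(1, 2), c(3, 4)), rbind(c(3, 4))),
    n_vertices = 4)
  tuples <- enumerate_tuples(4, 3, anchor = 1)
  expect_equal(nrow(tuples), count_tuples(4, 3, anchored = TRUE))  # 18
  mats <- lapply(seq_len(nrow(tuples)), function(i) {
    local_transition_matrix(transition_list(g, tuples[i, ]), k = 3,
                            tuple = tuples[i, ])
  })
  tensor <- assemble_tensor(1, mats)
  expect_length(tensor$slices, 18L)
  expect_equal(dim(tensor$S), c(8L, 18L))
  # per-slice totals are the raw transitions leaving each state
  expect_equal(colSums(tensor$S), rep(g$tau - 1, 18))

  # a slice whose tuple lacks the vertex is refused
  bad <- local_transition_matrix(data.frame(from = 0, to = 0), k = 3,
                                 tuple = c(2, 3, 4))
  expect_error(assemble_tensor(1, list(bad)), "must contain the vertex")
})

test_that("global matrix pools counts like the explicit weighted sum", {
  mk <- function(counts, tuple) {
    structure(list(counts = counts, n_states = 2L, k = 2L, tuple = tuple,
                   pseudocount = 0, n_transitions = sum(counts)),
              class = "transition_matrix")
  }
  c1 <- rbind(c(6, 2), c(1, 1))   # row totals 8, 2
  c2 <- rbind(c(1, 1), c(4, 4))   # row totals 2, 8
  gm <- global_matrix(assemble_tensor(1, list(mk(c1, c(1, 2)), mk(c2, c(1, 3)))))
  # oracle: per-state weights = slice row total / summed row total
  expected <- matrix(0, 2, 2)
  for (i in 1:2) {
    w1 <- sum(c1[i, ]) / (sum(c1[i, ]) + sum(c2[i, ]))
    expected[i, ] <- w1 * c1[i, ] / sum(c1[i, ]) +
      (1 - w1) * c2[i, ] / sum(c2[i, ])
  }
  expect_equal(gm$matrix, expected)

  # one slice: the row-normalized slice itself
  g1 <- global_matrix(assemble_tensor(1, list(mk(c1, c(1, 2)))))
  expect_equal(g1$matrix, c1 / rowSums(c1))

  # identical slices: same as either alone (weighting idempotence)
  g2 <- global_matrix(assemble_tensor(1, list(mk(c1, c(1, 2)), mk(c1, c(1, 3)))))
  expect_equal(g2$matrix, g1$matrix)

  # a state with no observed transitions gets a uniform row
  c3 <- rbind(c(0, 0), c(3, 1))
  g3 <- global_matrix(assemble_tensor(1, list(mk(c3, c(1, 2)))))
  expect_equal(g3$matrix[1, ], c(0.5, 0.5))
})

test_that("stationary distributions solve pi T = pi", {
  expect_equal(stationary_distribution(rbind(c(0.5, 0.5), c(0.5, 0.5))),
               c(0.5, 0.5))
  expect_equal(stationary_distribution(rbind(c(0.9, 0.1), c(0.5, 0.5))),
               c(5 / 6, 1 / 6), tolerance = 1e-12)

  # property: matches an independent linear solve on random chains
  set.seed(14)
  for (i in 1:10) {
    n <- sample(2:12, 1)
    P <- matrix(stats::rexp(n * n), n)
    P <- P / rowSums(P)
    expect_equal(stationary_distribution(P), stationary_by_solve(P),
                 tolerance = 1e-8)
  }
  expect_error(stationary_distribution(rbind(c(0.7, 0.7), c(0.5, 0.5))),
               "not row-stochastic")
})

test_that("degenerate chains warn but return deterministically", {
  expect_warning(p1 <- stationary_distribution(diag(2)), "not unique")
  expect_warning(p2 <- stationary_distribution(diag(2)), "not unique")
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1)
})

test_that("large state spaces use the iterative path correctly", {
  set.seed(77)
  n <- 128
  P <- matrix(stats::rexp(n * n)^3, n)
  P <- P / rowSums(P)
  pi <- stationary_distribution(P)
  expect_lt(max(abs(as.vector(pi %*% P) - pi)), 1e-8)
  expect_equal(pi, stationary_by_solve(P), tolerance = 1e-8)
})

test_that("entropies follow the Shannon formula in bits", {
  expect_equal(entropy_bits(rep(1 / 8, 8)), 3)
  expect_equal(entropy_bits(c(1, rep(0, 7))), 0)
  expect_equal(entropy_bits(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(delta_entropy(3, 1.5), 1.5)
  expect_error(entropy_bits(c(0.9, 0.2)), "probability vector")
  expect_error(entropy_bits(c(1.2, -0.2)), "probability vector")
})

test_that("a known chain is recovered from a sampled id sequence", {
  P <- rbind(c(0.80, 0.15, 0.05, 0.00),
             c(0.10, 0.70, 0.10, 0.10),
             c(0.05, 0.05, 0.80, 0.10),
             c(0.10, 0.20, 0.10, 0.60))
  set.seed(2024)
  trans <- sample_chain(P, 1e4)
  tm <- local_transition_matrix(trans, n_states = 4)
  est <- tm$counts / rowSums(tm$counts)
  expect_lt(max(abs(est - P)), 0.05)
  expect_lt(max(abs(stationary_distribution(est) - stationary_by_solve(P))),
            0.02)
})

test_that("pseudo-count influence on pi vanishes with run length", {
  P <- rbind(c(0.9, 0.1), c(0.3, 0.7))
  set.seed(31)
  gap <- vapply(c(1e2, 1e4), function(len) {
    trans <- sample_chain(P, len)
    pi_on <- stationary_distribution(
      local_transition_matrix(trans, n_states = 2, pseudocount = TRUE)$counts /
        rowSums(local_transition_matrix(trans, n_states = 2,
                                        pseudocount = TRUE)$counts))
    pi_off <- stationary_distribution(
      local_transition_matrix(trans, n_states = 2)$counts /
        rowSums(local_transition_matrix(trans, n_states = 2)$counts))
    max(abs(pi_on - pi_off))
  }, numeric(1))
  expect_lt(gap[2], gap[1])
  expect_lt(gap[2], 1e-3)
})
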