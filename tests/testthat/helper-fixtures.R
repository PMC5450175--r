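# Shared fixture builders: all generated in code, no data files.

# list of tau random snapshots on n vertices (each edge present w.p. p)
random_snapshots <- function(n, tau, p = 0.3) {
  pairs <- t(combn(n, 2))
  lapply(seq_len(tau), function(t) {
    pairs[runif(nrow(pairs)) < p, , drop = FALSE]
  })
}

# sample an id sequence of length len from a transition matrix P over
# 0-based states, starting from its first state
sample_chain <- function(P, len, start = 0L) {
  n <- nrow(P)
  ids <- integer(len)
  ids[1L] <- start
  for (t in 2:len) {
    ids[t] <- sample.int(n, 1L, prob = P[ids[t - 1L] + 1L, ]) - 1L
  }
  data.frame(from = ids[-len], to = ids[-1L])
}

# analytic stationary distribution by linear solve (independent of the
# eigen/power-iteration implementation under test)
stationary_by_solve <- function(P) {
  n <- nrow(P)
  A <- rbind(t(P) - diag(n), rep(1, n))
  as.vector(qr.solve(A, c(rep(0, n), 1)))
}

# naive per-tuple replay through the module-level operations: the oracle the
# one-pass pipeline must reproduce bit for bit
naive_global_model <- function(g, k, a, pseudocount = TRUE, tuples = NULL) {
  if (is.null(tuples)) tuples <- enumerate_tuples(g$n_vertices, k, anchor = a)
  mats <- lapply(seq_len(nrow(tuples)), function(i) {
    local_transition_matrix(transition_list(g, tuples[i, ]), k = k,
                            pseudocount = pseudocount, tuple = tuples[i, ])
  })
  global_matrix(assemble_tensor(a, mats))
}

# multi-model PDB text for given coordinates: coords is a list of n x 3
# matrices (one per model); each residue gets a P atom and (unless listed in
# `drop_c3`, as model:residue pairs) a C3' atom
pdb_lines <- function(coords, drop_c3 = NULL, resname = "  G") {
  lines <- character(0)
  for (m in seq_along(coords)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    serial <- 0L
    x <- coords[[m]]
    for (i in seq_len(nrow(x))) {
      for (nm in c("P", "C3'")) {
        if (nm == "C3'" && !is.null(drop_c3) &&
            any(drop_c3[, 1] == m & drop_c3[, 2] == i)) next
        serial <- serial + 1L
        lines <- c(lines, sprintf(
          "ATOM  %5d %-4s%4s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, nm, resname, i, x[i, 1], x[i, 2], x[i, 3]))
      }
    }
    lines <- c(lines, "ENDMDL")
  }
  c(lines, "END")
}

expect_valid_model <- function(m) {
  expect_true(all(abs(rowSums(m$matrix) - 1) < 1e-9))
  expect_true(all(m$pi >= 0))
  expect_equal(sum(m$pi), 1, tolerance = 1e-9)
  expect_lt(max(abs(as.vector(m$pi %*% m$matrix) - m$pi)), 1e-8)
  expect_gte(m$entropy, 0)
  expect_lte(m$entropy, log2(m$n_states) + 1e-9)
}
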