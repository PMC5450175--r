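# Local transition matrices, per-vertex transition tensors, the pooled
# global row-stochastic matrix, stationary distributions and entropies.

#' Local transition count matrix of one vertex tuple
#'
#' Counts the multiplicity of every consecutive adjacency-id pair `(i, j)` in
#' a transition list, including self-transitions on the diagonal. Because a
#' finite run need not visit every state, a minimal pseudo-count
#' \eqn{P_k = 1/|A_k|} can be added to every cell, which makes the chain
#' irreducible and the stationary distribution unique.
#'
#' @param transitions a data frame with columns `from` and `to` (0-based
#'   adjacency ids), e.g. from [transition_list()], or a list/two-column
#'   matrix coercible to one.
#' @param k tuple size; sets the dimension to `adjacency_state_count(k)`.
#'   May be omitted when `n_states` is given directly (e.g. for chains that
#'   are not adjacency-derived).
#' @param n_states state-space dimension; default `adjacency_state_count(k)`.
#' @param pseudocount logical; add \eqn{1/n_{states}} to every cell.
#' @param tuple optional ordered vertex tuple the matrix describes (carried
#'   along for [assemble_tensor()]).
#' @return object of class `transition_matrix`: list with `counts`
#'   (`n_states` x `n_states`, pseudo-counts included when requested),
#'   `n_states`, `k`, `tuple`, `pseudocount` (the per-cell value added, 0 when
#'   off) and `n_transitions` (raw transition total, `tau - 1`).
#' @export
local_transition_matrix <- function(transitions, k = NULL, n_states = NULL,
                                    pseudocount = FALSE, tuple = NULL) {
  if (is.matrix(transitions)) {
    transitions <- data.frame(from = transitions[, 1L], to = transitions[, 2L])
  }
  if (is.null(n_states)) {
    if (is.null(k)) stop("give either k or n_states", call. = FALSE)
    n_states <- adjacency_state_count(k)
  }
  if (is.null(tuple)) tuple <- attr(transitions, "tuple")
  if (is.null(k)) k <- attr(transitions, "k")
  from <- transitions$from
  to <- transitions$to
  if (length(from) != length(to)) stop("from/to length mismatch", call. = FALSE)
  if (length(from) && (min(from, to) < 0 || max(from, to) >= n_states)) {
    stop("adjacency id out of range for the state space", call. = FALSE)
  }
  counts <- matrix(0, n_states, n_states)
  if (length(from)) {
    tab <- rowsum(rep(1, length(from)), from * n_states + to)
    key <- as.numeric(rownames(tab))
    counts[cbind(key %/% n_states + 1, key %% n_states + 1)] <- tab[, 1L]
  }
  pc <- if (isTRUE(pseudocount)) 1 / n_states else 0
  structure(
    list(counts = counts + pc, n_states = n_states, k = k, tuple = tuple,
         pseudocount = pc, n_transitions = length(from)),
    class = "transition_matrix"
  )
}

raw_counts <- function(tm) tm$counts - tm$pseudocount

#' Assemble the transition tensor of a vertex
#'
#' Collects all local transition matrices whose tuple contains the vertex
#' `a` into a tensor (a list of slices in deterministic lexicographic tuple
#' order) together with the per-slice, per-state totals `S`: the number of
#' raw transitions leaving each state in each slice (row sums of the raw
#' counts, pseudo-counts excluded).
#'
#' @param a vertex index.
#' @param matrices list of [local_transition_matrix()] results, each carrying
#'   its `tuple`; every tuple must contain `a` and all must share `k`.
#' @return object of class `transition_tensor`: list with `vertex`, `slices`
#'   (ordered list of `transition_matrix`), and `S` (`n_states` x n_slices
#'   matrix of per-state raw row totals).
#' @export
assemble_tensor <- function(a, matrices) {
  if (length(matrices) == 0L) stop("empty tensor", call. = FALSE)
  ks <- vapply(matrices, function(m) as.integer(m$k), integer(1))
  if (length(unique(ks)) != 1L) {
    stop("all slices must share the same k", call. = FALSE)
  }
  for (m in matrices) {
    if (is.null(m$tuple) || !(a %in% m$tuple)) {
      stop("every slice's tuple must contain the vertex", call. = FALSE)
    }
  }
  ord <- order(vapply(matrices, function(m) {
    paste(formatC(m$tuple, width = 9, flag = "0"), collapse = ",")
  }, character(1)))
  slices <- matrices[ord]
  S <- vapply(slices, function(m) rowSums(raw_counts(m)),
              numeric(slices[[1L]]$n_states))
  S <- matrix(S, nrow = slices[[1L]]$n_states)
  structure(list(vertex = a, slices = slices, S = S),
            class = "transition_tensor")
}

#' Combine a transition tensor into a global model
#'
#' Pools the counts of all slices — row i of the global matrix is
#' proportional to the summed counts of row i across slices — and
#' row-normalizes to a stochastic matrix. This is identical to weighting each
#' slice's row-conditional transition probabilities by that slice's share of
#' all transitions leaving the state, so slices that visit a state often
#' dominate its global row. Rows with zero total count (possible only with
#' pseudo-counts off) are set to the uniform distribution to keep the matrix
#' stochastic.
#'
#' @param tensor a [assemble_tensor()] result.
#' @return object of class `global_model`: list with `vertex`, `matrix`
#'   (row-stochastic), `pi` (stationary distribution), `entropy` (bits),
#'   `n_states`, `k` and `n_slices`.
#' @export
global_matrix <- function(tensor) {
  stopifnot(inherits(tensor, "transition_tensor"))
  ns <- tensor$slices[[1L]]$n_states
  pooled <- Reduce(`+`, lapply(tensor$slices, `[[`, "counts"))
  finish_global_model(tensor$vertex, pooled, ns,
                      k = tensor$slices[[1L]]$k,
                      n_slices = length(tensor$slices))
}

# pooled counts -> row-stochastic matrix + stationary distribution + entropy
finish_global_model <- function(vertex, pooled, n_states, k = NULL,
                                n_slices = NA_integer_, keep_matrix = TRUE) {
  rs <- rowSums(pooled)
  zero <- rs == 0
  Tg <- pooled / ifelse(rs == 0, 1, rs)
  if (any(zero)) Tg[zero, ] <- 1 / n_states
  pi <- stationary_distribution(Tg)
  structure(
    list(vertex = vertex, matrix = if (keep_matrix) Tg else NULL,
         pi = pi, entropy = entropy_bits(pi),
         n_states = n_states, k = k, n_slices = n_slices),
    class = "global_model"
  )
}

#' @export
print.global_model <- function(x, ...) {
  cat(sprintf(
    "global model: vertex %s, %d states (k = %s), %s slices, H = %.4f bits\n",
    format(x$vertex), x$n_states, format(x$k), format(x$n_slices), x$entropy))
  invisible(x)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Solves \eqn{\pi T = \pi} with \eqn{\pi \ge 0}, \eqn{\sum_i \pi_i = 1}.
#' For state spaces up to 64 the dominant left eigenvector is taken from a
#' dense eigendecomposition; larger matrices use power iteration on the lazy
#' chain \eqn{(I + T)/2} (same fixed point, aperiodic) with tolerance 1e-12
#' and at most 1e5 iterations. Components below 1e-12 are clipped to zero and
#' the vector renormalized. A reducible chain (non-unique dominant
#' eigenvector) triggers a warning and a deterministic tie-break: the first
#' eigenvector in the eigenvalue sort order.
#'
#' @param mat square row-stochastic matrix.
#' @return stationary probability vector.
#' @export
stationary_distribution <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (ncol(mat) != n) stop("matrix must be square", call. = FALSE)
  if (any(mat < 0) || any(abs(rowSums(mat) - 1) > 1e-6)) {
    stop("matrix is not row-stochastic", call. = FALSE)
  }
  if (n <= 64L) {
    eg <- eigen(t(mat))
    mods <- Mod(eg$values)
    i1 <- which.max(mods)
    if (sum(mods > 1 - 1e-9) > 1L) {
      warning("dominant eigenvector is not unique (reducible or periodic chain); ",
              "returning a deterministic representative")
    }
    v <- eg$vectors[, i1]
    v <- Re(v)
    if (sum(v) < 0) v <- -v
  } else {
    v <- rep(1 / n, n)
    for (it in seq_len(1e5)) {
      nxt <- 0.5 * (v + as.vector(v %*% mat))
      if (max(abs(nxt - v)) < 1e-12) {
        v <- nxt
        break
      }
      v <- nxt
    }
  }
  v[v < 1e-12] <- 0
  s <- sum(v)
  if (s <= 0) stop("failed to extract a non-negative stationary vector",
                   call. = FALSE)
  v / s
}

#' Conformational entropy of a stationary distribution
#'
#' Shannon entropy \eqn{H = -\sum_i \pi_i \log_2 \pi_i} in bits, with the
#' convention \eqn{0 \log 0 = 0}. For a k-tuple state space H lies in
#' `[0, log2(adjacency_state_count(k))]`.
#'
#' @param pi probability vector (non-negative, summing to 1).
#' @return entropy in bits.
#' @export
entropy_bits <- function(pi) {
  if (any(pi < -1e-12) || abs(sum(pi) - 1) > 1e-6) {
    stop("pi must be a probability vector", call. = FALSE)
  }
  p <- pi[pi > 0]
  -sum(p * log2(p))
}

#' Entropy difference between a reference and another run
#'
#' \eqn{\Delta H = H_{ref} - H_{other}} in bits; with the reference the free
#' (wild-type) molecule and the other the ligand-bound complex, a positive
#' value indicates a loss of conformational entropy upon binding.
#'
#' @param h_ref,h_other entropies in bits (scalars or equal-length vectors).
#' @return `h_ref - h_other`.
#' @export
delta_entropy <- function(h_ref, h_other) h_ref - h_other
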