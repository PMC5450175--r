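# Orchestration: ordered-tuple enumeration (with closed-form counts and
# contact filtering), the one-pass streamed computation of per-vertex global
# models, and run comparison (delta-H, delta-RMSF).
#
# The one pass never replays the graph per tuple. It tracks one adjacency id
# per *sorted* vertex combination; an edge event only touches combinations
# containing both endpoints (looked up through a per-pair index). Run-length
# encoding turns the id timelines into sparse (from, to, count) events, which
# are pooled into per-vertex count matrices in the combination's canonical
# vertex order and then summed over all k! position permutations — the
# permuted bit layouts of the ordered tuples — to obtain exactly the pooled
# counts of the full ordered enumeration.

#' Count ordered k-tuples of distinct vertices
#'
#' Closed forms: without an anchor there are \eqn{|V|!/(|V|-k)!} ordered
#' k-tuples (equivalently \eqn{C(|V|,k) \cdot k!}); the ordered tuples
#' containing one fixed vertex number \eqn{k \cdot (|V|-1)!/(|V|-k)!}.
#'
#' @param n_vertices vertex count.
#' @param k tuple size.
#' @param anchored count only tuples containing one fixed vertex.
#' @return the count as a double.
#' @export
count_tuples <- function(n_vertices, k, anchored = FALSE) {
  n <- as.numeric(n_vertices)
  k <- as.integer(k)
  if (k < 2L || k > n) stop("need 2 <= k <= n_vertices", call. = FALSE)
  if (anchored) k * prod(seq(n - 1, n - k + 1)) else prod(seq(n, n - k + 1))
}

#' Enumerate ordered k-tuples of distinct vertices
#'
#' Materializes all ordered k-tuples (rows, lexicographic order), optionally
#' restricted to those containing an anchor vertex. Intended for small
#' instances (oracles, spot checks); the streamed pipeline never materializes
#' this set, so enumeration refuses to build more than `max_tuples` rows.
#'
#' @param n_vertices vertex count.
#' @param k tuple size.
#' @param anchor optional vertex index every tuple must contain.
#' @param max_tuples refusal threshold.
#' @return integer matrix with k columns, one ordered tuple per row.
#' @export
enumerate_tuples <- function(n_vertices, k, anchor = NULL, max_tuples = 1e6) {
  n <- as.integer(n_vertices)
  k <- as.integer(k)
  total <- count_tuples(n, k, anchored = !is.null(anchor))
  if (total > max_tuples) {
    stop(sprintf("refusing to materialize %.0f tuples (max_tuples = %.0f)",
                 total, max_tuples), call. = FALSE)
  }
  grow <- function(prefix) {
    if (length(prefix) == k) return(matrix(prefix, nrow = 1L))
    rest <- setdiff(seq_len(n), prefix)
    do.call(rbind, lapply(rest, function(v) grow(c(prefix, v))))
  }
  out <- grow(integer(0))
  if (!is.null(anchor)) {
    out <- out[apply(out == as.integer(anchor), 1L, any), , drop = FALSE]
  }
  out
}

#' Filter tuples by contact probability
#'
#' Keeps a tuple iff at least one vertex pair inside it has contact
#' probability above `min_prob` (default 0, i.e. the pair touches in at
#' least one frame). Tuples whose vertices are never in mutual contact stay
#' in a single adjacency state for the whole run and carry no transition
#' information.
#'
#' @param tuples matrix with one tuple per row (ordered or sorted).
#' @param P contact probability matrix ([contact_probability()]).
#' @param min_prob inclusion threshold; a pair counts when `P > min_prob`.
#' @return the surviving rows of `tuples`.
#' @export
contact_filter <- function(tuples, P, min_prob = 0) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) {
    stop("P must be a square matrix", call. = FALSE)
  }
  if (nrow(tuples) == 0L) return(tuples)
  if (max(tuples) > nrow(P)) {
    stop("tuple vertex outside the contact matrix", call. = FALSE)
  }
  keep <- combos_with_contact(t(tuples), P, min_prob)
  tuples[keep, , drop = FALSE]
}

# columns of `combos` (k x m) with at least one pair above the threshold
combos_with_contact <- function(combos, P, min_prob) {
  k <- nrow(combos)
  keep <- rep(FALSE, ncol(combos))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      keep <- keep | P[cbind(combos[i, ], combos[j, ])] > min_prob
    }
  }
  keep
}

# all permutations of 1..k as a k! x k matrix, lexicographic
permutations <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(first) {
    rest <- seq_len(k)[-first]
    cbind(first, matrix(rest[sub], nrow(sub)))
  }))
}

# state-permutation map for one position permutation sigma: entry [id+1] is
# the id of the same edge pattern when the tuple is reordered by sigma
state_permutation_map <- function(sigma) {
  k <- length(sigma)
  pp <- position_pairs(k)
  K <- nrow(pp)
  pidx <- matrix(0L, k, k)
  pidx[pp] <- seq_len(K)
  # bit b of the permuted id reads the canonical bit of the pair
  # (sigma(i), sigma(j)) for the permuted position pair (i, j)
  src <- vapply(seq_len(K), function(b) {
    a <- sigma[pp[b, 1L]]
    c <- sigma[pp[b, 2L]]
    pidx[min(a, c), max(a, c)]
  }, integer(1))
  S <- 2^K
  ids <- 0:(S - 1)
  bits <- vapply(seq_len(K), function(b) floor(ids / 2^(K - b)) %% 2,
                 numeric(S))
  as.vector(bits[, src, drop = FALSE] %*% 2^((K - 1L):0))
}

#' Full per-vertex global-model computation over a dynamic graph
#'
#' Runs the complete pipeline for tuple size `k`: every (optionally
#' contact-filtered) ordered k-tuple contributes its adjacency-transition
#' counts to the transition tensor of each of its k member vertices, and each
#' vertex's tensor is pooled into a global row-stochastic matrix with
#' stationary distribution and conformational entropy. All tuples are
#' processed in a single pass over the batch stream; the result is identical
#' to enumerating tuples and replaying the graph per tuple, but feasible at
#' the scale of a 65-vertex molecular graph.
#'
#' State spaces grow as \eqn{2^{k(k-1)/2}}, so the full computation is
#' limited to `k <= 5`; for `k = 5` (1024 states) stationary distributions
#' come from power iteration and the per-vertex stochastic matrices are not
#' retained.
#'
#' @param g a [dynamic_graph()].
#' @param k tuple size (2..5).
#' @param pseudocount add the minimal pseudo-count \eqn{1/|A_k|} to every
#'   cell of every local matrix (recommended: makes every chain irreducible).
#' @param contact_prob optional contact probability matrix (same cut-off as
#'   the graph); tuples with no pair above `min_contact_prob` are skipped.
#' @param min_contact_prob threshold used with `contact_prob`.
#' @param vertices vertices to build global models for (default all).
#' @param max_combinations refusal threshold on the number of sorted vertex
#'   combinations tracked (cost guard for large `n`/`k`).
#' @return object of class `msm_run`: list with `models` (per-vertex list of
#'   [global_matrix()]-style `global_model` objects, named by vertex label),
#'   `k`, `pseudocount`, `filtered`, `min_contact_prob`, `n_tuples` (ordered
#'   tuples represented), `n_combinations`, `tau` and `labels`.
#' @export
run_full_computation <- function(g, k, pseudocount = TRUE,
                                 contact_prob = NULL, min_contact_prob = 0,
                                 vertices = NULL, max_combinations = 2e6) {
  stopifnot(inherits(g, "dynamic_graph"))
  n <- g$n_vertices
  k <- as.integer(k)
  if (k < 2L || k > min(n, 10L)) {
    stop("need 2 <= k <= min(n_vertices, 10)", call. = FALSE)
  }
  if (k > 5L) {
    stop(sprintf(
      "full computation is limited to k <= 5: k = %d implies %d x %d state matrices (%.3g tuples)",
      k, adjacency_state_count(k), adjacency_state_count(k),
      count_tuples(n, k)), call. = FALSE)
  }
  m_full <- choose(n, k)
  if (m_full > max_combinations) {
    stop(sprintf(
      "refusing to track %.0f vertex combinations (max_combinations = %.0f); estimated memory %.1f GB",
      m_full, max_combinations, m_full * k * 8 / 1e9), call. = FALSE)
  }
  combos <- utils::combn(n, k)                      # k x m, columns sorted
  if (!is.null(contact_prob)) {
    if (!is.matrix(contact_prob) || nrow(contact_prob) != n) {
      stop("contact_prob must be an n x n matrix", call. = FALSE)
    }
    combos <- combos[, combos_with_contact(combos, contact_prob,
                                           min_contact_prob), drop = FALSE]
  }
  m <- ncol(combos)
  S <- adjacency_state_count(k)
  K <- k * (k - 1L) / 2L
  pp <- position_pairs(k)
  w_pp <- 2^((K - 1L):0)
  if (is.null(vertices)) vertices <- seq_len(n)
  vertices <- as.integer(vertices)

  events <- stream_combination_events(g, combos, pp, w_pp, m, n, K)

  # pool events into per-vertex canonical count tables -----------------------
  nev <- length(events$combo)
  if (nev) {
    vert <- as.vector(combos[, events$combo])        # k members per event
    rep_e <- rep(seq_len(nev), each = k)
    from <- events$from[rep_e]
    to <- events$to[rep_e]
    cnt <- events$count[rep_e]
    key <- (as.numeric(vert) - 1) * S * S + from * S + to
    agg <- rowsum(cnt, key)
    akey <- as.numeric(rownames(agg))
    a_vert <- as.integer(akey %/% (S * S) + 1)
    rem <- akey %% (S * S)
    a_from <- as.integer(rem %/% S)
    a_to <- as.integer(rem %% S)
    a_cnt <- agg[, 1L]
  } else {
    a_vert <- integer(0); a_from <- integer(0); a_to <- integer(0)
    a_cnt <- numeric(0)
  }

  perm_maps <- apply(permutations(k), 1L, state_permutation_map,
                     simplify = FALSE)
  slices_per_combo <- factorial(k)
  combos_of <- tabulate(as.vector(combos), nbins = n)
  pc <- if (isTRUE(pseudocount)) 1 / S else 0

  models <- vector("list", length(vertices))
  names(models) <- as.character(g$labels[vertices])
  keep_matrix <- S <= 64
  for (vi in seq_along(vertices)) {
    a <- vertices[vi]
    idx <- a_vert == a
    M <- matrix(0, S, S)
    if (any(idx)) {
      M[cbind(a_from[idx] + 1L, a_to[idx] + 1L)] <- a_cnt[idx]
    }
    pooled <- matrix(0, S, S)
    for (pm in perm_maps) {
      Mp <- matrix(0, S, S)
      Mp[pm + 1L, pm + 1L] <- M
      pooled <- pooled + Mp
    }
    n_slices <- slices_per_combo * combos_of[a]
    pooled <- pooled + n_slices * pc
    models[[vi]] <- finish_global_model(g$labels[a], pooled, S, k = k,
                                        n_slices = n_slices,
                                        keep_matrix = keep_matrix)
  }

  structure(
    list(models = models, k = k, pseudocount = isTRUE(pseudocount),
         filtered = !is.null(contact_prob),
         min_contact_prob = min_contact_prob,
         n_tuples = slices_per_combo * m, n_combinations = m,
         tau = g$tau, labels = g$labels, vertices = vertices),
    class = "msm_run"
  )
}

# one pass over the batch stream; returns run-length-encoded transition
# events per combination: parallel vectors combo, from, to, count
stream_combination_events <- function(g, combos, pp, w_pp, m, n, K) {
  empty <- list(combo = integer(0), from = numeric(0), to = numeric(0),
                count = numeric(0))
  if (m == 0L || g$tau < 2L) return(empty)
  # pair-key -> (combination, bit weight) index in CSR layout
  keymat <- matrix(0, m, K)
  wflat <- numeric(m * K)
  for (b in seq_len(K)) {
    u <- combos[pp[b, 1L], ]
    v <- combos[pp[b, 2L], ]
    keymat[, b] <- (as.numeric(u) - 1) * n + v
    wflat[((b - 1L) * m + 1L):(b * m)] <- w_pp[b]
  }
  key_flat <- as.vector(keymat)
  cidx_flat <- rep(seq_len(m), times = K)
  ord <- order(key_flat, method = "radix")
  skeys <- key_flat[ord]
  scombo <- cidx_flat[ord]
  sweight <- wflat[ord]
  runs <- rle(skeys)
  ukeys <- runs$values
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  # initial ids
  e1k <- edge_keys(g$initial, n)
  ids <- as.vector((matrix(key_flat %in% e1k, m, K) * 1) %*% w_pp)
  last_t <- rep(1L, m)
  ev <- vector("list", length(g$batches) + 1L)
  for (t in 2L:g$tau) {
    btch <- g$batches[[t - 1L]]
    ka <- edge_keys(btch$additions, n)
    kr <- edge_keys(btch$removals, n)
    ek <- c(ka, kr)
    if (!length(ek)) next
    sgn <- c(rep(1, length(ka)), rep(-1, length(kr)))
    rows <- match(ek, ukeys)
    hit <- !is.na(rows)
    if (!any(hit)) next
    rows <- rows[hit]
    sgn <- sgn[hit]
    lens <- ends[rows] - starts[rows] + 1L
    seg <- sequence(lens) + rep(starts[rows] - 1L, lens)
    cids <- scombo[seg]
    contrib <- sweight[seg] * rep(sgn, lens)
    d <- rowsum(contrib, cids)
    uc <- as.integer(rownames(d))
    dv <- d[, 1L]
    old <- ids[uc]
    new <- old + dv
    runlen <- (t - 1L) - last_t[uc]
    has_run <- runlen > 0L
    ev[[t - 1L]] <- list(
      combo = c(uc[has_run], uc),
      from = c(old[has_run], old),
      to = c(old[has_run], new),
      count = c(as.numeric(runlen[has_run]), rep(1, length(uc)))
    )
    ids[uc] <- new
    last_t[uc] <- t
  }
  tail_len <- g$tau - last_t
  has_tail <- tail_len > 0L
  ev[[length(ev)]] <- list(
    combo = which(has_tail),
    from = ids[has_tail],
    to = ids[has_tail],
    count = as.numeric(tail_len[has_tail])
  )
  ev <- ev[!vapply(ev, is.null, logical(1))]
  list(
    combo = unlist(lapply(ev, `[[`, "combo"), use.names = FALSE),
    from = unlist(lapply(ev, `[[`, "from"), use.names = FALSE),
    to = unlist(lapply(ev, `[[`, "to"), use.names = FALSE),
    count = unlist(lapply(ev, `[[`, "count"), use.names = FALSE)
  )
}

#' @export
print.msm_run <- function(x, ...) {
  cat(sprintf(
    "global-model run: k = %d, %d vertices, %s ordered tuples (%s), tau = %d\n",
    x$k, length(x$models), format(x$n_tuples, big.mark = ","),
    if (x$filtered) "contact-filtered" else "full enumeration", x$tau))
  invisible(x)
}

#' Entropy per vertex of a run
#'
#' @param run an [run_full_computation()] result.
#' @return named numeric vector of conformational entropies in bits.
#' @export
run_entropies <- function(run) {
  stopifnot(inherits(run, "msm_run"))
  vapply(run$models, `[[`, numeric(1), "entropy")
}

#' Compare two runs: entropy and fluctuation differences
#'
#' Per-vertex \eqn{\Delta H = H_{ref} - H_{other}} (bits) and, when both
#' trajectories are supplied, \eqn{\Delta RMSF = RMSF_{ref} - RMSF_{other}}
#' (Angstrom). With the reference the free molecule and the other the
#' ligand-bound complex, positive values indicate a loss of conformational
#' entropy (or fluctuation) upon binding.
#'
#' @param reference,other [run_full_computation()] results over the same
#'   vertex set and with the same `k`.
#' @param ref_traj,other_traj optional [as_trajectory()] objects matching the
#'   two runs.
#' @return data frame with columns `vertex`, `H_ref`, `H_other`, `delta_H`
#'   and, when trajectories are given, `rmsf_ref`, `rmsf_other`,
#'   `delta_rmsf`.
#' @export
compare_runs <- function(reference, other, ref_traj = NULL,
                         other_traj = NULL) {
  stopifnot(inherits(reference, "msm_run"), inherits(other, "msm_run"))
  if (reference$k != other$k) stop("runs use different k", call. = FALSE)
  if (!identical(names(reference$models), names(other$models))) {
    stop("runs cover different vertex sets", call. = FALSE)
  }
  h_ref <- run_entropies(reference)
  h_other <- run_entropies(other)
  out <- data.frame(
    vertex = names(reference$models),
    H_ref = unname(h_ref),
    H_other = unname(h_other),
    delta_H = unname(delta_entropy(h_ref, h_other)),
    stringsAsFactors = FALSE
  )
  if (!is.null(ref_traj) && !is.null(other_traj)) {
    r <- rmsf(ref_traj)
    o <- rmsf(other_traj)
    if (length(r) != nrow(out) || length(o) != nrow(out)) {
      stop("trajectory atom counts do not match the runs", call. = FALSE)
    }
    out$rmsf_ref <- unname(r)
    out$rmsf_other <- unname(o)
    out$delta_rmsf <- unname(r - o)
  }
  out
}
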