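# Adjacency ids: the strict upper triangle of the adjacency matrix of a
# tuple-induced subgraph, read row by row as a binary number (first pair =
# most significant bit). Ids are held in doubles; k <= 10 needs at most
# 45 bits, well inside exact double-integer range.

# row-major position pairs (i, j), i < j, for tuple size k
position_pairs <- function(k) {
  i <- rep.int(seq_len(k - 1L), times = (k - 1L):1L)
  j <- unlist(lapply(seq_len(k - 1L), function(a) (a + 1L):k))
  cbind(i = i, j = j)
}

check_tuple <- function(tuple, k = length(tuple)) {
  if (k < 2L || k > 10L) {
    stop("tuple size k must be in [2, 10]", call. = FALSE)
  }
  if (anyDuplicated(tuple)) {
    stop("tuple vertices must be distinct", call. = FALSE)
  }
  if (any(tuple < 1L) || anyNA(tuple)) {
    stop("tuple contains invalid vertex indices", call. = FALSE)
  }
  invisible(tuple)
}

#' Number of adjacency states for tuple size k
#'
#' The state space of a k-vertex tuple is the set of labeled adjacency
#' matrices on k ordered vertices, of size \eqn{|A_k| = 2^{k(k-1)/2}}.
#'
#' @param k tuple size, 2..10.
#' @return the number of states as a double (exact; up to \eqn{2^{45}}).
#' @export
adjacency_state_count <- function(k) {
  k <- as.integer(k)
  if (any(k < 2L | k > 10L)) stop("k must be in [2, 10]", call. = FALSE)
  2^(k * (k - 1) / 2)
}

#' Adjacency id of a tuple-induced subgraph
#'
#' Encodes the induced subgraph of the ordered vertex tuple as an integer:
#' the bits of the strict upper triangle of its k-by-k adjacency matrix are
#' concatenated row by row — first the pair (1,2), last the pair (k-1,k) —
#' and interpreted as a binary number with the first pair as the most
#' significant bit. The tuple *order* defines the bit layout, so permuted
#' tuples generally have different ids.
#'
#' @param edges snapshot edge set: a canonical 2-column matrix (see
#'   [dynamic_graph()]), or a `dynamic_graph` whose initial snapshot is used.
#' @param tuple ordered vector of k distinct vertex indices (1-based).
#' @return the adjacency id, a double in `[0, adjacency_state_count(k))`.
#' @examples
#' # 4 vertices a,b,c,d = 1,2,3,4 with edges a-c, a-d, b-d, c-d
#' edges <- rbind(c(1, 3), c(1, 4), c(2, 4), c(3, 4))
#' adjacency_id(edges, c(1, 2, 3, 4))  # 27 (binary 011011)
#' @export
adjacency_id <- function(edges, tuple) {
  if (inherits(edges, "dynamic_graph")) edges <- edges$initial
  tuple <- as.integer(tuple)
  k <- length(tuple)
  check_tuple(tuple, k)
  pp <- position_pairs(k)
  K <- nrow(pp)
  a <- tuple[pp[, 1L]]
  b <- tuple[pp[, 2L]]
  u <- pmin(a, b)
  v <- pmax(a, b)
  base <- max(tuple, edges, 1L)
  want <- (as.numeric(u) - 1) * base + v
  have <- if (nrow(edges)) {
    eu <- pmin(edges[, 1L], edges[, 2L])
    ev <- pmax(edges[, 1L], edges[, 2L])
    (as.numeric(eu) - 1) * base + ev
  } else numeric(0)
  bits <- as.numeric(want %in% have)
  sum(bits * 2^((K - 1L):0))
}

#' Bit position of an edge inside a tuple's adjacency id
#'
#' For an edge `{a, b}` with both endpoints in the ordered tuple, returns the
#' exponent `e` such that toggling the edge changes the adjacency id by
#' \eqn{\pm 2^e}: with `i < j` the (1-based) positions of `a` and `b` in the
#' tuple, \eqn{e = k(k-1)/2 - [(i-1)k + j - i(i+1)/2]}.
#'
#' @param a,b vertex indices, both contained in `tuple`.
#' @param tuple ordered vector of k distinct vertex indices.
#' @return integer bit position in `[0, k(k-1)/2 - 1]`.
#' @export
edge_bit_position <- function(a, b, tuple) {
  pos_a <- match(a, tuple)
  pos_b <- match(b, tuple)
  if (is.na(pos_a) || is.na(pos_b) || a == b) {
    stop("both endpoints must be distinct members of the tuple", call. = FALSE)
  }
  k <- length(tuple)
  i <- min(pos_a, pos_b)
  j <- max(pos_a, pos_b)
  as.integer(k * (k - 1) / 2 - ((i - 1) * k + j - i * (i + 1) / 2))
}

#' Update an adjacency id for a single streamed edge event
#'
#' Applies one edge addition or removal to a maintained adjacency id. Edges
#' with an endpoint outside the tuple leave the id unchanged. Adding an edge
#' whose bit is already set (or removing an unset one) signals an
#' inconsistent stream and raises an error.
#'
#' @param id current adjacency id of `tuple`.
#' @param edge length-2 vector `c(u, v)`.
#' @param type `"add"` or `"remove"`.
#' @param tuple ordered vector of k distinct vertex indices.
#' @return the updated adjacency id.
#' @export
stream_update <- function(id, edge, type = c("add", "remove"), tuple) {
  type <- match.arg(type)
  k <- length(tuple)
  K <- k * (k - 1) / 2
  if (id < 0 || id >= 2^K) stop("id out of range for k", call. = FALSE)
  if (!(edge[1L] %in% tuple) || !(edge[2L] %in% tuple)) return(id)
  e <- edge_bit_position(edge[1L], edge[2L], tuple)
  bit <- floor(id / 2^e) %% 2
  if (type == "add") {
    if (bit != 0) {
      stop(sprintf("inconsistent stream: edge {%d,%d} already present (bit %d set)",
                   edge[1L], edge[2L], e), call. = FALSE)
    }
    id + 2^e
  } else {
    if (bit != 1) {
      stop(sprintf("inconsistent stream: edge {%d,%d} not present (bit %d unset)",
                   edge[1L], edge[2L], e), call. = FALSE)
    }
    id - 2^e
  }
}

#' Update an adjacency id for a whole batch
#'
#' Folds [stream_update()] over all removals and then all additions of a
#' batch (the order is irrelevant because a valid batch's additions and
#' removals are disjoint), yielding the id at snapshot t from the id at t-1.
#'
#' @param id current adjacency id of `tuple`.
#' @param batch list with 2-column matrices `additions` and `removals`.
#' @param tuple ordered vector of k distinct vertex indices.
#' @return the updated adjacency id.
#' @export
batch_update <- function(id, batch, tuple) {
  r <- batch$removals
  if (!is.null(r) && nrow(r)) {
    for (i in seq_len(nrow(r))) id <- stream_update(id, r[i, ], "remove", tuple)
  }
  a <- batch$additions
  if (!is.null(a) && nrow(a)) {
    for (i in seq_len(nrow(a))) id <- stream_update(id, a[i, ], "add", tuple)
  }
  id
}

#' Adjacency-id transition list of a tuple over a dynamic graph
#'
#' Computes the id of the tuple-induced subgraph at every snapshot in a
#' single pass over the batch stream and returns all consecutive pairs
#' `(id_t, id_{t+1})`, *including* self-transitions where the id did not
#' change.
#'
#' @param g a [dynamic_graph()].
#' @param tuple ordered vector of k distinct vertex indices.
#' @return data frame with columns `time` (1..tau-1), `from`, `to`; the `k`
#'   and `tuple` are attached as attributes.
#' @export
transition_list <- function(g, tuple) {
  tuple <- as.integer(tuple)
  check_tuple(tuple)
  if (any(tuple > g$n_vertices)) {
    stop("tuple contains vertices outside the graph", call. = FALSE)
  }
  tau <- g$tau
  ids <- numeric(tau)
  ids[1L] <- adjacency_id(g$initial, tuple)
  for (t in seq_along(g$batches)) {
    ids[t + 1L] <- batch_update(ids[t], g$batches[[t]], tuple)
  }
  out <- data.frame(
    time = seq_len(max(0L, tau - 1L)),
    from = ids[seq_len(max(0L, tau - 1L))],
    to = ids[seq_len(max(0L, tau - 1L)) + 1L]
  )
  attr(out, "k") <- length(tuple)
  attr(out, "tuple") <- tuple
  out
}
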