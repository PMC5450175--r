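# Dynamic graphs: a fixed vertex set with a time-ordered sequence of edge
# sets, stored as an initial snapshot plus batches of additions/removals.
# Edges are canonical 2-column integer matrices with u < v, rows sorted.

# ---- internal edge helpers -------------------------------------------------

# canonicalize an edge matrix: u < v per row, rows sorted lexicographically.
# `n` is the number of vertices; indices are 1-based internally.
canonical_edges <- function(edges, n, what = "edge set") {
  if (is.null(edges) || length(edges) == 0) {
    return(matrix(integer(0), ncol = 2L))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) {
    stop(what, ": edges must be a 2-column matrix", call. = FALSE)
  }
  storage.mode(edges) <- "integer"
  if (anyNA(edges)) stop(what, ": NA vertex index", call. = FALSE)
  if (any(edges < 1L) || any(edges > n)) {
    stop(what, ": vertex index outside [1, ", n, "]", call. = FALSE)
  }
  if (any(edges[, 1L] == edges[, 2L])) {
    stop(what, ": self-loops are not allowed", call. = FALSE)
  }
  u <- pmin(edges[, 1L], edges[, 2L])
  v <- pmax(edges[, 1L], edges[, 2L])
  k <- edge_keys(cbind(u, v), n)
  if (anyDuplicated(k)) stop(what, ": duplicate edges", call. = FALSE)
  ord <- order(k)
  out <- cbind(u[ord], v[ord])
  dimnames(out) <- list(NULL, c("u", "v"))
  out
}

# numeric key for canonical edges (u < v): disjoint per u, exact in doubles
edge_keys <- function(edges, n) {
  if (nrow(edges) == 0L) return(numeric(0))
  (as.numeric(edges[, 1L]) - 1) * n + as.numeric(edges[, 2L])
}

keys_to_edges <- function(keys, n) {
  if (length(keys) == 0L) return(matrix(integer(0), ncol = 2L))
  keys <- sort(keys)
  u <- as.integer((keys - 1) %/% n + 1)
  v <- as.integer(keys - (u - 1) * n)
  out <- cbind(unname(u), unname(v))
  dimnames(out) <- list(NULL, c("u", "v"))
  out
}

# run a seeded block without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# ---- constructor ------------------------------------------------------------

#' Construct a dynamic graph
#'
#' A dynamic graph is a fixed vertex set `1..n_vertices` together with a
#' time-ordered sequence of edge sets \eqn{E_1, \dots, E_\tau}, stored as the
#' initial snapshot \eqn{E_1} plus, for every subsequent time step, a *batch*
#' of edge additions \eqn{E^+_t = E_t \setminus E_{t-1}} and removals
#' \eqn{E^-_t = E_{t-1} \setminus E_t}. Graphs are undirected, without
#' self-loops, and the vertex set does not change over time.
#'
#' @param initial 2-column matrix of edges at time 1 (1-based vertex indices;
#'   orientation and row order are irrelevant, storage is canonicalized).
#' @param batches list of `tau - 1` batches; each batch is a list with
#'   elements `additions` and `removals`, both 2-column edge matrices.
#' @param n_vertices number of vertices.
#' @param labels optional external vertex labels (length `n_vertices`);
#'   defaults to the 0-based integers `0:(n_vertices-1)` used by the stream
#'   file dialect.
#' @param validate replay all batches and check the snapshot invariants
#'   (additions absent before, removals present before, no self-loops).
#'
#' @return An object of class `dynamic_graph` with fields `n_vertices`,
#'   `initial`, `batches`, `tau` and `labels`.
#' @seealso [snapshots_to_batches()], [replay_snapshots()],
#'   [generate_random_dynamic_graph()], [read_dynamic_graph()]
#' @export
dynamic_graph <- function(initial, batches = list(), n_vertices,
                          labels = NULL, validate = TRUE) {
  n_vertices <- as.integer(n_vertices)
  if (is.na(n_vertices) || n_vertices < 1L) {
    stop("n_vertices must be a positive integer", call. = FALSE)
  }
  if (is.null(labels)) labels <- 0:(n_vertices - 1L)
  if (length(labels) != n_vertices) {
    stop("labels must have length n_vertices", call. = FALSE)
  }
  initial <- canonical_edges(initial, n_vertices, "initial snapshot")
  batches <- lapply(seq_along(batches), function(i) {
    b <- batches[[i]]
    list(
      additions = canonical_edges(b$additions, n_vertices,
                                  sprintf("batch %d additions", i + 1L)),
      removals  = canonical_edges(b$removals, n_vertices,
                                  sprintf("batch %d removals", i + 1L))
    )
  })
  g <- structure(
    list(n_vertices = n_vertices, initial = initial, batches = batches,
         tau = length(batches) + 1L, labels = labels),
    class = "dynamic_graph"
  )
  if (validate) validate_dynamic_graph(g)
  g
}

validate_dynamic_graph <- function(g) {
  n <- g$n_vertices
  cur <- edge_keys(g$initial, n)
  for (i in seq_along(g$batches)) {
    b <- g$batches[[i]]
    ka <- edge_keys(b$additions, n)
    kr <- edge_keys(b$removals, n)
    if (any(ka %in% kr)) {
      stop(sprintf("batch %d: additions and removals overlap", i + 1L),
           call. = FALSE)
    }
    if (any(ka %in% cur)) {
      stop(sprintf("batch %d: adds an edge already present", i + 1L),
           call. = FALSE)
    }
    if (!all(kr %in% cur)) {
      stop(sprintf("batch %d: removes an edge not present", i + 1L),
           call. = FALSE)
    }
    cur <- c(cur[!(cur %in% kr)], ka)
  }
  invisible(g)
}

#' @export
print.dynamic_graph <- function(x, ...) {
  st <- batch_statistics(x)
  cat(sprintf(
    "dynamic graph: %d vertices, %d snapshots, |E_1| = %d, delta_avg = %.3g\n",
    x$n_vertices, x$tau, nrow(x$initial), st$delta_avg))
  invisible(x)
}

# ---- replay / conversion ----------------------------------------------------

#' Replay a dynamic graph into per-snapshot edge sets
#'
#' Applies the batches one after another to the initial snapshot and returns
#' the full edge set of every snapshot in canonical form.
#'
#' @param g a [dynamic_graph()].
#' @return list of `tau` canonical 2-column edge matrices.
#' @export
replay_snapshots <- function(g) {
  n <- g$n_vertices
  out <- vector("list", g$tau)
  cur <- edge_keys(g$initial, n)
  out[[1L]] <- g$initial
  for (i in seq_along(g$batches)) {
    b <- g$batches[[i]]
    kr <- edge_keys(b$removals, n)
    ka <- edge_keys(b$additions, n)
    cur <- c(cur[!(cur %in% kr)], ka)
    out[[i + 1L]] <- keys_to_edges(cur, n)
  }
  out
}

#' Convert a list of full snapshots to the batch representation
#'
#' Computes the minimal per-step batches as set differences
#' \eqn{E^+_t = E_t \setminus E_{t-1}} and \eqn{E^-_t = E_{t-1} \setminus E_t},
#' so that replaying the result reproduces every input snapshot exactly.
#'
#' @param snapshots non-empty list of 2-column edge matrices over a common
#'   vertex set.
#' @param n_vertices number of vertices; defaults to the largest index seen.
#' @param labels optional external vertex labels, see [dynamic_graph()].
#' @return a [dynamic_graph()].
#' @export
snapshots_to_batches <- function(snapshots, n_vertices = NULL, labels = NULL) {
  if (length(snapshots) == 0L) {
    stop("need at least one snapshot", call. = FALSE)
  }
  if (is.null(n_vertices)) {
    n_vertices <- max(1L, unlist(lapply(snapshots, function(e) {
      if (length(e)) max(e) else 1L
    })))
  }
  n <- as.integer(n_vertices)
  snaps <- lapply(seq_along(snapshots), function(t) {
    canonical_edges(snapshots[[t]], n, sprintf("snapshot %d", t))
  })
  keys <- lapply(snaps, edge_keys, n = n)
  batches <- vector("list", length(snaps) - 1L)
  for (t in seq_along(batches)) {
    prev <- keys[[t]]
    cur <- keys[[t + 1L]]
    batches[[t]] <- list(
      additions = keys_to_edges(cur[!(cur %in% prev)], n),
      removals  = keys_to_edges(prev[!(prev %in% cur)], n)
    )
  }
  dynamic_graph(snaps[[1L]], batches, n, labels = labels, validate = FALSE)
}

#' Batch-size statistics of a dynamic graph
#'
#' The batch size \eqn{\delta_t = |E^+_t| + |E^-_t|} counts the edges changed
#' between consecutive snapshots; the average batch size is defined as
#' \eqn{\delta_{avg} = \sum_t \delta_t / \tau} with \eqn{\tau} the number of
#' snapshots (note: the denominator is the snapshot count, not the number of
#' batches).
#'
#' @param g a [dynamic_graph()].
#' @return list with `delta` (length `tau - 1` vector of per-step batch sizes)
#'   and `delta_avg`.
#' @export
batch_statistics <- function(g) {
  delta <- vapply(g$batches, function(b) {
    nrow(b$additions) + nrow(b$removals)
  }, integer(1))
  list(delta = delta, delta_avg = sum(delta) / g$tau)
}

# ---- random generator -------------------------------------------------------

#' Generate a seeded random dynamic graph
#'
#' The initial snapshot draws `n_edges` edges uniformly from all vertex pairs.
#' Every batch removes `floor(batch_size/2)` uniformly chosen existing edges
#' and adds `ceiling(batch_size/2)` uniformly chosen absent edges (for odd
#' sizes the extra change is an addition), so for even `batch_size` the edge
#' count stays `n_edges` at every snapshot and every \eqn{\delta_t} equals
#' `batch_size`. The same seed reproduces the graph exactly.
#'
#' @param n_vertices,n_edges,batch_size,tau graph dimensions; `tau` is the
#'   number of snapshots.
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @return a [dynamic_graph()].
#' @export
generate_random_dynamic_graph <- function(n_vertices, n_edges, batch_size,
                                          tau, seed = NULL) {
  n <- as.integer(n_vertices)
  n_edges <- as.integer(n_edges)
  batch_size <- as.integer(batch_size)
  tau <- as.integer(tau)
  npairs <- n * (n - 1) / 2
  if (n < 1L || tau < 1L || n_edges < 0L || batch_size < 0L) {
    stop("all generator parameters must be non-negative (n, tau positive)",
         call. = FALSE)
  }
  if (n_edges > npairs) {
    stop("n_edges exceeds the number of vertex pairs", call. = FALSE)
  }
  n_rem <- batch_size %/% 2L
  n_add <- batch_size - n_rem
  if (n_rem > n_edges || n_add > npairs - n_edges) {
    stop("batch_size infeasible for the requested edge count", call. = FALSE)
  }
  with_preserved_seed(seed, {
    allp <- if (n >= 2L) t(utils::combn(n, 2L)) else matrix(integer(0), ncol = 2L)
    present <- rep(FALSE, nrow(allp))
    present[sample.int(nrow(allp), n_edges)] <- TRUE
    initial <- allp[present, , drop = FALSE]
    batches <- vector("list", max(0L, tau - 1L))
    for (t in seq_along(batches)) {
      rem_idx <- which(present)
      add_idx <- which(!present)
      if (n_rem > length(rem_idx) || n_add > length(add_idx)) {
        stop(sprintf("batch_size infeasible at step %d: %d edges present, %d absent",
                     t + 1L, length(rem_idx), length(add_idx)), call. = FALSE)
      }
      rem <- if (n_rem > 0L) rem_idx[sample.int(length(rem_idx), n_rem)] else integer(0)
      add <- if (n_add > 0L) add_idx[sample.int(length(add_idx), n_add)] else integer(0)
      present[rem] <- FALSE
      present[add] <- TRUE
      batches[[t]] <- list(additions = allp[add, , drop = FALSE],
                           removals  = allp[rem, , drop = FALSE])
    }
    dynamic_graph(initial, batches, n, validate = FALSE)
  })
}

# ---- stream file dialect ----------------------------------------------------

#' Read / write a dynamic graph in the text stream dialect
#'
#' The format is line-oriented UTF-8 with `#` comments. A `nodes N` header is
#' followed by a `snapshot 1` block of `e u v` lines (the initial edges,
#' 0-based labels), then one `batch t` block per step with `+ u v` and
#' `- u v` lines. Alternatively the file may contain a `snapshot t` block for
#' *every* time step (full snapshots); such files are converted to batches via
#' [snapshots_to_batches()] on read. Labels must be integers in `[0, N)`.
#'
#' `write_dynamic_graph()` emits canonical output (edges sorted, `u < v`), so
#' writing and re-reading is the identity on canonical content.
#'
#' @param path file path.
#' @param g a [dynamic_graph()].
#' @return `read_dynamic_graph()` returns a [dynamic_graph()];
#'   `write_dynamic_graph()` returns `path` invisibly.
#' @export
read_dynamic_graph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stripped <- sub("#.*$", "", lines)
  stripped <- trimws(stripped)
  perr <- function(i, msg) {
    stop(sprintf("%s:%d: %s", path, i, msg), call. = FALSE)
  }
  n <- NULL
  labels <- NULL
  # blocks: list of list(type = "snapshot"/"batch", t, add, rem)
  blocks <- list()
  cur <- NULL
  parse_vertex <- function(tok, i) {
    v <- suppressWarnings(as.integer(tok))
    if (is.na(v)) perr(i, sprintf("not an integer vertex label: '%s'", tok))
    if (v < 0L || v >= n) {
      perr(i, sprintf("vertex label %d outside [0, %d)", v, n))
    }
    v + 1L
  }
  flush_block <- function() {
    if (!is.null(cur)) blocks[[length(blocks) + 1L]] <<- cur
    cur <<- NULL
  }
  for (i in seq_along(stripped)) {
    line <- stripped[i]
    if (line == "") next
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    kw <- tok[1]
    if (kw == "nodes") {
      if (!is.null(n)) perr(i, "duplicate 'nodes' header")
      if (length(tok) != 2L) perr(i, "expected: nodes <N>")
      n <- suppressWarnings(as.integer(tok[2]))
      if (is.na(n) || n < 1L) perr(i, "invalid vertex count")
    } else if (kw %in% c("snapshot", "batch")) {
      if (is.null(n)) perr(i, "'nodes' header must come first")
      if (length(tok) != 2L) perr(i, sprintf("expected: %s <t>", kw))
      t <- suppressWarnings(as.integer(tok[2]))
      if (is.na(t) || t < 1L) perr(i, "invalid time index")
      flush_block()
      cur <- list(type = kw, t = t, add = list(), rem = list(), line = i)
    } else if (kw %in% c("e", "+", "-")) {
      if (is.null(cur)) perr(i, "edge line outside a snapshot/batch block")
      if (length(tok) != 3L) perr(i, "expected: <op> <u> <v>")
      u <- parse_vertex(tok[2], i)
      v <- parse_vertex(tok[3], i)
      if (u == v) perr(i, "self-loop")
      if (kw == "e") {
        if (cur$type != "snapshot") perr(i, "'e' line inside a batch block")
        cur$add[[length(cur$add) + 1L]] <- c(min(u, v), max(u, v))
      } else {
        if (cur$type != "batch") perr(i, sprintf("'%s' line outside a batch block", kw))
        slot <- if (kw == "+") "add" else "rem"
        cur[[slot]][[length(cur[[slot]]) + 1L]] <- c(min(u, v), max(u, v))
      }
    } else {
      perr(i, sprintf("unknown directive '%s'", kw))
    }
  }
  flush_block()
  if (is.null(n)) stop(path, ": missing 'nodes' header", call. = FALSE)
  if (length(blocks) == 0L) stop(path, ": no snapshot blocks", call. = FALSE)
  types <- vapply(blocks, `[[`, "", "type")
  times <- vapply(blocks, `[[`, 0L, "t")
  if (blocks[[1]]$type != "snapshot" || blocks[[1]]$t != 1L) {
    perr(blocks[[1]]$line, "file must start with 'snapshot 1'")
  }
  to_edges <- function(lst) {
    if (length(lst) == 0L) matrix(integer(0), ncol = 2L)
    else do.call(rbind, lst)
  }
  check_seq <- function() {
    if (!identical(times, seq_along(blocks))) {
      stop(path, ": time indices must be consecutive starting at 1",
           call. = FALSE)
    }
  }
  wrap <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop(path, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  if (all(types == "snapshot")) {
    check_seq()
    snaps <- lapply(blocks, function(b) to_edges(b$add))
    wrap(snapshots_to_batches(snaps, n_vertices = n))
  } else if (all(types[-1] == "batch")) {
    check_seq()
    batches <- lapply(blocks[-1], function(b) {
      list(additions = to_edges(b$add), removals = to_edges(b$rem))
    })
    wrap(dynamic_graph(to_edges(blocks[[1]]$add), batches, n))
  } else {
    stop(path, ": mixed snapshot/batch blocks are not supported", call. = FALSE)
  }
}

#' @rdname read_dynamic_graph
#' @export
write_dynamic_graph <- function(g, path) {
  stopifnot(inherits(g, "dynamic_graph"))
  # the stream dialect always carries 0-based vertex indices; non-integer
  # labels (e.g. residue names) live only on the in-memory object
  lab <- function(idx) idx - 1L
  out <- character(0)
  out <- c(out, paste("nodes", g$n_vertices), "snapshot 1")
  e <- g$initial
  if (nrow(e)) out <- c(out, sprintf("e %s %s", lab(e[, 1]), lab(e[, 2])))
  for (i in seq_along(g$batches)) {
    b <- g$batches[[i]]
    out <- c(out, paste("batch", i + 1L))
    a <- b$additions
    r <- b$removals
    if (nrow(a)) out <- c(out, sprintf("+ %s %s", lab(a[, 1]), lab(a[, 2])))
    if (nrow(r)) out <- c(out, sprintf("- %s %s", lab(r[, 1]), lab(r[, 2])))
  }
  writeLines(out, path)
  invisible(path)
}
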