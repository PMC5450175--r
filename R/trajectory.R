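# Coordinate trajectories: reading (multi-model PDB, plain XYZ tables),
# contact matrices and probabilities, RMSF, conversion to dynamic graphs,
# and a seeded synthetic generator used throughout the test-suite.

#' Construct a trajectory object
#'
#' @param coords numeric array `T x n x 3`: frames by atoms by Cartesian
#'   coordinates in Angstrom. A single `n x 3` matrix is treated as one frame.
#' @param labels optional atom/residue labels (length n).
#' @return object of class `trajectory` with fields `coords`, `labels`,
#'   `n_frames`, `n_atoms`.
#' @export
as_trajectory <- function(coords, labels = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("coords must be a T x n x 3 array", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  n <- dim(coords)[2]
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (length(labels) != n) stop("labels must have length n", call. = FALSE)
  structure(list(coords = coords, labels = as.character(labels),
                 n_frames = dim(coords)[1], n_atoms = n),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms\n", x$n_frames, x$n_atoms))
  invisible(x)
}

frame_coords <- function(traj, t) {
  matrix(traj$coords[t, , ], ncol = 3L,
         dimnames = list(traj$labels, c("x", "y", "z")))
}

# ---- readers ----------------------------------------------------------------

#' Read a coordinate trajectory
#'
#' Supports two plain-text formats. Multi-model PDB: `MODEL`/`ENDMDL` blocks
#' of fixed-column `ATOM`/`HETATM` records, from which one representative
#' atom per residue is selected by atom name (default `C3'`, the ribose
#' carbon conventionally used for one-bead-per-nucleotide RNA coarse
#' graining); every residue must contain the atom in every model, and all
#' models must agree. XYZ table: whitespace-separated `frame atom x y z`
#' rows, one per atom per frame (the `atom` column carries the label).
#'
#' @param path file path.
#' @param atom atom name selecting one atom per residue (PDB only).
#' @param format `"auto"` (by extension: `.pdb` vs anything else), `"pdb"`,
#'   or `"xyz"`.
#' @return a [as_trajectory()] object; residue order of the file is kept.
#' @export
read_trajectory <- function(path, atom = "C3'",
                            format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (format == "pdb") read_pdb_trajectory(path, atom)
  else read_xyz_trajectory(path)
}

read_pdb_trajectory <- function(path, atom) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- rec == "MODEL "
  is_end <- rec == "ENDMDL"
  # assign a model index to every atom record
  model_of <- cumsum(is_model)
  if (!any(is_model)) model_of <- rep(1L, length(lines))
  ai <- which(is_atom)
  if (length(ai) == 0L) stop(path, ": no ATOM records", call. = FALSE)
  if (any(is_model) && any(model_of[ai] == 0L)) {
    stop(path, ": ATOM record before the first MODEL", call. = FALSE)
  }
  al <- lines[ai]
  name <- trimws(substr(al, 13, 16))
  resname <- trimws(substr(al, 18, 20))
  chain <- trimws(substr(al, 22, 22))
  resseq <- trimws(substr(al, 23, 26))
  model <- model_of[ai]
  reskey <- paste0(chain, ":", resseq)
  models <- sort(unique(model))
  # residue order from the first model
  first <- model == models[1L]
  res_order <- unique(reskey[first])
  res_label <- paste0(resname, resseq)[first][match(res_order, reskey[first])]
  sel <- name == atom
  n <- length(res_order)
  coords <- array(NA_real_, c(length(models), n, 3L))
  for (mi in seq_along(models)) {
    inm <- model == models[mi]
    m_res <- unique(reskey[inm])
    if (!identical(sort(m_res), sort(res_order))) {
      stop(sprintf("%s: model %d has a different residue set than model %d",
                   path, models[mi], models[1L]), call. = FALSE)
    }
    pick <- inm & sel
    got <- reskey[pick]
    missing <- setdiff(res_order, got)
    if (length(missing)) {
      lab <- res_label[match(missing[1L], res_order)]
      stop(sprintf("%s: residue %s (%s) lacks atom '%s' in model %d",
                   path, missing[1L], lab, atom, models[mi]), call. = FALSE)
    }
    if (anyDuplicated(got)) {
      stop(sprintf("%s: residue %s has multiple '%s' atoms in model %d",
                   path, got[anyDuplicated(got)], atom, models[mi]),
           call. = FALSE)
    }
    idx <- which(pick)[match(res_order, got)]
    coords[mi, , 1L] <- as.numeric(substr(al[idx], 31, 38))
    coords[mi, , 2L] <- as.numeric(substr(al[idx], 39, 46))
    coords[mi, , 3L] <- as.numeric(substr(al[idx], 47, 54))
  }
  if (anyNA(coords)) stop(path, ": unparseable coordinate field", call. = FALSE)
  as_trajectory(coords, res_label)
}

read_xyz_trajectory <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("frame", "atom", "x", "y", "z"),
                           colClasses = c("integer", "character", "numeric",
                                          "numeric", "numeric"))
  frames <- sort(unique(tab$frame))
  first <- tab[tab$frame == frames[1L], ]
  labels <- first$atom
  n <- nrow(first)
  coords <- array(NA_real_, c(length(frames), n, 3L))
  for (fi in seq_along(frames)) {
    blk <- tab[tab$frame == frames[fi], ]
    if (nrow(blk) != n || !identical(blk$atom, labels)) {
      stop(sprintf("%s: frame %d has inconsistent atoms", path, frames[fi]),
           call. = FALSE)
    }
    coords[fi, , ] <- as.matrix(blk[, c("x", "y", "z")])
  }
  as_trajectory(coords, labels)
}

#' Write a trajectory as an XYZ table
#'
#' Inverse of the XYZ reader: whitespace-separated `frame atom x y z` rows.
#'
#' @param traj a [as_trajectory()] object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  rows <- do.call(rbind, lapply(seq_len(traj$n_frames), function(t) {
    cbind(frame = t, atom = traj$labels,
          format(frame_coords(traj, t), trim = TRUE, digits = 17))
  }))
  utils::write.table(rows, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# ---- contacts & RMSF --------------------------------------------------------

#' Binary contact matrix of one frame
#'
#' `B[i, j] = 1` iff the Euclidean distance between atoms i and j is
#' *strictly* below the cut-off `d` (and `i != j`); exact equality counts as
#' no contact. The result is symmetric with a zero diagonal.
#'
#' @param coords `n x 3` coordinate matrix (one frame), or a trajectory whose
#'   frame `frame` is used.
#' @param d cut-off distance in Angstrom (`d > 0`).
#' @param frame frame index when `coords` is a trajectory.
#' @return `n x n` 0/1 matrix.
#' @export
contact_matrix <- function(coords, d, frame = 1L) {
  if (inherits(coords, "trajectory")) coords <- frame_coords(coords, frame)
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  if (!is.numeric(d) || d <= 0) stop("cut-off d must be positive", call. = FALSE)
  dm <- as.matrix(stats::dist(coords))
  B <- (dm < d) * 1
  diag(B) <- 0
  dimnames(B) <- NULL
  B
}

#' Contact probability matrix over a trajectory
#'
#' Entry (i, j) is the fraction of frames in which atoms i and j are in
#' contact at cut-off `d`: the time average of the per-frame binary contact
#' matrices.
#'
#' @param traj a [as_trajectory()] object.
#' @param d cut-off distance in Angstrom.
#' @return symmetric `n x n` matrix with entries in `[0, 1]`.
#' @export
contact_probability <- function(traj, d) {
  stopifnot(inherits(traj, "trajectory"))
  P <- matrix(0, traj$n_atoms, traj$n_atoms)
  for (t in seq_len(traj$n_frames)) {
    P <- P + contact_matrix(frame_coords(traj, t), d)
  }
  P <- P / traj$n_frames
  dimnames(P) <- list(traj$labels, traj$labels)
  P
}

#' Root-mean-square fluctuation per atom
#'
#' \eqn{RMSF_i = \sqrt{\frac{1}{T}\sum_t \lVert r_i(t) - \bar r_i \rVert^2}}
#' about the per-atom time-averaged position. No superposition or fitting is
#' applied; pre-align the trajectory externally if rigid-body motion should
#' be removed.
#'
#' @param traj a [as_trajectory()] object.
#' @return named numeric vector of per-atom RMSF values in Angstrom.
#' @export
rmsf <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  mean_pos <- apply(traj$coords, c(2L, 3L), mean)
  dev2 <- sweep(traj$coords, c(2L, 3L), mean_pos)^2
  out <- sqrt(apply(dev2, 2L, sum) / traj$n_frames)
  names(out) <- traj$labels
  out
}

#' RMSF difference between a reference and another trajectory
#'
#' \eqn{\Delta RMSF = RMSF_{ref} - RMSF_{other}} per atom; positive values
#' indicate a loss of fluctuation relative to the reference.
#'
#' @param ref,other [as_trajectory()] objects with matching atom counts.
#' @return numeric vector.
#' @export
delta_rmsf <- function(ref, other) {
  r <- rmsf(ref)
  o <- rmsf(other)
  if (length(r) != length(o)) stop("atom counts differ", call. = FALSE)
  r - o
}

#' Convert a trajectory to a dynamic contact graph
#'
#' Snapshot t has an edge `{i, j}` exactly when atoms i and j are in contact
#' (distance strictly below `d`) in frame t; the per-frame edge sets are
#' converted to the batch representation via [snapshots_to_batches()].
#'
#' @param traj a [as_trajectory()] object.
#' @param d cut-off distance in Angstrom (typically 10-15 for C3' RNA graphs).
#' @return a [dynamic_graph()] with `tau = n_frames` and one vertex per atom.
#' @export
trajectory_to_dynamic_graph <- function(traj, d) {
  stopifnot(inherits(traj, "trajectory"))
  snaps <- lapply(seq_len(traj$n_frames), function(t) {
    B <- contact_matrix(frame_coords(traj, t), d)
    which(upper.tri(B) & B == 1, arr.ind = TRUE)
  })
  snapshots_to_batches(snaps, n_vertices = traj$n_atoms,
                       labels = traj$labels)
}

# ---- synthetic generator ----------------------------------------------------

#' Generate a synthetic coarse-grained trajectory
#'
#' Emulates a one-bead-per-nucleotide RNA trajectory. The base fold is a
#' self-avoiding random walk with fixed step length (default 6 Angstrom, the
#' typical consecutive C3'-C3' distance) confined to a sphere: non-adjacent
#' beads keep at least `min_separation` apart, the excluded volume of a
#' nucleotide, so the contact density at 10-15 Angstrom cut-offs matches
#' folded RNA (mean degree around 7 at 13 Angstrom for the defaults) instead
#' of the unphysical pile-up of a plain random walk. Every frame then
#' displaces each bead by a temporally correlated AR(1) fluctuation with
#' stationary standard deviation `fluctuation` per coordinate; the
#' correlated noise makes pairs near the cut-off oscillate across it, so the
#' derived dynamic graphs have non-trivial batches.
#'
#' @param n_residues number of beads (vertices of the derived graph).
#' @param n_frames number of frames.
#' @param seed optional integer seed (caller's RNG state is preserved).
#' @param step_length backbone step in Angstrom.
#' @param confinement_radius radius of the confining sphere in Angstrom.
#' @param min_separation minimum distance between non-consecutive beads in
#'   the base fold, in Angstrom.
#' @param fluctuation per-coordinate stationary fluctuation SD in Angstrom.
#' @param correlation AR(1) frame-to-frame correlation in `[0, 1)`.
#' @return a [as_trajectory()] object with labels `"R1" ... "Rn"`.
#' @export
generate_synthetic_trajectory <- function(n_residues = 65L, n_frames = 1000L,
                                          seed = NULL, step_length = 6,
                                          confinement_radius = 24,
                                          min_separation = 9,
                                          fluctuation = 1.5,
                                          correlation = 0.9) {
  n <- as.integer(n_residues)
  T <- as.integer(n_frames)
  stopifnot(n >= 2L, T >= 1L, step_length > 0, confinement_radius > 0,
            min_separation >= 0, fluctuation >= 0,
            correlation >= 0, correlation < 1)
  with_preserved_seed(seed, {
    base <- saw_fold(n, step_length, confinement_radius, min_separation)
    phi <- correlation
    innov_sd <- fluctuation * sqrt(1 - phi^2)
    coords <- array(0, c(T, n, 3L))
    disp <- matrix(stats::rnorm(n * 3L, sd = fluctuation), n, 3L)
    coords[1L, , ] <- base + disp
    if (T > 1L) {
      for (t in 2:T) {
        disp <- phi * disp + matrix(stats::rnorm(n * 3L, sd = innov_sd), n, 3L)
        coords[t, , ] <- base + disp
      }
    }
    as_trajectory(coords, paste0("R", seq_len(n)))
  })
}

# self-avoiding confined walk for the base fold; restarts from a random
# earlier prefix when a dead end is reached
saw_fold <- function(n, step, radius, min_sep) {
  base <- matrix(0, n, 3L)
  i <- 2L
  stalls <- 0L
  while (i <= n) {
    placed <- FALSE
    for (try in seq_len(200L)) {
      dir <- stats::rnorm(3L)
      cand <- base[i - 1L, ] + step * dir / sqrt(sum(dir^2))
      if (sum(cand^2) > radius^2) next
      if (i > 2L) {
        prev <- base[seq_len(i - 2L), , drop = FALSE]
        d2 <- rowSums(sweep(prev, 2L, cand)^2)
        if (min(d2) < min_sep^2) next
      }
      base[i, ] <- cand
      placed <- TRUE
      break
    }
    if (placed) {
      i <- i + 1L
    } else {
      stalls <- stalls + 1L
      if (stalls > 1000L) {
        stop("could not grow a self-avoiding fold; loosen min_separation or enlarge confinement_radius",
             call. = FALSE)
      }
      i <- max(2L, i - sample.int(min(5L, i - 2L) + 1L, 1L) + 1L)
    }
  }
  base
}
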