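## Frame-by-frame clustering of molecular-dynamics trajectory ensembles:
## multi-frame XYZ I/O, internal-coordinate features with rates of change,
## per-frame PCA reduction, per-frame clustering, and assembly of trajectories
## into reaction channels via checkpoint frames.

#' Read an ensemble of multi-frame XYZ trajectories
#'
#' Standard XYZ blocks (atom-count line, comment line, then `element x y z`
#' rows) repeated per frame. All trajectories must share the atom count and
#' frame count; coordinates are in Angstrom, the time grid is uniform.
#'
#' @param paths character vector of XYZ file paths, one trajectory each.
#' @param dt time step between frames in femtoseconds (default 0.5).
#' @return object of class `donkey_ensemble`: `coords` (array
#'   `n_traj x n_frames x n_atoms x 3`), `elements`, `times` (fs).
#' @export
read_xyz_trajectories <- function(paths, dt = 0.5) {
  trajs <- lapply(paths, .read_xyz_file)
  na <- vapply(trajs, function(t) dim(t$coords)[2L], integer(1))
  nf <- vapply(trajs, function(t) dim(t$coords)[1L], integer(1))
  if (length(unique(na)) != 1L) {
    stop("inconsistent atom counts across files: ",
         paste(basename(paths[which(na != na[1L])]), collapse = ", "))
  }
  if (length(unique(nf)) != 1L) {
    stop("inconsistent frame counts across files: ",
         paste(basename(paths[which(nf != nf[1L])]), collapse = ", "))
  }
  coords <- array(0, c(length(trajs), nf[1L], na[1L], 3L))
  for (i in seq_along(trajs)) coords[i, , , ] <- trajs[[i]]$coords
  structure(list(coords = coords, elements = trajs[[1L]]$elements,
                 times = (seq_len(nf[1L]) - 1L) * dt),
            class = "donkey_ensemble")
}

.read_xyz_file <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list()
  elements <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(na) || na <= 0L) {
      stop(sprintf("%s: line %d: expected an atom count, got '%s'",
                   basename(path), pos, lines[pos]))
    }
    if (pos + 1L + na > length(lines)) {
      stop(sprintf("%s: truncated frame starting at line %d",
                   basename(path), pos))
    }
    block <- lines[(pos + 2L):(pos + 1L + na)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(vapply(toks, length, integer(1)) < 4L)
    xyz <- matrix(NA_real_, na, 3L)
    el <- character(na)
    for (j in seq_len(na)) {
      tk <- toks[[j]]
      if (length(tk) < 4L) {
        stop(sprintf("%s: line %d: malformed coordinate line",
                     basename(path), pos + 1L + j))
      }
      v <- suppressWarnings(as.numeric(tk[2:4]))
      if (anyNA(v)) {
        stop(sprintf("%s: line %d: malformed coordinate line",
                     basename(path), pos + 1L + j))
      }
      el[j] <- tk[1L]
      xyz[j, ] <- v
    }
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + na
  }
  if (!length(frames)) stop(basename(path), ": no frames found")
  coords <- array(0, c(length(frames), nrow(frames[[1L]]), 3L))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  list(coords = coords, elements = elements)
}

#' Write one trajectory as a multi-frame XYZ file
#'
#' @param coords array `n_frames x n_atoms x 3` (Angstrom).
#' @param elements character vector of element symbols.
#' @param path output file.
#' @param comments optional per-frame comment lines.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(coords, elements, path, comments = NULL) {
  nf <- dim(coords)[1L]
  na <- dim(coords)[2L]
  if (is.null(comments)) comments <- sprintf("frame %d", seq_len(nf))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(as.character(na), con)
    writeLines(comments[f], con)
    writeLines(sprintf("%s %.10f %.10f %.10f", elements,
                       coords[f, , 1L], coords[f, , 2L], coords[f, , 3L]),
               con)
  }
  invisible(path)
}

#' @export
print.donkey_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat("Trajectory ensemble: ", d[1L], " trajectories x ", d[2L],
      " frames x ", d[3L], " atoms (dt = ",
      format(x$times[2L] - x$times[1L]), " fs)\n", sep = "")
  invisible(x)
}

#' Internal-coordinate features of a four-atom motif
#'
#' For key atoms C1..C4, computes per frame the wing separation
#' `(R12 + R34)/2`, the (signed) rhombicity `R13 - R24`, and the wing length
#' `(R14 + R23)/2`, where `Rab` is the C_a - C_b distance, plus their rates
#' of change by central finite differences over the time grid (one-sided at
#' the ends). These six features are the frame-wise clustering space.
#'
#' @param ensemble a `donkey_ensemble`.
#' @param atoms integer indices of the four key atoms (default `1:4`).
#' @param abs_rhombicity use `|R13 - R24|` instead of the signed difference.
#' @return object of class `donkey_features`: `values` (array
#'   `n_traj x n_frames x 6`), `feature_names`, `times`, `atoms`.
#' @export
compute_features <- function(ensemble, atoms = 1:4, abs_rhombicity = FALSE) {
  stopifnot(inherits(ensemble, "donkey_ensemble"), length(atoms) == 4L)
  d <- dim(ensemble$coords)
  if (any(atoms < 1L | atoms > d[3L])) stop("atom index out of range")
  if (d[2L] < 2L) stop("at least two frames are needed to compute rates")
  dist_pair <- function(i, j) {
    dx <- ensemble$coords[, , atoms[i], , drop = FALSE] -
          ensemble$coords[, , atoms[j], , drop = FALSE]
    sqrt(apply(dx^2, c(1L, 2L), sum))
  }
  r12 <- dist_pair(1L, 2L); r34 <- dist_pair(3L, 4L)
  r13 <- dist_pair(1L, 3L); r24 <- dist_pair(2L, 4L)
  r14 <- dist_pair(1L, 4L); r23 <- dist_pair(2L, 3L)
  wing_sep <- (r12 + r34) / 2
  rhomb <- r13 - r24
  if (abs_rhombicity) rhomb <- abs(rhomb)
  wing_len <- (r14 + r23) / 2
  rate <- function(f) {
    t_ <- ensemble$times
    nf <- length(t_)
    out <- f
    if (nf > 2L) {
      out[, 2:(nf - 1L)] <- (f[, 3:nf, drop = FALSE] -
                             f[, 1:(nf - 2L), drop = FALSE]) /
        rep(t_[3:nf] - t_[1:(nf - 2L)], each = nrow(f))
    }
    out[, 1L] <- (f[, 2L] - f[, 1L]) / (t_[2L] - t_[1L])
    out[, nf] <- (f[, nf] - f[, nf - 1L]) / (t_[nf] - t_[nf - 1L])
    out
  }
  vals <- array(0, c(d[1L], d[2L], 6L))
  vals[, , 1L] <- wing_sep
  vals[, , 2L] <- rhomb
  vals[, , 3L] <- wing_len
  vals[, , 4L] <- rate(wing_sep)
  vals[, , 5L] <- rate(rhomb)
  vals[, , 6L] <- rate(wing_len)
  structure(list(
    values = vals,
    feature_names = c("wing_separation", "rhombicity", "wing_length",
                      "d_wing_separation", "d_rhombicity", "d_wing_length"),
    times = ensemble$times, atoms = atoms
  ), class = "donkey_features")
}

#' Reduce a frame's feature matrix by principal components
#'
#' Mean-centred PCA keeping exactly the components whose explained-variance
#' ratio exceeds the threshold; the leading component is always kept. The
#' reduction is recomputed independently for every clustered frame.
#'
#' @param frame_matrix N x F numeric matrix (one row per trajectory).
#' @param evr_threshold explained-variance-ratio cut (default 0.01).
#' @return N x d matrix of principal-component scores (d >= 1), with the
#'   retained explained-variance ratios as attribute `"evr"`.
#' @export
reduce_features <- function(frame_matrix, evr_threshold = 0.01) {
  frame_matrix <- as.matrix(frame_matrix)
  if (nrow(frame_matrix) < 2L) stop("need at least two rows")
  pc <- stats::prcomp(frame_matrix, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot == 0) {
    warning("zero-variance feature matrix; returning a single zero column")
    out <- matrix(0, nrow(frame_matrix), 1L)
    attr(out, "evr") <- 1
    return(out)
  }
  evr <- pc$sdev^2 / tot
  d <- max(1L, sum(evr > evr_threshold))
  out <- pc$x[, seq_len(d), drop = FALSE]
  attr(out, "evr") <- evr[seq_len(d)]
  out
}

#' Cluster a trajectory ensemble frame by frame
#'
#' At every clustering frame (multiples of `frame_interval` on the time
#' grid), assembles the per-trajectory six-feature matrix, reduces it by PCA,
#' and runs the full density-based clustering pipeline. Each frame is
#' clustered independently.
#'
#' @param features a `donkey_features`.
#' @param frame_interval clustering cadence in the time units of the grid
#'   (default 5 fs).
#' @param evr_threshold passed to [reduce_features()].
#' @param ... further arguments passed to [donkey()] (e.g. `alpha`, `beta`).
#' @return named list keyed by time (`"t=<fs>"`), each element holding
#'   `time`, `labels`, `n_clusters`, `reduced_dim`, and the full `result`.
#' @export
cluster_frames <- function(features, frame_interval = 5, evr_threshold = 0.01,
                           ...) {
  stopifnot(inherits(features, "donkey_features"))
  t_ <- features$times
  sel <- which(abs(t_ / frame_interval - round(t_ / frame_interval)) < 1e-9)
  out <- list()
  for (fi in sel) {
    mat <- features$values[, fi, ]
    red <- reduce_features(mat, evr_threshold)
    res <- donkey(red, ...)
    out[[sprintf("t=%g", t_[fi])]] <- list(
      time = t_[fi],
      labels = res$labels,
      n_clusters = length(res$maxima),
      reduced_dim = ncol(red),
      result = res
    )
  }
  out
}

#' Assemble trajectories into channels from checkpoint frames
#'
#' A channel is a distinct tuple of cluster labels over the chosen checkpoint
#' times: trajectories that cluster identically at every checkpoint share a
#' channel. Channels are reported with member counts, sorted descending.
#'
#' @param frame_results output of [cluster_frames()].
#' @param checkpoint_times numeric times (must all have been clustered).
#' @return object of class `donkey_channels`: `channel` (per-trajectory
#'   channel id), `key` (per-trajectory label tuple as a string), and
#'   `table` (data frame of channels with counts, descending).
#' @export
assemble_channels <- function(frame_results, checkpoint_times) {
  keys <- sprintf("t=%g", checkpoint_times)
  missing <- setdiff(keys, names(frame_results))
  if (length(missing)) {
    stop("no clustering result at checkpoint(s): ",
         paste(missing, collapse = ", "))
  }
  lab <- sapply(keys, function(k) frame_results[[k]]$labels)
  tuples <- apply(as.matrix(lab), 1L, paste, collapse = "|")
  counts <- sort(table(tuples), decreasing = TRUE)
  channel <- match(tuples, names(counts))
  structure(list(
    channel = channel,
    key = tuples,
    checkpoint_times = checkpoint_times,
    table = data.frame(channel = seq_along(counts),
                       key = names(counts),
                       n = as.integer(counts), row.names = NULL)
  ), class = "donkey_channels")
}

#' @export
print.donkey_channels <- function(x, ...) {
  cat("Channel assignment over checkpoints t = ",
      paste(x$checkpoint_times, collapse = ", "), " fs: ",
      nrow(x$table), " channel(s)\n", sep = "")
  print(x$table)
  invisible(x)
}

## ---- synthetic branching ensemble -----------------------------------------

# Four-atom planar motif realizing prescribed (wing separation w, rhombicity
# rho, wing length L): a sheared trapezoid with top edge offset s solved from
# rho; vertical separation v = sqrt(L^2 - s^2).
.motif_geometry <- function(w, rho, L) {
  f <- function(s) sqrt((w - s)^2 + L^2 - s^2) -
                   sqrt((w + s)^2 + L^2 - s^2) - rho
  smax <- 0.999 * L
  s <- stats::uniroot(f, c(-smax, smax), tol = 1e-12)$root
  v <- sqrt(max(L^2 - s^2, 0))
  rbind(c(-w / 2 + s,  v / 2, 0),
        c( w / 2 + s,  v / 2, 0),
        c( w / 2,     -v / 2, 0),
        c(-w / 2,     -v / 2, 0))
}

# Default template paths: a common approach followed by a rhombicity
# bifurcation at branch_times[1] (+/- branches) and a wing-separation
# bifurcation at branch_times[2] (product-like vs returning), giving four
# channels. A smooth ramp models each transition.
.default_templates <- function(times, branch_times) {
  ramp <- function(t0, width = 4) 0.5 * (1 + tanh((times - t0) / width))
  mk <- function(rho_sign, w_dir) {
    w <- 2.5 - 0.5 * ramp(branch_times[1L]) +
         w_dir * 0.6 * ramp(branch_times[2L])
    rho <- rho_sign * 0.8 * ramp(branch_times[1L])
    L <- 1.5 + 0.1 * ramp(branch_times[1L])
    cbind(wing_separation = w, rhombicity = rho, wing_length = L)
  }
  list(mk(+1, +1), mk(+1, -1), mk(-1, +1), mk(-1, -1))
}

#' Generate a synthetic branching trajectory ensemble
#'
#' Emulates a photochemical trajectory swarm that bifurcates into distinct
#' reaction channels: smooth template paths in the three internal-coordinate
#' features (wing separation, rhombicity, wing length), perturbed per
#' trajectory by constant Gaussian offsets, and realized as four-atom
#' Cartesian geometries whose pairwise distances reproduce those features.
#' With `noise_sd = 0` every trajectory coincides exactly with its template.
#'
#' @param n_traj number of trajectories (split evenly over the templates).
#' @param n_frames frames per trajectory.
#' @param dt time step (fs).
#' @param branch_times times of the two bifurcations (fs), used by the
#'   default templates.
#' @param path_templates optional list of `n_frames x 3` feature matrices
#'   (columns: wing separation, rhombicity, wing length), one per channel.
#' @param noise_sd standard deviation of the per-trajectory feature offsets.
#' @param seed RNG seed.
#' @return list with `ensemble` (a `donkey_ensemble`), `truth_channels`
#'   (generating template index per trajectory), and `templates`.
#' @export
make_branching_ensemble <- function(n_traj = 40L, n_frames = 41L, dt = 1,
                                    branch_times = c(10, 25),
                                    path_templates = NULL, noise_sd = 0.02,
                                    seed = 1L) {
  times <- (seq_len(n_frames) - 1L) * dt
  if (is.null(path_templates)) {
    path_templates <- .default_templates(times, branch_times)
  }
  if (length(unique(vapply(path_templates, nrow, integer(1)))) != 1L ||
      nrow(path_templates[[1L]]) != n_frames) {
    stop("all path templates must have n_frames rows")
  }
  k <- length(path_templates)
  counts <- .even_split(n_traj, k)
  truth <- rep(seq_len(k), counts)
  .with_seed(seed, {
    coords <- array(0, c(n_traj, n_frames, 4L, 3L))
    for (i in seq_len(n_traj)) {
      tpl <- path_templates[[truth[i]]]
      offset <- stats::rnorm(3L, sd = noise_sd)
      feats <- sweep(tpl, 2L, -offset)
      for (f in seq_len(n_frames)) {
        coords[i, f, , ] <- .motif_geometry(feats[f, 1L], feats[f, 2L],
                                            feats[f, 3L])
      }
    }
    ensemble <- structure(list(coords = coords,
                               elements = rep("C", 4L), times = times),
                          class = "donkey_ensemble")
    list(ensemble = ensemble, truth_channels = truth,
         templates = path_templates)
  })
}
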