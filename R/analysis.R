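#' Sort replica trajectories into constant-parameter trajectories
#'
#' Demultiplexes the frames of a [run_grest()] result by rung: the frame
#' recorded from replica a at time t is assigned to the rung m(a, t) the
#' replica held at that time.  The rung-1 stream (largest scaling
#' parameter, i.e. the unscaled ensemble) is the primary analysis
#' trajectory.
#'
#' @param run a `grest_run`.
#' @return Object of class `sorted_trajectory`: a list with one element per
#'   rung, each holding `coords` (list of n x 3 matrices), `sweep`,
#'   `replica` (source replica per frame), and `E_scaled` (the scaled total
#'   energy E_m at that rung).
#' @export
sort_by_parameter <- function(run) {
  if (!inherits(run, "grest_run")) stop("run must be a grest_run")
  fr <- run$frames
  if (anyNA(fr$param)) stop("exchange log does not cover every frame time")
  M <- run$config$M
  out <- lapply(seq_len(M), function(m) {
    idx <- which(fr$param == m)
    idx <- idx[order(fr$sweep[idx])]
    list(coords = fr$coords[idx], sweep = fr$sweep[idx],
         replica = fr$replica[idx], E_scaled = fr$E_scaled[idx])
  })
  names(out) <- paste0("m", seq_len(M))
  structure(out, class = "sorted_trajectory", M = M)
}

#' Kabsch-superposed RMSD of trajectory frames against a reference
#'
#' Each frame is optimally superposed (rotation + translation) onto the
#' reference using the atoms in `fit_selection`, then the RMSD is evaluated
#' over `rmsd_selection`.  The two selections are independent; by default
#' both equal the full atom set (set them to the loop atoms to reproduce
#' the loop-RMSD protocol).
#'
#' @param frames list of n x 3 coordinate matrices (or a single matrix).
#' @param reference n x 3 reference coordinates.
#' @param fit_selection atom indices used for superposition (>= 3,
#'   non-collinear).
#' @param rmsd_selection atom indices over which the RMSD is computed.
#' @return Numeric vector of per-frame RMSD values.
#' @export
rmsd_traj <- function(frames, reference,
                      fit_selection = seq_len(nrow(reference)),
                      rmsd_selection = fit_selection) {
  if (is.matrix(frames)) frames <- list(frames)
  reference <- as.matrix(reference)
  if (length(fit_selection) < 3) stop("need at least 3 fit atoms")
  if (length(rmsd_selection) < 1) stop("rmsd selection is empty")
  ref_fit <- reference[fit_selection, , drop = FALSE]
  if (.collinear(ref_fit)) stop("fit atoms are collinear; superposition is degenerate")
  fx <- as.vector(t(reference))
  fit_xyz <- as.vector(t(cbind(3 * (fit_selection - 1) + 1,
                               3 * (fit_selection - 1) + 2,
                               3 * (fit_selection - 1) + 3)))
  vapply(frames, function(fr) {
    fr <- as.matrix(fr)
    if (!all(dim(fr) == dim(reference))) stop("frame/reference atom count mismatch")
    mob <- matrix(as.vector(t(fr)), nrow = 1)
    fitted <- bio3d::fit.xyz(fixed = fx, mobile = mob,
                             fixed.inds = fit_xyz, mobile.inds = fit_xyz)
    fitted <- matrix(fitted[1, ], ncol = 3, byrow = TRUE)
    d <- fitted[rmsd_selection, , drop = FALSE] -
      reference[rmsd_selection, , drop = FALSE]
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
}

.collinear <- function(x) {
  x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)$d
  sum(sv > max(sv) * 1e-8) < 2
}

#' Principal component analysis on pairwise-distance features
#'
#' Per frame, the feature vector is the flattened upper triangle of the
#' pairwise-distance matrix over the selected atoms (superposition-free by
#' construction).  Features are mean-centred and eigen-decomposed; each
#' component is oriented so that its largest-magnitude loading is positive.
#'
#' @param frames list of n x 3 coordinate matrices (>= 2 frames).
#' @param atom_selection indices of the atoms entering the distance matrix
#'   (>= 2).
#' @param n_components number of components to return; truncated with a
#'   warning if it exceeds the feature rank.
#' @return List with `scores` (frames x components), `eigenvalues`
#'   (non-increasing, all components), and `loadings`.
#' @export
distance_matrix_pca <- function(frames, atom_selection, n_components = 2) {
  if (length(frames) < 2) stop("need at least 2 frames")
  if (length(atom_selection) < 2) stop("need at least 2 selected atoms")
  feats <- t(vapply(frames, function(fr) {
    as.vector(stats::dist(as.matrix(fr)[atom_selection, , drop = FALSE]))
  }, numeric(length(atom_selection) * (length(atom_selection) - 1) / 2)))
  pc <- stats::prcomp(feats, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  rank <- sum(eig > max(eig, 0) * 1e-12)
  if (n_components > rank) {
    warning(sprintf("n_components = %d exceeds feature rank %d; truncated",
                    n_components, rank))
    n_components <- max(rank, 1L)
  }
  keep <- seq_len(n_components)
  scores <- pc$x[, keep, drop = FALSE]
  loadings <- pc$rotation[, keep, drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, eigenvalues = eig, loadings = loadings)
}

#' Exchange statistics from a gREST run
#'
#' @param run a `grest_run` (or its exchange log together with a mapping
#'   history via the `mapping_history` argument).
#' @param mapping_history optional matrix (phases + 1) x M of rung indices
#'   per replica; taken from `run` when `run` is a `grest_run`.
#' @return Object of class `exchange_stats`: list with `pairs` (data.frame:
#'   pair, attempts, accepted, ratio, se; zero-attempt pairs keep `ratio =
#'   NA`), `paths` (matrix, rung index of each replica over phases), and
#'   `round_trips` (per replica, completed rung-1 -> rung-M -> rung-1
#'   traversals).
#' @export
exchange_statistics <- function(run, mapping_history = NULL) {
  if (inherits(run, "grest_run")) {
    log <- run$exchange_log
    mapping_history <- run$mapping_history
    M <- run$config$M
  } else {
    log <- run
    if (is.null(mapping_history)) stop("mapping_history required with a raw log")
    M <- ncol(mapping_history)
  }
  pairs <- data.frame(pair = seq_len(max(M - 1, 0)))
  pairs$attempts <- vapply(pairs$pair, function(m) sum(log$pair == m), integer(1))
  pairs$accepted <- vapply(pairs$pair, function(m)
    sum(log$accepted[log$pair == m]), integer(1))
  pairs$ratio <- ifelse(pairs$attempts > 0, pairs$accepted / pairs$attempts, NA)
  pairs$se <- ifelse(pairs$attempts > 0,
                     sqrt(pmax(pairs$ratio * (1 - pairs$ratio), 0) / pairs$attempts),
                     NA)
  paths <- t(mapping_history)  # M x (phases + 1)
  round_trips <- apply(paths, 1, function(p) .count_round_trips(p, M))
  structure(list(pairs = pairs, paths = paths, round_trips = round_trips),
            class = "exchange_stats")
}

.count_round_trips <- function(path, M) {
  if (M < 2) return(0L)
  trips <- 0L
  stage <- 0L  # 0: waiting for rung 1; 1: seen 1, waiting for M; 2: seen M, waiting for 1
  for (m in path) {
    if (stage == 0L && m == 1L) stage <- 1L
    else if (stage == 1L && m == M) stage <- 2L
    else if (stage == 2L && m == 1L) { trips <- trips + 1L; stage <- 1L }
  }
  trips
}

#' @export
print.exchange_stats <- function(x, ...) {
  cat("exchange_stats:\n")
  print(x$pairs, row.names = FALSE)
  cat(sprintf("round trips per replica: %s\n",
              paste(x$round_trips, collapse = ", ")))
  invisible(x)
}

#' Energy-RMSD diagnostic on the rung-1 trajectory
#'
#' Emits per-frame (RMSD, scaled total energy E_m) pairs for the rung-1
#' stream and their Pearson correlation.  A positive correlation (lower
#' energy at lower RMSD) indicates that the tempered ensemble ranks the
#' reference basin as the stable state.
#'
#' @param sorted a `sorted_trajectory` (uses its rung-1 stream) or one
#'   stream element of it.
#' @param reference n x 3 reference coordinates.
#' @param fit_selection,rmsd_selection passed to [rmsd_traj()].
#' @return List with `rmsd`, `energy`, `pearson_r`, and `undefined`
#'   (TRUE when either series has zero variance, in which case
#'   `pearson_r` is NA).
#' @export
energy_rmsd_correlation <- function(sorted, reference,
                                    fit_selection = seq_len(nrow(reference)),
                                    rmsd_selection = fit_selection) {
  stream <- if (inherits(sorted, "sorted_trajectory")) sorted[[1]] else sorted
  if (is.null(stream$E_scaled)) stop("stream carries no per-frame scaled energies")
  r <- rmsd_traj(stream$coords, reference, fit_selection, rmsd_selection)
  e <- stream$E_scaled
  undefined <- stats::var(r) == 0 || stats::var(e) == 0
  list(rmsd = r, energy = e,
       pearson_r = if (undefined) NA_real_ else stats::cor(r, e),
       undefined = undefined)
}

#' Measure a dihedral angle over frames
#'
#' IUPAC-sign dihedral defined by four atom indices, in radians in
#' (-pi, pi].
#'
#' @param frames list of n x 3 matrices or a single matrix.
#' @param atoms integer vector of 4 atom indices.
#' @return Numeric vector of angles.
#' @export
measure_dihedral <- function(frames, atoms) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(atoms) == 4)
  vapply(frames, function(fr) {
    fr <- as.matrix(fr)
    b1 <- fr[atoms[2], ] - fr[atoms[1], ]
    b2 <- fr[atoms[3], ] - fr[atoms[2], ]
    b3 <- fr[atoms[4], ] - fr[atoms[3], ]
    n1 <- .cross(b1, b2); n2 <- .cross(b2, b3)
    atan2(sum(.cross(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
  }, numeric(1))
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Count cis/trans well transitions of a dihedral series
#'
#' Classifies each angle as cis (|phi| < pi/2) or trans and counts the
#' changes of label along the series.
#'
#' @param phi numeric vector of dihedral angles (radians).
#' @return Integer transition count.
#' @export
count_well_transitions <- function(phi) {
  lab <- abs(phi) < pi / 2
  if (length(lab) < 2) return(0L)
  sum(lab[-1] != lab[-length(lab)])
}
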