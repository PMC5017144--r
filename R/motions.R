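#' @title Correlated motions and gate geometry
#' @description Generalized correlation coefficients from the linear mutual
#'   information (LMI) between residues' C-alpha displacement distributions,
#'   LMI(i,j) = (1/2) [ln det C_i + ln det C_j - ln det C_ij] and
#'   r_LMI = sqrt(1 - exp(-2 LMI / 3)), plus the gate-geometry metrics used
#'   to follow channel opening: quadrilateral areas spanned by four gate
#'   atoms, per-chain distances to the pore axis, and helix bend angles.
#' @name motions
NULL

#' Displacement covariance blocks from a trajectory
#'
#' Superposes every frame onto frame 1 using `fit_indices` (rigid-body
#' least squares), then computes the covariance of the selected atoms'
#' coordinates about their trajectory mean.  The per-residue 3x3 blocks
#' C_i and per-pair 6x6 blocks C_ij are slices of the stored full matrix.
#'
#' @param traj A [trajectory3d()] with at least 10 frames.
#' @param ca_indices Atom indices (typically one C-alpha per residue) whose
#'   motions are analysed, in residue order.
#' @param fit_indices Atoms used for the per-frame superposition onto frame
#'   1 — pass a selection that is stationary relative to the motions of
#'   interest (fitting on the analysed atoms themselves would subtract the
#'   very displacements being correlated).  `NULL` (default) skips the fit
#'   and uses raw coordinates.
#' @return A `cov_blocks`: list with `cov` (3m x 3m), `residues` (data
#'   frame: chain, resno, resname), and `m`.
#' @export
covariance_blocks <- function(traj, ca_indices, fit_indices = NULL) {
  stopifnot(inherits(traj, "trajectory3d"))
  nf <- n_frames(traj)
  if (nf < 10L) stop("need at least 10 frames for covariances")
  m <- length(ca_indices)
  ref <- traj$coords[, , 1L]
  X <- matrix(NA_real_, nf, 3L * m)
  for (f in seq_len(nf)) {
    xyz <- if (is.null(fit_indices)) traj$coords[, , f]
           else superpose(traj$coords[, , f], ref, fit_indices)$xyz
    X[f, ] <- as.vector(t(xyz[ca_indices, , drop = FALSE]))
  }
  at <- traj$topology$atoms[ca_indices, ]
  structure(list(cov = stats::cov(X), m = m,
                 residues = data.frame(chain = at$chain, resno = at$resno,
                                       resname = at$resname,
                                       stringsAsFactors = FALSE)),
            class = "cov_blocks")
}

logdet_chol <- function(M) 2 * sum(log(diag(chol(M))))

#' LMI generalized correlation matrix
#'
#' For every residue pair the linear mutual information is computed from
#' the 3x3 marginal and 6x6 joint displacement covariances (regularized by
#' `eps` on the diagonal) and mapped to the generalized correlation
#' coefficient r_LMI = sqrt(1 - exp(-2 LMI / 3)) in [0, 1].  The diagonal
#' is 1 by definition.
#'
#' @param blocks A `cov_blocks` from [covariance_blocks()].
#' @param eps Diagonal regularization (Angstrom^2, default 1e-8).
#' @return An `lmi_result`: list with symmetric matrix `r` and the residue
#'   table.
#' @export
lmi_matrix <- function(blocks, eps = 1e-8) {
  stopifnot(inherits(blocks, "cov_blocks"))
  m <- blocks$m
  C <- blocks$cov + diag(eps, 3L * m)
  ld1 <- numeric(m)
  for (i in seq_len(m)) {
    ii <- (3L * (i - 1L) + 1L):(3L * i)
    ld1[i] <- tryCatch(logdet_chol(C[ii, ii]),
                       error = function(e) stop("residue block ", i,
                                                " not positive definite"))
  }
  r <- diag(1, m)
  for (i in seq_len(m - 1L)) {
    ii <- (3L * (i - 1L) + 1L):(3L * i)
    for (j in (i + 1L):m) {
      jj <- (3L * (j - 1L) + 1L):(3L * j)
      Cij <- C[c(ii, jj), c(ii, jj)]
      ldij <- tryCatch(logdet_chol(Cij), error = function(e) NA_real_)
      lmi <- if (is.na(ldij)) Inf else 0.5 * (ld1[i] + ld1[j] - ldij)
      lmi <- max(lmi, 0)  # Fischer inequality can be violated numerically
      val <- sqrt(1 - exp(-2 * lmi / 3))
      r[i, j] <- r[j, i] <- min(max(val, 0), 1)
    }
  }
  structure(list(r = r, residues = blocks$residues), class = "lmi_result")
}

#' Residues correlated with a reference residue
#'
#' Returns the residues whose r_LMI with the reference reaches `threshold`,
#' reported per chain so single-subunit (asymmetric) correlation patterns
#' are visible.
#'
#' @param result An `lmi_result`.
#' @param reference Row index into `result$residues`, or a list/data frame
#'   row with `chain` and `resno`.
#' @param threshold r_LMI cutoff (default 0.7); membership uses `>=`.
#' @return Data frame of the selected residues (chain, resno, resname,
#'   r_lmi), ordered by chain then residue number.
#' @export
correlated_region <- function(result, reference, threshold = 0.7) {
  stopifnot(inherits(result, "lmi_result"))
  res <- result$residues
  if (is.numeric(reference) && length(reference) == 1L) {
    ref <- as.integer(reference)
  } else {
    ref <- which(res$chain == reference$chain & res$resno == reference$resno)
    if (length(ref) != 1L) stop("reference residue not found (or ambiguous)")
  }
  if (ref < 1L || ref > nrow(res)) stop("reference index out of range")
  sel <- which(result$r[ref, ] >= threshold)
  out <- cbind(res[sel, , drop = FALSE],
               data.frame(r_lmi = result$r[ref, sel]))
  out <- out[order(out$chain, out$resno), ]
  rownames(out) <- NULL
  out
}

#' Area of a quadrilateral spanned by four atoms
#'
#' Points are ordered by azimuth about the pore axis (default: the z-axis
#' through their centroid), then the area is the sum of the two triangles
#' obtained by splitting along one diagonal.  Collinear input degenerates
#' to zero with a warning.  The area is invariant under rigid motion and
#' cyclic relabeling.
#'
#' @param points Numeric 4 x 3 matrix.
#' @param axis_point Point on the ordering axis (default: centroid).
#' @param axis Axis direction (default z).
#' @return Area in Angstrom^2.
#' @export
quadrilateral_area <- function(points, axis_point = NULL, axis = c(0, 0, 1)) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) != 4L) stop("exactly four points required")
  if (anyDuplicated(points)) stop("points must be distinct")
  if (is.null(axis_point)) axis_point <- colMeans(points)
  axis_point <- as.numeric(axis_point)
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  rel <- sweep(points, 2, axis_point)
  # in-plane components for azimuthal ordering
  e1 <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- e1 - sum(e1 * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  ang <- atan2(rel %*% e2, rel %*% e1)
  p <- points[order(ang), , drop = FALSE]
  tri <- function(a, b, c) {
    v1 <- b - a; v2 <- c - a
    0.5 * sqrt(sum(c(v1[2] * v2[3] - v1[3] * v2[2],
                     v1[3] * v2[1] - v1[1] * v2[3],
                     v1[1] * v2[2] - v1[2] * v2[1])^2))
  }
  area <- tri(p[1, ], p[2, ], p[3, ]) + tri(p[1, ], p[3, ], p[4, ])
  if (area < 1e-9) warning("degenerate (collinear) quadrilateral; area 0")
  area
}

#' Per-frame quadrilateral-area series for a gate
#'
#' @param traj A [trajectory3d()].
#' @param atom_indices Four atom indices (e.g. the gate residue's C-alpha
#'   in each of the four chains).
#' @return Numeric vector, one area (Angstrom^2) per frame.
#' @export
gate_area_series <- function(traj, atom_indices) {
  stopifnot(inherits(traj, "trajectory3d"), length(atom_indices) == 4L)
  vapply(seq_len(n_frames(traj)), function(f)
    quadrilateral_area(traj$coords[atom_indices, , f]), 1.0)
}

#' Per-frame, per-chain distances to the pore axis
#'
#' The pore axis is the vertical (z) line through the per-frame centroid of
#' `axis_indices` (default: the selected atoms themselves).  Distances are
#' perpendicular (in-plane) and reported individually per selected atom,
#' not averaged over chains.
#'
#' @param traj A [trajectory3d()].
#' @param atom_indices Atoms to track (e.g. one C-alpha per chain).
#' @param axis_indices Atoms whose centroid defines the axis.
#' @return Matrix frames x atoms; columns named by chain.
#' @export
axis_distance_series <- function(traj, atom_indices, axis_indices = atom_indices) {
  stopifnot(inherits(traj, "trajectory3d"))
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nf, length(atom_indices))
  for (f in seq_len(nf)) {
    ax <- matrix(traj$coords[axis_indices, 1:2, f], ncol = 2L)
    ctr <- colMeans(ax)
    p <- matrix(traj$coords[atom_indices, 1:2, f], ncol = 2L)
    out[f, ] <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
  }
  colnames(out) <- traj$topology$atoms$chain[atom_indices]
  out
}

# least-squares 3D line direction through points, oriented first -> last
segment_axis <- function(p) {
  ctr <- colMeans(p)
  v <- svd(sweep(p, 2, ctr))$v[, 1L]
  if (sum(v * (p[nrow(p), ] - p[1L, ])) < 0) v <- -v
  v
}

#' Helix bend-angle series
#'
#' Splits an ordered C-alpha trace at a pivot residue, fits a least-squares
#' 3D axis to each flank (at least 4 residues per flank) and reports the
#' angle between the two axes per frame; 0 degrees = straight.  This is a
#' simplified kink metric, not a full local-curvature (Bendix-style)
#' analysis.
#'
#' @param traj A [trajectory3d()].
#' @param ca_indices Ordered C-alpha atom indices along the helix.
#' @param pivot Position of the pivot within `ca_indices`.
#' @return Numeric vector of per-frame bend angles in degrees.
#' @export
bend_angle_series <- function(traj, ca_indices, pivot) {
  stopifnot(inherits(traj, "trajectory3d"))
  pivot <- as.integer(pivot)
  if (pivot < 4L || pivot > length(ca_indices) - 3L ||
      pivot - 1L < 3L || length(ca_indices) - pivot < 3L)
    stop("need at least 4 residues on each side of the pivot")
  i1 <- ca_indices[1:pivot]
  i2 <- ca_indices[pivot:length(ca_indices)]
  if (length(i1) < 4L || length(i2) < 4L)
    stop("need at least 4 residues on each side of the pivot")
  vapply(seq_len(n_frames(traj)), function(f) {
    a1 <- segment_axis(traj$coords[i1, , f])
    a2 <- segment_axis(traj$coords[i2, , f])
    acos(min(max(sum(a1 * a2), -1), 1)) * 180 / pi
  }, 1.0)
}
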