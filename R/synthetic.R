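#' @title Synthetic channels, alkanes and trajectories with known ground truth
#' @description Generators for the test fixtures used throughout the
#'   package: four-fold symmetric channel walls with a prescribed accessible
#'   radius profile and hydrophobic/hydrophilic residue rings (optionally
#'   occluded by plug disks), all-anti n-alkane model compounds for the
#'   methylene surface calibration, and trajectories with prescribed
#'   correlated motions and a single-subunit opening event.  Every generator
#'   is deterministic for a fixed seed.
#' @name synthetic_data
NULL

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Channel geometry specification
#'
#' Describes a pseudo-atomic channel: wall rings stacked along z with
#' `n_fold` rotational symmetry, an accessible-radius profile (the radius a
#' probe sees, i.e. wall atom centres sit at `radius_profile(z) + wall
#' atom vdW radius`), a per-ring hydrophobicity pattern, and optional plug
#' disks that locally occlude the lumen.
#'
#' @param radius_profile Function z (Angstrom) -> accessible radius (Angstrom).
#' @param z_range Channel extent along z (Angstrom).
#' @param spacing Wall atom spacing within and between rings (Angstrom).
#' @param ring_pattern Function z -> `"phobic"` or `"philic"` wall character.
#' @param plugs Numeric vector of z positions of occluding plug disks.
#' @param n_fold Rotational symmetry order (chains are angular sectors).
#' @param atom_radius Pseudo-atom vdW radius (Angstrom).
#' @param wall_layers Number of concentric wall shells (>= 2 emulates the
#'   thick protein wall of a real channel, which keeps the exterior surface
#'   well away from the pore cavity).
#' @param layer_gap Radial gap between wall shells (Angstrom).
#' @return A `channel_spec` list.
#' @export
channel_spec <- function(radius_profile = function(z) rep(5, length(z)),
                         z_range = c(-20, 20), spacing = 1.6,
                         ring_pattern = function(z) rep("philic", length(z)),
                         plugs = numeric(0), n_fold = 4L, atom_radius = 1.7,
                         wall_layers = 3L, layer_gap = 2.4) {
  stopifnot(is.function(radius_profile), is.function(ring_pattern),
            length(z_range) == 2L, z_range[1] < z_range[2], spacing > 0,
            wall_layers >= 1L, layer_gap > 0)
  structure(list(radius_profile = radius_profile, z_range = z_range,
                 spacing = spacing, ring_pattern = ring_pattern,
                 plugs = plugs, n_fold = as.integer(n_fold),
                 atom_radius = atom_radius,
                 wall_layers = as.integer(wall_layers), layer_gap = layer_gap),
            class = "channel_spec")
}

#' Build a synthetic channel structure
#'
#' Wall pseudo-atoms tile a surface of revolution whose accessible radius
#' follows `spec$radius_profile`; rings are labelled hydrophobic (`HPB`,
#' f = +1) or hydrophilic (`HPL`, f = -1) via the fixture constants.  Plug
#' positions are filled with atom disks (residue `PLG`).  Chains `A`..`D`
#' (for 4-fold) are angular quadrants so per-chain asymmetry reporting can be
#' exercised.
#'
#' @param spec A [channel_spec()].
#' @return A [structure3d()]; `atoms$role` marks `"wall"` vs `"plug"`.
#' @export
make_channel <- function(spec) {
  stopifnot(inherits(spec, "channel_spec"))
  zs <- seq(spec$z_range[1], spec$z_range[2], by = spec$spacing)
  rows <- list()
  chains <- LETTERS[seq_len(spec$n_fold)]
  for (iz in seq_along(zs)) {
    z <- zs[iz]
    r_acc <- spec$radius_profile(z)
    if (r_acc <= 0) stop("radius profile must be positive where walls are built")
    kind <- spec$ring_pattern(z)
    for (layer in seq_len(spec$wall_layers) - 1L) {
      r_wall <- r_acc + spec$atom_radius + layer * spec$layer_gap
      if (spec$spacing > r_wall) stop("wall spacing exceeds wall radius")
      per_sector <- max(1L, round(2 * pi * r_wall / (spec$spacing * spec$n_fold)))
      nat <- per_sector * spec$n_fold
      ang <- 2 * pi * (seq_len(nat) - 1L) / nat
      rows[[length(rows) + 1L]] <- data.frame(
        x = r_wall * cos(ang), y = r_wall * sin(ang), z = z,
        chain = chains[(floor(ang / (2 * pi) * spec$n_fold) %% spec$n_fold) + 1L],
        resno = iz,
        resname = if (identical(kind, "phobic")) "HPB" else "HPL",
        mhp_class = if (identical(kind, "phobic")) "WALL_PHOBIC" else "WALL_PHILIC",
        role = "wall", stringsAsFactors = FALSE)
    }
  }
  plug_res <- length(zs)
  for (zp in spec$plugs) {
    plug_res <- plug_res + 1L
    r_lumen <- spec$radius_profile(zp)
    radii <- seq(0, r_lumen, by = spec$spacing)
    for (rr in radii) {
      nat <- if (rr < 1e-9) 1L else max(spec$n_fold, round(2 * pi * rr / spec$spacing))
      ang <- 2 * pi * (seq_len(nat) - 1L) / nat
      rows[[length(rows) + 1L]] <- data.frame(
        x = rr * cos(ang), y = rr * sin(ang), z = zp,
        chain = "A", resno = plug_res, resname = "PLG",
        mhp_class = "WALL_PHOBIC", role = "plug", stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  atoms <- data.frame(id = seq_len(nrow(tab)),
                      name = "PS", element = "C",
                      resname = tab$resname, resno = tab$resno,
                      chain = tab$chain, vdw = spec$atom_radius,
                      f = NA_real_, mhp_class = tab$mhp_class,
                      role = tab$role, stringsAsFactors = FALSE)
  structure3d(atoms, cbind(tab$x, tab$y, tab$z), frame_label = "synthetic channel")
}

#' Build an n-alkane model compound
#'
#' All-anti united-atom chain (implicit hydrogens): C-C 1.53 Angstrom,
#' C-C-C 111.6 degrees, laid along x.  Terminal carbons are classed
#' `ALK_CH3`, internal ones `ALK_CH2`.
#'
#' @param n_carbons Chain length (>= 2); 5 = pentane, 6 = hexane.
#' @return A [structure3d()].
#' @export
make_alkane <- function(n_carbons) {
  n_carbons <- as.integer(n_carbons)
  if (n_carbons < 2L) stop("an alkane needs at least 2 carbons")
  bond <- 1.53
  half <- 111.6 / 2 * pi / 180
  a <- bond * sin(half)                 # axial advance per bond
  c_off <- bond * cos(half)             # zig-zag offset
  i <- seq_len(n_carbons) - 1L
  xyz <- cbind(i * a, 0, (i %% 2L) * c_off - c_off / 2)
  cls <- ifelse(i == 0L | i == n_carbons - 1L, "ALK_CH3", "ALK_CH2")
  atoms <- data.frame(id = seq_len(n_carbons),
                      name = paste0("C", seq_len(n_carbons)),
                      element = "C", resname = "ALK", resno = 1L,
                      chain = "A", vdw = 1.7, f = NA_real_,
                      mhp_class = cls, stringsAsFactors = FALSE)
  structure3d(atoms, xyz, frame_label = sprintf("n-alkane C%d", n_carbons))
}

#' Motion specification for synthetic trajectories
#'
#' @param n_frames Number of frames.
#' @param groups List of correlated-motion groups.  Each group is a list
#'   with `members` (a list of atom-index vectors; every member moves as a
#'   rigid unit), `amplitude` (per-axis sd of the common-mode displacement,
#'   Angstrom) and `rho` (cross-correlation of members 2.. with member 1).
#' @param ramp Optional single-chain displacement: list with `indices`
#'   (atoms), `direction` (3-vector or `"radial"`), `amplitude` (Angstrom)
#'   and `onset` (frame index at which the shift switches on).
#' @param noise_sd Independent per-atom Gaussian noise sd (Angstrom).
#' @param dt Frame spacing (ns).
#' @param seed RNG seed; the trajectory is bit-identical for a fixed seed.
#' @return A `motion_spec` list.
#' @export
motion_spec <- function(n_frames = 100L, groups = list(), ramp = NULL,
                        noise_sd = 0.1, dt = 0.2, seed = 1L) {
  for (g in groups) {
    stopifnot(is.list(g$members), length(g$members) >= 1L)
    if (!is.null(g$rho) && abs(g$rho) > 1) stop("rho must lie in [-1, 1]")
  }
  structure(list(n_frames = as.integer(n_frames), groups = groups,
                 ramp = ramp, noise_sd = noise_sd, dt = dt,
                 seed = as.integer(seed)),
            class = "motion_spec")
}

ramp_direction <- function(dir, base_xyz, idx) {
  if (identical(dir, "radial")) {
    v <- base_xyz[idx, 1:2, drop = FALSE]
    nr <- sqrt(rowSums(v^2))
    v <- cbind(ifelse(nr > 1e-9, v[, 1] / nr, 1),
               ifelse(nr > 1e-9, v[, 2] / nr, 0), 0)
    v
  } else {
    dir <- dir / sqrt(sum(dir^2))
    matrix(dir, nrow = length(idx), ncol = 3L, byrow = TRUE)
  }
}

#' Generate a synthetic trajectory
#'
#' Frames are the base coordinates plus (i) per-group Gaussian common modes
#' with the prescribed cross-correlation between group members, (ii) an
#' optional step displacement of one atom set from an onset frame, and
#' (iii) independent per-atom Gaussian noise.
#'
#' @param base A [structure3d()].
#' @param spec A [motion_spec()].
#' @return A [trajectory3d()].
#' @export
make_trajectory <- function(base, spec) {
  stopifnot(inherits(base, "structure3d"), inherits(spec, "motion_spec"))
  na <- n_atoms(base)
  nf <- spec$n_frames
  with_seed(spec$seed, {
    disp <- array(0, c(na, 3L, nf))
    for (g in spec$groups) {
      amp <- if (is.null(g$amplitude)) 1 else g$amplitude
      rho <- if (is.null(g$rho)) 1 else g$rho
      lead <- matrix(stats::rnorm(nf * 3L, sd = amp), nf, 3L)
      for (m in seq_along(g$members)) {
        mode <- if (m == 1L) lead else
          rho * lead + sqrt(1 - rho^2) * matrix(stats::rnorm(nf * 3L, sd = amp), nf, 3L)
        for (f in seq_len(nf))
          disp[g$members[[m]], , f] <- disp[g$members[[m]], , f] +
            matrix(mode[f, ], length(g$members[[m]]), 3L, byrow = TRUE)
      }
    }
    if (spec$noise_sd > 0)
      disp <- disp + array(stats::rnorm(length(disp), sd = spec$noise_sd), dim(disp))
    coords <- array(0, c(na, 3L, nf))
    for (f in seq_len(nf)) coords[, , f] <- base$xyz + disp[, , f]
    if (!is.null(spec$ramp)) {
      r <- spec$ramp
      dirs <- ramp_direction(r$direction, base$xyz, r$indices)
      for (f in seq_len(nf)) if (f >= r$onset)
        coords[r$indices, , f] <- coords[r$indices, , f] + dirs * r$amplitude
    }
    trajectory3d(base, coords, times = seq(0, by = spec$dt, length.out = nf))
  })
}

#' Generate a gating trajectory with a known opening event
#'
#' Builds the closed channel (walls + plugs), assigns all plug atoms to the
#' active chain, and from `onset_frame` on displaces them radially to the
#' wall so the lumen clears at the plug z-positions.  The returned
#' trajectory carries the ground truth in its `truth` element.
#'
#' @param closed A [channel_spec()] with at least one plug (the closed state).
#' @param onset_frame Frame at which the plugs clear (`Inf` for a
#'   never-opening control).
#' @param active_chain Chain label the moving plug atoms belong to.
#' @param n_frames,noise_sd,dt,seed Passed to the motion model.
#' @return A [trajectory3d()] with `$truth = list(onset_frame, plug_z,
#'   active_chain)`.
#' @export
make_gating_trajectory <- function(closed, onset_frame, active_chain = "A",
                                   n_frames = 10L, noise_sd = 0.05,
                                   dt = 0.2, seed = 1L) {
  stopifnot(inherits(closed, "channel_spec"))
  if (length(closed$plugs) == 0L) stop("closed spec must contain plug(s)")
  base <- make_channel(closed)
  plug_idx <- which(base$atoms$role == "plug")
  base$atoms$chain[plug_idx] <- active_chain
  ramp <- NULL
  if (is.finite(onset_frame)) {
    # radial shift large enough to tuck every plug atom into the wall
    max_shift <- max(closed$radius_profile(closed$plugs)) + closed$atom_radius +
      closed$layer_gap
    ramp <- list(indices = plug_idx, direction = "radial",
                 amplitude = max_shift, onset = onset_frame)
  }
  spec <- motion_spec(n_frames = n_frames, groups = list(), ramp = ramp,
                      noise_sd = noise_sd, dt = dt, seed = seed)
  traj <- make_trajectory(base, spec)
  traj$truth <- list(onset_frame = onset_frame, plug_z = closed$plugs,
                     active_chain = active_chain)
  traj
}
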