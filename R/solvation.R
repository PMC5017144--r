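#' @title Residue solvation energetics and heat-capacity estimators
#' @description Per-residue solvation energies from the atomic-solvation-
#'   parameter formalism, E_solv(residue) = sum over its atoms of
#'   ASP(atom class) x ASA(atom); ranking of open/closed solvation changes
#'   over trajectories; and the surface-MHP based methylene-equivalent and
#'   heat-capacity (delta C_P) estimators.
#' @name solvation_thermo
NULL

#' Solvent-accessible surface area (Shrake--Rupley)
#'
#' Point-counting ASA on a deterministic spiral lattice: `sphere_points`
#' test points per atom on the probe-extended sphere; a point is accessible
#' if outside every other atom's extended sphere.
#'
#' @param x A [structure3d()] with vdW radii assigned.
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param sphere_points Lattice points per atom (default 960).
#' @return Numeric vector of per-atom ASA in Angstrom^2.
#' @export
compute_asa <- function(x, probe = 1.4, sphere_points = 960L) {
  stopifnot(inherits(x, "structure3d"))
  xyz <- x$xyz
  ext <- x$atoms$vdw + probe
  n <- nrow(xyz)
  u <- fibonacci_sphere(sphere_points)
  asa <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(u * ext[i], 2, xyz[i, ], `+`)
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ext[i] + ext)^2 & seq_len(n) != i)
    keep <- rep(TRUE, sphere_points)
    for (j in nb) {
      if (!any(keep)) break
      keep[keep] <- rowSums(sweep(pts[keep, , drop = FALSE], 2, xyz[j, ])^2) >=
        ext[j]^2 * (1 - 1e-9)
    }
    asa[i] <- 4 * pi * ext[i]^2 * sum(keep) / sphere_points
  }
  asa
}

# atom -> Eisenberg-McLachlan solvation class; NA for unhandled elements
asp_classify <- function(atoms) {
  el <- toupper(atoms$element)
  key <- paste(atoms$resname, atoms$name)
  cls <- rep(NA_character_, nrow(atoms))
  cls[el == "C"] <- "C"
  cls[el == "S"] <- "S"
  cls[el %in% c("N", "O")] <- "N/O"
  carboxylate <- key %in% c("ASP OD1", "ASP OD2", "GLU OE1", "GLU OE2") |
    atoms$name == "OXT"
  cls[carboxylate] <- "O-"
  charged_n <- key %in% c("LYS NZ", "ARG NE", "ARG NH1", "ARG NH2")
  cls[charged_n] <- "N+"
  cls
}

#' Residue solvation energies (ASP x ASA)
#'
#' Multiplies each atom's solvation parameter by its accessible area and
#' sums into residues.  ASP values are in cal/(mol A^2); energies are
#' reported in kcal/mol.  Atoms without a solvation class contribute zero
#' (with a warning).
#'
#' @param x A [structure3d()].
#' @param asa Per-atom ASA from [compute_asa()] (computed if missing).
#' @param asp ASP table, see [asp_table()].
#' @param probe,sphere_points Passed to [compute_asa()] when `asa` is NULL.
#' @return A `solvation_result`: list with `per_atom` (data frame: class,
#'   asa, e_solv) and `per_residue` (chain, resno, resname, e_solv kcal/mol).
#' @export
solvation_energy <- function(x, asa = NULL, asp = asp_table(),
                             probe = 1.4, sphere_points = 960L) {
  stopifnot(inherits(x, "structure3d"))
  if (is.null(asa)) asa <- compute_asa(x, probe, sphere_points)
  if (any(asa < 0)) stop("ASA must be non-negative")
  cls <- asp_classify(x$atoms)
  a <- asp$asp[match(cls, asp$class)]
  unmapped <- is.na(a)
  if (any(unmapped)) {
    warning(sum(unmapped), " atom(s) without solvation class; contribution 0")
    a[unmapped] <- 0
  }
  e_atom <- a * asa / 1000  # cal -> kcal
  res_key <- paste(x$atoms$chain, x$atoms$resno, x$atoms$resname, sep = "|")
  agg <- tapply(e_atom, res_key, sum)
  parts <- do.call(rbind, strsplit(names(agg), "|", fixed = TRUE))
  ord <- order(parts[, 1], as.integer(parts[, 2]))
  per_res <- data.frame(chain = parts[ord, 1],
                        resno = as.integer(parts[ord, 2]),
                        resname = parts[ord, 3],
                        e_solv = unname(agg[ord]),
                        stringsAsFactors = FALSE)
  structure(list(per_atom = data.frame(class = cls, asa = asa, e_solv = e_atom),
                 per_residue = per_res),
            class = "solvation_result")
}

# per-residue solvation energies for every frame: residues x frames matrix
solvation_series <- function(traj, asp = asp_table(), probe = 1.4,
                             sphere_points = 960L) {
  first <- solvation_energy(traj_frame(traj, 1L), asp = asp,
                            probe = probe, sphere_points = sphere_points)
  res <- first$per_residue[, c("chain", "resno", "resname")]
  m <- matrix(NA_real_, nrow(res), n_frames(traj))
  m[, 1L] <- first$per_residue$e_solv
  for (f in seq_len(n_frames(traj))[-1L]) {
    sr <- solvation_energy(traj_frame(traj, f), asp = asp,
                           probe = probe, sphere_points = sphere_points)
    m[, f] <- sr$per_residue$e_solv
  }
  list(residues = res, e_solv = m)
}

#' Rank residues by open/closed solvation-energy change
#'
#' Averages per-residue solvation energies over the frames of two
#' trajectories (two states) and ranks residues by the magnitude of the
#' mean change.  Swapping the trajectories flips the sign of `delta` but
#' not the ranking.
#'
#' @param traj_a,traj_b [trajectory3d()]s with identical residue numbering.
#' @param top_k Keep the `top_k` largest |delta| rows (default: all).
#' @param threshold Alternatively keep rows with |delta| above this value
#'   (kcal/mol).
#' @param asp,probe,sphere_points Passed to the per-frame energies.
#' @return List with `ranking` (data frame: chain, resno, resname, mean_a,
#'   sd_a, mean_b, sd_b, delta = mean_b - mean_a, ordered by |delta|) and
#'   per-state per-frame matrices `series_a`, `series_b`.
#' @export
rank_solvation_change <- function(traj_a, traj_b, top_k = Inf,
                                  threshold = NULL, asp = asp_table(),
                                  probe = 1.4, sphere_points = 960L) {
  sa <- solvation_series(traj_a, asp, probe, sphere_points)
  sb <- solvation_series(traj_b, asp, probe, sphere_points)
  if (!identical(sa$residues, sb$residues))
    stop("residue numbering differs between the two trajectories")
  mean_a <- rowMeans(sa$e_solv); mean_b <- rowMeans(sb$e_solv)
  sd_a <- apply(sa$e_solv, 1, stats::sd)
  sd_b <- apply(sb$e_solv, 1, stats::sd)
  rk <- cbind(sa$residues,
              data.frame(mean_a = mean_a, sd_a = sd_a,
                         mean_b = mean_b, sd_b = sd_b,
                         delta = mean_b - mean_a))
  rk <- rk[order(-abs(rk$delta)), ]
  if (!is.null(threshold)) rk <- rk[abs(rk$delta) > threshold, ]
  if (is.finite(top_k)) rk <- utils::head(rk, top_k)
  rownames(rk) <- NULL
  list(ranking = rk, series_a = sa$e_solv, series_b = sb$e_solv,
       residues = sa$residues)
}

#' Methylene equivalents of a total surface-MHP change
#'
#' Converts a change in total surface MHP into the equivalent number of
#' solvent-exposed CH2 groups using the per-methylene calibration (about 50
#' MHP units per CH2 on alkane model compounds).
#'
#' @param delta_mhp_total Total surface-MHP difference (MHP units).
#' @param mhp_per_ch2 Calibration constant (MHP units per CH2, default 50).
#' @return Sign-preserving quotient (dimensionless CH2 count).
#' @export
methylene_equivalents <- function(delta_mhp_total, mhp_per_ch2 = 50) {
  if (mhp_per_ch2 <= 0) stop("mhp_per_ch2 must be positive")
  delta_mhp_total / mhp_per_ch2
}

#' Heat-capacity change from methylene equivalents
#'
#' Transfer of one nonpolar methylene group into water raises the heat
#' capacity by about 15 cal/(mol K); the estimator is linear.
#'
#' @param n_ch2_equiv Methylene-equivalent count.
#' @param cp_per_ch2 Heat-capacity increment per CH2 in cal/(mol K)
#'   (default 15).
#' @return delta C_P in kcal/(mol K).
#' @export
delta_cp <- function(n_ch2_equiv, cp_per_ch2 = 15) {
  n_ch2_equiv * cp_per_ch2 / 1000
}
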