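#' Structure container
#'
#' A `structure3d` holds one conformation: an atom table plus an `n x 3`
#' coordinate matrix in Angstrom.  The atom table carries per-atom metadata
#' (serial id, atom name, element, residue name/number, chain) together with
#' the assigned van der Waals radius and, once [assign_constants()] has run,
#' the atomic hydrophobicity constant `f`.
#'
#' @param atoms Data frame with columns `id`, `name`, `element`, `resname`,
#'   `resno`, `chain`; optional `vdw`, `f`, `mhp_class`.
#' @param xyz Numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param frame_label Free-text label for the conformation.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atoms, xyz, frame_label = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz <- as.matrix(xyz)
  required <- c("id", "name", "element", "resname", "resno", "chain")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0L)
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(atoms) == 0L) stop("structure must contain at least one atom")
  if (anyDuplicated(atoms$id)) stop("atom ids must be unique")
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3L)
    stop("xyz must be an n x 3 matrix matching the atom table")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (is.null(atoms$vdw)) atoms$vdw <- vdw_lookup(atoms$element)
  if (any(!is.na(atoms$vdw) & atoms$vdw <= 0)) stop("vdW radii must be positive")
  if (is.null(atoms$f)) atoms$f <- NA_real_
  if (is.null(atoms$mhp_class)) atoms$mhp_class <- NA_character_
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  obj <- list(atoms = atoms, xyz = xyz, frame_label = as.character(frame_label))
  class(obj) <- "structure3d"
  obj
}

#' @export
print.structure3d <- function(x, ...) {
  cat("structure3d:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)")
  if (nzchar(x$frame_label)) cat(" [", x$frame_label, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param x A [structure3d()].
#' @return Integer atom count.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records of one MODEL (via bio3d) and assigns van der
#' Waals radii from the bundled element table.  Unknown elements fall back to
#' `default_radius` with a warning.
#'
#' @param path PDB file.
#' @param model 1-based model index (multi-model files).
#' @param radii Radius table, see [vdw_table()].
#' @param default_radius Fallback radius in Angstrom for unknown elements.
#' @return A [structure3d()].
#' @export
read_structure <- function(path, model = 1L, radii = vdw_table(),
                           default_radius = 1.7) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nmod <- nrow(pdb$xyz)
  if (model < 1L || model > nmod)
    stop("model ", model, " not present (file has ", nmod, ")")
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem))))
    elem <- substr(trimws(at$elety), 1L, 1L)
  elem <- trimws(elem)
  blank <- is.na(elem) | !nzchar(elem)
  elem[blank] <- substr(trimws(at$elety[blank]), 1L, 1L)
  atoms <- data.frame(
    id = at$eleno,
    name = trimws(at$elety),
    element = toupper(elem),
    resname = trimws(at$resid),
    resno = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    stringsAsFactors = FALSE
  )
  atoms$vdw <- vdw_lookup(atoms$element, radii, default_radius)
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  structure3d(atoms, xyz, frame_label = basename(path))
}

#' Write a structure (or trajectory) as PDB
#'
#' `write_structure()` writes one conformation; `write_trajectory()` writes a
#' multi-model PDB with one MODEL per frame (the canonical trajectory
#' interchange format here).
#'
#' @param x A [structure3d()] or [trajectory3d()].
#' @param path Output file.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "structure3d"))
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(x$xyz)),
                   resno = x$atoms$resno,
                   resid = x$atoms$resname,
                   eleno = x$atoms$id,
                   elety = x$atoms$name,
                   chain = x$atoms$chain,
                   elesy = x$atoms$element)
  invisible(path)
}

#' Trajectory container
#'
#' Topology plus an `n_atoms x 3 x n_frames` coordinate array and per-frame
#' times in nanoseconds (strictly increasing).
#'
#' @param topology A [structure3d()].
#' @param coords Numeric array `n_atoms x 3 x n_frames`.
#' @param times Numeric vector of frame times (ns).
#' @return An object of class `trajectory3d`.
#' @export
trajectory3d <- function(topology, coords, times = NULL) {
  stopifnot(inherits(topology, "structure3d"))
  coords <- as.array(coords)
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  if (dim(coords)[3] == 0L) stop("trajectory must contain at least one frame")
  if (dim(coords)[1] != n_atoms(topology) || dim(coords)[2] != 3L)
    stop("frame atom count does not match topology")
  nf <- dim(coords)[3]
  if (is.null(times)) times <- seq(0, by = 0.2, length.out = nf)
  if (length(times) != nf) stop("times length must equal frame count")
  if (nf > 1L && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  obj <- list(topology = topology, coords = coords, times = as.numeric(times))
  class(obj) <- "trajectory3d"
  obj
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat("trajectory3d:", dim(x$coords)[3], "frames,",
      n_atoms(x$topology), "atoms, t =", min(x$times), "-", max(x$times), "ns\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory3d()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame of a trajectory as a structure
#'
#' @param traj A [trajectory3d()].
#' @param i 1-based frame index.
#' @return A [structure3d()] with that frame's coordinates.
#' @export
traj_frame <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory3d"))
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  s <- traj$topology
  s$xyz <- traj$coords[, , i, drop = TRUE]
  dim(s$xyz) <- c(n_atoms(traj$topology), 3L)
  dimnames(s$xyz) <- list(NULL, c("x", "y", "z"))
  s$frame_label <- sprintf("frame %d (t=%.3g ns)", i, traj$times[i])
  s
}

#' Read a trajectory from multi-model PDB file(s)
#'
#' All MODELs of each file become frames, in file order.  Frame times default
#' to a uniform stride of `dt` ns starting at 0.
#'
#' @param paths Character vector of PDB files.
#' @param topology Optional [structure3d()] giving the atom table; defaults to
#'   the first model of the first file.
#' @param times Explicit frame times (ns), or `NULL` to use `dt`.
#' @param dt Uniform frame spacing in ns used when `times` is `NULL`.
#' @return A [trajectory3d()].
#' @export
read_trajectory <- function(paths, topology = NULL, times = NULL, dt = 0.2) {
  frames <- list()
  for (p in paths) {
    if (!file.exists(p)) stop("no such file: ", p)
    pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
    for (m in seq_len(nrow(pdb$xyz)))
      frames[[length(frames) + 1L]] <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
  }
  if (length(frames) == 0L) stop("no frames read")
  if (is.null(topology)) topology <- read_structure(paths[[1L]], model = 1L)
  na <- n_atoms(topology)
  bad <- which(vapply(frames, nrow, 1L) != na)
  if (length(bad) > 0L)
    stop("frame(s) ", paste(bad, collapse = ","), " have atom counts differing from topology")
  coords <- array(unlist(frames), c(na, 3L, length(frames)))
  if (is.null(times)) times <- seq(0, by = dt, length.out = length(frames))
  trajectory3d(topology, coords, times)
}

#' @rdname write_structure
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "trajectory3d"))
  con <- file(path, "w")
  on.exit(close(con))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  for (i in seq_len(n_frames(x))) {
    write_structure(traj_frame(x, i), tmp)
    lines <- readLines(tmp)
    lines <- lines[grepl("^(ATOM|HETATM|TER)", lines)]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select atom indices
#'
#' Deterministic, order-preserving selection by chain, residue number range
#' and atom name.  All criteria are optional and combined with AND; `NULL`
#' means "any".  An empty result is allowed (a message is emitted).
#'
#' @param x A [structure3d()].
#' @param chain Character vector of chain ids.
#' @param resno Integer vector of residue numbers (use `a:b` for ranges).
#' @param name Character vector of atom names (e.g. `"CA"`).
#' @return Integer vector of atom indices into `x$atoms`.
#' @export
select_atoms <- function(x, chain = NULL, resno = NULL, name = NULL) {
  stopifnot(inherits(x, "structure3d"))
  keep <- rep(TRUE, n_atoms(x))
  if (!is.null(chain)) {
    if (!is.character(chain)) stop("chain must be a character vector")
    keep <- keep & x$atoms$chain %in% chain
  }
  if (!is.null(resno)) {
    if (!is.numeric(resno)) stop("resno must be numeric")
    keep <- keep & x$atoms$resno %in% as.integer(resno)
  }
  if (!is.null(name)) {
    if (!is.character(name)) stop("name must be a character vector")
    keep <- keep & x$atoms$name %in% name
  }
  idx <- which(keep)
  if (length(idx) == 0L) message("selection matched no atoms")
  idx
}

kabsch <- function(P, Q) {
  # optimal rotation mapping centred P onto centred Q
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$u %*% t(s$v)))
  # rotation acts on row vectors from the right: y = x %*% R
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, center_mobile = cp, center_ref = cq)
}

#' Rigid-body least-squares superposition
#'
#' Fits `mobile` onto `reference` by the optimal rotation + translation
#' (Kabsch) computed on `fit_indices`, applies the transform to all atoms and
#' reports the RMSD over the fit set.
#'
#' @param mobile,reference Numeric `n x 3` coordinate matrices (same atom
#'   order), or [structure3d()] objects.
#' @param fit_indices Atom indices used for the fit (default: all).
#' @return List with `xyz` (transformed mobile coordinates), `rmsd`
#'   (Angstrom, over the fit set), `rotation` (3x3) and `translation`.
#' @export
superpose <- function(mobile, reference, fit_indices = NULL) {
  if (inherits(mobile, "structure3d")) mobile <- mobile$xyz
  if (inherits(reference, "structure3d")) reference <- reference$xyz
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(fit_indices)) fit_indices <- seq_len(nrow(mobile))
  if (length(fit_indices) < 3L) stop("need at least 3 atoms to fit")
  P <- mobile[fit_indices, , drop = FALSE]
  Q <- reference[fit_indices, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("fit sets differ in size")
  rk <- qr(sweep(P, 2, colMeans(P)))$rank
  if (rk < 2L) stop("degenerate (collinear) fit set")
  k <- kabsch(P, Q)
  out <- sweep(mobile, 2, k$center_mobile) %*% k$R
  out <- sweep(out, 2, k$center_ref, `+`)
  fitted <- out[fit_indices, , drop = FALSE]
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  translation <- k$center_ref - as.vector(k$center_mobile %*% k$R)
  list(xyz = out, rmsd = rmsd, rotation = k$R, translation = translation)
}
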