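#' @title Grid-based pore detection and pore mapping
#' @description The pore pipeline: a coarse 3D occupancy grid locates
#'   cavities; cavities that overlap in the membrane (xy) plane are merged
#'   and the largest merged cavity is taken as the pore; surface dots in
#'   pore cells or their neighbours form the pore border (set S); slabs of S
#'   yield per-z centre C(z), radius R(z) and hydrophobicity H(z) profiles;
#'   2D unrollings give cylindrical (angle, z) maps for one frame and
#'   dynamic (time, z) maps over a trajectory.
#' @name pore_mapping
NULL

#' Build an occupancy grid
#'
#' A cell is occupied iff at least one heavy-atom centre lies inside it (the
#' coarse cell size implicitly absorbs the atomic radius).  The grid covers
#' the structure's bounding box plus a one-cell margin on every side.
#'
#' @param x A [structure3d()].
#' @param cell_size Cell edge in Angstrom (default 3.4).
#' @return An `occupancy_grid`: list with `origin`, `cell_size`, `dim`, and
#'   logical array `occ`.
#' @export
build_grid <- function(x, cell_size = 3.4) {
  stopifnot(inherits(x, "structure3d"))
  if (cell_size <= 0) stop("cell_size must be positive")
  lo <- apply(x$xyz, 2, min) - cell_size
  hi <- apply(x$xyz, 2, max) + cell_size
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / cell_size)))
  # register the lattice on the bounding-box centre (odd cell counts put the
  # centre at a cell centre), so narrow axial pores are not split across cells
  dims <- dims + 1L - (dims %% 2L)
  ctr <- (lo + hi) / 2
  lo <- ctr - dims * cell_size / 2
  occ <- array(FALSE, dims)
  idx <- cell_index(x$xyz, lo, cell_size, dims)
  occ[unique(idx)] <- TRUE
  structure(list(origin = lo, cell_size = cell_size, dim = dims, occ = occ),
            class = "occupancy_grid")
}

# linear cell indices of points; NA outside the grid
cell_index <- function(points, origin, cell_size, dims) {
  ijk <- floor(sweep(matrix(points, ncol = 3L), 2, origin) / cell_size) + 1
  bad <- ijk < 1 | sweep(ijk, 2, dims, `>`)
  ijk[bad] <- NA
  out <- ijk[, 1] + (ijk[, 2] - 1) * dims[1] + (ijk[, 3] - 1) * dims[1] * dims[2]
  out[apply(bad, 1, any)] <- NA
  as.integer(out)
}

# per-z-layer 2D flood fill from the lattice boundary over empty cells:
# the "xy-exterior" bulk. Returns logical array marking bulk cells.
bulk_mask <- function(grid) {
  d <- grid$dim
  bulk <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    lay <- grid$occ[, , k]
    seen <- matrix(FALSE, d[1], d[2])
    stack <- integer(0)
    push <- function(i, j) (j - 1L) * d[1] + i
    for (i in seq_len(d[1])) for (j in c(1L, d[2]))
      if (!lay[i, j]) stack <- c(stack, push(i, j))
    for (j in seq_len(d[2])) for (i in c(1L, d[1]))
      if (!lay[i, j]) stack <- c(stack, push(i, j))
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[cur]) next
      seen[cur] <- TRUE
      i <- ((cur - 1L) %% d[1]) + 1L
      j <- ((cur - 1L) %/% d[1]) + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] >= 1L && nb[1] <= d[1] && nb[2] >= 1L && nb[2] <= d[2]) {
          lin <- (nb[2] - 1L) * d[1] + nb[1]
          if (!lay[lin] && !seen[lin]) stack <- c(stack, lin)
        }
      }
    }
    bulk[, , k] <- seen
  }
  bulk
}

#' Detect the pore cavity
#'
#' Interior unoccupied cells (bulk solvent outside the protein, reached by
#' in-plane flood fill from the grid boundary, is excluded) are grouped into
#' 6-connected cavities; cavities whose xy-projections share at least one
#' projected cell are merged transitively; the largest merged cavity is the
#' pore.  Ties break towards larger z-extent, then lowest cell index.
#'
#' @param grid An `occupancy_grid` from [build_grid()].
#' @return A `cavity`: list with `cells` (linear indices), `ijk` (n x 3
#'   integer matrix), `size`, and the originating `grid`.
#' @export
detect_pore <- function(grid) {
  stopifnot(inherits(grid, "occupancy_grid"))
  d <- grid$dim
  cav_mask <- !grid$occ & !bulk_mask(grid)
  if (!any(cav_mask)) stop("no interior cavity found")
  comp <- array(0L, d)
  ncomp <- 0L
  nxy <- d[1] * d[2]
  todo <- which(cav_mask)
  for (start in todo) {
    if (comp[start] > 0L) next
    ncomp <- ncomp + 1L
    stack <- start
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[cur] > 0L) next
      comp[cur] <- ncomp
      i <- ((cur - 1L) %% d[1]) + 1L
      j <- (((cur - 1L) %/% d[1]) %% d[2]) + 1L
      k <- ((cur - 1L) %/% nxy) + 1L
      nbs <- c(if (i > 1L) cur - 1L, if (i < d[1]) cur + 1L,
               if (j > 1L) cur - d[1], if (j < d[2]) cur + d[1],
               if (k > 1L) cur - nxy, if (k < d[3]) cur + nxy)
      nbs <- nbs[cav_mask[nbs] & comp[nbs] == 0L]
      stack <- c(stack, nbs)
    }
  }
  # merge components sharing xy-projection cells (transitively, union-find)
  cells <- which(comp > 0L)
  proj <- ((cells - 1L) %% nxy) + 1L
  labs <- comp[cells]
  parent <- seq_len(ncomp)
  for (p in split(labs, proj)) {
    u <- unique(p)
    if (length(u) > 1L) {
      roots <- unique(vapply(u, function(a) { while (parent[a] != a) a <- parent[a]; a }, 1L))
      for (r in roots[-1L]) parent[r] <- roots[1L]
    }
  }
  root <- vapply(seq_len(ncomp), function(a) { while (parent[a] != a) a <- parent[a]; a }, 1L)
  merged <- root[labs]
  sizes <- tabulate(merged, nbins = ncomp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    zext <- vapply(best, function(m) {
      ks <- ((cells[merged == m] - 1L) %/% nxy) + 1L
      diff(range(ks))
    }, 1L)
    best <- best[zext == max(zext)]
    if (length(best) > 1L)
      best <- best[which.min(vapply(best, function(m) min(cells[merged == m]), 1L))]
  }
  keep <- cells[merged == best]
  k <- ((keep - 1L) %/% nxy) + 1L
  j <- (((keep - 1L) %/% d[1]) %% d[2]) + 1L
  i <- ((keep - 1L) %% d[1]) + 1L
  structure(list(cells = keep, ijk = cbind(i, j, k), size = length(keep),
                 grid = grid),
            class = "cavity")
}

#' Extract the pore border (set S)
#'
#' Keeps the surface dots lying in pore-cavity grid cells or any of their 26
#' neighbouring cells.
#'
#' @param dots A `dotset` from [dot_surface()] of the same structure.
#' @param cavity A `cavity` from [detect_pore()].
#' @return The `dotset` subset, with class `pore_border`.
#' @export
pore_border <- function(dots, cavity) {
  stopifnot(inherits(cavity, "cavity"))
  grid <- cavity$grid
  d <- grid$dim
  mask <- array(FALSE, d)
  mask[cavity$cells] <- TRUE
  # dilate by one cell in all 26 directions
  dil <- array(FALSE, d)
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    si <- pmin(pmax(seq_len(d[1]) + di, 1L), d[1])
    sj <- pmin(pmax(seq_len(d[2]) + dj, 1L), d[2])
    sk <- pmin(pmax(seq_len(d[3]) + dk, 1L), d[3])
    dil <- dil | mask[si, sj, sk]
  }
  idx <- cell_index(cbind(dots$x, dots$y, dots$z), grid$origin, grid$cell_size, d)
  keep <- !is.na(idx) & dil[pmax(idx, 1L)]
  if (!any(keep)) message("pore border is empty (fully occluded pore?)")
  out <- dots[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pore_border", "dotset", "data.frame")
  out
}

#' Per-slab pore profile C(z), R(z), H(z)
#'
#' For each z sample the slab S_z holds the border dots with |dot_z - z| <=
#' dz.  C(z) is the mean point of S_z, R(z) the mean in-plane (xy) distance
#' from C(z) to the slab dots (set `dist = "3d"` for full distances), H(z)
#' the mean per-dot MHP.  Samples with empty slabs are flagged undefined.
#'
#' @param border A `pore_border` (or any `dotset`).
#' @param z_min,z_max,dz Sampling range and half-window step (Angstrom).
#' @param dist `"xy"` (default) or `"3d"` radius convention.
#' @return A `pore_profile` data frame: `z`, `cx`, `cy`, `cz`, `R`, `H`,
#'   `n`, `defined`.
#' @export
pore_profile <- function(border, z_min = -20, z_max = 20, dz = 0.5,
                         dist = c("xy", "3d")) {
  dist <- match.arg(dist)
  if (nrow(border) == 0L) stop("border is empty")
  zs <- seq(z_min, z_max, by = dz)
  out <- data.frame(z = zs, cx = NA_real_, cy = NA_real_, cz = NA_real_,
                    R = NA_real_, H = NA_real_, n = 0L, defined = FALSE)
  have_mhp <- !anyNA(border$mhp)
  for (s in seq_along(zs)) {
    in_slab <- abs(border$z - zs[s]) <= dz
    n <- sum(in_slab)
    if (n == 0L) next
    sx <- border$x[in_slab]; sy <- border$y[in_slab]; sz <- border$z[in_slab]
    cx <- mean(sx); cy <- mean(sy); cz <- mean(sz)
    r <- if (dist == "xy") sqrt((sx - cx)^2 + (sy - cy)^2)
         else sqrt((sx - cx)^2 + (sy - cy)^2 + (sz - cz)^2)
    out$cx[s] <- cx; out$cy[s] <- cy; out$cz[s] <- cz
    out$R[s] <- mean(r)
    if (have_mhp) out$H[s] <- mean(border$mhp[in_slab])
    out$n[s] <- n
    out$defined[s] <- TRUE
  }
  class(out) <- c("pore_profile", "data.frame")
  out
}

#' Occluded bands of a pore profile
#'
#' Contiguous z-runs where the profile is undefined or the radius falls
#' below `r_min` (sub-probe: effectively closed).  Runs narrower than
#' `min_extent` are discarded: an isolated empty slab reflects a gap in dot
#' coverage at the shoulder of a constriction, not a gate.
#'
#' @param profile A `pore_profile`.
#' @param r_min Radius cutoff in Angstrom (default 1).
#' @param min_extent Minimum band z-extent in Angstrom (default 1).
#' @return Data frame `band`, `z_lo`, `z_hi` (empty if the pore is open
#'   throughout).
#' @export
occluded_bands <- function(profile, r_min = 1, min_extent = 1) {
  closed <- !profile$defined | (!is.na(profile$R) & profile$R < r_min)
  r <- rle(closed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  out <- data.frame(z_lo = profile$z[starts[sel]],
                    z_hi = profile$z[ends[sel]])
  out <- out[out$z_hi - out$z_lo >= min_extent, , drop = FALSE]
  rownames(out) <- NULL
  cbind(band = seq_len(nrow(out)), out)
}

#' Cylindrical (angle, z) pore map
#'
#' Unrolls the pore border onto (alpha, z): each dot's azimuth alpha is
#' measured about the axis through the per-slab centreline C(z); cells hold
#' the binned mean of the chosen property (per-dot MHP, or distance to the
#' centreline for the radius variant).  Bins without dots are NA (rendered
#' white/closed).
#'
#' @param border A `pore_border`.
#' @param value `"mhp"` or `"radius"`.
#' @param alpha_bins Number of azimuth bins over [0, 360).
#' @param z_min,z_max,dz Elevation sampling (matching [pore_profile()]).
#' @return A `pore_map`: list with `kind = "cylindrical"`, `value`, `alpha`
#'   (bin midpoints, degrees), `z`, and matrix `map` (z rows x alpha cols).
#' @export
cylindrical_map <- function(border, value = c("mhp", "radius"),
                            alpha_bins = 36L, z_min = -20, z_max = 20, dz = 0.5) {
  value <- match.arg(value)
  if (nrow(border) == 0L) stop("border is empty")
  prof <- pore_profile(border, z_min, z_max, dz)
  zs <- prof$z
  # nearest defined centreline point per dot
  defd <- which(prof$defined)
  if (length(defd) == 0L) stop("no defined slabs on the centreline")
  zz <- zs[defd]
  lo <- pmin(pmax(findInterval(border$z, zz), 1L), length(zz))
  hi <- pmin(lo + 1L, length(zz))
  near <- defd[ifelse(abs(border$z - zz[lo]) <= abs(border$z - zz[hi]), lo, hi)]
  cx <- prof$cx[near]; cy <- prof$cy[near]
  alpha <- (atan2(border$y - cy, border$x - cx) * 180 / pi) %% 360
  val <- if (value == "mhp") border$mhp else sqrt((border$x - cx)^2 + (border$y - cy)^2)
  ab <- floor(alpha / (360 / alpha_bins)) + 1L
  zb <- findInterval(border$z, c(zs - dz / 2, max(zs) + dz / 2),
                     rightmost.closed = TRUE)
  ok <- zb >= 1L & zb <= length(zs)
  m <- matrix(NA_real_, length(zs), alpha_bins)
  agg <- tapply(val[ok], list(zb[ok], ab[ok]), mean)
  m[cbind(as.integer(rownames(agg)[row(agg)]), as.integer(colnames(agg)[col(agg)]))] <-
    as.vector(agg)
  structure(list(kind = "cylindrical", value = value,
                 alpha = (seq_len(alpha_bins) - 0.5) * 360 / alpha_bins,
                 z = zs, map = m),
            class = "pore_map")
}

#' @export
print.pore_map <- function(x, ...) {
  cat("pore_map (", x$kind, ", ", x$value, "): ",
      nrow(x$map), " x ", ncol(x$map), " cells, ",
      sum(is.na(x$map)), " undefined\n", sep = "")
  invisible(x)
}

# single-frame pipeline: surface dots -> grid -> pore -> border
frame_border <- function(s, cell_size, dot_density, probe, lambda,
                         with_mhp = TRUE) {
  if (with_mhp && anyNA(s$atoms$f)) s <- assign_constants(s)
  dots <- dot_surface(s, dot_density = dot_density, probe = probe)
  if (with_mhp) dots <- surface_mhp(dots, s, lambda = lambda)
  cav <- detect_pore(build_grid(s, cell_size))
  pore_border(dots, cav)
}

#' Dynamic (time, z) pore map over a trajectory
#'
#' Runs the per-frame pipeline (dot surface, occupancy grid, pore detection,
#' border, profile) on every frame; column f of the map is frame f's R(z)
#' or H(z) profile.  Frames where no cavity is found yield all-undefined
#' columns.
#'
#' @param traj A [trajectory3d()].
#' @param value `"radius"` or `"mhp"`.
#' @param cell_size,dot_density,probe,lambda Pipeline parameters.
#' @param z_min,z_max,dz Profile sampling.
#' @return A `pore_map` with `kind = "dynamic"`, `times` (ns), `z`, and
#'   matrix `map` (z rows x frame columns).
#' @export
dynamic_map <- function(traj, value = c("radius", "mhp"), cell_size = 3.4,
                        dot_density = 3, probe = 1.4, lambda = 2,
                        z_min = -20, z_max = 20, dz = 0.5) {
  value <- match.arg(value)
  stopifnot(inherits(traj, "trajectory3d"))
  zs <- seq(z_min, z_max, by = dz)
  m <- matrix(NA_real_, length(zs), n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    col <- tryCatch({
      b <- frame_border(traj_frame(traj, f), cell_size, dot_density, probe,
                        lambda, with_mhp = (value == "mhp"))
      p <- pore_profile(b, z_min, z_max, dz)
      if (value == "radius") p$R else p$H
    }, error = function(e) rep(NA_real_, length(zs)))
    m[, f] <- col
  }
  structure(list(kind = "dynamic", value = value, times = traj$times,
                 z = zs, map = m),
            class = "pore_map")
}

#' Locate the opening frame at a gate elevation
#'
#' First frame at which the dynamic radius map at the z sample nearest
#' `z_gate` is defined and exceeds `r_open`.
#'
#' @param dmap A dynamic `pore_map` with `value = "radius"`.
#' @param z_gate Gate elevation (Angstrom).
#' @param r_open Opening radius threshold (Angstrom, default 1.5).
#' @return Frame index, or `NA` if the gate never opens.
#' @export
detect_opening <- function(dmap, z_gate, r_open = 1.5) {
  stopifnot(identical(dmap$kind, "dynamic"), identical(dmap$value, "radius"))
  row <- which.min(abs(dmap$z - z_gate))
  v <- dmap$map[row, ]
  open <- which(!is.na(v) & v >= r_open)
  if (length(open) == 0L) NA_integer_ else open[1L]
}

#' Align the pore axis with z
#'
#' `"pca"` rotates the dominant principal axis of the selection onto +z;
#' `"c4"` additionally requires that axis to be a 4-fold symmetry axis
#' (checked by nearest-neighbour RMS after a 90-degree rotation) and errors
#' otherwise; `"none"` returns the structure unchanged.  For the aligning
#' modes, z = 0 is placed at the mean z of `ref_indices` (default: all
#' atoms).
#'
#' @param x A [structure3d()].
#' @param mode `"none"`, `"pca"` or `"c4"`.
#' @param ref_indices Atoms defining z = 0 after alignment.
#' @param sel_indices Atoms whose principal axis defines the pore axis
#'   (default: all).
#' @param c4_tol Mean nearest-neighbour distance (Angstrom) tolerated under
#'   the 90-degree rotation test.
#' @return The aligned [structure3d()].
#' @export
align_pore_axis <- function(x, mode = c("none", "pca", "c4"),
                            ref_indices = NULL, sel_indices = NULL,
                            c4_tol = 1.0) {
  mode <- match.arg(mode)
  if (mode == "none") return(x)
  if (is.null(sel_indices)) sel_indices <- seq_len(n_atoms(x))
  if (is.null(ref_indices)) ref_indices <- seq_len(n_atoms(x))
  pts <- x$xyz[sel_indices, , drop = FALSE]
  ctr <- colMeans(pts)
  ev <- eigen(stats::cov(pts), symmetric = TRUE)
  axis <- ev$vectors[, 1L]
  if (axis[3] < 0) axis <- -axis
  R <- rotation_to_z(axis)
  xyz <- sweep(x$xyz, 2, ctr) %*% t(R)
  if (mode == "c4") {
    p <- xyz[sel_indices, , drop = FALSE]
    th <- pi / 2
    Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
                 byrow = TRUE)
    q <- p %*% t(Rz)
    nn <- vapply(seq_len(nrow(q)), function(i)
      min(sqrt(rowSums(sweep(p, 2, q[i, ])^2))), 1.0)
    if (mean(nn) > c4_tol)
      stop("no 4-fold symmetry about the detected axis (mean NN ",
           round(mean(nn), 2), " A)")
  }
  z0 <- mean(xyz[ref_indices, 3])
  xyz[, 3] <- xyz[, 3] - z0
  x$xyz <- xyz
  dimnames(x$xyz) <- list(NULL, c("x", "y", "z"))
  x
}

# minimal rotation taking unit vector v onto +z
rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  axis <- c(v[2] * z[3] - v[3] * z[2], v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(axis^2))
  axis <- axis / s
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(acos(c_)) * K + (1 - c_) * K %*% K
}
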