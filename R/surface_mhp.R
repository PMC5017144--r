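#' @title Molecular Hydrophobicity Potential over dot surfaces
#' @description Dot Connolly-type surface generation and MHP evaluation.
#'   The MHP at a point p is the distance-weighted sum of empirical atomic
#'   hydrophobicity constants, MHP(p) = sum_i f_i * exp(-d(i,p)/lambda);
#'   positive values mark hydrophobic surface, negative hydrophilic, in
#'   logP-derived units.
#' @name mhp_surface
NULL

# deterministic Fibonacci lattice on the unit sphere; seed-free
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# protein heavy-atom -> hydrophobicity class; NA when no rule applies
classify_protein_atom <- function(resname, name, element) {
  key <- paste(resname, name)
  specific <- c(
    "ALA CB" = "CH3_ALI",
    "ILE CB" = "CH_ALI", "VAL CB" = "CH_ALI", "THR CB" = "CH_ALI",
    "PHE CG" = "C_ARO_SUB", "PHE CD1" = "C_ARO_H", "PHE CD2" = "C_ARO_H",
    "PHE CE1" = "C_ARO_H", "PHE CE2" = "C_ARO_H", "PHE CZ" = "C_ARO_H",
    "TYR CG" = "C_ARO_SUB", "TYR CZ" = "C_ARO_SUB", "TYR CD1" = "C_ARO_H",
    "TYR CD2" = "C_ARO_H", "TYR CE1" = "C_ARO_H", "TYR CE2" = "C_ARO_H",
    "TYR OH" = "O_HYDROXYL",
    "TRP CG" = "C_ARO_SUB", "TRP CD2" = "C_ARO_SUB", "TRP CE2" = "C_ARO_SUB",
    "TRP CD1" = "C_ARO_H", "TRP CE3" = "C_ARO_H", "TRP CZ2" = "C_ARO_H",
    "TRP CZ3" = "C_ARO_H", "TRP CH2" = "C_ARO_H", "TRP NE1" = "N_ARO",
    "HIS CG" = "C_ARO_SUB", "HIS CD2" = "C_ARO_H", "HIS CE1" = "C_ARO_H",
    "HIS ND1" = "N_ARO", "HIS NE2" = "N_ARO",
    "ASP CG" = "C_CARBOXYL", "ASP OD1" = "O_CARBOXYLATE", "ASP OD2" = "O_CARBOXYLATE",
    "GLU CG" = "CH2_ALI", "GLU CD" = "C_CARBOXYL",
    "GLU OE1" = "O_CARBOXYLATE", "GLU OE2" = "O_CARBOXYLATE",
    "ASN CG" = "C_CARBONYL", "ASN OD1" = "O_CARBONYL", "ASN ND2" = "N_AMIDE",
    "GLN CG" = "CH2_ALI", "GLN CD" = "C_CARBONYL",
    "GLN OE1" = "O_CARBONYL", "GLN NE2" = "N_AMIDE",
    "ARG CG" = "CH2_ALI", "ARG CD" = "CH2_ALI", "ARG CZ" = "C_GUANIDINIUM",
    "ARG NE" = "N_CHARGED", "ARG NH1" = "N_CHARGED", "ARG NH2" = "N_CHARGED",
    "LYS CG" = "CH2_ALI", "LYS CD" = "CH2_ALI", "LYS CE" = "CH2_ALI",
    "LYS NZ" = "N_CHARGED",
    "LEU CG" = "CH_ALI", "LEU CD1" = "CH3_ALI", "LEU CD2" = "CH3_ALI",
    "ILE CG1" = "CH2_ALI", "ILE CG2" = "CH3_ALI", "ILE CD1" = "CH3_ALI",
    "VAL CG1" = "CH3_ALI", "VAL CG2" = "CH3_ALI",
    "THR CG2" = "CH3_ALI", "THR OG1" = "O_HYDROXYL",
    "MET CG" = "CH2_ALI", "MET SD" = "S_THIOETHER", "MET CE" = "CH3_ALI",
    "CYS SG" = "S_THIOL",
    "SER OG" = "O_HYDROXYL",
    "PRO CG" = "CH2_ALI", "PRO CD" = "CH2_ALI"
  )
  cls <- unname(specific[key])
  backbone <- is.na(cls)
  cls[backbone & name == "C"] <- "C_CARBONYL"
  cls[backbone & name == "O"] <- "O_CARBONYL"
  cls[backbone & name == "OXT"] <- "O_CARBOXYLATE"
  cls[backbone & name == "N"] <- "N_AMIDE"
  gly <- backbone & name == "CA" & resname == "GLY"
  cls[gly] <- "CH2_ALI"
  cls[backbone & name == "CA" & resname != "GLY"] <- "CH_ALI"
  cls[is.na(cls) & name == "CB"] <- "CH2_ALI"
  cls
}

#' Assign atomic hydrophobicity constants
#'
#' Maps every heavy atom to a hydrophobicity class and sets the per-atom
#' constant `f` from the table.  Atoms whose `mhp_class` is already set (as
#' the synthetic generators do) keep it; protein atoms are classified by
#' residue/atom-name rules; anything else falls back to an element-level
#' class (`ELEM_C`, ...) and finally to `f = 0` with a warning.
#'
#' @param x A [structure3d()].
#' @param table Constant table, see [mhp_table()].
#' @return `x` with `atoms$f` (and `atoms$mhp_class`) filled in.
#' @export
assign_constants <- function(x, table = mhp_table()) {
  stopifnot(inherits(x, "structure3d"))
  cls <- x$atoms$mhp_class
  todo <- is.na(cls)
  if (any(todo))
    cls[todo] <- classify_protein_atom(x$atoms$resname[todo],
                                       x$atoms$name[todo],
                                       x$atoms$element[todo])
  todo <- is.na(cls)
  cls[todo] <- paste0("ELEM_", toupper(x$atoms$element[todo]))
  f <- table$f[match(cls, table$class)]
  unmapped <- is.na(f)
  if (any(unmapped)) {
    warning(sum(unmapped), " atom(s) not mappable to a hydrophobicity class; f set to 0")
    f[unmapped] <- 0
  }
  x$atoms$mhp_class <- cls
  x$atoms$f <- f
  x
}

#' Dot Connolly-type molecular surface
#'
#' Places dots on each atom's van der Waals sphere via a deterministic
#' spiral (Fibonacci) lattice at the requested density and keeps only
#' solvent-exposed dots: a dot survives if a probe sphere placed tangent to
#' it along the outward normal does not clash with any other atom's
#' probe-extended sphere (probe-rolling rejection; reentrant patches are
#' approximated by this criterion).  Each dot carries an equal share of its
#' atom's sphere area, so an isolated atom's dots sum to 4*pi*r^2.
#'
#' @param x A [structure3d()].
#' @param dot_density Dots per Angstrom^2 (default 3).
#' @param probe Probe radius in Angstrom (default 1.4).
#' @return A `dotset`: data frame with `x`, `y`, `z`, `area`, `owner`
#'   (atom row index), `owner_id` (atom id), and `mhp` (NA until
#'   [surface_mhp()] fills it).
#' @export
dot_surface <- function(x, dot_density = 3, probe = 1.4) {
  stopifnot(inherits(x, "structure3d"))
  if (dot_density <= 0) stop("dot_density must be positive")
  xyz <- x$xyz
  r <- x$atoms$vdw
  n <- nrow(xyz)
  ext <- r + probe
  out <- vector("list", n)
  # exactly coincident duplicates would shadow each other's probe test;
  # only the first of each coincident group contributes surface
  dup <- rep(FALSE, n)
  if (n > 1L) for (i in 2:n) {
    d2 <- rowSums(sweep(xyz[seq_len(i - 1L), , drop = FALSE], 2, xyz[i, ])^2)
    if (any(d2 < 1e-12 & r[seq_len(i - 1L)] >= r[i])) dup[i] <- TRUE
  }
  for (i in seq_len(n)) {
    if (dup[i]) next
    ndots <- max(12L, as.integer(round(4 * pi * r[i]^2 * dot_density)))
    u <- fibonacci_sphere(ndots)
    dots <- sweep(u * r[i], 2, xyz[i, ], `+`)
    pcent <- sweep(u * ext[i], 2, xyz[i, ], `+`)
    # neighbours whose probe-extended spheres could swallow the probe
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ext[i] + ext)^2 & seq_len(n) != i)
    keep <- rep(TRUE, ndots)
    for (j in nb) {
      if (!any(keep)) break
      keep[keep] <- rowSums(sweep(pcent[keep, , drop = FALSE], 2, xyz[j, ])^2) >=
        ext[j]^2 * (1 - 1e-9)
    }
    if (any(keep))
      out[[i]] <- data.frame(x = dots[keep, 1], y = dots[keep, 2], z = dots[keep, 3],
                             area = 4 * pi * r[i]^2 / ndots,
                             owner = i, owner_id = x$atoms$id[i])
  }
  dots <- do.call(rbind, out)
  if (is.null(dots))
    dots <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                       area = numeric(0), owner = integer(0), owner_id = integer(0))
  dots$mhp <- NA_real_
  class(dots) <- c("dotset", "data.frame")
  rownames(dots) <- NULL
  dots
}

#' Evaluate MHP at arbitrary points
#'
#' `MHP(p) = sum_i f_i * exp(-d(i, p) / lambda)` with `d` the distance from
#' atom centre `i` to point `p`.  Linear in the constants.
#'
#' @param x A [structure3d()] with constants assigned ([assign_constants()]).
#' @param points Numeric `m x 3` matrix of evaluation points (Angstrom).
#' @param lambda Decay length in Angstrom (default 2).
#' @return Numeric vector of MHP values (logP-derived units).
#' @export
mhp_at_points <- function(x, points, lambda = 2) {
  stopifnot(inherits(x, "structure3d"))
  if (anyNA(x$atoms$f)) stop("assign_constants() must be run first")
  points <- matrix(as.numeric(points), ncol = 3L)
  m <- nrow(points)
  if (m == 0L) return(numeric(0))
  f <- x$atoms$f
  xyz <- x$xyz
  vals <- numeric(m)
  chunk <- 4000L
  for (lo in seq(1L, m, by = chunk)) {
    hi <- min(lo + chunk - 1L, m)
    p <- points[lo:hi, , drop = FALSE]
    d2 <- outer(rowSums(p^2), rowSums(xyz^2), `+`) - 2 * p %*% t(xyz)
    d2[d2 < 0] <- 0
    vals[lo:hi] <- exp(-sqrt(d2) / lambda) %*% f
  }
  vals
}

#' Fill per-dot MHP values on a dot surface
#'
#' @param dots A `dotset` from [dot_surface()].
#' @param x The [structure3d()] (constants assigned) that owns the surface.
#' @param lambda Decay length in Angstrom.
#' @return The `dotset` with its `mhp` column filled.
#' @export
surface_mhp <- function(dots, x, lambda = 2) {
  dots$mhp <- mhp_at_points(x, cbind(dots$x, dots$y, dots$z), lambda = lambda)
  dots
}

#' Total surface MHP
#'
#' Sum of per-dot MHP values over a dot set (trajectory averaging is the
#' caller's loop).
#'
#' @param dots A `dotset` with `mhp` present.
#' @return Scalar, MHP units.
#' @export
total_surface_mhp <- function(dots) {
  if (nrow(dots) == 0L) return(0)
  if (anyNA(dots$mhp)) stop("per-dot MHP values missing; run surface_mhp()")
  sum(dots$mhp)
}

#' Per-methylene surface-MHP calibration
#'
#' Regresses the total dot-surface MHP of a series of n-alkane model
#' compounds on their carbon counts; the slope is the surface-MHP increment
#' contributed by one methylene (CH2) group.
#'
#' @param compounds List of alkane [structure3d()]s (at least two distinct
#'   chain lengths), e.g. from [make_alkane()].
#' @param table Hydrophobicity constant table.
#' @param dot_density,probe,lambda Surface and MHP parameters.
#' @return List with `slope` (MHP units per CH2), `intercept`, and the
#'   per-compound `totals` data frame.
#' @export
methylene_calibration <- function(compounds, table = mhp_table(),
                                  dot_density = 3, probe = 1.4, lambda = 2) {
  if (length(compounds) < 2L) stop("need at least two model compounds")
  nc <- vapply(compounds, function(s) sum(s$atoms$element == "C"), 1L)
  if (length(unique(nc)) < 2L)
    stop("compounds must differ in carbon count to define a slope")
  totals <- vapply(compounds, function(s) {
    s <- assign_constants(s, table)
    d <- dot_surface(s, dot_density = dot_density, probe = probe)
    total_surface_mhp(surface_mhp(d, s, lambda = lambda))
  }, 1.0)
  fit <- ch2_slope(nc, totals)
  list(slope = fit$slope, intercept = fit$intercept,
       totals = data.frame(n_carbons = nc, total_mhp = totals))
}

#' Least-squares per-CH2 slope of a total-MHP series
#'
#' The regression step of [methylene_calibration()], exposed so a total-MHP
#' series from any source can be fit: slope of `totals` against carbon
#' count.  On an exactly linear series the slope is recovered exactly.
#'
#' @param n_carbons Integer vector of carbon counts.
#' @param totals Total surface-MHP per compound (MHP units).
#' @return List with `slope` (MHP units per CH2) and `intercept`.
#' @export
ch2_slope <- function(n_carbons, totals) {
  if (length(n_carbons) != length(totals) || length(n_carbons) < 2L)
    stop("need matching series of at least two compounds")
  if (length(unique(n_carbons)) < 2L)
    stop("compounds must differ in carbon count to define a slope")
  co <- stats::coef(stats::lm(totals ~ n_carbons))
  list(slope = unname(co[2L]), intercept = unname(co[1L]))
}

#' Area-weighted MHP distribution of a surface
#'
#' Histogram of per-dot MHP with per-bin summed dot area (not normalised:
#' bin heights are surface areas in Angstrom^2).  Two distributions over the
#' same breaks subtract bin-wise to give a differential profile; the integral
#' of that difference is the net surface-area excess.
#'
#' @param dots A `dotset` with `mhp` present.
#' @param breaks Strictly increasing numeric vector of MHP bin edges.
#' @return Data frame with `lo`, `hi`, `mid`, `area` per bin.  Dots outside
#'   the break range are ignored.
#' @export
mhp_distribution <- function(dots, breaks = seq(-3, 3, by = 0.1)) {
  if (anyNA(dots$mhp) && nrow(dots) > 0L) stop("per-dot MHP values missing")
  if (is.unsorted(breaks, strictly = TRUE)) stop("breaks must be strictly increasing")
  nb <- length(breaks) - 1L
  bin <- findInterval(dots$mhp, breaks, rightmost.closed = TRUE)
  ok <- bin >= 1L & bin <= nb
  area <- vapply(seq_len(nb),
                 function(b) sum(dots$area[ok & bin == b]), 1.0)
  data.frame(lo = breaks[-length(breaks)], hi = breaks[-1L],
             mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
             area = area)
}
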