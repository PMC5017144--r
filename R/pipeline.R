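#' @title End-to-end drivers and configuration
#' @description A plain-text key/value configuration holding the mapping
#'   parameters (grid cell 3.4 A, dot density 3/A^2, probe 1.4 A, z range
#'   -20..20 A with dz 0.5, MHP decay 2 A, correlation threshold 0.7), and
#'   a driver that runs the requested stages in dependency order and writes
#'   TSV outputs with provenance headers.
#' @name cli_pipeline
NULL

#' Pipeline run configuration
#'
#' Defaults equal the standard mapping parameters.  Randomness anywhere in
#' a run flows from the single `seed`.
#'
#' @param ... Overrides of the defaults (see Details for fields).
#' @details Fields: `cell_size` (A), `dot_density` (/A^2), `probe` (A),
#'   `lambda` (A, MHP decay), `z_min`, `z_max`, `dz` (A), `alpha_bins`,
#'   `mhp_breaks_lo`, `mhp_breaks_hi`, `mhp_breaks_by`, `r_lmi_threshold`,
#'   `seed`, `out_prefix`, `verbose`.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(cell_size = 3.4, dot_density = 3, probe = 1.4, lambda = 2,
              z_min = -20, z_max = 20, dz = 0.5, alpha_bins = 36L,
              mhp_breaks_lo = -3, mhp_breaks_hi = 3, mhp_breaks_by = 0.1,
              r_lmi_threshold = 0.7, seed = 1L, out_prefix = "porescape",
              verbose = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration (lossless round trip)
#'
#' @param cfg A [run_config()].
#' @param path Text file (`key<TAB>value` lines).
#' @return `read_config` returns the reconstructed `run_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    val <- if (is.character(v)) v else
      paste(format(v, digits = 17, scientific = FALSE), collapse = ",")
    paste(k, val, sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  defaults <- run_config()
  cfg <- defaults
  for (p in parts) {
    k <- p[1]; v <- p[2]
    if (!k %in% names(defaults)) stop("unknown config key: ", k)
    proto <- defaults[[k]]
    cfg[[k]] <- if (is.character(proto)) v
      else if (is.logical(proto)) as.logical(v)
      else if (is.integer(proto)) as.integer(v)
      else as.numeric(v)
  }
  class(cfg) <- "run_config"
  cfg
}

# cheap djb2-style hash of the serialized config, for provenance headers
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 17), collapse = ","), ""), collapse = ";"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

provenance_header <- function(cfg) {
  ver <- tryCatch(as.character(utils::packageVersion("porescape")),
                  error = function(e) "dev")
  c(sprintf("# porescape %s", ver),
    sprintf("# config_hash %s", config_hash(cfg)))
}

write_tsv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(cfg), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

map_to_df <- function(map) {
  m <- as.data.frame(map$map)
  names(m) <- if (map$kind == "dynamic")
    sprintf("t%.4g", map$times) else sprintf("a%.4g", map$alpha)
  cbind(data.frame(z = map$z), m)
}

#' Run the pore-mapping pipeline
#'
#' Executes the requested stages in dependency order on a structure or
#' trajectory and writes one TSV per stage under `cfg$out_prefix` (`NaN`
#' marks undefined map cells).  Stages: `profile` (z, C(z), R(z), H(z), n),
#' `cmap` (cylindrical map), `mhpdist` (area-weighted surface-MHP
#' histogram of the pore border), `dmap` (dynamic map; needs a trajectory).
#' Outputs carry a provenance header (package version + config hash), so
#' identical runs produce byte-identical files.
#'
#' @param input A [structure3d()], a [trajectory3d()], or a path to a
#'   (multi-model) PDB file.
#' @param stages Character vector of stage names.
#' @param cfg A [run_config()].
#' @return Named list of output file paths (invisibly the computed objects
#'   are attached as attributes `"results"`).
#' @export
run_pipeline <- function(input, stages = c("profile", "cmap", "mhpdist"),
                         cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  known <- c("profile", "cmap", "mhpdist", "dmap")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.character(input)) {
    traj <- read_trajectory(input)
    input <- if (n_frames(traj) > 1L) traj else traj_frame(traj, 1L)
  }
  is_traj <- inherits(input, "trajectory3d")
  if ("dmap" %in% stages && !is_traj)
    stop("stage 'dmap' requires a trajectory input")
  say <- function(...) if (isTRUE(cfg$verbose)) message(...)
  outputs <- list(); results <- list()
  frame1 <- if (is_traj) traj_frame(input, 1L) else input
  need_border <- any(c("profile", "cmap", "mhpdist") %in% stages)
  if (need_border) {
    border <- frame_border(frame1, cfg$cell_size, cfg$dot_density,
                           cfg$probe, cfg$lambda)
    say("pore border: ", nrow(border), " dots")
    if ("profile" %in% stages) {
      prof <- pore_profile(border, cfg$z_min, cfg$z_max, cfg$dz)
      results$profile <- prof
      outputs$profile <- write_tsv(as.data.frame(prof),
                                   paste0(cfg$out_prefix, "_profile.tsv"), cfg)
    }
    if ("cmap" %in% stages) {
      cm <- cylindrical_map(border, "mhp", cfg$alpha_bins,
                            cfg$z_min, cfg$z_max, cfg$dz)
      results$cmap <- cm
      outputs$cmap <- write_tsv(map_to_df(cm),
                                paste0(cfg$out_prefix, "_cmap.tsv"), cfg)
    }
    if ("mhpdist" %in% stages) {
      breaks <- seq(cfg$mhp_breaks_lo, cfg$mhp_breaks_hi, by = cfg$mhp_breaks_by)
      dist <- mhp_distribution(border, breaks)
      results$mhpdist <- dist
      outputs$mhpdist <- write_tsv(dist,
                                   paste0(cfg$out_prefix, "_mhpdist.tsv"), cfg)
    }
  }
  if ("dmap" %in% stages) {
    dm <- dynamic_map(input, "radius", cfg$cell_size, cfg$dot_density,
                      cfg$probe, cfg$lambda, cfg$z_min, cfg$z_max, cfg$dz)
    results$dmap <- dm
    outputs$dmap <- write_tsv(map_to_df(dm),
                              paste0(cfg$out_prefix, "_dmap.tsv"), cfg)
  }
  attr(outputs, "results") <- results
  outputs
}

#' Export a dot surface
#'
#' TSV (`x`, `y`, `z`, `area`, `owner`, `mhp`) or PDB pseudo-atoms (one
#' HETATM per dot, MHP in the B-factor column) for visualization.
#'
#' @param dots A `dotset`.
#' @param path Output file.
#' @param format `"tsv"` or `"pdb"`.
#' @export
write_dotset <- function(dots, path, format = c("tsv", "pdb")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(as.data.frame(dots)[, c("x", "y", "z", "area",
                                               "owner", "mhp")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    n <- nrow(dots)
    b <- dots$mhp; b[is.na(b)] <- 0
    lines <- sprintf(
      "HETATM%5d  DOT SRF A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           D",
      seq_len(n) %% 100000L, seq_len(n) %% 10000L,
      dots$x, dots$y, dots$z, pmin(dots$area, 99.99), pmax(pmin(b, 99.99), -9.99))
    writeLines(c(lines, "END"), path)
  }
  invisible(path)
}
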