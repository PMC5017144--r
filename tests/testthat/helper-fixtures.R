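# Shared fixture builders.  Channels used in unit tests are shortened along
# z relative to the defaults to keep the suite fast; the acceptance tests
# use the full-length geometry.

atom_df <- function(n, name = "C", element = "C", resname = "ALA",
                    resno = 1L, chain = "A") {
  data.frame(id = seq_len(n), name = name, element = element,
             resname = resname, resno = resno, chain = chain,
             stringsAsFactors = FALSE)
}

one_atom <- function(element = "C") {
  structure3d(atom_df(1, element = element), matrix(0, 1, 3))
}

short_channel <- function(r = 5, ...) {
  channel_spec(radius_profile = function(z) rep(r, length(z)),
               z_range = c(-10, 10), ...)
}

# border + profile for a structure, optionally with MHP
channel_profile <- function(ch, z_min = -10, z_max = 10, with_mhp = TRUE) {
  if (with_mhp) ch <- assign_constants(ch)
  dots <- dot_surface(ch)
  if (with_mhp) dots <- surface_mhp(dots, ch)
  b <- pore_border(dots, detect_pore(build_grid(ch)))
  pore_profile(b, z_min, z_max, 0.5)
}

# small 4-chain C-alpha scaffold for motion tests
ca_scaffold <- function(n_res = 25L, seed = 3L) {
  n <- 4L * n_res
  atoms <- atom_df(n, name = "CA", resname = "GLY",
                   resno = rep(seq_len(n_res), 4L),
                   chain = rep(LETTERS[1:4], each = n_res))
  set.seed(seed)
  structure3d(atoms, matrix(rnorm(3 * n, sd = 10), n, 3))
}

rand_rotation <- function(seed = 1L) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
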