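test_that("occupancy grid marks exactly the cells holding atom centres", {
  g1 <- build_grid(one_atom())
  expect_equal(sum(g1$occ), 1L, ignore_attr = TRUE)
  expect_error(build_grid(one_atom(), cell_size = 0), "positive")
  # empty structures are rejected at construction
  empty_atoms <- data.frame(id = integer(0), name = character(0),
                            element = character(0), resname = character(0),
                            resno = integer(0), chain = character(0))
  expect_error(structure3d(empty_atoms, matrix(0, 0, 3)), "at least one atom")
  # toy cylinder: the axial column stays unoccupied
  ch <- make_channel(short_channel(r = 5))
  g <- build_grid(ch)
  mid <- (g$dim + 1) %/% 2
  expect_false(any(g$occ[mid[1], mid[2], ]))
})

test_that("pore detection excludes bulk, merges stacked cavities, errors on solids", {
  # solid block: no cavity anywhere
  g <- as.matrix(expand.grid(x = seq(0, 8, 2), y = seq(0, 8, 2), z = seq(0, 8, 2)))
  solid <- structure3d(atom_df(nrow(g)), g)
  expect_error(detect_pore(build_grid(solid)), "no interior cavity")
  # open cylinder: one cavity spanning the z extent
  ch <- make_channel(short_channel(r = 5))
  cav <- detect_pore(build_grid(ch))
  grid <- cav$grid
  zspan <- range(cav$ijk[, 3])
  atoms_k <- range(floor((ch$xyz[, 3] - grid$origin[3]) / grid$cell_size) + 1)
  expect_lte(atoms_k[1], zspan[1])
  expect_gte(zspan[2] + 1, atoms_k[2])
  # plugged channel: two vestibules stacked on the axis merge into one pore
  plugged <- make_channel(short_channel(r = 5, plugs = 0))
  cavp <- detect_pore(build_grid(plugged))
  ks <- sort(unique(cavp$ijk[, 3]))
  expect_gt(diff(range(ks)), 2)         # spans both vestibules
  expect_true(any(diff(ks) > 1))        # with a gap at the plug
})

test_that("pore border keeps dots in cavity cells and their 26-neighbourhood only", {
  ch <- make_channel(short_channel(r = 5))
  dots <- dot_surface(ch)
  cav <- detect_pore(build_grid(ch))
  b <- pore_border(dots, cav)
  # brute-force membership oracle
  grid <- cav$grid
  cell_of <- function(p) floor((p - grid$origin) / grid$cell_size) + 1
  cav_cells <- cav$ijk
  in_border <- function(p) {
    c0 <- cell_of(p)
    any(abs(cav_cells[, 1] - c0[1]) <= 1 &
        abs(cav_cells[, 2] - c0[2]) <= 1 &
        abs(cav_cells[, 3] - c0[3]) <= 1)
  }
  set.seed(2)
  probe_idx <- sample(nrow(dots), 300)
  expected <- vapply(probe_idx, function(i)
    in_border(c(dots$x[i], dots$y[i], dots$z[i])), TRUE)
  key <- function(d) paste(round(d$x, 6), round(d$y, 6), round(d$z, 6))
  got <- key(dots[probe_idx, ]) %in% key(b)
  expect_equal(got, expected)
})

test_that("profiles recover constructed geometry", {
  # hydrophilic cylinder of radius 5
  p <- channel_profile(make_channel(short_channel(r = 5)))
  sel <- p$defined & abs(p$z) < 7
  expect_lt(mean(abs(p$R[sel] - 5)), 0.5)
  expect_true(all(p$H[sel] < 0))
  # hourglass: R(z) minimum at the constriction
  hour <- short_channel()
  hour$radius_profile <- function(z) 7 - 4 * exp(-(z - 2)^2 / 8)
  ph <- channel_profile(make_channel(hour))
  selh <- ph$defined & abs(ph$z) < 7
  expect_lt(abs(ph$z[selh][which.min(ph$R[selh])] - 2), 1.5)
  # fully blocked slab is undefined / occluded on the profile
  blocked <- channel_profile(make_channel(short_channel(r = 5, plugs = 0)),
                             with_mhp = FALSE)
  z0 <- blocked[abs(blocked$z) <= 0.5, ]
  expect_true(all(!z0$defined | z0$R < 1))
})

test_that("radial dilation of the walls increases R(z) by the dilation", {
  p5 <- channel_profile(make_channel(short_channel(r = 5)), with_mhp = FALSE)
  p7 <- channel_profile(make_channel(short_channel(r = 7)), with_mhp = FALSE)
  sel <- p5$defined & p7$defined & abs(p5$z) < 7
  expect_equal(mean(p7$R[sel] - p5$R[sel]), 2, tolerance = 0.25)
})

test_that("cylindrical maps respect symmetry and integrate to the 1D profile", {
  sp <- short_channel(ring_pattern = function(z)
    if (abs(z - 1) < 2) "phobic" else "philic")
  ch <- assign_constants(make_channel(sp))
  dots <- surface_mhp(dot_surface(ch), ch)
  b <- pore_border(dots, detect_pore(build_grid(ch)))
  cm <- cylindrical_map(b, "mhp", alpha_bins = 36, z_min = -10, z_max = 10)
  # 4-fold symmetry: rotating by 90 degrees (9 bins) leaves the map unchanged
  rot <- cm$map[, c(10:36, 1:9)]
  ok <- !is.na(cm$map) & !is.na(rot)
  expect_gt(sum(ok), 100)
  expect_lt(mean(abs(cm$map[ok] - rot[ok])), 0.5)
  # azimuthal mean of the map reproduces H(z)
  prof <- pore_profile(b, -10, 10, 0.5)
  hbar <- rowMeans(cm$map, na.rm = TRUE)
  sel <- prof$defined & abs(prof$z) < 7 & !is.nan(hbar)
  expect_gt(stats::cor(hbar[sel], prof$H[sel]), 0.95)
  # the hydrophobic ring shows up as the only positive band
  expect_true(all(prof$H[sel][abs(prof$z[sel] - 1) < 1] > 0))
  expect_true(all(prof$H[sel][abs(prof$z[sel] - 1) > 4] < 0))
})

test_that("dynamic maps are per-frame profiles with openings flagged", {
  sp <- channel_spec(radius_profile = function(z) rep(4, length(z)),
                     z_range = c(-7, 7), plugs = 0)
  gt <- make_gating_trajectory(sp, onset_frame = 4, n_frames = 6,
                               noise_sd = 0, seed = 5)
  dm <- dynamic_map(gt, "radius", z_min = -7, z_max = 7)
  expect_equal(ncol(dm$map), 6L, ignore_attr = TRUE)
  # noise-free: pre-onset columns identical, post-onset columns identical
  expect_equal(dm$map[, 2], dm$map[, 1])
  expect_equal(dm$map[, 6], dm$map[, 5])
  # gate band closed before onset, open after (within +/- 2 frames)
  fr <- detect_opening(dm, z_gate = 0)
  expect_lte(abs(fr - 4), 2)
  # column equals an independent single-frame run
  b3 <- pore_border(dot_surface(traj_frame(gt, 5)),
                    detect_pore(build_grid(traj_frame(gt, 5))))
  p3 <- pore_profile(b3, -7, 7, 0.5)
  expect_equal(dm$map[, 5], p3$R)
})

test_that("axis alignment restores rotated channels and rejects asymmetric blobs", {
  # elongated channel: the dominant principal axis is unambiguously the pore
  sp <- channel_spec(radius_profile = function(z) rep(4, length(z)),
                     z_range = c(-14, 14))
  ch <- make_channel(sp)
  expect_identical(align_pore_axis(ch, "none"), ch)
  # rotate the channel arbitrarily, re-align by PCA, profiles must agree
  R <- rand_rotation(9)
  rot <- ch
  rot$xyz <- ch$xyz %*% R + matrix(c(8, -3, 5), nrow(ch$xyz), 3, byrow = TRUE)
  real <- align_pore_axis(rot, "pca")
  p0 <- channel_profile(ch, z_min = -12, z_max = 12, with_mhp = FALSE)
  p1 <- channel_profile(real, z_min = -12, z_max = 12, with_mhp = FALSE)
  sel <- p0$defined & p1$defined & abs(p0$z) < 10
  expect_lt(mean(abs(p0$R[sel] - p1$R[sel])), 0.3)
  # c4 mode accepts the 4-fold channel, rejects a random blob
  expect_silent(align_pore_axis(rot, "c4"))
  set.seed(4)
  blob <- structure3d(atom_df(60), matrix(rnorm(180, sd = 6), 60, 3))
  expect_error(align_pore_axis(blob, "c4"), "4-fold")
})
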