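test_that("covariance blocks match the direct-sum oracle and degenerate cases", {
  base <- ca_scaffold(n_res = 5, seed = 21)
  # frozen trajectory: all covariances vanish
  frozen <- trajectory3d(base, array(rep(base$xyz, 12), c(n_atoms(base), 3, 12)),
                         times = seq_len(12))
  cb0 <- covariance_blocks(frozen, ca_indices = 1:4)
  expect_true(all(abs(cb0$cov) < 1e-12))
  # 1D harmonic wiggle of one atom: one nonzero eigenvalue equal to the
  # signal variance
  nf <- 200L
  sig <- 0.8 * sin(seq_len(nf) / 5)
  coords <- array(rep(base$xyz, nf), c(n_atoms(base), 3, nf))
  coords[3, 1, ] <- coords[3, 1, ] + sig
  wig <- trajectory3d(base, coords, times = seq_len(nf))
  cb <- covariance_blocks(wig, ca_indices = 1:5)
  C3 <- cb$cov[7:9, 7:9]
  ev <- eigen(C3, symmetric = TRUE)$values
  expect_equal(ev[1], stats::var(sig), tolerance = 1e-10)
  expect_lt(ev[2], 1e-12)
  # random small trajectory against the oracle
  ms <- motion_spec(n_frames = 50L, groups = list(
    list(members = list(1:2, 4:5), amplitude = 0.7, rho = 0.6)),
    noise_sd = 0.2, seed = 31L)
  tr <- make_trajectory(base, ms)
  cb2 <- covariance_blocks(tr, ca_indices = c(1L, 2L, 4L))
  expect_equal(cb2$cov, oracle_covariance(tr, c(1L, 2L, 4L)), tolerance = 1e-10)
  expect_error(covariance_blocks(frozen, 1:4, fit_indices = 1:2), "3 atoms")
})

test_that("r_LMI obeys its closed form, bounds and limits", {
  base <- structure3d(atom_df(2, name = "CA", resname = "GLY", resno = 1:2),
                      matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE))
  run <- function(rho, nf = 4000L, seed = 42L) {
    ms <- motion_spec(n_frames = nf, groups = list(
      list(members = list(1L, 2L), amplitude = 1, rho = rho)),
      noise_sd = 0, seed = seed)
    lmi_matrix(covariance_blocks(make_trajectory(base, ms), 1:2))
  }
  # identical motion saturates at 1
  r1 <- run(1)
  expect_equal(r1$r[1, 2], 1, tolerance = 1e-6)
  expect_equal(diag(r1$r), c(1, 1))
  # independence: small finite-sample value
  expect_lt(run(0, nf = 10000L)$r[1, 2], 0.1)
  # closed form r_LMI = |rho| for the isotropic coupled pair
  expect_equal(run(0.6, nf = 10000L)$r[1, 2], 0.6, tolerance = 0.02)
  expect_equal(run(-0.6, nf = 10000L)$r[1, 2], 0.6, tolerance = 0.02)
  # matrix properties on a larger random system
  sc <- ca_scaffold(n_res = 6, seed = 2)
  ms <- motion_spec(n_frames = 300L, groups = list(
    list(members = list(1:6, 13:18), amplitude = 0.5, rho = 0.4)),
    noise_sd = 0.3, seed = 8L)
  lr <- lmi_matrix(covariance_blocks(make_trajectory(sc, ms), seq_len(24)))
  expect_true(isSymmetric(lr$r))
  expect_true(all(lr$r >= 0 & lr$r <= 1))
  expect_equal(diag(lr$r), rep(1, 24))
})

test_that("correlated regions isolate the constructed common-mode residues", {
  sc <- ca_scaffold(n_res = 25, seed = 3)
  grp <- which(sc$atoms$chain == "A" & sc$atoms$resno %in% 10:20)
  ms <- motion_spec(n_frames = 1500L, groups = list(
    list(members = list(grp), amplitude = 1, rho = 1)),
    noise_sd = 0.3, seed = 9L)
  lr <- lmi_matrix(covariance_blocks(make_trajectory(sc, ms),
                                     seq_len(n_atoms(sc))))
  ref <- which(sc$atoms$chain == "A" & sc$atoms$resno == 15)
  reg <- correlated_region(lr, ref, threshold = 0.7)
  expect_true(all(reg$chain == "A"))
  expect_equal(sort(reg$resno), 10:20)
  # reference addressable by chain/resno too
  reg2 <- correlated_region(lr, list(chain = "A", resno = 15), threshold = 0.7)
  expect_equal(reg2, reg)
  # threshold 1 keeps only perfect correlations (the reference itself)
  self <- correlated_region(lr, ref, threshold = 1)
  expect_equal(nrow(self), 1L, ignore_attr = TRUE)
  expect_equal(self$resno, 15L, ignore_attr = TRUE)
  # threshold 0 keeps everything
  expect_equal(nrow(correlated_region(lr, ref, threshold = 0)),
               n_atoms(sc), ignore_attr = TRUE)
})

test_that("quadrilateral areas agree with the shoelace oracle and invariances", {
  sq <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0), 4, 3, byrow = TRUE)
  expect_equal(quadrilateral_area(sq), 1)
  expect_equal(quadrilateral_area(3.9 * sq), 15.21)
  # ordering comes from azimuth, so shuffled input gives the same area
  expect_equal(quadrilateral_area(sq[c(3, 1, 4, 2), ]), 1)
  # random planar convex quadrilateral vs shoelace in its plane (convexity
  # makes the azimuthal ordering agree with the construction order)
  set.seed(14)
  for (k in 1:5) {
    ang <- sort(stats::runif(4, 0, 2 * pi))
    quad <- cbind(3 * cos(ang), 2 * sin(ang), 0)
    R <- rand_rotation(k); shift <- stats::rnorm(3)
    quad3 <- quad %*% R + matrix(shift, 4, 3, byrow = TRUE)
    # axis must follow the rotated plane normal for azimuthal ordering
    expect_equal(quadrilateral_area(quad3, axis = c(0, 0, 1) %*% R),
                 oracle_shoelace(quad), tolerance = 1e-9)
  }
  # collinear degenerates to zero with a warning
  line <- cbind(c(0, 1, 2, 3), 0, 0)
  expect_warning(a0 <- quadrilateral_area(line), "degenerate")
  expect_equal(a0, 0, tolerance = 1e-9)
})

test_that("axis distances trace individual chains, not averages", {
  sc <- ca_scaffold(n_res = 4, seed = 6)
  onaxis <- structure3d(atom_df(4, name = "CA",
                                chain = LETTERS[1:4], resno = 1L),
                        matrix(c(0, 0, 0, 3, 0, 1, 0, 4, 2, -3, 0, 3),
                               4, 3, byrow = TRUE))
  frames <- array(rep(onaxis$xyz, 5), c(4, 3, 5))
  tr <- trajectory3d(onaxis, frames, times = 1:5)
  d <- axis_distance_series(tr, 1:4, axis_indices = 1L)
  expect_equal(unname(d[, 1]), rep(0, 5))          # atom on the axis
  expect_equal(unname(d[, 2]), rep(3, 5))          # atom at (3, 0, z)
  # single-chain outward ramp moves only that chain's trace
  ms <- motion_spec(n_frames = 20L, ramp = list(indices = 2L,
    direction = c(1, 0, 0), amplitude = 3, onset = 11L),
    noise_sd = 0, seed = 1L)
  tr2 <- make_trajectory(onaxis, ms)
  d2 <- axis_distance_series(tr2, 1:4, axis_indices = 1L)
  expect_equal(unname(d2[20, 2] - d2[1, 2]), 3, tolerance = 1e-9)
  expect_equal(unname(d2[20, 3]), unname(d2[1, 3]), tolerance = 1e-9)
  expect_equal(unname(d2[20, 4]), unname(d2[1, 4]), tolerance = 1e-9)
})

test_that("bend angles read kinks and ignore rigid motion", {
  # ideal straight alpha-helix: 30 residues, 1.5 A rise, 100 degree twist;
  # flanks long enough that the least-squares axes track the helix axis
  t <- seq_len(30)
  helix <- cbind(2.3 * cos(t * 100 * pi / 180),
                 2.3 * sin(t * 100 * pi / 180), 1.5 * t)
  s <- structure3d(atom_df(30, name = "CA", resno = 1:30), helix)
  tr <- trajectory3d(s, array(rep(helix, 3), c(30, 3, 3)), times = 1:3)
  ang <- bend_angle_series(tr, 1:30, pivot = 15)
  expect_lt(max(ang), 5)
  # construct a 40-degree kink by rotating the second flank
  th <- 40 * pi / 180
  Rk <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)),
               3, 3, byrow = TRUE)
  bent <- helix
  pivot_pt <- helix[15, ]
  bent[16:30, ] <- sweep(sweep(helix[16:30, ], 2, pivot_pt) %*% Rk, 2,
                         pivot_pt, `+`)
  trb <- trajectory3d(s, array(rep(bent, 3), c(30, 3, 3)), times = 1:3)
  angb <- bend_angle_series(trb, 1:30, pivot = 15)
  expect_equal(angb[1], 40, tolerance = 2)
  # rigid rotation of the whole helix leaves the angle unchanged
  R <- rand_rotation(17)
  rot <- bent %*% R
  trr <- trajectory3d(s, array(rep(rot, 3), c(30, 3, 3)), times = 1:3)
  expect_equal(bend_angle_series(trr, 1:30, pivot = 15)[1], angb[1],
               tolerance = 1e-6)
  expect_error(bend_angle_series(tr, 1:30, pivot = 2), "4 residues")
})
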