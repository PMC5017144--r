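test_that("hydrophobicity constants follow chemical sign conventions", {
  alk <- assign_constants(make_alkane(6))
  expect_true(all(alk$atoms$f > 0))           # aliphatic carbons hydrophobic
  pep <- structure3d(
    atom_df(4, name = c("N", "CA", "C", "O"),
            element = c("N", "C", "C", "O"), resname = "ALA"),
    matrix(rnorm(12), 4, 3))
  pep <- assign_constants(pep)
  expect_lt(pep$atoms$f[pep$atoms$name == "O"], 0)  # carbonyl O polar
  expect_lt(pep$atoms$f[pep$atoms$name == "N"], 0)
  # all-zero table zeroes every constant
  zero <- mhp_table()
  zero$f <- 0
  expect_true(all(assign_constants(make_alkane(5), zero)$atoms$f == 0))
})

test_that("dot surface reproduces sphere areas and removes buried atoms", {
  d1 <- dot_surface(one_atom())
  expect_equal(sum(d1$area), 4 * pi * 1.7^2, tolerance = 0.01)
  # two coincident atoms expose the same surface as one
  two <- structure3d(atom_df(2), matrix(0, 2, 3))
  expect_equal(sum(dot_surface(two)$area), 4 * pi * 1.7^2, tolerance = 0.05)
  # an atom caged by close neighbours contributes no dots
  g <- as.matrix(expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2), z = c(-2, 0, 2)))
  cage <- structure3d(atom_df(27), g)
  expect_false(14L %in% dot_surface(cage)$owner)  # centre atom buried
  # halving or doubling the density leaves total area unbiased (within the
  # per-dot quantization noise of the coarser lattice)
  hex <- make_alkane(6)
  a3 <- sum(dot_surface(hex, dot_density = 3)$area)
  a1 <- sum(dot_surface(hex, dot_density = 1.5)$area)
  a6 <- sum(dot_surface(hex, dot_density = 6)$area)
  expect_equal(a1, a3, tolerance = 0.07)
  expect_equal(a6, a3, tolerance = 0.04)
})

test_that("MHP field matches the direct sum and is linear and rigid-invariant", {
  s <- structure3d(atom_df(3), matrix(c(0, 0, 0, 2, 0, 0, 0, 3, 1), 3, 3,
                                      byrow = TRUE))
  s$atoms$f <- c(1, -0.5, 0.3)
  pts <- matrix(c(1, 1, 1, -2, 0.5, 0, 4, 4, 4), 3, 3, byrow = TRUE)
  expect_equal(mhp_at_points(s, pts), oracle_mhp(s, pts), tolerance = 1e-9)
  # exp(0) = 1 at an isolated atom centre with f = 1
  one <- one_atom(); one$atoms$f <- 1
  expect_equal(mhp_at_points(one, matrix(0, 1, 3)), 1)
  # linearity in the constants
  s2 <- s; s2$atoms$f <- 2 * s$atoms$f
  expect_equal(mhp_at_points(s2, pts), 2 * mhp_at_points(s, pts))
  # joint rigid transform of structure and points leaves MHP unchanged
  R <- rand_rotation(7); shift <- c(4, -2, 1)
  sr <- s; sr$xyz <- s$xyz %*% R + matrix(shift, 3, 3, byrow = TRUE)
  ptr <- pts %*% R + matrix(shift, 3, 3, byrow = TRUE)
  expect_equal(mhp_at_points(sr, ptr), mhp_at_points(s, pts), tolerance = 1e-9)
})

test_that("total surface MHP is additive over disjoint molecules", {
  empty <- dot_surface(one_atom())[0, ]
  expect_equal(total_surface_mhp(empty), 0)
  a <- assign_constants(make_alkane(5))
  b <- assign_constants(make_alkane(6))
  b$xyz <- b$xyz + 50  # far apart: no mutual burial or MHP overlap
  ta <- total_surface_mhp(surface_mhp(dot_surface(a), a))
  tb <- total_surface_mhp(surface_mhp(dot_surface(b), b))
  both <- structure3d(rbind(
    transform(a$atoms, id = seq_len(nrow(a$atoms))),
    transform(b$atoms, id = nrow(a$atoms) + seq_len(nrow(b$atoms)),
              resno = 2L)),
    rbind(a$xyz, b$xyz))
  tboth <- total_surface_mhp(surface_mhp(dot_surface(both), both))
  expect_equal(tboth, ta + tb, tolerance = 1e-6)
})

test_that("methylene calibration recovers the per-CH2 increment", {
  cal <- methylene_calibration(list(make_alkane(5), make_alkane(6)))
  expect_equal(cal$slope, 50, tolerance = 0.01)
  # exactly linear synthetic series -> exact slope
  fit <- ch2_slope(4:8, 50 * (4:8) + 17)
  expect_equal(fit$slope, 50, tolerance = 1e-10)
  expect_error(methylene_calibration(list(make_alkane(5), make_alkane(5))),
               "differ in carbon count")
  expect_error(methylene_calibration(list(make_alkane(5))), "at least two")
})

test_that("MHP distributions are area-weighted and subtract bin-wise", {
  d <- dot_surface(make_alkane(4))
  d$mhp <- 0.55
  h <- mhp_distribution(d, breaks = seq(-1, 1, by = 0.1))
  expect_equal(sum(h$area > 0), 1L, ignore_attr = TRUE)
  expect_equal(sum(h$area), sum(d$area))
  expect_error(mhp_distribution(d, breaks = c(0, -1, 1)), "increasing")
  # identical sets difference is identically zero
  expect_true(all(h$area - h$area == 0))
  # constructed area excess A appears as the difference integral
  d2 <- d
  extra <- d[seq_len(10), ]
  extra$mhp <- 0.95
  d2 <- rbind(d2, extra)
  h2 <- mhp_distribution(d2, breaks = seq(-1, 1, by = 0.1))
  expect_equal(sum(h2$area - h$area), sum(extra$area))
})

test_that("a hydrophobic-belt channel shows a two-modal pore-surface MHP distribution", {
  sp <- short_channel(ring_pattern = function(z)
    if (abs(z) < 4) "phobic" else "philic")
  ch <- assign_constants(make_channel(sp))
  dots <- surface_mhp(dot_surface(ch), ch)
  b <- pore_border(dots, detect_pore(build_grid(ch)))
  h <- mhp_distribution(b, breaks = seq(-15, 15, by = 1))
  # distinct hydrophilic (negative) and hydrophobic (positive) modes
  neg <- h$area[h$mid < 0]; pos <- h$area[h$mid > 0]
  expect_gt(max(neg), 0)
  expect_gt(max(pos), 0)
  # modes are separated by a valley around zero
  valley <- h$area[abs(h$mid) <= 1]
  expect_lt(max(valley), max(neg))
  expect_lt(max(valley), max(pos))
})
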