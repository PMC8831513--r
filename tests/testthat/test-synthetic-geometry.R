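# Phantom generation, wall-shell extraction, surfaces, and mask round trips.

test_that("sphere phantom voxelizes the analytic volume and is reproducible", {
  g <- sphere_phantom_r2()
  analytic <- 4 / 3 * pi * 2^3
  vox <- sum(g$labels == 2L) * prod(g$spacing)
  expect_lt(abs(vox / analytic - 1), 0.02)

  g2 <- generate_phantom(phantom_spec("sphere", radius = 2, seed = 1))
  expect_identical(g$labels, g2$labels)
})

test_that("voxelized cavity volume converges to the analytic volume", {
  err <- sapply(c(0.2, 0.1), function(h) {
    g <- generate_phantom(phantom_spec("sphere", radius = 1.3, spacing = h,
                                       wall_thickness = 2 * h, padding = 0.6))
    abs(sum(g$labels == 2L) * h^3 / (4 / 3 * pi * 1.3^3) - 1)
  })
  expect_lt(err[2], err[1])
})

test_that("lobulated phantoms are single 6-connected cavities with the wall separation", {
  for (seed in c(7, 11)) {
    g <- generate_phantom(phantom_spec("lobulated", semi_axes = c(1.4, 1, 0.8),
                                       n_lobules = 4, lobule_amplitude = 0.5,
                                       spacing = 0.15, wall_thickness = 0.3,
                                       padding = 0.6, seed = seed))
    expect_silent(validate_label_grid(g))
    # determinism across calls
    g2 <- generate_phantom(phantom_spec("lobulated", semi_axes = c(1.4, 1, 0.8),
                                        n_lobules = 4, lobule_amplitude = 0.5,
                                        spacing = 0.15, wall_thickness = 0.3,
                                        padding = 0.6, seed = seed))
    expect_identical(g$labels, g2$labels)
  }
  # independent flood-fill oracle on a down-scaled lobulated cavity
  g <- generate_phantom(phantom_spec("lobulated", semi_axes = c(0.8, 0.6, 0.5),
                                     n_lobules = 4, lobule_amplitude = 0.35,
                                     spacing = 0.2, wall_thickness = 0.4,
                                     padding = 0.4, seed = 7))
  expect_identical(oracle_n_components(g$labels == 2L), 1)
})

test_that("phantom specs are validated", {
  expect_error(phantom_spec("sphere", radius = 4.2), "8 cm")
  expect_error(phantom_spec("lobulated", semi_axes = c(3.8, 2, 2),
                            lobule_amplitude = 0.5), "8 cm")
  expect_error(phantom_spec("sphere", radius = 0.05, spacing = 0.1),
               "degenerate")
  expect_error(phantom_spec("sphere", radius = 2, wall_thickness = 0.05,
                            spacing = 0.1), "wall thickness")
})

test_that("wall shell equals the brute-force distance-transform oracle", {
  set.seed(42)
  cav <- array(FALSE, c(12, 12, 12))
  cav[5:8, 5:8, 5:8] <- TRUE
  cav[9, 6, 6] <- TRUE  # protrusion
  h <- c(0.1, 0.1, 0.2)  # anisotropic
  for (t in c(0.2, 0.35)) {
    g <- extract_wall_shell(cav, h, t)
    expect_identical(g$labels == 1L, oracle_wall_shell(cav, h, t))
    expect_silent(validate_label_grid(g))
  }
})

test_that("one-voxel cavity with one-voxel thickness has its full 26-neighborhood ball wall", {
  cav <- array(FALSE, c(7, 7, 7)); cav[4, 4, 4] <- TRUE
  g <- extract_wall_shell(cav, 0.1, 0.1)
  w <- which(g$labels == 1L, arr.ind = TRUE)
  off <- abs(sweep(w, 2, c(4, 4, 4)))
  # center distance <= 0.1: exactly the 6 face neighbors
  expect_identical(nrow(w), 6L)
  expect_true(all(rowSums(off) == 1))
  # at larger thickness the Euclidean ball picks up the diagonal voxels too
  g2 <- extract_wall_shell(cav, 0.1, 0.15)
  expect_identical(sum(g2$labels == 1L), 18L)  # faces + edge diagonals
})

test_that("digitized wall shell volume converges toward the analytic shell", {
  rel_err <- sapply(c(0.1, 0.05), function(h) {
    g <- generate_phantom(phantom_spec("sphere", radius = 2, spacing = h,
                                       seed = 1))
    sum(g$labels == 1L) * h^3 / (4 / 3 * pi * (2.2^3 - 2^3)) - 1
  })
  expect_lt(abs(rel_err[2]), abs(rel_err[1]))
  expect_lt(abs(rel_err[2]), 0.10)
})

test_that("thickness below spacing is refused and a spanning wall warns", {
  cav <- array(FALSE, c(6, 6, 6)); cav[3:4, 3:4, 3:4] <- TRUE
  expect_error(extract_wall_shell(cav, 0.1, 0.05), "thickness")
  expect_warning(extract_wall_shell(cav, 0.1, 2), "no exterior")
})

test_that("cavity centroid is the physical center of mass", {
  g <- sphere_phantom_r2()
  ctr <- dim(g$labels) * g$spacing / 2
  com <- cavity_center_of_mass(g)
  expect_true(all(abs(com$point - ctr) <= g$spacing / 2))
  expect_true(com$inside)

  # single cavity voxel: exactly its center
  cav <- array(FALSE, c(7, 7, 7)); cav[2, 3, 5] <- TRUE
  g1 <- extract_wall_shell(cav, 0.1, 0.1)
  expect_equal(cavity_center_of_mass(g1)$point,
               (c(2, 3, 5) - 1) * 0.1 + 0.05)

  # two blobs merged under one label: centroid between them, flagged
  lab <- array(0L, c(13, 7, 7))
  lab[2:3, 3:5, 3:5] <- 2L
  lab[11:12, 3:5, 3:5] <- 2L
  lab[1:4, 2:6, 2:6][lab[1:4, 2:6, 2:6] == 0L] <- 1L
  lab[10:13, 2:6, 2:6][lab[10:13, 2:6, 2:6] == 0L] <- 1L
  lab[5:9, 3:5, 3:5] <- 1L  # bridge of wall keeps separation
  g2 <- label_grid(lab, rep(0.1, 3), check = FALSE)
  idx <- which(lab == 2L, arr.ind = TRUE)
  manual <- colMeans(sweep(sweep(idx - 1, 2, g2$spacing, `*`), 2,
                           g2$origin, `+`))
  expect_warning(com2 <- cavity_center_of_mass(g2), "outside")
  expect_equal(com2$point, unname(manual))
  expect_false(com2$inside)
})

test_that("wall surface voxels face the cavity and the sphere area is recovered", {
  g <- sphere_phantom_r2()
  s <- wall_surface(g)
  expect_true(all(g$labels[s$voxels] == 1L))
  # every surface voxel has >= 1 cavity 6-neighbor
  d <- dim(g$labels)
  has_cav <- rep(FALSE, nrow(s$voxels))
  for (ax in 1:3) for (sg in c(-1L, 1L)) {
    nb <- s$voxels; nb[, ax] <- nb[, ax] + sg
    ok <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
    hit <- ok; hit[ok] <- g$labels[nb[ok, , drop = FALSE]] == 2L
    has_cav <- has_cav | hit
  }
  expect_true(all(has_cav))
  expect_lt(abs(sum(s$area) / (4 * pi * 4) - 1), 0.10)
})

test_that("degenerate wall surfaces enumerate correctly", {
  # 1-voxel cavity: its 6 face neighbors
  cav <- array(FALSE, c(7, 7, 7)); cav[4, 4, 4] <- TRUE
  s <- wall_surface(extract_wall_shell(cav, 0.1, 0.1))
  expect_identical(nrow(s$voxels), 6L)
  # flat slab: two opposing layers plus the rim
  cav2 <- array(FALSE, c(9, 9, 5)); cav2[3:7, 3:7, 3] <- TRUE
  s2 <- wall_surface(extract_wall_shell(cav2, 0.1, 0.1))
  expect_identical(nrow(s2$voxels), 2L * 25L + 4L * 5L)
})

test_that("masks round-trip through NIfTI and binary masks grow a wall", {
  g <- generate_phantom(phantom_spec("sphere", radius = 1, spacing = 0.1,
                                     padding = 0.5))
  f <- tempfile(fileext = ".nii")
  save_mask(g, f)
  g2 <- load_mask(f)
  expect_identical(g2$labels, g$labels)
  expect_equal(g2$spacing, g$spacing)

  # binary cavity mask: loader must reproduce extract_wall_shell
  cav <- g$labels == 2L
  fb <- tempfile(fileext = ".nii")
  save_mask(label_grid(array(as.integer(cav), dim(cav)), g$spacing,
                       check = FALSE), fb)
  g3 <- load_mask(fb, wall_thickness = 0.2)
  ref <- extract_wall_shell(cav, g$spacing, 0.2)
  expect_identical(g3$labels, ref$labels)

  # all-zero volume is an empty-geometry error
  fz <- tempfile(fileext = ".nii")
  save_mask(label_grid(array(0L, c(8, 8, 8)), rep(0.1, 3), check = FALSE), fz)
  expect_error(load_mask(fz), "empty geometry")
})

test_that("label grids reject cavity voxels touching exterior", {
  lab <- array(0L, c(6, 6, 6))
  lab[3:4, 3:4, 3:4] <- 2L  # no wall at all
  expect_error(label_grid(lab, rep(0.1, 3)), "6-adjacent")
})
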