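# Monte Carlo kernel: source model, elementary samplers, conservation,
# determinism, and geometry-driven fluence structure. The quantitative
# closed-form transport oracles (inverse square, Beer-Lambert, diffusion)
# live in test-acceptance.R.

test_that("fiber launches fill the core disk and the acceptance cone in the medium", {
  src <- fiber_source(c(0, 0, 0), direction = c(0, 0, 1))
  L <- sample_launch(src, 1e5, seed = 11, n_medium = 1.33)
  r <- sqrt(L$x^2 + L$y^2)
  expect_lte(max(r), 0.02 + 1e-12)
  # uniform-disk moment: E[r] = 2/3 * R, sd(r)/sqrt(n) error bars
  se <- sd(r) / sqrt(nrow(L))
  expect_lt(abs(mean(r) - 2 / 3 * 0.02), 3 * se)
  # acceptance cone: asin(0.22 / 1.33) = 9.52 deg, uniform in solid angle
  theta_max <- asin(0.22 / 1.33)
  expect_equal(theta_max * 180 / pi, 9.52, tolerance = 0.01 / 9.52)
  theta <- acos(pmin(1, L$uz))
  expect_lte(max(theta), theta_max + 1e-9)
  expect_gt(max(theta), theta_max * 0.99)
  # cos(theta) uniform on [cos(theta_max), 1]
  expect_lt(abs(mean(L$uz) - (1 + cos(theta_max)) / 2), 3e-5)
})

test_that("a vanishing numerical aperture collapses launches onto the axis", {
  src <- fiber_source(c(0, 0, 0), direction = c(0, 0, 1), na = 1e-6)
  L <- sample_launch(src, 1000, seed = 2)
  expect_true(all(abs(L$uz - 1) < 1e-9))
})

test_that("Henyey-Greenstein sampling has the right moments and closed-form values", {
  u <- (0:999999 + 0.5) / 1e6  # stratified uniforms: mean is near-exact
  expect_lt(abs(mean(sample_hg(0, u))), 1e-6)
  for (g in c(0.7, 0.9, -0.5)) {
    expect_equal(mean(sample_hg(g, u)), g, tolerance = 1e-4)
    expect_true(all(abs(sample_hg(g, u)) <= 1))
  }
  # u = 0 plugs into the inversion formula directly
  expect_equal(sample_hg(0.7, 0), (1 + 0.49 - (0.51 / 0.3)^2) / 1.4)
  expect_equal(sample_hg(0.7, 0), -1)
  expect_error(sample_hg(1, 0.5), "g must")
})

test_that("Fresnel reflectance matches closed forms and total internal reflection", {
  expect_equal(fresnel_reflectance(1.4, 1.4, c(0.1, 0.5, 1))$reflectance,
               rep(0, 3))
  # normal incidence 1.33 -> 1.4
  expect_equal(fresnel_reflectance(1.33, 1.4, 1)$reflectance,
               ((1.4 - 1.33) / (1.4 + 1.33))^2)
  expect_equal(fresnel_reflectance(1.33, 1.4, 1)$reflectance, 6.57e-4,
               tolerance = 0.005)
  # beyond the critical angle 1.4 -> 1.33
  crit <- asin(1.33 / 1.4)
  expect_equal(crit * 180 / pi, 71.8, tolerance = 0.001)
  expect_equal(fresnel_reflectance(1.4, 1.33, cos(crit * 1.01))$reflectance, 1)
  expect_lt(fresnel_reflectance(1.4, 1.33, cos(crit * 0.99))$reflectance, 1)
  # Snell at a representative angle
  ct <- fresnel_reflectance(1.33, 1.4, cos(pi / 6))$cos_t
  expect_equal(sqrt(1 - ct^2), 1.33 * sin(pi / 6) / 1.4)
})

test_that("every run conserves launched weight and is seed-deterministic", {
  g <- sphere_phantom_small()
  src <- fiber_source(cavity_center_of_mass(g)$point)
  for (cell in list(property_cell(0.5, 0, 0),
                    suppressWarnings(property_cell(5, 43.48, 0.1)))) {
    m <- simulate_fluence(g, assemble_properties(cell), src,
                          n_photons = 5e3, seed = 9)
    expect_lt(abs(m$absorbed + m$escaped - 1), 1e-6)
    expect_true(all(m$values >= 0))
  }
  m1 <- simulate_fluence(g, assemble_properties(property_cell(0.5, 10, 0)),
                         src, n_photons = 5e3, seed = 4)
  m2 <- simulate_fluence(g, assemble_properties(property_cell(0.5, 10, 0)),
                         src, n_photons = 5e3, seed = 4)
  expect_identical(m1$values, m2$values)
  expect_identical(m1$absorbed, m2$absorbed)
  m3 <- simulate_fluence(g, assemble_properties(property_cell(0.5, 10, 0)),
                         src, n_photons = 5e3, seed = 5)
  expect_false(identical(m1$values, m3$values))
})

test_that("doubling the photon count keeps the mean and halves the variance", {
  g <- sphere_phantom_small()
  src <- fiber_source(cavity_center_of_mass(g)$point)
  opt <- assemble_properties(property_cell(1, 0, 0))
  surf <- wall_surface(g)
  stat <- function(n, seed) {
    m <- simulate_fluence(g, opt, src, n_photons = n, seed = seed)
    mean(wall_distribution(m, surf)$phi)
  }
  s1 <- sapply(1:8, function(s) stat(2000, s))
  s2 <- sapply(1:8, function(s) stat(4000, 100 + s))
  # same expectation
  se <- sqrt(var(s1) / 8 + var(s2) / 8)
  expect_lt(abs(mean(s1) - mean(s2)), 4 * se)
  # variance ratio ~ 2 (chi-square slop on 7+7 dof)
  expect_gt(var(s1) / var(s2), 0.7)
  expect_lt(var(s1) / var(s2), 6)
})

test_that("with a transparent cavity the fluence peaks at the wall facing the fiber", {
  g <- sphere_phantom_r2()
  com <- cavity_center_of_mass(g)
  src <- fiber_source(com$point, direction = c(0, 0, 1))
  m <- fixture("map_clear_cavity", function()
    simulate_fluence(g, assemble_properties(property_cell(1, 0, 0)), src,
                     n_photons = 2e4, seed = 21))
  surf <- wall_surface(g)
  d <- wall_distribution(m, surf)
  ctr <- sweep(sweep(surf$voxels - 1, 2, g$spacing, `*`), 2,
               g$origin - com$point, `+`)
  cosang <- ctr[, 3] / sqrt(rowSums(ctr^2))
  # hottest surface voxel sits in the polar cap around the fiber axis
  expect_gt(cosang[which.max(d$phi)], cos(20 * pi / 180))
  cap <- cosang > cos(15 * pi / 180)
  expect_gt(mean(d$phi[cap]), 10 * mean(d$phi[!cap]))
})

test_that("wall backscatter lights the hemisphere behind the fiber (integrating-sphere buildup)", {
  g <- sphere_phantom_r2()
  com <- cavity_center_of_mass(g)
  src <- fiber_source(com$point, direction = c(0, 0, 1))
  m <- fixture("map_integrating_sphere", function()
    simulate_fluence(g, assemble_properties(property_cell(0.2, 0, 0)), src,
                     n_photons = 2e4, seed = 22))
  surf <- wall_surface(g)
  d <- wall_distribution(m, surf)
  ctr <- sweep(sweep(surf$voxels - 1, 2, g$spacing, `*`), 2,
               g$origin - com$point, `+`)
  cosang <- ctr[, 3] / sqrt(rowSums(ctr^2))
  behind <- cosang < 0  # outside any line-of-sight cone of the forward fiber
  # direct line-of-sight prediction there is exactly zero; diffuse wall
  # reflections must still deliver strictly positive fluence everywhere
  expect_true(all(d$phi[behind] > 0))
  expect_gt(min(d$phi[behind]) * sum(surf$area), 0)
})

test_that("power scaling is linear and validated", {
  g <- sphere_phantom_small()
  src <- fiber_source(cavity_center_of_mass(g)$point)
  m <- simulate_fluence(g, assemble_properties(property_cell(0.5, 0, 0)),
                        src, n_photons = 2e3, seed = 1)
  expect_equal(scale_to_power(m, 0)$values, 0 * m$values)
  expect_equal(scale_to_power(m, 2000)$values, 2000 * m$values)
  a <- scale_to_power(m, 70)$values + scale_to_power(m, 30)$values
  expect_equal(a, scale_to_power(m, 100)$values)
  expect_error(scale_to_power(m, -1), ">= 0")
})

test_that("source placement is validated against the geometry", {
  g <- sphere_phantom_small()
  opt <- assemble_properties(property_cell(0.5, 0, 0))
  expect_error(simulate_fluence(g, opt, fiber_source(c(-5, 0, 0)), 100),
               "outside the grid")
  # tip in the wall region, not the cavity
  wall_vox <- which(g$labels == 1L, arr.ind = TRUE)[1, ]
  p <- (wall_vox - 1) * g$spacing + g$origin
  expect_error(simulate_fluence(g, opt, fiber_source(p), 100),
               "cavity region")
})
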