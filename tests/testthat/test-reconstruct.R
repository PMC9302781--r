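make_diff <- function(geometry, fill = 0 + 0i) {
  array(fill, dim = c(geometry$n_receivers, geometry$n_sections,
                      length(geometry$frequencies)))
}

test_that("zero differenced signal gives an identically zero field and map", {
  g <- test_geometry()
  grid <- reconstruction_grid(radial_step = 0.005, az_step = 15)
  E <- huygens_field(make_diff(g), g, medium_model(0.4), grid)
  expect_true(all(E == 0))
  I <- intensity_map(E, grid)
  expect_true(all(I$values == 0))
})

test_that("field is linear: scaling the data scales the field", {
  g <- test_geometry()
  grid <- reconstruction_grid(radial_step = 0.005, az_step = 15)
  set.seed(3)
  d <- make_diff(g)
  d[] <- complex(real = rnorm(length(d)), imaginary = rnorm(length(d)))
  E1 <- huygens_field(d, g, medium_model(0.4), grid)
  cc <- 2.5 - 1.25i
  E2 <- huygens_field(d * cc, g, medium_model(0.4), grid)
  expect_equal(E2, E1 * cc, tolerance = 1e-12)
})

test_that("intensity is |E|^2 pointwise and additive over frequencies", {
  g <- build_geometry(freq_step = 4e9)   # 1, 5, 9 GHz
  grid <- reconstruction_grid(radial_step = 0.005, az_step = 15)
  set.seed(4)
  d <- make_diff(g)
  d[] <- complex(real = rnorm(length(d)), imaginary = rnorm(length(d)))
  E <- huygens_field(d, g, medium_model(0.2), grid)
  ## single section, single frequency: I = |E|^2
  E1 <- E[, , 1, 1, drop = FALSE]
  I1 <- intensity_map(E1, grid)
  expect_equal(I1$values, Mod(E[, , 1, 1])^2)
  ## duplicating the frequency axis doubles the map exactly
  I <- intensity_map(E, grid)
  Edup <- array(c(E, E), dim = c(dim(E)[1:3], 2 * dim(E)[4]))
  Idup <- intensity_map(Edup, grid)
  expect_equal(Idup$values, 2 * I$values)
  expect_true(all(I$values >= 0))
})

test_that("scaling the dataset leaves the intensity argmax unchanged", {
  g <- test_geometry()
  ph <- phantom_spec(inclusions = list(
    list(rho = 0.025, phi = 210, radius = 0.004, amplitude = 1 + 0i)))
  s <- simulate_s21(ph, g, noise_sd = 0)
  grid <- reconstruction_grid(radial_step = 0.002, az_step = 6)
  m1 <- reconstruct_map(s, grid = grid, cartesian = FALSE)
  s$values <- s$values * (0.3 + 2i)
  m2 <- reconstruct_map(s, grid = grid, cartesian = FALSE)
  expect_equal(map_peak(m1), map_peak(m2))
})

test_that("polar-to-cartesian keeps constants, dimensions and peaks", {
  grid <- reconstruction_grid()
  v <- matrix(7.5, length(grid$radii), length(grid$az_deg))
  pmap <- intensity_map_new(v, kind = "polar", radii = grid$radii,
                            az_deg = grid$az_deg)
  cmap <- polar_to_cartesian(pmap)
  expect_equal(dim(cmap$values), c(141, 141))
  inside <- disc_mask(cmap)
  expect_equal(max(abs(cmap$values[inside] - 7.5)) / 7.5, 0, tolerance = 1e-9)
  expect_true(all(cmap$values[!inside] == 0))

  ## peaked map: maximum survives interpolation within a pixel
  v2 <- outer(exp(-((grid$radii - 0.03) / 0.008)^2),
              exp(-pmin(abs(grid$az_deg - 90), 360 - abs(grid$az_deg - 90))^2 / 200))
  pm2 <- intensity_map_new(v2, kind = "polar", radii = grid$radii,
                           az_deg = grid$az_deg)
  pk <- map_peak(polar_to_cartesian(pm2))
  expect_equal(pk$phi, 90, tolerance = 3)
  expect_equal(sqrt(pk$x^2 + pk$y^2), 0.03, tolerance = 0.0015)
})

test_that("grid invariants are enforced", {
  expect_error(reconstruction_grid(az_step = 7), "divide")
  expect_error(reconstruction_grid(max_radius = -1), "positive")
  g <- test_geometry()
  big <- reconstruction_grid(max_radius = 0.08)
  expect_error(huygens_field(make_diff(g), g, grid = big), "beyond")
})
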