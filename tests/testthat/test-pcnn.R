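test_that("stimulus normalization is min-max over the mask and scale invariant", {
  m <- matrix(c(10, 20, 30, 99), 2, 2)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  s <- normalize_input(m, mask)
  expect_equal(s, matrix(c(0, 0.5, 1, 0), 2, 2))
  expect_equal(normalize_input(m * 42, mask), s)        # positive scale invariance
  expect_warning(s0 <- normalize_input(matrix(5, 3, 3)), "constant")
  expect_true(all(s0 == 0))
})

test_that("linking field is the kernel impulse response with in-bounds neighbors", {
  p <- pcnn_params()
  o <- matrix(0, 5, 5); o[3, 3] <- 1
  L <- linking_field(o, p)
  expect_equal(L[2:4, 2:4], p$w)
  expect_equal(L[3, 3], 0)
  ## corner neuron: only in-bounds neighbors contribute
  o2 <- matrix(0, 4, 4); o2[1, 1] <- 1
  L2 <- linking_field(o2, p)
  expect_equal(L2[1, 2], 1)
  expect_equal(L2[2, 2], 1 / sqrt(2))
  expect_equal(sum(L2 > 0), 3)
})

test_that("linking field equals a brute-force neighborhood sum on random lattices", {
  p <- pcnn_params()
  for (seed in 1:5) {
    set.seed(seed)
    o <- matrix(rbinom(36, 1, 0.5), 6, 6)
    ref <- matrix(0, 6, 6)
    for (i in 1:6) for (j in 1:6)
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= 6 && jj >= 1 && jj <= 6)
          ref[i, j] <- ref[i, j] + p$w[di + 2, dj + 2] * o[ii, jj]
      }
    expect_equal(linking_field(o, p), ref)
  }
})

test_that("with t0 = 0 every positive-stimulus neuron fires at iteration 1", {
  p <- pcnn_params(t0 = 0)
  s <- matrix(runif(25, min = 0.01), 5, 5)
  st <- pcnn_step(pcnn_init(s, p), p)
  expect_true(all(st$o == 1))
  expect_true(all(st$t == p$v_t))
})

test_that("a huge threshold suppresses firing and decays by exactly exp(-alpha_t)", {
  p <- pcnn_params()
  st <- pcnn_init(matrix(runif(16), 4, 4), p)
  st$t[] <- 1e9
  st2 <- pcnn_step(st, p)
  expect_true(all(st2$o == 0))
  expect_equal(st2$t, st$t * exp(-0.2))
})

test_that("three steps on a 3x3 lattice match the scalar reference exactly", {
  s <- matrix(c(0.1, 0.9, 0.1, 0.9, 1.0, 0.9, 0.1, 0.9, 0.1), 3, 3)
  for (t0 in c(0, 2)) {
    p <- pcnn_params(n_iter = 3, t0 = t0)
    ref <- pcnn_reference(s, p)
    st <- pcnn_init(s, p)
    for (k in 1:3) {
      st <- pcnn_step(st, p)
      expect_identical(st$f, ref[[k]]$f)
      expect_identical(st$l, ref[[k]]$l)
      expect_identical(st$u, ref[[k]]$u)
      expect_identical(st$t, ref[[k]]$t)
      expect_identical(st$o, ref[[k]]$o)
    }
  }
})

test_that("run_pcnn yields one binary mask per iteration, deterministically", {
  s <- matrix(runif(100), 10, 10)
  stack <- run_pcnn(s)
  expect_length(stack$masks, 32)
  expect_true(all(vapply(stack$masks, function(m) all(m %in% c(0, 1)), logical(1))))
  stack2 <- run_pcnn(s)
  expect_identical(stack$masks, stack2$masks)
})

test_that("a spatially uniform stimulus fires uniformly at every iteration", {
  s <- matrix(0.7, 8, 8)
  stack <- run_pcnn(s)
  for (m in stack$masks)
    expect_true(all(m == m[1, 1]))
})

test_that("threshold recurrence: quiet neurons decay, fired neurons jump", {
  set.seed(9)
  p <- pcnn_params(n_iter = 10)
  st <- pcnn_init(matrix(runif(64), 8, 8), p)
  for (k in 1:10) {
    t_prev <- st$t
    st <- pcnn_step(st, p)
    quiet <- st$o == 0
    expect_equal(st$t[quiet], exp(-p$alpha_t) * t_prev[quiet])
    expect_true(all(st$t[!quiet] >= p$v_t))
  }
})

test_that("any positive-stimulus neuron eventually fires (guaranteed refire)", {
  s <- matrix(0.05, 3, 3)          # dim but positive
  stack <- run_pcnn(s, pcnn_params(n_iter = 32))
  expect_true(any(vapply(stack$masks, function(m) any(m == 1), logical(1))))
})

test_that("mask selection is 1-based and bounds-checked", {
  s <- matrix(runif(36), 6, 6)
  stack <- run_pcnn(s)
  expect_identical(select_mask(stack, 5), stack$masks[[5]])
  expect_identical(select_mask(stack), stack$masks[[5]])   # default selection
  expect_identical(select_mask(stack, 32), stack$masks[[32]])
  p0 <- pcnn_params(t0 = 0)
  st0 <- run_pcnn(matrix(runif(16, min = 0.01), 4, 4), p0)
  expect_true(all(select_mask(st0, 1) == 1))               # all-fire with t0 = 0
  expect_error(select_mask(stack, 0), "range")
  expect_error(select_mask(stack, 33), "range")
})

test_that("region extraction honors 8-connectivity and min_area", {
  m <- matrix(0, 12, 12)
  m[2:4, 2:4] <- 1
  m[8:10, 8:10] <- 1
  regs <- extract_regions(m, min_area = 1)
  expect_length(regs, 2)
  expect_equal(vapply(regs, `[[`, numeric(1), "area"), c(9, 9))
  ## diagonal touch merges under 8-connectivity
  m2 <- matrix(0, 6, 6); m2[2, 2] <- 1; m2[3, 3] <- 1
  expect_length(extract_regions(m2, min_area = 1), 1)
  ## min_area filters
  expect_length(extract_regions(m2, min_area = 5), 0)
  expect_length(extract_regions(matrix(0, 5, 5)), 0)
})

test_that("labeling matches a brute-force flood fill on random masks", {
  for (seed in 1:6) {
    set.seed(seed)
    m <- matrix(rbinom(400, 1, 0.35), 20, 20)
    regs <- extract_regions(m, min_area = 1)
    comps <- floodfill_components(m)
    expect_equal(length(regs), length(comps))
    expect_equal(sort(vapply(regs, `[[`, numeric(1), "area")),
                 sort(vapply(comps, nrow, numeric(1))))
  }
})

test_that("zone assignment splits at the center row with upper ties", {
  shape <- c(141, 141)
  up <- list(centroid = c(row = 30, col = 70))
  lo <- list(centroid = c(row = 100, col = 70))
  tie <- list(centroid = c(row = 71, col = 70))
  expect_equal(assign_zone(up, shape), "upper")
  expect_equal(assign_zone(lo, shape), "lower")
  expect_equal(assign_zone(tie, shape), "upper")
})

test_that("localize_lesion finds the blob region and its zone", {
  map <- synth_intensity_map(lesions = list(
    list(x = 0.01, y = -0.03, radius = 0.004, amplitude = 3000)),
    background_level = 1000, noise_sd = 20, seed = 5)
  reg <- localize_lesion(map)
  expect_equal(reg$zone, "lower")
  ## centroid near the blob center (row 101, col 81)
  expect_lt(abs(reg$centroid[["row"]] - 101), 4)
  expect_lt(abs(reg$centroid[["col"]] - 81), 4)
})
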