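test_that("constant maps are fixed points of replicate-padded smoothing", {
  m <- matrix(123.4, 141, 141)
  sm <- gaussian_smooth(m)
  expect_lt(max(abs(sm - 123.4)) / 123.4, 1e-9)
})

test_that("an interior impulse reproduces the discrete Gaussian profile", {
  m <- matrix(0, 141, 141); m[71, 71] <- 1
  sm <- gaussian_smooth(m)
  expect_equal(sm[71, 101] / sm[71, 71], exp(-0.5), tolerance = 1e-9)  # 30 px off
  expect_equal(sm[41, 71] / sm[71, 71], exp(-0.5), tolerance = 1e-9)
  expect_equal(sm[71, 72] / sm[71, 71], exp(-1 / (2 * 900)), tolerance = 1e-9)
  expect_true(all(sm >= 0))
})

test_that("smoothing keeps non-negative maps non-negative", {
  set.seed(2)
  m <- matrix(rexp(141^2), 141, 141)
  expect_true(all(gaussian_smooth(m) >= 0))
})

test_that("quartiles use the linear-interpolation estimator", {
  q <- intensity_quartiles(matrix(1:5, 1))
  expect_equal(c(q$q1, q$q2, q$q3), c(2, 3, 4))
  qc <- intensity_quartiles(matrix(7, 3, 3))
  expect_equal(c(qc$q1, qc$q2, qc$q3), c(7, 7, 7))
  expect_true(q$q1 <= q$q2 && q$q2 <= q$q3)
  expect_error(intensity_quartiles(matrix(1, 2, 2), mask = matrix(FALSE, 2, 2)),
               "empty")
})

test_that("quartiles of uniform noise sit near the theoretical quartiles", {
  set.seed(123)
  q <- intensity_quartiles(matrix(runif(10000), 100, 100))
  expect_equal(q$q1, 0.25, tolerance = 0.02)
  expect_equal(q$q2, 0.50, tolerance = 0.02)
  expect_equal(q$q3, 0.75, tolerance = 0.02)
})

test_that("quartile ordering holds for arbitrary inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    q <- intensity_quartiles(matrix(rcauchy(400), 20, 20))
    expect_true(q$q1 <= q$q2 && q$q2 <= q$q3)
    expect_true(q$whisker_low <= q$q1 && q$whisker_high >= q$q3)
  }
})

test_that("the cohort threshold averages the two group Q3 means", {
  mk <- function(q3) structure(list(q1 = 0, q2 = 0, q3 = q3), class = "mwi_boxplot")
  th <- cohort_threshold(list(mk(1600), mk(1500)), c("NF+BF", "MF"))
  expect_equal(th$theta, 1550)
  th2 <- cohort_threshold(lapply(rep(42, 6), mk), rep(c("NF+BF", "MF"), 3))
  expect_equal(th2$theta, 42)
  set.seed(6)
  q3s <- runif(30, 100, 2000)
  labs <- sample(c("MF", "NF+BF"), 30, replace = TRUE, prob = c(0.3, 0.7))
  th3 <- cohort_threshold(lapply(q3s, mk), labs)
  expect_equal(th3$theta,
               (mean(q3s[labs == "NF+BF"]) + mean(q3s[labs == "MF"])) / 2)
  expect_error(cohort_threshold(list(mk(1)), "MF"), "non-empty")
})

test_that("the median rule classifies with ties going to NF+BF", {
  th <- structure(list(theta = 1000, direction = "above"),
                  class = "mwi_threshold")
  mk <- function(q2) structure(list(q1 = 0, q2 = q2, q3 = 0), class = "mwi_boxplot")
  expect_equal(classify_breast(mk(1001), th), "MF")
  expect_equal(classify_breast(mk(1000), th), "NF+BF")
  expect_equal(classify_breast(mk(999), th), "NF+BF")
  th$direction <- "below"
  expect_equal(classify_breast(mk(999), th), "MF")
})

test_that("raising Q2 can only move a label towards MF", {
  th <- structure(list(theta = 500, direction = "above"),
                  class = "mwi_threshold")
  mk <- function(q2) structure(list(q1 = 0, q2 = q2, q3 = 0), class = "mwi_boxplot")
  labels <- vapply(seq(0, 1000, by = 50), function(q2)
    classify_breast(mk(q2), th), character(1))
  expect_true(all(diff(labels == "MF") >= 0))
})

test_that("smoothing, quartiles and classification commute with affine rescaling", {
  set.seed(10)
  maps <- lapply(1:6, function(i)
    synth_intensity_map(background_level = 500 + 300 * i, noise_sd = 15,
                        seed = i))
  labels <- c(rep("NF+BF", 4), rep("MF", 2))
  res1 <- classify_cohort(maps, labels)
  a <- 3.7; b <- 12
  maps2 <- lapply(maps, function(m) { m$values <- a * m$values + b; m })
  res2 <- classify_cohort(maps2, labels)
  q1 <- vapply(res1$summaries, `[[`, numeric(1), "q2")
  q2 <- vapply(res2$summaries, `[[`, numeric(1), "q2")
  expect_equal(q2, a * q1 + b, tolerance = 1e-9)
  expect_equal(res2$threshold$theta, a * res1$threshold$theta + b,
               tolerance = 1e-9)
  expect_identical(res1$predicted, res2$predicted)
})
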