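test_that("dtf validates monic denominator and no feedthrough", {
  expect_s3_class(dtf(1, c(1, -0.5)), "dtf")
  expect_error(dtf(1, c(2, -0.5)), "monic")
  expect_error(dtf(c(1, 0), c(1, -0.5)), "feedthrough")
  expect_error(dtf(1, 1), "order")
  expect_error(dtf(NaN, c(1, 0)), "finite")
})

test_that("simulate_tf reproduces hand-computed difference equations", {
  x <- c(3, 1, 4, 1, 5)
  # pure unit delay
  expect_equal(simulate_tf(dtf(1, c(1, 0)), x), c(0, 3, 1, 4, 1))
  # scaled delay
  expect_equal(simulate_tf(dtf(0.5, c(1, 0)), c(1, 0, 0, 0)),
               c(0, 0.5, 0, 0))
  # single pole at 0.5: impulse response 0, 1, 0.5, 0.25, ...
  expect_equal(simulate_tf(dtf(1, c(1, -0.5)), c(1, 0, 0, 0, 0)),
               c(0, 1, 0.5, 0.25, 0.125))
})

test_that("simulate_tf is linear and matches a convolution oracle", {
  for (s in 1:5) {
    set.seed(s)
    G <- random_stable_dtf(sample(0:3, 1), sample(4:5, 1))
    x1 <- rnorm(64); x2 <- rnorm(64)
    expect_equal(simulate_tf(G, 2 * x1 - 3 * x2),
                 2 * simulate_tf(G, x1) - 3 * simulate_tf(G, x2),
                 tolerance = 1e-12)
    expect_equal(simulate_tf(G, x1), sim_by_convolution(G, x1),
                 tolerance = 1e-10)
  }
})

test_that("simulate_tf flags unstable blow-ups with the offending sample", {
  G <- dtf(1, c(1, -3))   # pole at 3
  x <- rep(1, 700)
  expect_error(simulate_tf(G, x), "non-finite output at sample")
  expect_error(simulate_tf(G, c(1, NA, 1)), "finite")
})

test_that("goodness_of_fit matches its definition and edge identities", {
  y <- c(0.3, -1.2, 2.5, 0.1)
  expect_identical(goodness_of_fit(y, y), 100)
  expect_equal(goodness_of_fit(y, rep(mean(y), 4)), 0)
  expect_equal(goodness_of_fit(c(1, 2, 3), c(1, 2, 4)),
               100 * (1 - 1 / sqrt(2)), tolerance = 1e-12)
  # invariance under joint affine maps
  expect_equal(goodness_of_fit(3 * y + 2, 3 * (y + 0.1) + 2),
               goodness_of_fit(y, y + 0.1), tolerance = 1e-10)
  expect_error(goodness_of_fit(rep(1, 5), rep(1, 5)), "constant")
  expect_error(goodness_of_fit(1:3, 1:4), "length")
})

test_that("estimate_tf recovers exactly representable systems", {
  set.seed(3)
  x <- rnorm(300)
  # a delayed identity is exactly representable at orders (0, 1)
  fit <- estimate_tf(x, c(0, x[-300]), 0, 1)
  expect_equal(fit$tf$num, 1, tolerance = 1e-8)
  expect_equal(fit$tf$den, c(1, 0), tolerance = 1e-8)
  expect_gte(fit$gf, 99.999)
  # first-order pole
  G <- dtf(1, c(1, -0.5))
  y <- simulate_tf(G, x)
  fit <- estimate_tf(x, y, 0, 1)
  expect_equal(fit$tf$den[2], -0.5, tolerance = 1e-6)
})

test_that("estimate_tf achieves noise-free round-trip recovery at (4,5)", {
  set.seed(11)
  ok <- replicate(20, {
    G <- random_stable_dtf(4, 5)
    x <- rnorm(2048)
    y <- simulate_tf(G, x)
    fit <- estimate_tf(x, y, 4, 5)
    max(abs(c(fit$tf$num - G$num, fit$tf$den - G$den))) <= 1e-3 &&
      fit$gf >= 99.9
  })
  expect_gte(mean(ok), 0.95)
})

test_that("refinement never does worse than its initialization", {
  set.seed(21)
  for (s in 1:5) {
    G <- random_stable_dtf(2, 3)
    x <- rnorm(512)
    y <- simulate_tf(G, x) + rnorm(512, 0, 0.05)
    init <- estimate_tf(x, y, 2, 3, max_iter = 0L)
    fit <- estimate_tf(x, y, 2, 3)
    cost <- function(f) sum((y - simulate_tf(f$tf, x))^2)
    expect_lte(cost(fit), cost(init) + 1e-10)
  }
})

test_that("estimate_tf validates its preconditions", {
  x <- rnorm(100)
  expect_error(estimate_tf(x, x, 3, 3), "feedthrough")
  expect_error(estimate_tf(x, x, 0, 0), "den_order")
  expect_error(estimate_tf(x, x[-1], 0, 1), "length")
  expect_error(estimate_tf(rnorm(20), rnorm(20), 0, 2), "short")
  expect_error(estimate_tf(x, rep(1, 100), 0, 1), "constant")
})

test_that("is_stable agrees with direct pole-modulus computation", {
  expect_true(is_stable(dtf(1, c(1, -0.5))))
  expect_false(is_stable(dtf(1, c(1, -2))))
  G <- reference_gtf_bda()
  expect_identical(is_stable(G),
                   all(Mod(polyroot(rev(G$den))) < 1))
})

test_that("transfer-function JSON round trips exactly", {
  G <- reference_gtf_bda()
  path <- withr::local_tempfile(fileext = ".json")
  write_tf_json(G, path, fs = 1024)
  back <- read_tf_json(path)
  expect_identical(back$tf$num, G$num)
  expect_identical(back$tf$den, G$den)
  expect_identical(back$fs, 1024)
})
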