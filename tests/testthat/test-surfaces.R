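ref_surfaces <- allele_surfaces()

test_that("quadratic evaluation matches the published reference points", {
  # peak heights recomputed by direct arithmetic from the coefficient table
  expect_equal(evaluate_quadratic(ref_surfaces[["B73"]], 28.5, 4.5),
               37.61528, tolerance = 1e-6)
  expect_equal(evaluate_quadratic(ref_surfaces[["Mo17"]], -42, 7.5),
               4.475733, tolerance = 1e-6)
  zero <- quadratic_surface(0, 0, 0, 0, 0, 0)
  expect_equal(evaluate_quadratic(zero, 13, -5), 0)
  # all-zero coefficients return ell everywhere
  flat <- quadratic_surface(0, 0, 0, 0, 0, 3.25)
  expect_equal(evaluate_quadratic(flat, c(-42, 0, 42), c(7.5, 0, -7.5)),
               rep(3.25, 3))
  expect_error(evaluate_quadratic(zero, NaN, 0), class = "surfqtl_invalid_argument")
  expect_error(quadratic_surface(Inf, 0, 0, 0, 0, 0),
               class = "surfqtl_invalid_argument")
})

test_that("producing function has no constant term and matches hand arithmetic", {
  b73like <- example_producing_params("B73-like")
  mo17like <- example_producing_params("Mo17-like")
  expect_identical(evaluate_producing(b73like, 0, 0), 0)
  expect_identical(evaluate_producing(mo17like, 0, 0), 0)
  expect_equal(evaluate_producing(b73like, 1, 0), -0.175 * 0.260 + 2.575)
  expect_equal(evaluate_producing(mo17like, 0, 1), 0.551275)
  expect_error(evaluate_producing(b73like, 1, NA), class = "surfqtl_invalid_argument")
})

test_that("the planar part of the producing function is odd-symmetric", {
  set.seed(42)
  for (i in 1:10) {
    p <- producing_function(0, 0, runif(1, -1, 1), rnorm(1), rnorm(1))
    xw <- rnorm(5, sd = 20); xn <- rnorm(5, sd = 4)
    expect_equal(evaluate_producing(p, -xw, -xn), -evaluate_producing(p, xw, xn))
  }
})

test_that("surface_grid has the documented dimensions and orientation", {
  g <- eval_grid()
  z <- surface_grid(ref_surfaces[["B73"]], g)
  expect_equal(dim(z), c(169L, 31L))
  expect_equal(max(z), 37.61528, tolerance = 1e-6)
  # water ascends along rows, nitrogen along columns
  expect_equal(z["28.5", "4.5"], evaluate_quadratic(ref_surfaces[["B73"]], 28.5, 4.5),
               ignore_attr = TRUE)
  zero <- quadratic_surface(0, 0, 0, 0, 0, 0)
  expect_true(all(surface_grid(zero, g) == 0))
  expect_error(eval_grid(water = c(0, 0)), class = "surfqtl_invalid_argument")
  expect_error(eval_grid(step = 0.7), class = "surfqtl_invalid_argument")
})

test_that("find_peak agrees with an exhaustive brute-force oracle", {
  g <- eval_grid()
  set.seed(7)
  for (i in 1:12) {
    s <- quadratic_surface(rnorm(1, 0, 0.3), rnorm(1), rnorm(1, 0, 0.01),
                           rnorm(1, 0, 0.1), rnorm(1, 0, 0.02), rnorm(1, 20, 5))
    z <- surface_grid(s, g)
    pk <- find_peak(z, g)
    # oracle: scan every node independently of the vectorised path
    best <- -Inf; bw <- NA; bn <- NA
    for (w in g$water) for (n in g$nitrogen) {
      zz <- s$beta1 * w + s$beta2 * n + s$beta3 * w^2 + s$beta4 * n^2 +
        s$beta5 * w * n + s$ell
      if (zz > best) { best <- zz; bw <- w; bn <- n }
    }
    expect_equal(pk$zmax, best, tolerance = 1e-12)
    expect_equal(evaluate_quadratic(s, pk$xw, pk$xn), pk$zmax)
  }
})

test_that("find_peak tie-breaking and boundary flag are deterministic", {
  g <- eval_grid()
  flat <- surface_grid(quadratic_surface(0, 0, 0, 0, 0, 1), g)
  pk <- find_peak(flat, g)
  expect_equal(c(pk$xw, pk$xn), c(-42, -7.5))
  expect_true(pk$on_boundary)
  bowl <- surface_grid(quadratic_surface(0, 0, -1, -1, 0, 0), g)
  pk2 <- find_peak(bowl, g)
  expect_equal(c(pk2$xw, pk2$xn, pk2$zmax), c(0, 0, 0))
  expect_false(pk2$on_boundary)
  expect_error(find_peak(matrix(0, 2, 2), g), class = "surfqtl_invalid_argument")
})

test_that("the analytic maximiser of a definite dome lies within one grid step of the grid peak", {
  g <- eval_grid()
  set.seed(11)
  found <- 0
  while (found < 8) {
    b3 <- -runif(1, 0.002, 0.02); b4 <- -runif(1, 0.05, 0.3)
    b5 <- runif(1, -0.01, 0.01)
    if (4 * b3 * b4 - b5^2 <= 0) next
    b1 <- rnorm(1, 0, 0.2); b2 <- rnorm(1, 0, 1)
    # gradient system: 2 b3 xw + b5 xn = -b1 ; b5 xw + 2 b4 xn = -b2
    sol <- solve(matrix(c(2 * b3, b5, b5, 2 * b4), 2, byrow = TRUE), c(-b1, -b2))
    if (sol[1] < -41 || sol[1] > 41 || sol[2] < -7 || sol[2] > 7) next
    found <- found + 1
    s <- quadratic_surface(b1, b2, b3, b4, b5, 0)
    pk <- find_peak(surface_grid(s, g), g)
    expect_lte(abs(pk$xw - sol[1]), g$step)
    expect_lte(abs(pk$xn - sol[2]), g$step)
  }
})

test_that("shape classification reproduces the published category row", {
  pk <- surface_peaks(allele_surface_coefs())
  expect_equal(
    as.character(pk$category),
    c("domed", "domed", "hybrid", "hybrid", "shoulder", "shoulder",
      "shoulder", "trough")
  )
  expect_equal(sum(pk$category == "domed"), 2L)
  expect_equal(sum(pk$category == "hybrid"), 2L)
  expect_equal(sum(pk$category == "shoulder"), 3L)
  expect_equal(sum(pk$category == "trough"), 1L)
})

test_that("classify_shape flags threshold-adjacent peaks and honours curvature", {
  pk <- tibble::tibble(xw = 27.5, xn = 0, zmax = 10, on_boundary = FALSE)
  cl <- classify_shape(pk, curvature_sign = -1)
  expect_equal(as.character(cl$category), "domed")
  expect_true(cl$ambiguous)
  expect_equal(as.character(classify_shape(pk, curvature_sign = 1)$category),
               "trough")
  pk36 <- tibble::tibble(xw = 36, xn = 0, zmax = 10, on_boundary = FALSE)
  expect_equal(as.character(classify_shape(pk36, -1)$category), "shoulder")
})

test_that("sign patterns match the published parameter table", {
  pars <- as_producing_list(allele_producing_params())
  expect_equal(unname(sign_pattern(pars[["B73"]])), c("-", "-", "-", "+"))
  expect_equal(unname(sign_pattern(pars[["Mo17"]])), c("+", "+", "+", "-"))
  expect_equal(unname(sign_pattern(pars[["QTL1-Mo17"]])), c("+", "-", "+", "+"))
  zero <- producing_function(0, 0, 1, 0, 0)
  expect_equal(unname(sign_pattern(zero)), c("0", "0", "0", "0"))
})
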