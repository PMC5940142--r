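test_that("simulated genotypes have the documented structure", {
  g <- simulate_genotypes(89, seed = 1)
  expect_equal(dim(g$calls), c(89L, 200L))
  expect_true(all(g$calls %in% c("B73", "Mo17")))
  expect_equal(nrow(g$map), 200L)
  # markers strictly ordered within chromosome
  ord <- tapply(g$map$pos_cm, g$map$chrom, function(p) all(diff(p) > 0))
  expect_true(all(ord))
  # reproducible under a fixed seed
  g2 <- simulate_genotypes(89, seed = 1)
  expect_identical(g$calls, g2$calls)
  expect_error(simulate_genotypes(1), class = "surfqtl_invalid_argument")
})

test_that("allele frequencies are balanced across many lines", {
  g <- simulate_genotypes(500, tibble::tibble(n_markers = 20, length_cm = 100),
                          seed = 3)
  freq <- colMeans(g$calls == "B73")
  # binomial tolerance: SE = sqrt(0.25/500) ~ 0.022
  expect_true(all(abs(freq - 0.5) < 0.1))
})

test_that("adjacent-marker correlation follows the Haldane map function", {
  # two markers 50 cM apart, expansion 1: r = (1 - exp(-1))/2 ~ 0.3161
  g <- simulate_genotypes(4000, tibble::tibble(n_markers = 2, length_cm = 50),
                          expansion_factor = 1, seed = 5)
  switch_freq <- mean(g$calls[, 1] != g$calls[, 2])
  expect_equal(switch_freq, 0.5 * (1 - exp(-1)), tolerance = 0.1)
  # zero distance: perfectly correlated
  g0 <- simulate_genotypes(200, tibble::tibble(n_markers = 2, length_cm = 0),
                           seed = 6)
  expect_true(all(g0$calls[, 1] == g0$calls[, 2]))
})

test_that("the face-centered design has nine combinations with central replication", {
  d <- build_design()
  expect_equal(nrow(d), 9L)
  expect_equal(max(d$n_rep), 8)
  expect_equal(sum(d$n_rep), 40)
  expect_true(all(d$water_pct %in% c(8, 20, 50, 80, 92)))
  expect_true(all(d$nitrogen_pct %in% c(0, 2.5, 7.5, 12.5, 15)))
  expect_equal(sum(d$role == "corner"), 4L)
  expect_equal(d$n_rep[d$role == "center"], 8)
  # degenerate single-level design collapses to the centre point
  d1 <- build_design(water_levels = 50, nitrogen_levels = 7.5)
  expect_equal(nrow(d1), 1L)
  expect_error(
    build_design(combos = tibble::tibble(water_pct = 33, nitrogen_pct = 0,
                                         n_rep = 2)),
    class = "surfqtl_invalid_argument"
  )
})

test_that("kinship is identity-in-state sharing with unit diagonal", {
  calls <- rbind(rep("B73", 8),
                 rep("B73", 8),
                 rep("Mo17", 8))
  g <- make_genotypes(calls)
  k <- compute_kinship(g)
  expect_equal(k["L01", "L02"], 1, tolerance = 1e-5)
  expect_equal(k["L01", "L03"], 0, tolerance = 1e-5)
  expect_equal(unname(diag(k)), rep(1, 3), tolerance = 1e-5)
  expect_equal(k, t(k))
})

test_that("kinship estimates pairwise sharing and is numerically PSD", {
  set.seed(9)
  # three lines sharing ~50% of 1000 independent markers pairwise
  calls <- matrix(sample(c("B73", "Mo17"), 3000, replace = TRUE), nrow = 3)
  k <- compute_kinship(make_genotypes(calls))
  off <- k[upper.tri(k)]
  expect_true(all(abs(off - 0.5) < 0.06))  # binomial SE ~ 0.016
  g <- simulate_genotypes(40, tibble::tibble(n_markers = 30, length_cm = 100),
                          missing_rate = 0.1, seed = 10)
  k2 <- compute_kinship(g)
  expect_gte(min(eigen(k2, symmetric = TRUE, only.values = TRUE)$values), 0)
  # a pair with no shared informative markers is an error
  calls_na <- rbind(c("B73", NA), c(NA, "Mo17"))
  expect_error(compute_kinship(make_genotypes(calls_na)),
               class = "surfqtl_missing_data")
})

test_that("phenotypes decompose exactly in the noiseless cases", {
  g <- simulate_genotypes(12, tibble::tibble(n_markers = 3, length_cm = 50),
                          seed = 2)
  ph0 <- simulate_phenotypes(g, causal = NULL, baseline = 17, sigma_line = 0,
                             sigma_resid = 0, seed = 4)
  expect_true(all(ph0$diff_height_cm == 17))
  expect_equal(ph0$final_height_cm - ph0$initial_height_cm, ph0$diff_height_cm)
  expect_equal(nrow(ph0), 12 * 40)
  expect_true(all(ph0$xw == ph0$water_pct - 50))
  expect_true(all(ph0$xn == ph0$nitrogen_pct - 7.5))

  causal <- list(c1_m02 = list(B73 = example_producing_params("B73-like"),
                               Mo17 = example_producing_params("Mo17-like")))
  ph1 <- simulate_phenotypes(g, causal = causal, baseline = 17, sigma_line = 0,
                             sigma_resid = 0, seed = 4)
  expected <- ifelse(
    g$calls[ph1$line_id, "c1_m02"] == "B73",
    evaluate_producing(causal$c1_m02$B73, ph1$xw, ph1$xn),
    evaluate_producing(causal$c1_m02$Mo17, ph1$xw, ph1$xn)
  )
  expect_equal(ph1$diff_height_cm, 17 + expected)
})

test_that("residual noise has the requested scale", {
  g <- simulate_genotypes(250, tibble::tibble(n_markers = 2, length_cm = 50),
                          seed = 8)
  ph <- simulate_phenotypes(g, causal = NULL, baseline = 0, sigma_line = 0,
                            sigma_resid = 1, seed = 9)
  expect_gt(nrow(ph), 5000)
  expect_equal(sd(ph$diff_height_cm), 1, tolerance = 0.05)
})

test_that("phenotype tables round-trip through CSV exactly", {
  g <- simulate_genotypes(5, tibble::tibble(n_markers = 2, length_cm = 10),
                          seed = 12)
  ph <- simulate_phenotypes(g, build_design(reps = c(corner = 1, center = 2)),
                            seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotypes(ph, path)
  back <- read_phenotypes(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ph))
})

test_that("REML recovers the generative variance components", {
  # the stated recovery conditions: sigma_line = 2, sigma_resid = 1,
  # 89 lines x 9 combinations, averaged over 20 seeds, within 30%
  des <- build_design(reps = c(corner = 1, center = 1))
  est <- t(vapply(1:20, function(s) {
    g <- simulate_genotypes(89, tibble::tibble(n_markers = 40, length_cm = 120),
                            seed = 100 + s)
    k <- compute_kinship(g)
    ph <- simulate_phenotypes(g, des, causal = NULL, baseline = 25,
                              sigma_line = 2, sigma_resid = 1, kinship = k,
                              seed = 200 + s)
    fit_surface(ph, kinship = k)$vc
  }, numeric(2)))
  expect_equal(mean(est[, 1]), 4, tolerance = 0.3)
  expect_equal(mean(est[, 2]), 1, tolerance = 0.3)
})
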