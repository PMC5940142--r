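test_that("a noiseless model-generated surface is recovered exactly", {
  g <- simulate_genotypes(20, tibble::tibble(n_markers = 3, length_cm = 50),
                          seed = 21)
  truth <- quadratic_surface(0.23, 0.99, -0.006, -0.19, 0.026, 32)
  ph <- simulate_phenotypes(g, causal = NULL, baseline = 0, sigma_line = 0,
                            sigma_resid = 0, seed = 22)
  ph$diff_height_cm <- evaluate_quadratic(truth, ph$xw, ph$xn)
  fit <- fit_surface(ph, vc = c(sigma2_line = 0, sigma2_resid = 1))
  est <- fit$coefficients
  expect_equal(est$beta1, truth$beta1, tolerance = 1e-8)
  expect_equal(est$beta3, truth$beta3, tolerance = 1e-8)
  expect_equal(est$beta5, truth$beta5, tolerance = 1e-8)
  expect_equal(est$ell, truth$ell, tolerance = 1e-8)
  expect_lt(fit$weighted_rss, 1e-12)
  expect_equal(fit$n_fixed, 6L)
})

test_that("GLS under zero line variance equals the OLS oracle", {
  dat <- sim_small(seed = 31, sigma_line = 0, sigma_resid = 2)
  ph <- dat$phenotypes
  ols <- lm(diff_height_cm ~ xw + xn + I(xw^2) + I(xn^2) + I(xw * xn),
            data = ph)
  # forced sigma_line = 0: exact equivalence
  fit0 <- fit_surface(ph, kinship = dat$kinship,
                      vc = c(sigma2_line = 0, sigma2_resid = 1))
  est <- unlist(fit0$coefficients[1, c("ell", "beta1", "beta2", "beta3",
                                       "beta4", "beta5")])
  expect_equal(unname(est), unname(coef(ols)), tolerance = 1e-8)
  # REML on sigma_line = 0 data finds a near-zero component and stays at OLS
  fit <- fit_surface(ph, kinship = dat$kinship)
  expect_lt(fit$vc[["sigma2_line"]], 0.2 * fit$vc[["sigma2_resid"]])
  est2 <- unlist(fit$coefficients[1, c("ell", "beta1", "beta2", "beta3",
                                       "beta4", "beta5")])
  expect_equal(unname(est2), unname(coef(ols)), tolerance = 1e-4)
})

test_that("allele groups generated from one surface agree within sampling error", {
  g <- simulate_genotypes(200, tibble::tibble(n_markers = 3, length_cm = 80),
                          seed = 41)
  ph <- simulate_phenotypes(g, causal = NULL, baseline = 25, sigma_line = 0,
                            sigma_resid = 1, seed = 42)
  fit <- fit_surface(ph, genotypes = g, marker = "c1_m02")
  expect_equal(fit$n_fixed, 12L)
  expect_equal(nrow(fit$coefficients), 2L)
  est <- fit$coefficients
  # both groups see the same flat surface of height 25
  expect_equal(est$ell, c(25, 25), tolerance = 0.05)
  expect_equal(est$beta1, c(0, 0), tolerance = 0.01)
  expect_equal(est$beta4, c(0, 0), tolerance = 0.05)
})

test_that("the scan's F statistics are non-negative with nested RSS", {
  causal <- list(c1_m03 = list(B73 = example_producing_params("B73-like"),
                               Mo17 = example_producing_params("Mo17-like")))
  dat <- sim_small(seed = 51, causal = causal, sigma_resid = 3)
  sc <- marker_scan(dat$phenotypes, dat$genotypes, dat$kinship)
  ok <- !sc$skipped
  expect_true(all(is.finite(sc$F[ok])))
  expect_true(all(sc$F[ok] >= 0))
  expect_true(all(sc$raw_p[ok] >= 0 & sc$raw_p[ok] <= 1))
  # the planted marker dominates the scan
  expect_equal(sc$marker_id[which.max(sc$F)], "c1_m03")
})

test_that("identical allele surfaces with zero noise give F = 0, p = 1", {
  g <- simulate_genotypes(30, tibble::tibble(n_markers = 2, length_cm = 60),
                          seed = 61)
  truth <- quadratic_surface(0.2, 0.5, -0.004, -0.1, 0.01, 28)
  ph <- simulate_phenotypes(g, causal = NULL, baseline = 0, sigma_line = 0,
                            sigma_resid = 0, seed = 62)
  ph$diff_height_cm <- evaluate_quadratic(truth, ph$xw, ph$xn)
  sc <- marker_scan(ph, g, vc = c(sigma2_line = 0, sigma2_resid = 1))
  ok <- !sc$skipped
  expect_true(all(sc$F[ok] == 0))
  expect_true(all(sc$raw_p[ok] == 1))
})

test_that("markers with a rare allele class are skipped and flagged", {
  set.seed(71)
  calls <- cbind(matrix(sample(c("B73", "Mo17"), 40, replace = TRUE,
                               prob = c(0.5, 0.5)), ncol = 1),
                 c("Mo17", rep("B73", 39)))
  g <- make_genotypes(calls)
  ph <- simulate_phenotypes(g, build_design(reps = c(corner = 1, center = 1)),
                            sigma_line = 0, sigma_resid = 1, seed = 72)
  sc <- marker_scan(ph, g)
  expect_true(sc$skipped[2])
  expect_false(sc$skipped[1])
  expect_true(is.na(sc$raw_p[2]))
})

test_that("Simes smoothing matches hand computation and window rules", {
  # window of three: (0.03, 0.01, 0.02) -> sorted (0.01, 0.02, 0.03),
  # min(3*0.01/1, 3*0.02/2, 3*0.03/3) = 0.03
  sc <- make_scan(c(0.03, 0.01, 0.02))
  sm <- simes_smooth(sc, window = 3)
  expect_equal(sm$smoothed_p[2], 0.03)
  # window of one marker leaves p untouched
  expect_equal(simes_smooth(sc, window = 1)$smoothed_p, sc$raw_p)
  # all-ones stay at one
  expect_equal(simes_smooth(make_scan(rep(1, 6)), 5)$smoothed_p, rep(1, 6))
  # windows truncate at chromosome ends and never span chromosomes
  sc2 <- make_scan(c(1e-6, 1, 1, 1, 1, 1), chrom = c(1L, 1L, 1L, 2L, 2L, 2L))
  sm2 <- simes_smooth(sc2, window = 5)
  expect_true(all(sm2$smoothed_p[4:6] == 1))
  expect_lt(sm2$smoothed_p[1], 1e-5)
  expect_error(simes_smooth(sc, window = 4), class = "surfqtl_invalid_argument")
})

test_that("multiplicity adjustments match their closed forms", {
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "BH"), c(0.03, 0.04, 0.04))
  expect_equal(adjust_pvalues(0.2, "sidak", alpha = 0.05)$threshold, 0.05)
  sid2 <- adjust_pvalues(c(0.01, 0.3), "sidak", alpha = 0.05)
  expect_equal(sid2$threshold, 1 - 0.95^(1 / 2), tolerance = 1e-12)
  expect_equal(sid2$threshold, 0.025321, tolerance = 1e-4)
  expect_equal(sid2$significant, c(TRUE, FALSE))
  # Sidak threshold is bracketed by the Bonferroni bound and alpha
  for (m in c(1, 2, 10, 200)) {
    thr <- sidak_threshold(m, 0.05)
    expect_gte(thr, 0.05 / m - 1e-12)
    expect_lte(thr, 0.05 + 1e-12)
  }
  # BH-adjusted values are monotone in the sorted raw p
  set.seed(81)
  p <- runif(50)
  adj <- adjust_pvalues(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(adjust_pvalues(c(0.5, 1.2), "BH"),
               class = "surfqtl_invalid_argument")
  expect_error(adjust_pvalues(0.5, "sidak", alpha = 1.5),
               class = "surfqtl_invalid_argument")
})

test_that("QTL calling merges adjacent significant markers into intervals", {
  sm <- make_scan(rep(0.5, 5), smoothed_p = c(0.5, 1e-4, 2e-4, 0.5, 1e-4))
  sm <- adjust_scan(sm, alpha = 0.05)
  q <- call_qtl(sm, criterion = "sidak", alpha = 0.05)
  expect_equal(nrow(q), 2L)
  expect_equal(q$n_markers, c(2L, 1L))
  expect_equal(q$start_marker[1], "m02")
  expect_equal(q$end_marker[1], "m03")
  expect_equal(q$best_marker[1], "m02")
  # no significant markers -> empty interval table
  none <- adjust_scan(make_scan(rep(0.9, 4), smoothed_p = rep(0.9, 4)))
  expect_equal(nrow(call_qtl(none, "sidak")), 0L)
})
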