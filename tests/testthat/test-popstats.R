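test_that("ON/OFF calling counts against the control threshold", {
  call <- call_on_off(c(0.5, 2), c(1, 1, 1), k = 3)  # sd 0 -> threshold 1
  expect_equal(call$threshold, 1)
  expect_equal(call$on_fraction, 0.5)
  expect_equal(call$n_on + call$n_off, 2)
  low <- call_on_off(c(1, 2, 3), c(10, 12, 14), k = 3)
  expect_equal(low$on_fraction, 0)
  expect_error(call_on_off(numeric(0), c(1, 2)), "non-empty")
})

test_that("ON fraction is monotone non-increasing in k", {
  set.seed(2)
  vals <- c(rnorm(500, 5, 1), rlnorm(500, 4, 0.5))
  ctrl <- rnorm(100, 5, 1)
  fr <- vapply(c(0, 1, 2, 3, 5), function(k)
    call_on_off(vals, ctrl, k)$on_fraction, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("ON fraction estimate recovers a well-separated 83% mixture", {
  sp <- population_spec(
    list(channel_spec("cad", 0.83, "lognormal", loc = 5, scale = 0.4,
                      off_level = 2)),
    background_mean = 3, background_sd = 0.5,
    cells_per_field = 1000, seed = 21)
  cells <- simulate_population(sp)
  set.seed(22)
  control <- 2 + rnorm(500, 3, 0.5)  # non-tagged cells: off level + background
  est <- call_on_off(cells$cad_raw, control)$on_fraction
  ci <- qbinom(c(0.005, 0.995), 1000, 0.83) / 1000
  expect_gte(est, ci[1]); expect_lte(est, ci[2])
})

test_that("pearson matches the hand-computed product-moment value", {
  r <- pearson(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r$r, 3 / sqrt(2 * 14 / 3))   # 0.98198
  expect_equal(pearson(1:5, 1:5)$r, 1)
  expect_equal(pearson(1:5, -(1:5))$r, -1)
  expect_error(pearson(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson(1:2, 1:2), "n >= 3")
})

test_that("pearson is symmetric and affine-invariant", {
  set.seed(3)
  x <- rnorm(50); y <- 0.4 * x + rnorm(50)
  expect_equal(pearson(x, y)$r, pearson(y, x)$r)
  expect_equal(pearson(3 * x + 7, y)$r, pearson(x, y)$r)
})

test_that("pearson recovers latent correlations of the generator", {
  # Fig-3-like regime: targets within +/-0.05 at n = 1000 over 20 seeds
  for (rho in c(0.45, 0.11, -0.07)) {
    est <- vapply(1:20, function(s) {
      sp <- population_spec(
        list(channel_spec("x", 1, "normal", loc = 100, scale = 20),
             channel_spec("y", 1, "normal", loc = 60, scale = 12)),
        correlation = matrix(c(1, rho, rho, 1), 2),
        cells_per_field = 1000, seed = 400 + s)
      cells <- simulate_population(sp)
      pearson(cells$x_raw, cells$y_raw)$r
    }, numeric(1))
    expect_lt(abs(mean(est) - rho), 0.05)
  }
})

test_that("chi-square on counts matches the hand-worked 2x2 table", {
  cmp <- chi_square_counts(c(10, 10), c(5, 15))
  expect_equal(cmp$chi2, 8 / 3)   # expected 7.5 / 12.5 per row
  expect_equal(cmp$dof, 1)
  expect_equal(cmp$p_value, pchisq(8 / 3, 1, lower.tail = FALSE))
  # agreement with the standard homogeneity test, no continuity correction
  ct <- suppressWarnings(chisq.test(rbind(c(10, 10), c(5, 15)),
                                    correct = FALSE))
  expect_equal(cmp$chi2, unname(ct$statistic))
})

test_that("identical samples give chi2 = 0 and pooling respects expecteds", {
  x <- rep(1:10, each = 20)
  cmp <- chi_square_compare(x, x, n_bins = 10)
  expect_equal(cmp$chi2, 0)
  expect_equal(cmp$p_value, 1)
  set.seed(5)
  a <- rlnorm(300, 5, 0.6); b <- rlnorm(300, 5.2, 0.6)
  cmp2 <- chi_square_compare(a, b, n_bins = 20)
  tot <- cmp2$counts_a + cmp2$counts_b
  ea <- tot * sum(cmp2$counts_a) / sum(tot)
  eb <- tot * sum(cmp2$counts_b) / sum(tot)
  expect_true(all(pmin(ea, eb) >= 5) || length(tot) == 2)
  expect_equal(cmp2$dof, length(cmp2$counts_a) - 1)
})

test_that("chi-square type-I error is near nominal on same-generator data", {
  set.seed(6)
  p <- vapply(1:200, function(i)
    chi_square_compare(rlnorm(300, 5, 0.5), rlnorm(300, 5, 0.5))$p_value,
    numeric(1))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.01); expect_lte(rate, 0.10)
})

test_that("skewness matches moment oracles and classifies families", {
  expect_equal(as.numeric(skewness_g1(c(-1, 0, 1))), 0)
  expect_equal(attr(skewness_g1(c(-1, 0, 1)), "classification"), "symmetric")
  # m3 = 2/27, m2 = 2/9 -> g1 = sqrt(1/2)
  expect_equal(as.numeric(skewness_g1(c(0, 0, 1))), sqrt(0.5))
  expect_error(skewness_g1(c(2, 2, 2)), "zero variance")
  set.seed(7)
  ln <- vapply(1:20, function(i)
    as.numeric(skewness_g1(rlnorm(1000, 5, 0.6))), numeric(1))
  expect_true(all(ln > 0.5))     # lognormal flagged right-skewed
  gauss <- as.numeric(skewness_g1(rnorm(1000, 100, 10)))
  expect_lt(abs(gauss), 0.5)
})

test_that("skewness agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(8)
  x <- rlnorm(200, 3, 0.7)
  expect_equal(as.numeric(skewness_g1(x)), e1071::skewness(x, type = 1))
})

test_that("RLU normalization divides by volume and OD", {
  tc <- data.frame(time_min = c(0, 60, 114, 180),
                   counts_per_s = c(1000, 4000, 500, 300),
                   volume_ml = c(1, 1, 0.2, 1),
                   od600 = c(1, 0.8, 0.5, 1))
  out <- rlu_normalize(tc)
  expect_equal(out$records$rlu, c(1000, 5000, 5000, 300))
  expect_equal(out$t_max, 60)   # first maximum
  mono <- data.frame(time_min = 1:5, counts_per_s = 1:5,
                     volume_ml = 1, od600 = 1)
  expect_equal(rlu_normalize(mono)$t_max, 5)
  tc$od600[1] <- 0
  expect_error(rlu_normalize(tc), "od600")
})

test_that("population summary assembles the per-sample statistics", {
  set.seed(9)
  vals <- rlnorm(500, 5, 0.4)
  ctrl <- rnorm(200, 3, 1)
  s <- population_summary(vals, "cad", condition = "pH4.4", time_min = 300,
                          control_values = ctrl)
  expect_equal(s$n, 500)
  expect_equal(s$noise, compute_noise(vals)$noise)
  expect_equal(s$on_fraction, call_on_off(vals, ctrl)$on_fraction)
  expect_equal(s$channel, "cad")
})
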