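test_that("the brain age gap and MAE follow their definitions", {
  expect_equal(compute_brainage(70, 65), 5)
  expect_equal(compute_brainage(65, 65), 0)
  expect_equal(compute_brainage(60, 72), -12)
  expect_error(compute_brainage(NaN, 1), "finite")

  expect_equal(mae(c(60, 70), c(58, 74)), 3)
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  p <- c(61, 72, 55); a <- c(65, 70, 50)
  expect_equal(mae(p, a), mae(rev(p), rev(a)))  # order invariance
  expect_error(mae(numeric(0), numeric(0)), "non-empty")
})

test_that("the bias fit recovers exact and noisy linear age trends", {
  ages <- seq(20, 80, length.out = 40)
  b <- fit_bias_correction(0.5 * ages - 20, ages)
  expect_equal(b$alpha, 0.5, tolerance = 1e-10)
  expect_equal(b$beta, -20, tolerance = 1e-10)

  b2 <- fit_bias_correction(rep(3, 40), ages)
  expect_equal(b2$alpha, 0, tolerance = 1e-12)
  expect_equal(b2$beta, 3, tolerance = 1e-12)

  # OLS sampling theory: n = 500, sd 1 noise, slope 0.3
  ages3 <- with_seed(1, runif(500, 20, 80))
  gaps3 <- with_seed(2, 0.3 * ages3 - 10 + rnorm(500))
  b3 <- fit_bias_correction(gaps3, ages3)
  se <- 1 / sqrt(sum((ages3 - mean(ages3))^2))
  expect_lt(abs(b3$alpha - 0.3), 3 * se)

  expect_error(fit_bias_correction(c(1, 2, 3), c(50, 50, 50)), "variance")
  expect_error(fit_bias_correction(1:2, 1:2), "3 subjects")
})

test_that("applying the correction orthogonalizes the gap to age on the fit set", {
  ages <- with_seed(3, runif(200, 18, 88))
  gaps <- with_seed(4, 0.4 * ages - 15 + rnorm(200, 0, 2))
  tab <- data.frame(age = ages, gap_raw = gaps)
  b <- fit_bias_correction(gaps, ages)
  tab <- apply_bias_correction(tab, b)
  # OLS residual orthogonality
  expect_lt(abs(cor(tab$gap_corrected, tab$age)), 1e-8)
  refit <- fit_bias_correction(tab$gap_corrected, tab$age)
  expect_lt(abs(refit$alpha), 1e-8)
  expect_lt(abs(refit$beta), 1e-8)

  # identity correction and exact-bias annihilation
  id <- structure(list(alpha = 0, beta = 0, fit_set_id = "x"), class = "bias_model")
  expect_equal(apply_bias_correction(tab, id)$gap_corrected, tab$gap_raw)
  exact <- data.frame(age = ages, gap_raw = 0.4 * ages - 15)
  bex <- fit_bias_correction(exact$gap_raw, exact$age)
  expect_lt(max(abs(apply_bias_correction(exact, bex)$gap_corrected)), 1e-10)
})

test_that("gap_raw always equals predicted minus age in a prediction table", {
  ages <- with_seed(5, runif(50, 18, 88))
  pred <- with_seed(6, ages + rnorm(50, 2, 4))
  tab <- prediction_table(sprintf("s%02d", 1:50), ages, pred,
                          rep(c("control", "patient"), 25),
                          rep(c("F", "M"), 25))
  expect_identical(tab$gap_raw, tab$predicted_age - tab$age)
})

test_that("the BrainAGE ANCOVA matches the from-scratch GLM oracle", {
  for (i in 1:25) {
    dat <- with_seed(100 + i, {
      n <- sample(20:60, 1)
      data.frame(
        age = runif(n, 18, 88),
        sex = sample(c("F", "M"), n, replace = TRUE),
        group = c("control", "patient", sample(c("control", "patient"),
                                               n - 2, replace = TRUE)),
        gap_raw = rnorm(n, 0, 3))
    })
    dat$gap_raw <- dat$gap_raw + 2 * (dat$group == "patient")
    tab <- dat
    tab$gap_corrected <- tab$gap_raw
    got <- ancova_brainage(tab, gap = "raw")
    dat$group <- factor(dat$group); dat$sex <- factor(dat$sex)
    want <- oracle_ancova(dat, "gap_raw", c("group", "age", "sex"))
    expect_equal(got$F, want$F, tolerance = 1e-6)
    expect_equal(got$p, want$p, tolerance = 1e-6)
    expect_equal(got$SS, want$SS, tolerance = 1e-6)
    expect_equal(got$np2, want$np2, tolerance = 1e-6)
    expect_true(all(got$np2 >= 0 & got$np2 <= 1))
    expect_true(all(got$F >= 0))
  }
})

test_that("an injected patient offset is detected with high power", {
  dat <- with_seed(77, data.frame(
    age = runif(150, 18, 88),
    sex = sample(c("F", "M"), 150, replace = TRUE),
    group = rep(c("control", "patient"), length.out = 150)))
  dat$gap_corrected <- with_seed(78, rnorm(150, 0, 3)) + 8 * (dat$group == "patient")
  out <- ancova_brainage(dat, gap = "corrected")
  expect_lt(out$p[out$factor == "condition"], 1e-3)
})

test_that("a single group is rejected", {
  dat <- data.frame(age = runif(20, 20, 80), sex = "F", group = "control",
                    gap_corrected = rnorm(20))
  expect_error(ancova_brainage(dat), "two groups")
})
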