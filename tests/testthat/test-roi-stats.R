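test_that("parcellation matches the brute-force voxel loop and is linear", {
  atl <- build_atlas(atlas_spec(c(16, 16, 16), 6, seed = 21))
  v1 <- with_seed(1, array(rnorm(4096), dim = c(16, 16, 16)))
  v2 <- with_seed(2, array(rnorm(4096), dim = c(16, 16, 16)))

  expect_equal(unname(parcellate(v1, atl)),
               oracle_parcellate(v1, atl$labels, 6))

  # constant volume and the all-voxel single-region atlas
  expect_equal(unname(parcellate(array(3.5, c(16, 16, 16)), atl)), rep(3.5, 6))
  one <- list(labels = array(1L, c(16, 16, 16)),
              region_table = data.frame(label = 1L, name = "all", n_voxels = 4096L))
  expect_equal(unname(parcellate(v1, one)), mean(v1))

  # linearity to 1e-10
  lhs <- parcellate(2 * v1 - 3 * v2, atl)
  rhs <- 2 * parcellate(v1, atl) - 3 * parcellate(v2, atl)
  expect_lt(max(abs(lhs - rhs)), 1e-10)

  expect_error(parcellate(array(0, c(8, 8, 8)), atl), "mismatch")
})

test_that("BH correction reproduces hand computations and its oracle", {
  f <- fdr_correct(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_equal(f$q, rep(0.04, 4))
  expect_true(all(f$significant))

  expect_false(any(fdr_correct(rep(1, 8))$significant))
  expect_equal(fdr_correct(0.03)$q, 0.03)  # m = 1 identity

  for (i in 1:200) {
    p <- with_seed(i, runif(sample(1:200, 1))^sample(1:3, 1))
    f <- fdr_correct(p)
    q <- oracle_bh(p)
    expect_lt(max(abs(f$q - q)), 1e-12)
    expect_identical(f$significant, q < 0.05)
    expect_true(all(f$q >= p))
  }
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("percent significant is reported to two decimals", {
  expect_equal(percent_significant(c(rep(TRUE, 139), FALSE)), 99.29)
  expect_equal(percent_significant(rep(FALSE, 24)), 0)
  expect_equal(percent_significant(rep(TRUE, 24)), 100)
  expect_error(percent_significant(logical(0)), "empty")
})

make_roi_fixture <- function(n, K, shift_region = NULL, shift = 0, seed = 1) {
  with_seed(seed, {
    cohort <- data.frame(
      participant_id = sprintf("s%03d", seq_len(n)),
      age = runif(n, 18, 88),
      sex = sample(c("F", "M"), n, replace = TRUE),
      group = rep(c("control", "patient"), length.out = n))
    m <- matrix(rnorm(n * K), n, K,
                dimnames = list(cohort$participant_id,
                                sprintf("region_%03d", seq_len(K))))
    if (!is.null(shift_region)) {
      m[cohort$group == "patient", shift_region] <-
        m[cohort$group == "patient", shift_region] + shift
    }
    attr(m, "map_type") <- "morphometric"
    attr(m, "modality") <- "chan1"
    list(m = m, cohort = cohort)
  })
}

test_that("the per-region ANCOVA matches the GLM oracle region by region", {
  fx <- make_roi_fixture(40, 5, seed = 31)
  got <- roi_ancova(fx$m, fx$cohort, covariates = "age")
  dat <- data.frame(group = factor(fx$cohort$group), age = fx$cohort$age)
  for (r in 1:5) {
    dat$y <- fx$m[, r]
    want <- oracle_ancova(dat, "y", c("group", "age"))
    sub <- got[got$region == colnames(fx$m)[r], ]
    expect_equal(sub$F, want$F, tolerance = 1e-6)
    expect_equal(sub$p, want$p, tolerance = 1e-6)
  }
  # FDR is applied within each factor family across regions
  for (f in c("condition", "age")) {
    sub <- got[got$factor == f, ]
    expect_equal(sub$q, oracle_bh(sub$p), tolerance = 1e-12)
  }
})

test_that("an injected two-pooled-SD group shift is flagged after FDR", {
  fx <- make_roi_fixture(150, 8, shift_region = 3, shift = 2, seed = 32)
  got <- roi_ancova(fx$m, fx$cohort)
  hit <- got[got$region == "region_003" & got$factor == "condition", ]
  expect_lt(hit$q, 0.05)
  expect_true(hit$significant)
})

test_that("duplicated subjects do not break the fit and sharpen the p-value", {
  fx <- make_roi_fixture(30, 2, shift_region = 1, shift = 1, seed = 33)
  got1 <- roi_ancova(fx$m, fx$cohort)
  m2 <- rbind(fx$m, fx$m)
  co2 <- rbind(fx$cohort, fx$cohort)
  co2$participant_id <- sprintf("d%03d", seq_len(nrow(co2)))
  rownames(m2) <- co2$participant_id
  attr(m2, "map_type") <- "morphometric"; attr(m2, "modality") <- "chan1"
  got2 <- roi_ancova(m2, co2)
  expect_false(anyNA(got2$p))
  p1 <- got1$p[got1$region == "region_001" & got1$factor == "condition"]
  p2 <- got2$p[got2$region == "region_001" & got2$factor == "condition"]
  expect_lt(p2, p1)
})

test_that("misaligned subject ids are rejected", {
  fx <- make_roi_fixture(20, 2, seed = 34)
  bad <- fx$cohort
  bad$participant_id[1] <- "someone-else"
  expect_error(roi_ancova(fx$m, bad), "ids")
})
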