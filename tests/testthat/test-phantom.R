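test_that("minimal atlas has exactly background plus one non-empty region", {
  atl <- build_atlas(atlas_spec(c(16, 16, 16), 1, seed = 3))
  expect_setequal(unique(as.vector(atl$labels)), c(0L, 1L))
  expect_gt(atl$region_table$n_voxels, 0)
})

test_that("atlas generation is deterministic and labels are disjoint and complete", {
  spec <- atlas_spec(c(32, 32, 32), 24, seed = 9)
  a1 <- build_atlas(spec)
  a2 <- build_atlas(spec)
  expect_identical(a1$labels, a2$labels)

  # per-voxel scan: each voxel carries exactly one label, every region occurs,
  # and the region table counts sum to the foreground count
  lab <- as.vector(a1$labels)
  expect_true(all(lab %in% 0:24))
  counts <- tabulate(lab[lab > 0], nbins = 24)
  expect_true(all(counts >= 1))
  expect_identical(counts, a1$region_table$n_voxels)
  expect_equal(sum(a1$region_table$n_voxels), sum(lab > 0))
})

test_that("a grid too small for the requested regions raises a capacity error", {
  expect_error(build_atlas(atlas_spec(c(8, 8, 8), 30, seed = 1)), "too small")
})

test_that("cohort sampling honours split, bounds and the uniform mean", {
  co <- sample_cohort(100, 0.5, seed = 4)
  expect_equal(sum(co$group == "patient"), 50)
  expect_equal(sum(co$group == "control"), 50)

  co2 <- sample_cohort(500, 0.25, age_min = 20, age_max = 80, seed = 5)
  expect_equal(sum(co2$group == "patient"), 125)
  expect_gte(min(co2$age), 20)
  expect_lte(max(co2$age), 80)

  # CLT: uniform(20, 80) has mean 50, sd 60/sqrt(12)
  co3 <- sample_cohort(10000, 0, age_min = 20, age_max = 80, seed = 6)
  se <- 60 / sqrt(12) / sqrt(10000)
  expect_lt(abs(mean(co3$age) - 50), 3 * se)

  expect_error(sample_cohort(0, 0.5), "positive")
  expect_identical(sample_cohort(20, 0.5, seed = 7), sample_cohort(20, 0.5, seed = 7))
})

test_that("noise-free rendering reproduces the baseline template exactly", {
  atl <- build_atlas(atlas_spec(c(16, 16, 16), 4, seed = 2))
  eff <- effect_model(4, age_ref = 30, age_sensitive_set = integer(0),
                      subject_sd = 0, voxel_sd = 0,
                      n_channels = 1, channel_mixing = 1, seed = 2)
  rec <- list(participant_id = "s1", age = 55, sex = "F", group = "control")
  v <- render_subject(rec, atl, eff, seed = 1)$channels[[1]]
  template <- array(c(0, eff$baseline)[atl$labels + 1L], dim = dim(atl$labels))
  expect_identical(v, template)
})

test_that("noise-free region means are affine in age with the configured slope", {
  atl <- build_atlas(atlas_spec(c(16, 16, 16), 4, seed = 2))
  eff <- effect_model(4, age_ref = 20, subject_sd = 0, voxel_sd = 0,
                      n_channels = 1, channel_mixing = 1, seed = 3)
  mean_at <- function(age) {
    rec <- list(participant_id = "s1", age = age, sex = "F", group = "control")
    parcellate(render_subject(rec, atl, eff, seed = 1)$channels[[1]], atl)
  }
  m20 <- mean_at(20); m45 <- mean_at(45); m70 <- mean_at(70)
  # slope recovered exactly and the three points are collinear
  expect_equal(unname((m70 - m20) / 50), eff$age_slope, tolerance = 1e-10)
  expect_lt(max(abs((m45 - m20) - (m70 - m20) / 2)), 1e-10)
})

test_that("the disease offset is confined to the designated regions", {
  atl <- build_atlas(atlas_spec(c(16, 16, 16), 6, seed = 8))
  eff <- effect_model(6, age_ref = 20, disease_set = c(2, 5),
                      disease_offset = -10, subject_sd = 0, voxel_sd = 0,
                      n_channels = 2, channel_mixing = c(1, 0.5), seed = 8)
  ctrl <- list(participant_id = "s1", age = 60, sex = "M", group = "control")
  pat <- list(participant_id = "s1", age = 60, sex = "M", group = "patient")
  vc <- render_subject(ctrl, atl, eff, seed = 1)
  vp <- render_subject(pat, atl, eff, seed = 1)
  for (c in 1:2) {
    d <- vp$channels[[c]] - vc$channels[[c]]
    outside <- !(atl$labels %in% c(2, 5))
    expect_true(all(d[outside] == 0))
    expect_true(all(abs(d[atl$labels %in% c(2, 5)] -
                          eff$channel_mixing[c] * (-10)) < 1e-12))
  }
})

test_that("rendering is bit-reproducible for identical id and seed", {
  atl <- build_atlas(atlas_spec(c(16, 16, 16), 4, seed = 2))
  eff <- effect_model(4, n_channels = 2, seed = 2)
  rec <- list(participant_id = "x9", age = 40, sex = "F", group = "control")
  expect_identical(render_subject(rec, atl, eff, seed = 10),
                   render_subject(rec, atl, eff, seed = 10))
})

test_that("an effect model referencing regions beyond the atlas errors", {
  atl <- build_atlas(atlas_spec(c(16, 16, 16), 3, seed = 2))
  eff <- effect_model(2, seed = 1)  # atlas has label 3 the model cannot seat
  rec <- list(participant_id = "s", age = 30, sex = "F", group = "control")
  expect_error(render_subject(rec, atl, eff, seed = 1), "effect model")
})
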