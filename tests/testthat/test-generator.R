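# Synthetic knee generator: determinism, calibration, range containment,
# validation.

test_that("noise-free draw yields the calibrated native geometry exactly", {
  k <- noise_free_knee()
  expect_s3_class(k, "knee_model")
  expect_equal(measure_tttg(k)$distance, 21.0, tolerance = 1e-9)
  expect_equal(k$metadata$dz, 47.0)
  lm <- k$landmarks
  expect_identical(rownames(lm), owosim::KNEE_LANDMARKS)
  expect_gt(lm["trochlear_groove_deepest", "z"],
            lm["tibial_tuberosity_mid", "z"])
  expect_gt(lm["lat_condyle_posterior", "x"], lm["med_condyle_posterior", "x"])
})

test_that("same params and subject id reproduce a bitwise-identical model", {
  p <- generator_params(seed = 99L)
  expect_identical(sample_knee(p, 3L), sample_knee(p, 3L))
  c1 <- sample_cohort(p); c2 <- sample_cohort(p)
  expect_identical(c1, c2)
  # distinct subjects differ
  expect_false(identical(c1[[1]]$landmarks, c1[[2]]$landmarks))
  # drawing a knee leaves the caller's RNG state untouched
  set.seed(5); before <- .Random.seed
  invisible(sample_knee(p, 1L))
  expect_identical(.Random.seed, before)
})

test_that("native TT-TG is calibrated and truncated to its range", {
  p <- generator_params(seed = 2024L)
  draws <- vapply(1:4000, function(i) measure_tttg(sample_knee(p, i))$distance,
                  numeric(1))
  expect_true(all(draws >= 18 & draws <= 24))
  # symmetric truncation leaves the mean at the target
  expect_lt(abs(mean(draws) - 21.0), 0.1)
  # realized sd equals the analytic truncated-normal sd (NOT the parent sd:
  # truncating N(21, 2.1) to [18, 24] shrinks it)
  a <- 3 / 2.1
  sd_trunc <- 2.1 * sqrt(1 - 2 * a * dnorm(a) / (2 * pnorm(a) - 1))
  expect_lt(abs(sd(draws) - sd_trunc), 0.1)
})

test_that("cohort draws respect every configured range", {
  for (s in 1:25) {
    cohort <- sample_cohort(generator_params(seed = s))
    for (k in cohort) {
      expect_true(k$metadata$tttg_native >= 18 && k$metadata$tttg_native <= 24)
      expect_true(k$metadata$dz >= 40 && k$metadata$dz <= 58)
      expect_true(k$metadata$hka_deg >= 1.5 && k$metadata$hka_deg <= 6.0)
    }
  }
})

test_that("mirrored left knees measure the same TT-TG magnitude", {
  for (s in 1:5) {
    k <- sample_knee(generator_params(seed = s), 1L)
    left <- mirror_knee(k)
    expect_identical(left$side, "left")
    expect_equal(abs(measure_tttg(left)$distance),
                 abs(measure_tttg(k)$distance), tolerance = 1e-12)
    expect_identical(mirror_knee(left), k)  # involution
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_params(n_subjects = 0), "n_subjects")
  expect_error(generator_params(tttg_sd = -1), "standard deviations")
  expect_error(generator_params(tttg_range = c(24, 18)), "ordered")
  # truncation window unreachable: range excludes the mean by > 6 sd
  expect_error(generator_params(tttg_mean = 21, tttg_sd = 0.1,
                                tttg_range = c(30, 31)),
               "excludes the mean")
})

test_that("landmark files round-trip through JSON and CSV", {
  k <- sample_knee(generator_params(seed = 11L), 2L)
  jp <- withr::local_tempfile(fileext = ".json")
  write_landmarks_json(k, jp)
  k2 <- read_landmarks_json(jp)
  expect_equal(k2$landmarks, k$landmarks, tolerance = 1e-12)
  expect_identical(k2$side, k$side)

  cp <- withr::local_tempfile(fileext = ".csv")
  write_landmarks_csv(k, cp)
  expect_equal(read_landmarks_csv(cp)$landmarks, k$landmarks,
               tolerance = 1e-6)

  # a missing landmark is reported by name
  obj <- jsonlite::read_json(jp, simplifyVector = TRUE)
  obj$landmarks$tibial_tuberosity_mid <- NULL
  jsonlite::write_json(obj, jp, auto_unbox = TRUE)
  expect_error(read_landmarks_json(jp), "tibial_tuberosity_mid")
})
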