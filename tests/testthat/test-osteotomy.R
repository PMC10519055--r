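# Osteotomy plan construction, fragment classification, varus rotation and
# the closed-form pendulum oracle.

test_that("the plan satisfies its geometric contracts", {
  k <- noise_free_knee()
  plan <- build_osteotomy_plan(k)
  # pivot 10 mm from the apex, on the osteotomy plane
  expect_equal(sqrt(sum((plan$pivot - plan$apex)^2)), 10, tolerance = 1e-6)
  expect_lt(abs(signed_distance(plan$pivot, plan$plane)), 1e-6)
  # plane contains entry and apex; normal has no anteroposterior component
  expect_lt(abs(signed_distance(plan$entry, plan$plane)), 1e-9)
  expect_lt(abs(signed_distance(plan$apex, plan$plane)), 1e-9)
  expect_equal(plan$plane$normal[2], 0, tolerance = 1e-12)
  expect_equal(plan$axis_dir, c(0, 1, 0), tolerance = 1e-9)
  # entry is 20 mm proximal to the lateral epicondyle
  expect_equal(plan$entry,
               unname(k$landmarks["lateral_epicondyle", ] + c(0, 0, 20)))
})

test_that("a mirrored left knee yields the mirror-image plan", {
  k <- sample_knee(generator_params(seed = 5L), 1L)
  plan_r <- build_osteotomy_plan(k)
  plan_l <- build_osteotomy_plan(mirror_knee(k))
  # plans are expressed in the canonical right frame, so they coincide
  expect_equal(plan_l$entry, plan_r$entry, tolerance = 1e-12)
  expect_equal(plan_l$pivot, plan_r$pivot, tolerance = 1e-12)
})

test_that("fragment classification follows the plane and the merged-bone rule", {
  k <- noise_free_knee()
  plan <- build_osteotomy_plan(k)
  lab <- classify_fragment(k, plan)
  distal <- c("trochlear_groove_deepest", "tibial_tuberosity_mid",
              "med_condyle_posterior", "lat_condyle_posterior",
              "lat_tibial_condyle_posterior", "lateral_epicondyle",
              "adductor_tubercle")
  expect_true(all(lab[distal] == "distal"))
  expect_identical(unname(lab["medial_cortex_apex"]), "proximal")

  # a synthetic shaft point 50 mm proximal to the entry is proximal
  k2 <- k
  k2$landmarks["lateral_epicondyle", ] <- plan$entry + c(0, 0, 50)
  expect_identical(unname(classify_fragment(k2, plan)["lateral_epicondyle"]),
                   "proximal")
  # tibial landmarks stay distal regardless of where the plane cuts
  k3 <- k
  k3$landmarks["tibial_tuberosity_mid", "z"] <- 40  # would be proximal side
  k3$landmarks["trochlear_groove_deepest", "z"] <- 41
  expect_identical(unname(classify_fragment(k3, plan)["tibial_tuberosity_mid"]),
                   "distal")

  # a non-hinge landmark exactly on the plane is surfaced, not guessed
  k4 <- k
  k4$landmarks["lateral_epicondyle", ] <- plan$apex +
    0.5 * (plan$entry - plan$apex)
  expect_error(classify_fragment(k4, plan), "ambiguous")
})

test_that("varus rotation is identity at 0, composes, and preserves y", {
  k <- noise_free_knee()
  plan <- build_osteotomy_plan(k)
  expect_equal(apply_varus(k, plan, 0)$landmarks, k$landmarks,
               tolerance = 1e-12)
  # six 2-degree steps equal one 12-degree rotation
  k_step <- k
  for (i in 1:6) {
    rotated <- apply_varus(k, plan, 2 * i)
    # composition: rotating the previous result by a further 2 degrees
    lab <- classify_fragment(k, plan)
    expect_equal(rotated$landmarks[names(lab)[lab == "distal"], ],
                 rotate_points(k_step$landmarks[names(lab)[lab == "distal"], ],
                               rigid_rotation(plan$pivot, c(0, 1, 0), 2)),
                 tolerance = 1e-9)
    k_step <- rotated
  }
  # anteroposterior coordinates are untouched at any angle
  for (a in c(2, 7.5, 12, 30))
    expect_equal(apply_varus(k, plan, a)$landmarks[, "y"],
                 k$landmarks[, "y"], tolerance = 1e-12)
  expect_error(apply_varus(k, plan, -1), "\\[0, 30\\]")
  expect_error(apply_varus(k, plan, 31), "\\[0, 30\\]")
})

test_that("positive varus displaces distal landmarks medially", {
  k <- noise_free_knee()
  rotated <- apply_varus(k, build_osteotomy_plan(k), 10)
  # tuberosity is far distal to the pivot: it must move toward -x
  expect_lt(rotated$landmarks["tibial_tuberosity_mid", "x"],
            k$landmarks["tibial_tuberosity_mid", "x"])
})

test_that("closed-form pendulum model matches its arithmetic and monotonicity", {
  expect_equal(closed_form_tttg(21, 47, 0), 21)
  th <- 12 * pi / 180
  expect_equal(closed_form_tttg(21, 47, 12), 21 * cos(th) - 47 * sin(th),
               tolerance = 1e-12)
  expect_equal(round(closed_form_tttg(21, 47, 12), 2), 10.77)
  # strictly decreasing over the schedule for dz > 0
  v <- closed_form_tttg(21, 47, seq(0, 12, by = 0.5))
  expect_true(all(diff(v) < 0))
  # general vector form agrees with the reduced form for a mediolateral PCL
  expect_equal(closed_form_tttg(NA, NA, 9, pcl_vector = c(44, 0, 0),
                                tt_minus_tg = c(21, 13, -47)),
               closed_form_tttg(21, 47, 9), tolerance = 1e-12)
  expect_error(closed_form_tttg(21, 47, 0, pcl_vector = c(0, 0, 1)),
               "degenerate")
})

test_that("full 3D schedule equals the closed form on a noise-free knee", {
  k <- noise_free_knee()
  s <- run_schedule(k)
  expect_s3_class(s, "tttg_series")
  expect_equal(s$tttg_mm, closed_form_tttg(21, 47, REF_ANGLES),
               tolerance = 1e-6)
  expect_true(all(diff(s$tttg_mm) < 0))
  s0 <- run_schedule(k, angles = 0)
  expect_equal(s0$tttg_mm, measure_tttg(k)$distance)
  expect_error(run_schedule(k, angles = c(4, 2)), "increasing")
})

test_that("measured TT-TG is invariant to the pivot location", {
  k <- sample_knee(generator_params(seed = 31L), 1L)
  plan <- build_osteotomy_plan(k)
  base <- run_schedule(k, plan)
  set.seed(7)
  for (i in 1:10) {
    plan2 <- plan
    plan2$pivot <- plan$pivot + rnorm(3, sd = 30)  # anywhere at all
    expect_equal(run_schedule(k, plan2)$tttg_mm, base$tttg_mm,
                 tolerance = 1e-9)
  }
})

test_that("left-knee pipeline output equals the right-knee output", {
  k <- sample_knee(generator_params(seed = 13L), 1L)
  s_r <- run_schedule(k)
  s_l <- run_schedule(mirror_knee(k))
  expect_equal(abs(s_l$tttg_mm), abs(s_r$tttg_mm), tolerance = 1e-9)
})

test_that("pendulum fit recovers dz on noise-free knees to 0.1 mm", {
  for (s in 1:5) {
    p <- generator_params(seed = s, condyle_dz_jitter_sd = 0)
    k <- sample_knee(p, 1L)
    cf <- coef(pendulum_fit(run_schedule(k)))
    expect_lt(abs(cf[["dz"]] - k$metadata$dz), 0.1)
    expect_lt(abs(cf[["tttg_native"]] - k$metadata$tttg_native), 0.1)
  }
})

test_that("plans serialise losslessly to JSON", {
  plan <- build_osteotomy_plan(noise_free_knee())
  p <- withr::local_tempfile(fileext = ".json")
  write_plan_json(plan, p)
  plan2 <- read_plan_json(p)
  expect_equal(plan2$pivot, plan$pivot, tolerance = 1e-12)
  expect_equal(plan2$plane$normal, plan$plane$normal, tolerance = 1e-12)
})
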