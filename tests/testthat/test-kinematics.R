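test_that("elbow and shoulder angles reproduce hand-computable poses", {
  expect_equal(elbow_angle(c(0, 2), c(0, 1), c(0, 0)), 180)
  expect_equal(elbow_angle(c(1, 1), c(0, 1), c(0, 0)), 90)
  expect_equal(trunk_axis(c(-1, 10), c(1, 10), c(-1, 0), c(1, 0)), c(0, 1))
  # translation of the whole configuration leaves the axis unchanged
  expect_equal(trunk_axis(c(4, 17), c(6, 17), c(4, 7), c(6, 7)), c(0, 1))
  expect_equal(shoulder_angle(c(0, 5), c(0, 0), c(0, 1)), 0)
  expect_equal(shoulder_angle(c(5, 0), c(0, 0), c(0, 1)), 90)
})

test_that("angles match an atan2 oracle on random poses", {
  # oracle via atan2(|cross|, dot): an independent trigonometric route
  atan2_angle <- function(u, v) {
    atan2(abs(u[1] * v[2] - u[2] * v[1]), sum(u * v)) * 180 / pi
  }
  set.seed(11)
  for (i in 1:1000) {
    w <- runif(2, -50, 50); e <- runif(2, -50, 50); s <- runif(2, -50, 50)
    if (all(w == e) || all(s == e)) next
    expect_equal(elbow_angle(w, e, s),
                 atan2_angle(w - e, s - e), tolerance = 1e-9)
    axis <- c(0, 1)
    expect_equal(shoulder_angle(e, s, axis),
                 atan2_angle(e - s, axis), tolerance = 1e-9)
  }
})

test_that("degenerate segments yield NA angles", {
  expect_true(is.na(elbow_angle(c(1, 1), c(1, 1), c(0, 0))))
  expect_true(is.na(shoulder_angle(c(2, 2), c(2, 2), c(0, 1))))
  expect_true(all(is.na(trunk_axis(c(0, 0), c(2, 0), c(0, 0), c(2, 0)))))
})

test_that("static poses give the expected whole-trace angles", {
  tp <- compute_angle_traces(static_trace(30, "tpose"))
  expect_true(all(abs(tp$shoulder_L - 90) < 1e-9))
  expect_true(all(abs(tp$shoulder_R - 90) < 1e-9))
  an <- compute_angle_traces(static_trace(30, "anatomical"))
  expect_true(all(abs(an$shoulder_L) < 1e-9))
  expect_true(all(abs(an$elbow_L - 180) < 1e-9))
  expect_true(all(abs(an$elbow_R - 180) < 1e-9))
})

test_that("angle traces are invariant to translation and uniform scale", {
  cfg <- noiseless_config()
  sim <- simulate_trial(cfg, "p1", 1, severity = 3, seed = 5)
  base <- compute_angle_traces(sim$trace)

  frames <- tibble::as_tibble(sim$trace)
  for (lm in gaitarm:::LANDMARKS) {
    frames[[paste0(lm, "_x")]] <- frames[[paste0(lm, "_x")]] * 2.5 + 37
    frames[[paste0(lm, "_y")]] <- frames[[paste0(lm, "_y")]] * 2.5 - 11
  }
  moved <- landmark_trace(frames, "t", "p1", "ABI")
  shifted <- compute_angle_traces(moved)
  for (a in c("elbow_L", "elbow_R", "shoulder_L", "shoulder_R")) {
    expect_equal(shifted[[a]], base[[a]], tolerance = 1e-9)
  }
})

test_that("mirroring the frame swaps left and right angle series exactly", {
  cfg <- noiseless_config()
  sim <- simulate_trial(cfg, "p1", 1, severity = 4, seed = 8)
  base <- compute_angle_traces(sim$trace)

  frames <- tibble::as_tibble(sim$trace)
  mirrored <- frames["frame"]
  for (lm in gaitarm:::LANDMARKS) {
    other <- if (startsWith(lm, "L_")) sub("^L_", "R_", lm) else
      sub("^R_", "L_", lm)
    mirrored[[paste0(lm, "_x")]] <- 1920 - frames[[paste0(other, "_x")]]
    mirrored[[paste0(lm, "_y")]] <- frames[[paste0(other, "_y")]]
    mirrored[[paste0(lm, "_likelihood")]] <-
      frames[[paste0(other, "_likelihood")]]
  }
  mir <- compute_angle_traces(landmark_trace(mirrored, "t", "p1", "ABI"))
  expect_equal(mir$elbow_L, base$elbow_R, tolerance = 1e-9)
  expect_equal(mir$elbow_R, base$elbow_L, tolerance = 1e-9)
  expect_equal(mir$shoulder_L, base$shoulder_R, tolerance = 1e-9)
  expect_equal(mir$shoulder_R, base$shoulder_L, tolerance = 1e-9)
})

test_that("angle traces track the generator's closed-form angles", {
  cfg <- noiseless_config()
  sim <- simulate_trial(cfg, "p1", 1, severity = 2, seed = 2,
                        affected_side = "R")
  got <- compute_angle_traces(sim$trace)
  truth <- dplyr::semi_join(sim$angles_true, got, by = "frame")
  for (a in c("elbow_L", "elbow_R", "shoulder_L", "shoulder_R")) {
    expect_equal(got[[a]], truth[[a]], tolerance = 1e-6)
  }

  # with jitter the series still track within a few degrees
  noisy <- simulate_trial(synth_config(), "p1", 1, severity = 2, seed = 2,
                          affected_side = "R")
  gotn <- compute_angle_traces(noisy$trace)
  truthn <- dplyr::semi_join(noisy$angles_true, gotn, by = "frame")
  expect_lt(mean(abs(gotn$elbow_R - truthn$elbow_R)), 3)
  expect_lt(mean(abs(gotn$shoulder_R - truthn$shoulder_R)), 3)
})

test_that("angle outputs stay in [0, 180] with no NA over a random cohort", {
  co <- generate_cohort(small_cohort_config(seed = 6))
  for (tr in co$traces[1:6]) {
    ang <- compute_angle_traces(tr)
    vals <- unlist(ang[c("elbow_L", "elbow_R", "shoulder_L", "shoulder_R")])
    expect_false(anyNA(vals))
    expect_true(all(vals >= 0 & vals <= 180))
  }
})
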