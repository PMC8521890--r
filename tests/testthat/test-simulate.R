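test_that("a static posture measures pure gravity: |a| = 9.81 everywhere", {
  for (act in c("Standing", "LFU", "LFD", "LS")) {
    rec <- one_activity_rec(act, 5, sigma_e = 0,
                            params = list(sway = list(amp = 0),
                                          standing = list(sway_scale = 0)))
    r <- vector_magnitude(rec$ax, rec$ay, rec$az)
    expect_equal(r, rep(9.81, nrow(rec)), tolerance = 1e-12)
  }
})

test_that("an upright sensor with no mounting offset reads (0, 0, 9.81)", {
  rec <- simulate_recording(sim_config(
    tibble::tibble(activity = "Standing", duration = 10),
    sigma_e = 0, trn_duration = 0, placements = "waist",
    params = list(sway = list(amp = 0), standing = list(sway_scale = 0),
                  mount = list(roll = 0, pitch = -0.05))  # cancels site offset
  ))
  expect_equal(nrow(rec), 1000)
  expect_equal(rec$ax, rep(0, 1000), tolerance = 1e-9)
  expect_equal(rec$az, rep(9.81, 1000), tolerance = 1e-9)
})

test_that("lying postures put gravity on distinct body axes", {
  axis_of <- function(act) {
    rec <- one_activity_rec(act, 2, params = list(sway = list(amp = 0)))
    mean_acc <- colMeans(rec[, c("ax", "ay", "az")])
    which.max(abs(mean_acc))
  }
  expect_equal(axis_of("LFU"), c(ax = 1L))
  expect_equal(axis_of("LFD"), c(ax = 1L))
  expect_equal(axis_of("LS"), c(ay = 2L))
  # face-up and face-down have opposite sign on the same axis
  up <- one_activity_rec("LFU", 2, params = list(sway = list(amp = 0)))
  down <- one_activity_rec("LFD", 2, params = list(sway = list(amp = 0)))
  expect_gt(mean(up$ax), 9)
  expect_lt(mean(down$ax), -9)
})

test_that("gait magnitude has its spectral peak at the configured frequency", {
  for (f in c(1.4, 1.8, 2.8)) {
    rec <- one_activity_rec("Walking", 10, params = list(
      walking = list(freq = f, amp_v = 2, amp_f = 1)
    ))
    r <- vector_magnitude(rec$ax, rec$ay, rec$az)
    r <- r - mean(r)
    spec <- Mod(stats::fft(r))[2:500]
    freqs <- (1:499) / 10
    expect_equal(freqs[which.max(spec)], f, tolerance = 1e-9)
  }
})

test_that("recordings are bit-identical under a fixed seed", {
  cfg <- tiny_config(seed = 42)
  expect_identical(simulate_recording(cfg), simulate_recording(cfg))
})

test_that("noise SD of a static segment converges to sigma_e", {
  sigma <- 0.05
  rec <- simulate_recording(sim_config(
    tibble::tibble(activity = "Standing", duration = 100),
    sigma_e = sigma, trn_duration = 0, placements = "ear_left",
    params = list(sway = list(amp = 0), standing = list(sway_scale = 0))
  ))
  se <- sigma / sqrt(2 * nrow(rec))
  for (axn in c("ax", "ay", "az")) {
    expect_lt(abs(sd(rec[[axn]]) - sigma), 3 * se)
  }
})

test_that("label stream follows the script sample for sample", {
  cfg <- tiny_config(seed = 3, placements = "ear_left")
  rec <- simulate_recording(cfg)
  segs <- rle(as.character(rec$label))
  script_acts <- cfg$script$activity
  expect_equal(segs$values[seq(1, length(segs$values), by = 2)], script_acts)
  expect_true(all(segs$values[seq(2, length(segs$values) - 1, by = 2)] == "TRN"))
  expect_equal(segs$lengths[seq(1, length(segs$values), by = 2)],
               as.integer(cfg$script$duration * cfg$fs))
  expect_true(all(segs$lengths[seq(2, length(segs$values) - 1, by = 2)] ==
                    cfg$trn_duration * cfg$fs))
  expect_setequal(unique(as.character(rec$label)), c(script_acts, "TRN"))
})

test_that("emitted rotations stay orthonormal through interpolation", {
  q0 <- quat_from_euler(0.1, 0.2, 0.3)
  q1 <- quat_from_euler(-1.2, pi / 2, 0.4)
  qs <- quat_slerp(q0, q1, seq(0, 1, length.out = 50))
  for (i in seq_len(nrow(qs))) {
    R <- quat_to_matrix(qs[i, ])
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("the two ear streams are correlated but not identical", {
  rec <- simulate_recording(tiny_config(seed = 5,
                                        placements = c("ear_left", "ear_right")))
  l <- dplyr::filter(rec, placement == "ear_left")
  r <- dplyr::filter(rec, placement == "ear_right")
  expect_gt(cor(l$az, r$az), 0.9)
  expect_false(isTRUE(all.equal(l$az, r$az)))
})

test_that("config validation rejects bad scripts", {
  expect_error(sim_config(tibble::tibble(activity = "Running", duration = 5)),
               "Unknown activity")
  expect_error(sim_config(tibble::tibble(activity = "Walking", duration = -1)),
               "duration")
  expect_error(sim_config(tibble::tibble(activity = character(0),
                                         duration = numeric(0))),
               "at least one segment")
})

test_that("cohorts contain every subject and placement, deterministically", {
  base <- tiny_config(seed = 9)
  coh <- make_cohort(3, base, seed = 9)
  tab <- dplyr::count(coh, subject_id, placement)
  expect_equal(nrow(tab), 3 * 3)
  expect_equal(length(unique(tab$n)), 1)
  expect_identical(coh, make_cohort(3, base, seed = 9))
  expect_error(make_cohort(0, base), ">= 1")
})

test_that("a one-subject zero-jitter cohort reproduces the base recording", {
  base <- tiny_config(seed = 21, placements = "waist")
  expect_identical(make_cohort(1, base, jitter = 0),
                   simulate_recording(base))
})

test_that("jitter makes subjects differ", {
  base <- tiny_config(seed = 13, placements = "ear_left")
  coh <- make_cohort(2, base, seed = 13)
  s1 <- dplyr::filter(coh, subject_id == "S01")
  s2 <- dplyr::filter(coh, subject_id == "S02")
  expect_false(isTRUE(all.equal(s1$az, s2$az)))
})
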