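test_that("vector magnitude and tilt angles evaluate their formulas", {
  expect_equal(vector_magnitude(3, 4, 0), 5)
  expect_equal(vector_magnitude(0, 0, 9.81), 9.81)
  expect_equal(vector_magnitude(1, 1, 1), sqrt(3))

  expect_equal(unlist(tilt_angles(0, 0, 9.81)),
               c(tilt_x = pi / 2, tilt_y = pi / 2, tilt_z = 0))
  expect_equal(unlist(tilt_angles(9.81, 0, 0)),
               c(tilt_x = 0, tilt_y = pi / 2, tilt_z = pi / 2))
  expect_equal(unlist(tilt_angles(1, 1, 1)),
               rep(acos(1 / sqrt(3)), 3), ignore_attr = TRUE)
  # zero magnitude: undefined, returned as NA
  expect_true(all(is.na(unlist(tilt_angles(0, 0, 0)))))
  # direction cosines square-sum to 1
  set.seed(1)
  a <- matrix(rnorm(300), ncol = 3)
  ta <- tilt_angles(a[, 1], a[, 2], a[, 3])
  expect_equal(cos(ta$tilt_x)^2 + cos(ta$tilt_y)^2 + cos(ta$tilt_z)^2,
               rep(1, 100))
})

test_that("AVC matches hand-evaluated examples", {
  expect_equal(avc(c(5, 5, 5, 5), fs = 100), rep(0, 4))
  expect_equal(avc(c(1, 2), fs = 100)[1], 100)
  # M = 2 window centered at the middle sample averages both differences
  expect_equal(avc(c(0, 1, 3), fs = 1, M = 2)[2], 1.5)
  expect_true(all(avc(rnorm(50), fs = 10) >= 0))
})

test_that("SMA matches hand-evaluated examples", {
  expect_equal(sma(1, -1, 0.5), 2.5)
  expect_equal(sma(rep(0, 5), rep(0, 5), rep(0, 5)), rep(0, 5))
  expect_equal(sma(c(1, 2), c(-1, 0), c(0.5, -0.5), M = 2), c(2.5, 2.5))
})

test_that("windowed axis statistics match hand evaluation with divisor M", {
  st <- axis_stats(c(1, 2, 3, 4, 5), M = 5)[3, ]
  expect_equal(st$mean, 3)
  expect_equal(st$sd, sqrt(2))      # population divisor
  expect_equal(st$rms, sqrt(11))
  expect_equal(st$min, 1)
  expect_equal(st$max, 5)
  expect_equal(st$median, 3)
  expect_equal(st$mad, 1)
  expect_equal(st$skew, 0)

  cst <- axis_stats(rep(2.5, 10), M = 4)
  expect_equal(cst$mean, rep(2.5, 10))
  expect_equal(cst$sd, rep(0, 10))
  expect_equal(cst$mad, rep(0, 10))
  expect_equal(cst$skew, rep(0, 10))   # 0/0 convention
  expect_equal(cst$rms, rep(2.5, 10))

  skw <- axis_stats(c(0, 0, 9), M = 3)[2, ]$skew
  expect_gt(skw, 0)                    # right-skewed window
})

test_that("every feature matches an independent brute-force oracle", {
  set.seed(99)
  for (rep_i in 1:100) {
    n <- sample(150:300, 1)
    df <- tibble::tibble(
      time_s = (seq_len(n) - 1) / 100,
      ax = rnorm(n, sd = runif(1, 0.1, 5)),
      ay = rnorm(n, sd = runif(1, 0.1, 5)),
      az = 9.81 + rnorm(n, sd = runif(1, 0.1, 5)),
      label = activity_factor(rep("Walking", n)),
      placement = "ear_left", subject_id = "S01"
    )
    f <- extract_features(df)
    rows <- sample(n, 5)
    for (i in rows) {
      expected <- brute_force_features(df, i)
      got <- unlist(f[i, names(expected)])
      expect_equal(got, expected, tolerance = 1e-9)
    }
  }
})

test_that("counts column equals the per-epoch counts at each sample", {
  rec <- one_activity_rec("Walking", 6, sigma_e = 0.05, seed = 2)
  f <- extract_features(rec)
  r <- vector_magnitude(rec$ax, rec$ay, rec$az)
  cp <- counts_per_sec(r, 100)
  idx <- pmin(floor((seq_len(nrow(rec)) - 1) / 100) + 1, nrow(cp))
  expect_equal(f$counts_ps, cp$counts_per_sec[idx])
})

test_that("statistics are shift-invariant / equivariant as appropriate", {
  set.seed(5)
  x <- rnorm(200)
  a <- axis_stats(x, M = 30)
  b <- axis_stats(x + 7, M = 30)
  expect_equal(b$mean, a$mean + 7)
  expect_equal(b$median, a$median + 7)
  expect_equal(b$min, a$min + 7)
  expect_equal(b$max, a$max + 7)
  expect_equal(b$sd, a$sd)
  expect_equal(b$mad, a$mad)
  expect_equal(b$skew, a$skew)
})

test_that("scaling the signal scales amplitude features and fixes the rest", {
  set.seed(6)
  n <- 150
  df <- tibble::tibble(
    time_s = (seq_len(n) - 1) / 100,
    ax = rnorm(n), ay = rnorm(n), az = 9.81 + rnorm(n),
    label = activity_factor(rep("Jogging", n)),
    placement = "waist", subject_id = "S01"
  )
  s <- 3
  df2 <- dplyr::mutate(df, ax = s * ax, ay = s * ay, az = s * az)
  f1 <- extract_features(df, M_stats = 20)
  f2 <- extract_features(df2, M_stats = 20)
  for (col in c("mean_x", "sd_y", "rms_z", "min_x", "max_y", "median_z",
                "mad_x", "sma", "avc")) {
    expect_equal(f2[[col]], s * f1[[col]], tolerance = 1e-9)
  }
  for (col in c("skew_x", "skew_y", "skew_z", "tilt_x", "tilt_y", "tilt_z")) {
    expect_equal(f2[[col]], f1[[col]], tolerance = 1e-9)
  }
})

test_that("feature matrices have the documented shape and order", {
  rec <- flat_recording(1000)
  f <- extract_features(rec)
  expect_equal(nrow(f), 1000)   # shrink keeps every sample
  expect_identical(setdiff(names(f), meta_cols()), feature_names())
  expect_length(feature_names(), 33)
  # gravity-only stream: z tilt 0, no motion
  expect_equal(f$tilt_z, rep(0, 1000))
  expect_equal(f$avc, rep(0, 1000))
  expect_equal(f$counts_ps, rep(0, 1000))
  # dropping edges removes exactly the samples with truncated windows
  fd <- extract_features(rec, edge_policy = "drop")
  expect_equal(nrow(fd), 1000 - 99)
})

test_that("sensor concatenation prefixes columns and checks labels", {
  rec <- simulate_recording(tiny_config(seed = 4))
  f <- extract_features(rec, stride = 25)
  w2 <- concat_sensors(f, c("ear_left", "ear_right"))
  expect_equal(length(feature_cols(w2)), 66)
  w3 <- concat_sensors(f)
  expect_equal(length(feature_cols(w3)), 99)
  expect_true(all(startsWith(feature_cols(w2), "ear_")))
  # conflicting labels must error
  f_bad <- f
  f_bad$label[f_bad$placement == "waist"] <-
    rev(f_bad$label[f_bad$placement == "waist"])
  expect_error(concat_sensors(f_bad), "Label streams differ")
  expect_error(concat_sensors(f, c("ear_left", "ankle")), "not present")
})
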