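test_that("gravity offset removal zeroes the standing-window mean and leaves gyro alone", {
  # constant 1 G channel becomes all-zero; constant gyro is untouched
  acc <- matrix(1, 100, 3)
  gyr <- matrix(5, 100, 3)
  tr <- make_toy_trial(acc, gyr, standing = c(1, 50), run = c(51, 100))
  out <- suppressWarnings(remove_gravity_offset(tr))
  expect_equal(out$accel, matrix(0, 100, 3), ignore_attr = TRUE)
  expect_equal(out$gyro, gyr, ignore_attr = TRUE)

  # sine + offset over an integer number of periods: post-removal window
  # mean vanishes (brute-force mean subtraction oracle)
  n <- 200
  ch <- sin(2 * pi * 4 * (0:(n - 1)) / 100) + 0.3 # 8 full periods in 1..200
  tr2 <- make_toy_trial(cbind(ch, ch, ch), standing = c(1, 100),
                        run = c(101, n))
  out2 <- suppressWarnings(remove_gravity_offset(tr2))
  oracle <- ch - mean(ch[1:100])
  expect_equal(out2$accel[, 1], oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(abs(mean(out2$accel[1:100, 1])), 1e-12)
})

test_that("offset removal is idempotent and rejects unusable windows", {
  acc <- matrix(rnorm(300), 100, 3)
  tr <- make_toy_trial(acc, standing = c(1, 60), run = c(61, 100))
  once <- suppressWarnings(remove_gravity_offset(tr))
  twice <- suppressWarnings(remove_gravity_offset(once))
  expect_equal(twice$accel, once$accel)

  short <- make_toy_trial(acc, standing = c(1, 10), run = c(11, 100))
  expect_error(remove_gravity_offset(short), "unusable")
  expect_warning(remove_gravity_offset(short, min_window_s = 0.1),
                 "shortened standing window")
})

test_that("run segmentation restricts all channels and composes", {
  acc <- matrix(rnorm(1500), 500, 3)
  gyr <- matrix(rnorm(1500), 500, 3)
  tr <- make_toy_trial(acc, gyr, standing = c(1, 100), run = c(101, 400))
  seg <- segment_run(tr)
  expect_equal(nrow(seg$accel), 300)
  expect_equal(nrow(seg$gyro), 300)
  expect_equal(seg$accel, acc[101:400, ], ignore_attr = TRUE)

  # identity when the segment spans everything
  tr_id <- make_toy_trial(acc, gyr, standing = NULL, run = NULL)
  tr_id$run_segment <- c(1L, 500L)
  tr_id$standing_window <- NULL
  expect_equal(segment_run(tr_id)$accel, acc, ignore_attr = TRUE)

  # nested segmentation equals composed segmentation (brute force)
  seg2 <- seg
  seg2$run_segment <- c(51L, 250L)
  nested <- segment_run(seg2)
  composed <- tr
  composed$run_segment <- c(151L, 350L) # 101 + 50 .. 101 + 249
  composed$standing_window <- c(1L, 100L)
  expect_equal(nested$accel, segment_run(composed)$accel,
               ignore_attr = TRUE)

  bad <- tr
  bad$run_segment <- c(200L, 200L)
  expect_error(segment_run(bad), "degenerate")
})

test_that("mean_abs, am_series and trial_am follow their definitions", {
  expect_equal(mean_abs(c(1, -1, 1, -1)), 1.0)
  expect_equal(mean_abs(c(0, 0, 0)), 0.0)
  expect_equal(mean_abs(c(0.3, -0.5, 0.2)), (0.3 + 0.5 + 0.2) / 3)
  expect_error(mean_abs(numeric(0)), "empty")

  expect_equal(am_series(3, 4, 0), 5.0)
  expect_equal(am_series(rep(0, 5), rep(0, 5), rep(0, 5)), rep(0, 5))
  expect_error(am_series(1:3, 1:2, 1:3), "equal length")

  set.seed(42)
  ax <- rnorm(10); ay <- rnorm(10); az <- rnorm(10)
  oracle <- vapply(1:10, function(k) sqrt(ax[k]^2 + ay[k]^2 + az[k]^2),
                   numeric(1))
  expect_equal(am_series(ax, ay, az), oracle, tolerance = 1e-12)
  expect_equal(trial_am(ax, ay, az), mean(oracle), tolerance = 1e-12)
  # triangle property per sample and axis
  for (v in list(ax, ay, az)) expect_true(all(oracle >= abs(v) - 1e-15))
  expect_equal(trial_am(rep(3, 100), rep(4, 100), rep(0, 100)), 5.0)
})

test_that("acceleration ratios apportion AM per sample and average per trial", {
  expect_equal(acceleration_ratios(c(2, -1), c(0, 0), c(0, 0)),
               c(x = 100, y = 0, z = 0), ignore_attr = TRUE)
  r <- acceleration_ratios(rep(1, 4), rep(1, 4), rep(1, 4))
  expect_equal(unname(r), rep(100 / sqrt(3), 3), tolerance = 1e-12,
               ignore_attr = TRUE)

  set.seed(7)
  ax <- rnorm(50); ay <- rnorm(50); az <- rnorm(50)
  am <- sqrt(ax^2 + ay^2 + az^2)
  oracle <- c(mean(100 * abs(ax) / am), mean(100 * abs(ay) / am),
              mean(100 * abs(az) / am))
  got <- acceleration_ratios(ax, ay, az)
  expect_equal(unname(got), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
  s <- sum(got)
  expect_gte(s, 100 - 1e-9)
  expect_lte(s, 100 * sqrt(3) + 1e-9)

  # AM = 0 samples are dropped and counted; all-zero input is rejected
  got2 <- acceleration_ratios(c(0, 3), c(0, 4), c(0, 0))
  expect_equal(attr(got2, "n_dropped"), 1L)
  expect_equal(unname(got2), c(60, 80, 0), ignore_attr = TRUE)
  expect_error(acceleration_ratios(0, 0, 0), "no motion")

  # averaging per sample is NOT the ratio of trial means
  ratio_of_means <- 100 * mean(abs(ax)) / mean(am)
  expect_false(isTRUE(all.equal(unname(got)[1], ratio_of_means)))
})

test_that("summaries are scale- and permutation-equivariant", {
  set.seed(11)
  acc <- matrix(rnorm(300, sd = 0.5), 100, 3)
  gyr <- matrix(rnorm(300, sd = 20), 100, 3)
  tr <- make_toy_trial(acc, gyr, standing = c(1, 50), run = c(51, 100))
  base <- summarize_trial(segment_run(suppressWarnings(remove_gravity_offset(tr))))

  # scaling acceleration by c > 0 scales Ax..AM, leaves ratios unchanged
  tr_sc <- make_toy_trial(acc * 2.5, gyr, standing = c(1, 50),
                          run = c(51, 100))
  sc <- summarize_trial(segment_run(suppressWarnings(remove_gravity_offset(tr_sc))))
  expect_equal(unlist(sc[c("Ax", "Ay", "Az", "AM")]),
               2.5 * unlist(base[c("Ax", "Ay", "Az", "AM")]),
               tolerance = 1e-10)
  expect_equal(unlist(sc[c("Ax_ratio", "Ay_ratio", "Az_ratio")]),
               unlist(base[c("Ax_ratio", "Ay_ratio", "Az_ratio")]),
               tolerance = 1e-10)

  # permuting input axes permutes the outputs and leaves AM unchanged
  tr_pm <- make_toy_trial(acc[, c(3, 1, 2)], gyr[, c(3, 1, 2)],
                          standing = c(1, 50), run = c(51, 100))
  pm <- summarize_trial(segment_run(suppressWarnings(remove_gravity_offset(tr_pm))))
  expect_equal(unlist(pm[c("Ax", "Ay", "Az")]),
               unlist(base[c("Az", "Ax", "Ay")]), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unlist(pm[c("Ax_ratio", "Ay_ratio", "Az_ratio")]),
               unlist(base[c("Az_ratio", "Ax_ratio", "Ay_ratio")]),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(pm$AM, base$AM, tolerance = 1e-12)
})

test_that("a static noise-free trial is rejected at the ratio stage", {
  acc <- matrix(1, 100, 3) # constant: all-zero after offset removal
  tr <- make_toy_trial(acc, standing = c(1, 50), run = c(51, 100))
  proc <- segment_run(suppressWarnings(remove_gravity_offset(tr)))
  expect_error(summarize_trial(proc), "no motion")
})

test_that("recording construction enforces sensor range and window layout", {
  expect_error(make_toy_trial(matrix(9, 10, 3)), "8 G")
  expect_error(make_toy_trial(matrix(0, 10, 3),
                              gyro = matrix(1001, 10, 3)), "1000 dps")
  expect_error(make_toy_trial(matrix(0, 10, 3), standing = c(1, 6),
                              run = c(4, 10)), "overlap")
  expect_error(make_toy_trial(matrix(0, 10, 3), standing = c(1, 12),
                              run = c(5, 10)), "within")
})

test_that("session summary averages passes per dog, region and month", {
  s1 <- data.frame(dog_id = "d1", phenotype = "WT", region = "lumbar",
                   month = 2L, AM = 1.0, Ax = 0.5)
  s2 <- s1; s2$AM <- 2.0; s2$Ax <- 0.7
  out <- session_summary(rbind(s1, s2))
  expect_equal(nrow(out), 1)
  expect_equal(out$AM, 1.5)
  expect_equal(out$Ax, 0.6)
})
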