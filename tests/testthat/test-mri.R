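roi_row <- function(snr, px, muscle = "TC", side = "Right", idx = 1,
                    sd_air = 1) {
  data.frame(muscle = muscle, side = side, roi_index = idx,
             mean_intensity = snr * sd_air, pixel_count = px,
             sd_air = sd_air, stringsAsFactors = FALSE)
}

test_that("ROI SNR is intensity over background noise", {
  expect_equal(roi_snr(100, 10), 10)
  expect_equal(roi_snr(0, 3), 0)
  expect_equal(roi_snr(89.5, 4.3), 89.5 / 4.3)
  expect_error(roi_snr(10, 0), "sd_air")
  expect_error(roi_snr(-1, 2), "non-negative")
})

test_that("average SNR is the pixel-weighted bilateral mean", {
  two <- rbind(roi_row(10, 100), roi_row(20, 100, side = "Left"))
  expect_equal(average_snr(two)$ave_snr, 15)

  one <- roi_row(12.5, 77)
  expect_equal(average_snr(one)$ave_snr, 12.5)
  expect_equal(average_snr(one)$total_pixels, 77L)

  # hand-computed: SNRs (8, 12, 20), pixels (50, 150, 300), mirrored
  snrs <- c(8, 12, 20); px <- c(50, 150, 300)
  both <- do.call(rbind, lapply(c("Right", "Left"), function(s)
    do.call(rbind, Map(roi_row, snrs, px, side = s, idx = 1:3))))
  expect_equal(average_snr(both)$ave_snr,
               (8 * 50 + 12 * 150 + 20 * 300) * 2 / 1000)
  expect_equal(average_snr(both)$ave_snr, 16.4)

  expect_error(average_snr(rbind(roi_row(1, 10),
                                 roi_row(1, 10, muscle = "GL"))),
               "single muscle")
  expect_error(average_snr(roi_row(1, 10)[0, ]), "no ROIs")
})

test_that("average SNR is invariant to splitting an ROI with preserved SNR", {
  base <- rbind(roi_row(9, 200), roi_row(15, 100, side = "Left"))
  split <- rbind(roi_row(9, 120), roi_row(9, 80, idx = 2),
                 roi_row(15, 100, side = "Left"))
  expect_equal(average_snr(split)$ave_snr, average_snr(base)$ave_snr)
  # bounds: between min and max component SNR
  a <- average_snr(base)$ave_snr
  expect_gte(a, 9); expect_lte(a, 15)
})

test_that("Mann-Whitney exact p matches the printed small-sample cases", {
  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 4.5)
  expect_equal(same$p_value, 1.0)

  sep <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_value, 0.1) # 2 / C(6,3) extreme assignments

  full <- mann_whitney_u(c(1, 2, 3, 4, 5), c(10, 11, 12, 13, 14, 15))
  expect_equal(full$p_value, 2 / choose(11, 5))
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact enumeration equals the bitmask oracle, ties included", {
  for (case in 1:30) {
    set.seed(300 + case)
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    # draw from a small support to force ties often
    a <- sample(1:4, n1, replace = TRUE)
    b <- sample(1:4, n2, replace = TRUE)
    got <- mann_whitney_u(a, b, method = "exact")
    expect_equal(got$p_value, mw_exact_oracle(a, b))
    expect_gt(got$p_value, 0); expect_lte(got$p_value, 1)
  }
})

test_that("the normal approximation agrees with the standard tie-corrected test", {
  set.seed(8)
  a <- round(rnorm(15, 0.3), 1)
  b <- round(rnorm(18), 1)
  got <- mann_whitney_u(a, b, method = "normal")
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = TRUE))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Pearson correlation matches closed forms and is affine-invariant", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1.0)
  expect_equal(pearson_correlation(x, -x)$r, -1.0)

  y <- c(2, 1, 4, 3, 6)
  # brute-force covariance formula
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- pearson_correlation(x, y)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$r, 10 / sqrt(10 * 14.8), tolerance = 1e-12)

  expect_equal(pearson_correlation(10 * x - 3, 0.5 * y + 7)$r, got$r,
               tolerance = 1e-12)
  expect_equal(pearson_correlation(x, -y)$r, -got$r, tolerance = 1e-12)
  expect_error(pearson_correlation(x, rep(1, 5)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("AM-SNR correlation table recovers planted associations", {
  dogs <- paste0("d", 1:5)
  am <- data.frame(dog_id = rep(dogs, 2),
                   region = rep(c("thoracic", "lumbar"), each = 5),
                   AM = c(1.0, 1.2, 0.8, 1.5, 0.9,
                          1.1, 1.3, 0.7, 1.6, 1.0))
  # TC SNR exactly anti-linear in lumbar AM: r = -1 for (lumbar, TC)
  lum <- am$AM[am$region == "lumbar"]
  snrs <- rbind(
    data.frame(dog_id = dogs, muscle = "TC", ave_snr = 30 - 5 * lum),
    data.frame(dog_id = dogs, muscle = "FDS", ave_snr = 10 + 4 * lum))
  tab <- am_snr_correlation_table(am, snrs)
  expect_equal(nrow(tab), 2 * 2)
  expect_equal(tab$r[tab$region == "lumbar" & tab$muscle == "TC"], -1,
               tolerance = 1e-12)
  expect_equal(tab$r[tab$region == "lumbar" & tab$muscle == "FDS"], 1,
               tolerance = 1e-12)
  expect_true(all(c("r", "p_value", "significant") %in% names(tab)))

  # constant AMs are rejected through the zero-variance guard
  am0 <- am; am0$AM <- 1
  expect_error(am_snr_correlation_table(am0, snrs), "zero variance")
  expect_error(am_snr_correlation_table(am[am$dog_id %in% dogs[1:2], ],
                                        snrs), "fewer than 3 dogs")
})
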