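#' ROI signal-to-noise ratio
#'
#' SNR = ROI mean signal intensity / SD_air, where SD_air is the standard
#' deviation of the background noise of the image.
#'
#' @param mean_intensity non-negative ROI mean intensity (vectorized).
#' @param sd_air positive background-noise SD.
#' @return non-negative SNR value(s).
#' @export
roi_snr <- function(mean_intensity, sd_air) {
  if (any(!is.finite(sd_air)) || any(sd_air <= 0))
    stop("sd_air must be positive")
  if (any(mean_intensity < 0))
    stop("mean_intensity must be non-negative")
  mean_intensity / sd_air
}

#' Pixel-weighted bilateral average SNR of one muscle
#'
#' Ave SNR = (sum over right-side ROIs of SNR_i * Pixel_i + sum over
#' left-side ROIs of SNR_i * Pixel_i) / Pixel_Total, with Pixel_Total the
#' summed pixel count of all listed ROIs of the muscle (both sides,
#' i = 1,2 or 1,2,3).
#'
#' @param rois data.frame of ROI rows for a single muscle, with columns
#'   `muscle`, `mean_intensity`, `pixel_count`, `sd_air` (and usually
#'   `side`, `roi_index`).
#' @return one-row data.frame (muscle, ave_snr, total_pixels, n_rois).
#'   The average always lies between the smallest and largest component
#'   ROI SNR.
#' @export
average_snr <- function(rois) {
  stopifnot(is.data.frame(rois))
  if (nrow(rois) < 1) stop("no ROIs supplied")
  if (length(unique(rois$muscle)) != 1)
    stop("average_snr expects ROIs of a single muscle")
  if (any(rois$pixel_count < 1)) stop("pixel_count must be at least 1")
  snr <- roi_snr(rois$mean_intensity, rois$sd_air)
  total <- sum(rois$pixel_count)
  data.frame(muscle = rois$muscle[1],
             ave_snr = sum(snr * rois$pixel_count) / total,
             total_pixels = as.integer(total), n_rois = nrow(rois),
             stringsAsFactors = FALSE)
}

#' Mann-Whitney U test (exact with ties, or normal approximation)
#'
#' Two-sided rank-sum test comparing two independent groups. For small
#' samples (combined n at or below `exact_limit`, default 12, covering
#' the study's 5-vs-6 design) the p-value is computed by exhaustive
#' enumeration of all group assignments of the pooled midranks, so ties
#' are handled exactly: p = proportion of assignments whose U deviates
#' from its null mean n1*n2/2 at least as much as the observed U. For
#' larger samples the normal approximation with tie correction (and
#' optional continuity correction) is used.
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @param method "auto" (exact when combined n <= `exact_limit`),
#'   "exact", or "normal".
#' @param exact_limit combined-sample-size bound for automatic exact
#'   enumeration.
#' @param correct apply the continuity correction in the normal
#'   approximation.
#' @return list (statistic = U of `group_a`, p_value, method).
#' @export
mann_whitney_u <- function(group_a, group_b,
                           method = c("auto", "exact", "normal"),
                           exact_limit = 12, correct = TRUE) {
  method <- match.arg(method)
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty")
  n <- n1 + n2
  r <- rank(c(group_a, group_b)) # midranks for ties
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (method == "auto") method <- if (n <= exact_limit) "exact" else "normal"
  if (method == "exact") {
    obs <- abs(U1 - mu)
    offset <- n1 * (n1 + 1) / 2 + mu # U-from-rank-sum shift
    sel <- combn(n, n1)
    stats <- abs(colSums(matrix(r[sel], nrow = n1)) - offset)
    p <- mean(stats >= obs - 1e-9)
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- U1 - mu
      if (correct) d <- sign(d) * max(0, abs(d) - 0.5)
      p <- min(1, 2 * pnorm(-abs(d) / sqrt(sigma2)))
    }
  }
  list(statistic = unname(U1), p_value = p, method = method)
}

#' Pearson correlation with significance test
#'
#' Pearson's product-moment correlation with the p-value from the t
#' distribution on n - 2 degrees of freedom (via [stats::cor.test]), and
#' a significance flag at the 5% level.
#'
#' @param x,y equal-length numeric vectors, length >= 3, each with
#'   non-zero variance.
#' @return list (r, p_value, n, significant).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 paired observations required")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       significant = ct$p.value < 0.05)
}

#' Correlation table of gait AM against muscle Ave SNRs
#'
#' For dystrophic dogs at the MRI age (1 year), correlates each region's
#' trial acceleration magnitude with each muscle's Ave SNR across dogs:
#' 2 regions x 7 muscles records of (r, p, significant at 5%). A negative
#' r means dogs with worse muscle involvement (higher T2 SNR) show lower
#' acceleration.
#'
#' @param summaries data.frame with columns `dog_id`, `region`, `AM`
#'   (one row per dog and region).
#' @param snrs data.frame with columns `dog_id`, `muscle`, `ave_snr`
#'   (one row per dog and muscle).
#' @return data.frame (region, muscle, n, r, p_value, significant).
#' @export
am_snr_correlation_table <- function(summaries, snrs) {
  stopifnot(all(c("dog_id", "region", "AM") %in% names(summaries)),
            all(c("dog_id", "muscle", "ave_snr") %in% names(snrs)))
  regions <- sort(unique(summaries$region))
  muscles <- unique(snrs$muscle)
  rows <- list()
  for (reg in regions) {
    am <- summaries[summaries$region == reg, c("dog_id", "AM")]
    for (mus in muscles) {
      sn <- snrs[snrs$muscle == mus, c("dog_id", "ave_snr")]
      merged <- merge(am, sn, by = "dog_id")
      merged <- merged[stats::complete.cases(merged), , drop = FALSE]
      if (nrow(merged) < 3)
        stop(sprintf("fewer than 3 dogs with complete data for %s / %s",
                     reg, mus))
      ct <- pearson_correlation(merged$AM, merged$ave_snr)
      rows[[length(rows) + 1]] <- data.frame(
        region = reg, muscle = mus, n = ct$n, r = ct$r,
        p_value = ct$p_value, significant = ct$significant,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
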