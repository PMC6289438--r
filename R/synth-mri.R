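# Baseline T2-weighted ROI mean intensities (arbitrary units) and nominal
# per-ROI pixel counts for the seven crus muscles. Order matches the
# standard muscle panel: TC tibialis cranialis, EDL extensor digitorum
# longus, FDL flexor digitorum longus, FHL flexor hallucis longus, GM/GL
# gastrocnemius medial/lateral heads, FDS flexor digitorum superficialis.
.mri_baseline_intensity <- c(TC = 60, EDL = 62, FDL = 58, FHL = 59,
                             GM = 61, GL = 60, FDS = 57)
.mri_base_pixels <- c(TC = 220, EDL = 140, FDL = 120, FHL = 160,
                      GM = 260, GL = 240, FDS = 130)

#' Crus muscle panel
#'
#' The seven crus muscles evaluated on T2-weighted MRI, with their
#' fast/slow fiber-type grouping (metadata only; not used in any
#' computation): fast = TC, EDL; slow = GM, GL, FDS (GM is the usual sign
#' exception in gait correlations).
#'
#' @return data.frame (muscle, fiber_type).
#' @export
crus_muscles <- function() {
  data.frame(
    muscle = c("TC", "EDL", "FDL", "FHL", "GM", "GL", "FDS"),
    fiber_type = c("fast", "fast", "mixed", "mixed", "slow", "slow", "slow"),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic MRI ROI measurements for one subject
#'
#' Emulates the ROI tables drawn on T2-weighted images of the crus
#' muscles: two or three ROIs per side per muscle, each with a mean
#' signal intensity, a pixel count, and one shared background-noise SD
#' (SD_air). Intensities are a fixed per-muscle baseline plus, for
#' dystrophic subjects, `group_shift` (hyperintensity of involved
#' muscle), plus optional per-muscle shifts, a subject-level random
#' intercept, and per-ROI noise. Pixel counts are deterministic per
#' (muscle, ROI index), mirrored across sides.
#'
#' @param muscles character vector of muscle codes (default the seven
#'   crus muscles).
#' @param group "WT" or "DYS".
#' @param n_rois_per_side 2 or 3.
#' @param group_shift intensity added for DYS subjects.
#' @param seed integer seed.
#' @param noise_sd per-ROI intensity noise SD.
#' @param subject_sd SD of the subject-level intensity intercept.
#' @param sd_air background-noise SD shared by all ROIs of the image.
#' @param muscle_shifts optional named vector of extra per-muscle
#'   intensity shifts (e.g. to plant gait-MRI correlations).
#' @return data.frame (muscle, side, roi_index, mean_intensity,
#'   pixel_count, sd_air).
#' @export
generate_mri_rois <- function(muscles = crus_muscles()$muscle,
                              group = c("WT", "DYS"),
                              n_rois_per_side = 3, group_shift = 0,
                              seed = 1, noise_sd = 4, subject_sd = 0,
                              sd_air = 4.5, muscle_shifts = NULL) {
  group <- match.arg(group)
  if (!n_rois_per_side %in% c(2, 3))
    stop("n_rois_per_side must be 2 or 3")
  stopifnot(sd_air > 0, noise_sd >= 0, subject_sd >= 0)
  unknown <- setdiff(muscles, names(.mri_baseline_intensity))
  if (length(unknown))
    stop("unknown muscle code(s): ", paste(unknown, collapse = ", "))
  grid <- expand.grid(roi_index = seq_len(n_rois_per_side),
                      side = c("Right", "Left"), muscle = muscles,
                      stringsAsFactors = FALSE)[, c("muscle", "side", "roi_index")]
  with_seed(derive_seed(seed, "mri", group), {
    subject_eff <- if (subject_sd > 0) rnorm(1, 0, subject_sd) else 0
    shift <- if (group == "DYS") group_shift else 0
    extra <- if (is.null(muscle_shifts)) rep(0, nrow(grid))
             else ifelse(grid$muscle %in% names(muscle_shifts),
                         muscle_shifts[grid$muscle], 0)
    noise <- if (noise_sd > 0) rnorm(nrow(grid), 0, noise_sd) else 0
    intensity <- .mri_baseline_intensity[grid$muscle] + shift + extra +
      subject_eff + noise
    px <- round(.mri_base_pixels[grid$muscle] *
                  c(1, 0.85, 0.7)[grid$roi_index])
    data.frame(
      muscle = grid$muscle, side = grid$side, roi_index = grid$roi_index,
      mean_intensity = pmax(unname(intensity), 0),
      pixel_count = as.integer(px), sd_air = sd_air,
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
}
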