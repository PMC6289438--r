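#' Generate a clinical-score or locomotor-activity covariate series
#'
#' Emulates the two clinical covariates of the study design:
#'
#' * `clinical_score` — a total grading score summing seven clinical signs
#'   (gait/mobility abnormality, limb and temporal muscle atrophy,
#'   drooling, macroglossia, dysphagia, abnormal sitting posture), each
#'   graded 1 (none) to 5 (severe), so totals lie in \[7, 35\]. Each
#'   sign's grade is a non-decreasing step process: per month it steps up
#'   with probability `0.25 * severity`, then plateaus at 5 — scores rise
#'   and plateau with age, faster at higher severity.
#' * `locomotor_activity` — non-negative spontaneous-movement counts
#'   (summed 07:00-09:00 cage counts), Poisson around a dog-specific
#'   baseline that decays exponentially with month at rate
#'   `0.15 * severity` — activity falls with age for dystrophic-like
#'   severity.
#'
#' @param kind "clinical_score" or "locomotor_activity".
#' @param dog_ids character vector of dogs.
#' @param months integer months.
#' @param severity real in \[0, 1\]: how fast scores rise / activity falls.
#' @param seed integer seed.
#' @return data.frame (dog_id, month, value).
#' @export
generate_covariate_series <- function(kind, dog_ids, months, severity = 0.5,
                                      seed = 1) {
  if (!is.character(kind) || length(kind) != 1 ||
      !kind %in% c("clinical_score", "locomotor_activity"))
    stop(sprintf("unknown covariate kind: %s",
                 paste(as.character(kind), collapse = ", ")))
  stopifnot(severity >= 0, severity <= 1, length(months) >= 1)
  months <- sort(as.integer(months))
  rows <- lapply(dog_ids, function(dog) {
    with_seed(derive_seed(seed, "covariate", kind, dog), {
      if (kind == "clinical_score") {
        grades <- rep(1L, 7) # seven signs, each graded 1..5
        value <- vapply(seq_along(months), function(k) {
          if (k > 1)
            grades <<- pmin(5L, grades + rbinom(7, 1, 0.25 * severity))
          sum(grades)
        }, numeric(1))
      } else {
        base <- rpois(1, 3000) + 500
        lambda <- base * exp(-0.15 * severity * (months - months[1]))
        value <- rpois(length(months), lambda)
      }
      data.frame(dog_id = dog, month = months, value = value,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standardize a covariate series to mean 0, SD 1
#'
#' Centering and scaling applied across all (dog, month) cells; used
#' before covariate-coefficient fits so that beta is per SD of the
#' covariate.
#'
#' @param covariate data.frame (dog_id, month, value).
#' @return the data.frame with `value` standardized (column `x` added for
#'   direct use as a covariate table).
#' @export
standardize_covariate <- function(covariate) {
  s <- sd(covariate$value)
  if (!is.finite(s) || s == 0) stop("covariate has zero variance")
  covariate$x <- (covariate$value - mean(covariate$value)) / s
  covariate
}
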