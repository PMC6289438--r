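#' The study cohort
#'
#' The eleven littermate-ordered subjects of the study design: five
#' dystrophic and six wild-type dogs followed from 2 to 12 months of age.
#'
#' @return data.frame (dog_id, phenotype, sex).
#' @export
study_dogs <- function() {
  data.frame(
    dog_id = c("13103FN", "13102MA", "13301MN", "13303MA", "13401MA",
               "13402FN", "13802MA", "13804MN", "13805MN", "14102MA",
               "14103MN"),
    phenotype = c("WT", "DYS", "WT", "DYS", "DYS", "WT", "DYS", "WT",
                  "WT", "DYS", "WT"),
    sex = c("F", "M", "M", "M", "M", "F", "M", "M", "M", "M", "M"),
    stringsAsFactors = FALSE
  )
}

#' Missing dog-months of the study design
#'
#' The packaged incompleteness pattern: thoracic-region gait recordings,
#' clinical scores and locomotor-activity counts absent for specific
#' dog-months, as encountered in the original cohort.
#'
#' @param dataset optional filter: "thoracic_gait", "clinical_score" or
#'   "locomotor_activity".
#' @return data.frame (dataset, dog_id, month).
#' @export
study_missing_data <- function(dataset = NULL) {
  path <- system.file("extdata", "missing_dog_months.csv",
                      package = "dogait", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(dataset)) df <- df[df$dataset %in% dataset, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build a study configuration
#'
#' Declarative description of a full synthetic study: cohort, month
#' window, regions, trial-generation settings, trend outcomes with their
#' transforms, covariate-coefficient fits (panels simulated from the
#' local-level model with a planted beta), MRI settings, and MCMC
#' control. Defaults encode the study design: 11 dogs (5 dystrophic, 6
#' wild-type), months 2-12, thoracic and lumbar sensors, 15-m runs x 4
#' passes at 20 ms sampling with a 10-s standing window, and the packaged
#' missing-data pattern.
#'
#' @param seed integer base seed; every stage derives its own stream.
#' @param dogs cohort data.frame (dog_id, phenotype, sex).
#' @param months contiguous integer month window.
#' @param regions sensor regions.
#' @param passes 15-m passes per session.
#' @param trial list: duration_s, sampling_interval_ms, standing_s,
#'   base_amplitudes (WT peak per-axis G), dog_gain_sd (SD of the
#'   log-normal per-dog amplitude gain).
#' @param outcomes named list mapping trend outcomes (columns of the
#'   trial summaries) to their transform.
#' @param covariate_fits list of covariate-coefficient fits, each a list
#'   (kind, beta, severity); panels are simulated per region from the
#'   local-level model with `cov_sim` parameters and the planted beta on
#'   the standardized covariate.
#' @param cov_sim list: m1 (starting level, log scale), sigma0_sq,
#'   sigma1_sq of the simulated covariate panels.
#' @param mri list: group_shift (dystrophic T2 intensity shift),
#'   noise_sd, subject_sd, sd_air, n_rois_per_side,
#'   correlation_strength (intensity units per SD of month-12 lumbar
#'   AM), muscle_signs (named +1/-1/0 per muscle).
#' @param mcmc an [mcmc_control] (its seed is overridden per fit from
#'   the study seed).
#' @param write_trials write every generated trial as CSV + sidecar.
#' @return list of class `study_config`.
#' @export
study_config <- function(seed = 1,
                         dogs = study_dogs(),
                         months = 2:12,
                         regions = c("thoracic", "lumbar"),
                         passes = 4,
                         trial = list(),
                         outcomes = list(AM = "log", Az_ratio = "logit100"),
                         covariate_fits = list(
                           list(kind = "clinical_score", beta = -0.5,
                                severity = 0.8),
                           list(kind = "locomotor_activity", beta = 0.5,
                                severity = 0.8)
                         ),
                         cov_sim = list(m1 = 0.4, sigma0_sq = 0.04,
                                        sigma1_sq = 0.01),
                         mri = list(),
                         mcmc = mcmc_control(),
                         write_trials = TRUE) {
  trial_defaults <- list(duration_s = 14, sampling_interval_ms = 20,
                         standing_s = 10, base_amplitudes = c(1.6, 1.0, 2.2),
                         dog_gain_sd = 0.12)
  mri_defaults <- list(group_shift = 25, noise_sd = 4, subject_sd = 2,
                       sd_air = 4.5, n_rois_per_side = 3,
                       correlation_strength = 10,
                       muscle_signs = c(TC = -1, EDL = -1, FDL = 0, FHL = 0,
                                        GM = -1, GL = 1, FDS = 1))
  trial <- utils::modifyList(trial_defaults, trial)
  mri <- utils::modifyList(mri_defaults, as.list(mri))
  cfg <- structure(list(
    seed = as.integer(seed), dogs = dogs, months = as.integer(months),
    regions = regions, passes = as.integer(passes), trial = trial,
    outcomes = outcomes, covariate_fits = covariate_fits,
    cov_sim = cov_sim, mri = mri, mcmc = mcmc,
    missing = study_missing_data(), write_trials = isTRUE(write_trials)
  ), class = "study_config")
  validate_study_config(cfg)
  cfg
}

#' Packaged strong-effect configuration
#'
#' The default cohort and design with deliberately large planted effects:
#' beta = -0.8 of the standardized clinical score on log AM, a 40-unit
#' dystrophic T2 intensity shift, and strong planted gait-MRI
#' correlations. Used for end-to-end recovery checks: the dystrophic AM
#' trend should sit below the wild-type trend in both regions, the
#' clinical-score coefficient should exclude zero, and planted
#' fast-muscle correlations should be recovered with negative sign.
#'
#' @param seed integer base seed.
#' @param ... overrides passed on to [study_config].
#' @return a `study_config`.
#' @export
strong_effect_config <- function(seed = 1, ...) {
  study_config(
    seed = seed,
    covariate_fits = list(
      list(kind = "clinical_score", beta = -0.8, severity = 0.9),
      list(kind = "locomotor_activity", beta = 0.5, severity = 0.9)
    ),
    mri = list(group_shift = 40, correlation_strength = 18),
    ...
  )
}

validate_study_config <- function(cfg) {
  if (anyDuplicated(cfg$dogs$dog_id)) stop("dog ids must be unique")
  if (!all(cfg$dogs$phenotype %in% c("WT", "DYS")))
    stop("phenotype must be WT or DYS")
  if (any(diff(cfg$months) != 1)) stop("months must be contiguous")
  if (!all(cfg$regions %in% c("thoracic", "lumbar")))
    stop("regions must be thoracic and/or lumbar")
  if (cfg$passes < 1) stop("passes must be at least 1")
  for (o in names(cfg$outcomes))
    if (!cfg$outcomes[[o]] %in% c("log", "logit100"))
      stop("outcome transforms must be log or logit100")
  for (cf in cfg$covariate_fits)
    if (!all(c("kind", "beta", "severity") %in% names(cf)))
      stop("each covariate fit needs kind, beta and severity")
  invisible(cfg)
}

#' Write / read a study configuration as YAML
#'
#' The declarative parts of a [study_config] round-trip through YAML so
#' a study is fully described by one text file plus the package version.
#'
#' @param config a `study_config`.
#' @param path YAML file path.
#' @return `write_study_config` returns `path` invisibly;
#'   `read_study_config` returns a `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  out <- unclass(config)
  out$dogs <- as.list(config$dogs)
  out$missing <- NULL # packaged fixture, not user state
  out$mcmc <- unclass(config$mcmc)
  out$mri$muscle_signs <- as.list(config$mri$muscle_signs)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$dogs <- as.data.frame(raw$dogs, stringsAsFactors = FALSE)
  raw$mcmc <- do.call(mcmc_control, raw$mcmc)
  raw$trial$base_amplitudes <- as.numeric(raw$trial$base_amplitudes)
  raw$mri$muscle_signs <- unlist(raw$mri$muscle_signs)
  do.call(study_config, raw[setdiff(names(raw), "write_trials")] |>
            c(list(write_trials = isTRUE(raw$write_trials))))
}

stage_run <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full synthetic study end to end
#'
#' Orchestrates simulate -> process -> trend fits -> covariate fits ->
#' MRI/correlation on a single configuration and seed:
#'
#' 1. generates every 15-m trial (per dog, region, month and pass, with a
#'    per-dog amplitude gain and the configured missing dog-months),
#'    removes the gravity offset, segments the run and summarizes it;
#' 2. fits the local-level trend per outcome, region and phenotype group
#'    and compares wild-type vs dystrophic trends month by month;
#' 3. fits the covariate-coefficient models on panels simulated from the
#'    local-level model with the planted beta (dystrophic dogs only) and
#'    assembles the coefficient forest table;
#' 4. generates per-dog MRI ROI tables (dystrophic intensity shift plus
#'    per-muscle shifts planted against each dog's month-12 lumbar AM),
#'    computes Ave SNRs, compares groups per muscle by exact Mann-Whitney
#'    U, and correlates AMs with Ave SNRs across dystrophic dogs.
#'
#' All outputs are plain CSV/JSON under `out_dir`; reruns with the same
#' configuration and seed are byte-identical. Stages that cannot run
#' (e.g. no dystrophic dogs) are skipped with the reason recorded in the
#' run manifest.
#'
#' @param config a [study_config].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (summaries,
#'   fits, trend comparisons, coefficient forest, SNR, Mann-Whitney and
#'   correlation tables, manifest).
#' @export
run_study <- function(config, out_dir) {
  stopifnot(inherits(config, "study_config"))
  validate_study_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  dogs <- config$dogs
  months <- config$months
  skipped <- list()
  miss_gait <- study_missing_data("thoracic_gait")

  ## 1. simulate + process trials -------------------------------------
  res1 <- stage_run("simulate/process", {
    if (config$write_trials)
      dir.create(file.path(out_dir, "trials"), showWarnings = FALSE)
    rows <- list(); n_dropped <- 0L; n_sat <- 0L; n_trials <- 0L
    for (d in seq_len(nrow(dogs))) {
      dog <- dogs$dog_id[d]; phen <- dogs$phenotype[d]
      gain <- with_seed(derive_seed(seed, "gain", dog),
                        exp(rnorm(1, 0, config$trial$dog_gain_sd)))
      for (reg in config$regions) {
        for (mo in months) {
          if (reg == "thoracic" &&
              any(miss_gait$dog_id == dog & miss_gait$month == mo)) next
          for (p in seq_len(config$passes)) {
            prof <- default_gait_profile(
              phen, mo, reg,
              base_amplitudes = config$trial$base_amplitudes, gain = gain)
            tr <- generate_gait_trial(
              prof, duration_s = config$trial$duration_s,
              sampling_interval_ms = config$trial$sampling_interval_ms,
              standing_s = config$trial$standing_s,
              seed = derive_seed(seed, "trial", dog, reg, mo, p),
              dog_id = dog, region = reg, month = mo)
            tr <- segment_run(remove_gravity_offset(tr))
            sm <- summarize_trial(tr)
            sm$pass <- p
            n_dropped <- n_dropped + attr(sm, "n_dropped")
            n_sat <- n_sat + attr(sm, "n_saturated")
            n_trials <- n_trials + 1L
            rows[[length(rows) + 1]] <- sm
            if (config$write_trials)
              write_trial_csv(tr, file.path(out_dir, "trials",
                sprintf("%s_%s_m%02d_p%d.csv", dog, reg, mo, p)))
          }
        }
      }
    }
    passes <- do.call(rbind, rows)
    session <- session_summary(passes[setdiff(names(passes), "pass")])
    write.csv(passes, file.path(out_dir, "summaries_passes.csv"),
              row.names = FALSE)
    write.csv(session, file.path(out_dir, "summaries.csv"),
              row.names = FALSE)
    list(session = session, n_trials = n_trials, n_dropped = n_dropped,
         n_sat = n_sat)
  })
  session <- res1$session

  ## 2. trend fits per outcome, region, group -------------------------
  fits <- list(); comparisons <- list(); convergence <- list()
  trend_rows <- list()
  stage_run("fit-trend", {
    groups <- intersect(c("WT", "DYS"), unique(dogs$phenotype))
    for (outcome in names(config$outcomes)) {
      transform <- config$outcomes[[outcome]]
      for (reg in config$regions) {
        gfits <- list()
        for (grp in groups) {
          sub <- session[session$phenotype == grp & session$region == reg, ]
          pan <- gait_panel(
            data.frame(dog_id = sub$dog_id, month = sub$month,
                       value = sub[[outcome]], stringsAsFactors = FALSE),
            transform = transform, months = months)
          mc <- config$mcmc
          mc$seed <- derive_seed(seed, "fit", outcome, reg, grp)
          fit <- fit_local_level(pan, mcmc = mc)
          key <- paste(outcome, reg, grp, sep = "_")
          gfits[[grp]] <- fit
          fits[[key]] <- fit
          convergence[[key]] <- fit$converged
          trend_rows[[length(trend_rows) + 1]] <- cbind(
            outcome = outcome, region = reg, group = grp, fit$trend)
          jsonlite::write_json(
            list(outcome = outcome, region = reg, group = grp,
                 transform = transform, trend = fit$trend,
                 sigma0_sq = fit$sigma0_sq, sigma1_sq = fit$sigma1_sq,
                 diagnostics = fit$diagnostics, converged = fit$converged),
            file.path(out_dir, sprintf("fit_%s.json", key)),
            auto_unbox = TRUE, digits = NA)
        }
        if (all(c("WT", "DYS") %in% names(gfits)))
          comparisons[[paste(outcome, reg, sep = "_")]] <-
            cbind(outcome = outcome, region = reg,
                  compare_trends(gfits$WT, gfits$DYS))
      }
    }
    write.csv(do.call(rbind, trend_rows),
              file.path(out_dir, "trends.csv"), row.names = FALSE)
    if (length(comparisons))
      write.csv(do.call(rbind, comparisons),
                file.path(out_dir, "trend_comparison.csv"),
                row.names = FALSE)
  })

  ## 3. covariate-coefficient fits (dystrophic dogs) ------------------
  dys_ids <- dogs$dog_id[dogs$phenotype == "DYS"]
  forest <- NULL
  if (length(dys_ids) == 0) {
    skipped$covariate_fits <- "no dystrophic dogs in the cohort"
  } else {
    forest <- stage_run("covariate-fit", {
      rows <- list()
      for (cf in config$covariate_fits) {
        miss_cov <- study_missing_data(cf$kind)
        for (reg in config$regions) {
          cov <- generate_covariate_series(
            cf$kind, dys_ids, months, severity = cf$severity,
            seed = derive_seed(seed, "covseries", cf$kind, reg))
          cov <- cov[!paste(cov$dog_id, cov$month) %in%
                       paste(miss_cov$dog_id, miss_cov$month), ]
          cov <- standardize_covariate(cov)
          m_true <- simulate_latent_trend(
            months, m1 = config$cov_sim$m1,
            sigma1_sq = config$cov_sim$sigma1_sq,
            seed = derive_seed(seed, "covtrend", cf$kind, reg))
          params <- true_panel_params(
            m_true, sigma0_sq = config$cov_sim$sigma0_sq,
            sigma1_sq = config$cov_sim$sigma1_sq, beta = cf$beta,
            transform = "log")
          drop <- if (reg == "thoracic")
            rbind(miss_gait[c("dog_id", "month")],
                  miss_cov[c("dog_id", "month")])
          else miss_cov[c("dog_id", "month")]
          pan <- generate_panel(
            params, dys_ids, months,
            covariate_table = cov[c("dog_id", "month", "x")],
            missing = drop,
            seed = derive_seed(seed, "covpanel", cf$kind, reg))
          mc <- config$mcmc
          mc$seed <- derive_seed(seed, "covfit", cf$kind, reg)
          fit <- fit_local_level(pan, mcmc = mc)
          rep <- coefficient_report(fit)
          key <- paste("AM", reg, cf$kind, sep = "_")
          convergence[[paste0("cov_", key)]] <- fit$converged
          rows[[length(rows) + 1]] <- data.frame(
            outcome = "AM", region = reg, covariate = cf$kind,
            estimate = rep$estimate, lower = rep$lower, upper = rep$upper,
            excludes_zero = rep$excludes_zero, true_beta = cf$beta,
            stringsAsFactors = FALSE)
        }
      }
      out <- do.call(rbind, rows)
      write.csv(out, file.path(out_dir, "coefficient_forest.csv"),
                row.names = FALSE)
      out
    })
  }

  ## 4. MRI: SNR, group comparison, gait correlation ------------------
  mri_res <- stage_run("mri", {
    last <- max(months)
    am12 <- session[session$month == last, c("dog_id", "region", "AM")]
    lum <- am12[am12$region == "lumbar", ]
    snr_rows <- list()
    for (d in seq_len(nrow(dogs))) {
      dog <- dogs$dog_id[d]; phen <- dogs$phenotype[d]
      shifts <- NULL
      if (phen == "DYS" && nrow(lum[lum$dog_id %in% dys_ids, ]) >= 2) {
        dys_am <- lum$AM[lum$dog_id %in% dys_ids]
        zam <- (lum$AM[lum$dog_id == dog] - mean(dys_am)) / sd(dys_am)
        if (length(zam) == 1 && is.finite(zam))
          shifts <- config$mri$muscle_signs *
            config$mri$correlation_strength * zam
      }
      rois <- generate_mri_rois(
        group = if (phen == "DYS") "DYS" else "WT",
        n_rois_per_side = config$mri$n_rois_per_side,
        group_shift = config$mri$group_shift,
        seed = derive_seed(seed, "mri", dog),
        noise_sd = config$mri$noise_sd, subject_sd = config$mri$subject_sd,
        sd_air = config$mri$sd_air, muscle_shifts = shifts)
      for (mus in unique(rois$muscle)) {
        a <- average_snr(rois[rois$muscle == mus, ])
        a$dog_id <- dog; a$phenotype <- phen
        snr_rows[[length(snr_rows) + 1]] <- a
      }
    }
    snr <- do.call(rbind, snr_rows)
    snr <- snr[c("dog_id", "phenotype", "muscle", "ave_snr",
                 "total_pixels", "n_rois")]
    write.csv(snr, file.path(out_dir, "snr.csv"), row.names = FALSE)

    mw <- NULL; corr <- NULL
    if (length(dys_ids) == 0 || length(dys_ids) == nrow(dogs)) {
      skipped$mri_comparison <- "group comparison needs both phenotypes"
    } else {
      mw <- do.call(rbind, lapply(unique(snr$muscle), function(mus) {
        a <- snr$ave_snr[snr$muscle == mus & snr$phenotype == "DYS"]
        b <- snr$ave_snr[snr$muscle == mus & snr$phenotype == "WT"]
        t <- mann_whitney_u(a, b)
        data.frame(muscle = mus, median_dys = median(a), median_wt = median(b),
                   U = t$statistic, p_value = t$p_value, method = t$method,
                   significant = t$p_value < 0.05, stringsAsFactors = FALSE)
      }))
      write.csv(mw, file.path(out_dir, "mann_whitney.csv"),
                row.names = FALSE)
    }
    if (length(dys_ids) < 3) {
      skipped$mri_correlation <-
        "fewer than 3 dystrophic dogs with complete data"
    } else {
      corr <- am_snr_correlation_table(
        am12[am12$dog_id %in% dys_ids, ],
        snr[snr$phenotype == "DYS", c("dog_id", "muscle", "ave_snr")])
      write.csv(corr, file.path(out_dir, "correlations.csv"),
                row.names = FALSE)
    }
    list(snr = snr, mann_whitney = mw, correlations = corr)
  })

  ## 5. manifest -------------------------------------------------------
  manifest <- list(
    package = "dogait",
    version = as.character(packageVersion("dogait")),
    seed = seed,
    n_dogs = nrow(dogs), months = range(months),
    n_trials = res1$n_trials,
    n_ratio_samples_dropped = res1$n_dropped,
    n_saturated_samples = res1$n_sat,
    convergence = convergence,
    skipped = if (length(skipped)) skipped else NULL
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    summaries = session, fits = fits, trend_comparisons = comparisons,
    forest = forest, snr = mri_res$snr, mann_whitney = mri_res$mann_whitney,
    correlations = mri_res$correlations, manifest = manifest,
    out_dir = out_dir
  ))
}
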