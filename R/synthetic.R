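# Synthetic cohorts with the statistical structure of an intensive
# reach-training study: per-subject parameters drawn around configured
# population medians, a 600-trial session per subject (120 trials to each
# of 5 targets in pseudo-random order), additive Gaussian trial noise, and
# pre-training / 1-month test-phase summaries whose long-term change is
# driven by the learning component.

# Half the central 50% mass of a standard normal; converts an IQR to an SD
# (normal) or a log-IQR to a log-scale SD (log-normal).
IQR_TO_SD <- 1 / (2 * qnorm(0.75))

#' Configuration of a synthetic training cohort
#'
#' Population medians anchor each parameter's distribution: `A` and `tau`
#' are log-normal (strictly positive, right-skewed, median
#' `exp(meanlog)`), `C` and the per-target asymptotes `D_1..D_5` are
#' normal. Dispersions are given as log-scale SDs for `A`/`tau` and plain
#' SDs for `C`/`D`; [iqr_dispersion()] converts a reported interquartile
#' range into either form.
#'
#' @param group Cohort label, `"stroke"` or `"control"`.
#' @param n_subjects Number of subjects.
#' @param median_A,median_tau,median_C Population medians: exponential
#'   amplitude (ms), decay rate (trials), fatigue slope (ms/trial).
#' @param median_D Numeric length `n_targets`: per-target asymptote
#'   medians (ms), typically monotone increasing with target number.
#' @param sdlog_A,sdlog_tau Log-scale SDs of the log-normal `A` and `tau`
#'   distributions (>= 0).
#' @param sd_C SD of the normal `C` distribution (ms/trial, >= 0).
#' @param sd_D SD(s) of the normal `D_k` distributions (ms); scalar or
#'   length `n_targets`.
#' @param residual_sd Trial-noise SD in ms (> 0 unless exactly 0 for
#'   noise-free checks).
#' @param retention_fraction Fraction of the learned amplitude retained at
#'   the 1-month test, in `[0, 1]`. Synthetic-only construct: the paperless
#'   generative link between training and retention.
#' @param retention_noise_sd SD (ms) of the noise on each test-phase mean
#'   MT (the standard error of a short test block's mean).
#' @param n_targets Number of training targets.
#' @param trials_per_target Trials per target per session.
#' @param no_repeat If `TRUE` (default), the pseudo-random target sequence
#'   never shows the same target twice in a row.
#' @return A `cohort_config` list.
#' @seealso [stroke_cohort_config()], [control_cohort_config()],
#'   [simulate_cohort()]
#' @export
cohort_config <- function(group = c("stroke", "control"),
                          n_subjects,
                          median_A, median_tau, median_C, median_D,
                          sdlog_A = 0, sdlog_tau = 0, sd_C = 0, sd_D = 0,
                          residual_sd = 0,
                          retention_fraction = 0.8,
                          retention_noise_sd = 0,
                          n_targets = 5L,
                          trials_per_target = 120L,
                          no_repeat = TRUE) {
  group <- match.arg(group)
  n_targets <- as.integer(n_targets)
  trials_per_target <- as.integer(trials_per_target)
  stopifnot(n_subjects >= 1, n_targets >= 2, trials_per_target >= 1)
  if (median_A <= 0 || median_tau <= 0) {
    stop("log-normal parameters `A` and `tau` need strictly positive medians",
         call. = FALSE)
  }
  if (length(median_D) != n_targets || any(median_D <= 0)) {
    stop("`median_D` must hold ", n_targets, " strictly positive medians",
         call. = FALSE)
  }
  sd_D <- rep_len(as.numeric(sd_D), n_targets)
  disp <- c(sdlog_A, sdlog_tau, sd_C, sd_D)
  if (any(disp < 0)) stop("dispersions must be >= 0", call. = FALSE)
  if (residual_sd < 0 || retention_noise_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (retention_fraction < 0 || retention_fraction > 1) {
    stop("`retention_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    group = group, n_subjects = as.integer(n_subjects),
    median_A = median_A, median_tau = median_tau, median_C = median_C,
    median_D = as.numeric(median_D),
    sdlog_A = sdlog_A, sdlog_tau = sdlog_tau, sd_C = sd_C, sd_D = sd_D,
    residual_sd = residual_sd,
    retention_fraction = retention_fraction,
    retention_noise_sd = retention_noise_sd,
    n_targets = n_targets, trials_per_target = trials_per_target,
    no_repeat = no_repeat
  ), class = "cohort_config")
}

#' Convert a reported interquartile range into a dispersion parameter
#'
#' For a normal distribution, `SD = (q75 - q25) / (2 * qnorm(0.75))`; for a
#' log-normal, the same identity holds on the log scale. Used to calibrate
#' the generator's dispersions to reported 25-75% IQRs.
#'
#' @param q25,q75 Lower and upper quartiles.
#' @param log Calibrate on the log scale (for log-normal parameters)?
#' @return The (log-scale) SD.
#' @export
iqr_dispersion <- function(q25, q75, log = FALSE) {
  stopifnot(q75 >= q25)
  if (log) {
    stopifnot(q25 > 0)
    (base::log(q75) - base::log(q25)) * IQR_TO_SD
  } else {
    (q75 - q25) * IQR_TO_SD
  }
}

# Interpolate medians/SDs for interior targets between the reported
# first- and last-target values (asymptotes increase monotonically with
# target number; only the endpoints are reported).
interp_targets <- function(first, last, n = 5L) {
  seq(first, last, length.out = n)
}

#' Default cohort configurations at the reported group operating points
#'
#' `stroke_cohort_config()` and `control_cohort_config()` return
#' [cohort_config()]s whose medians are the reported group medians
#' (stroke: A = 279 ms, tau = 64 trials, C = 1.11 ms/trial, D rising 328
#' to 432 ms; control: A = 128 ms, tau = 36 trials, C = 0.12 ms/trial, D
#' rising 227 to 293 ms), with dispersions calibrated to the reported
#' 25-75% IQRs and residual noise SDs of 76 ms (stroke) and 24 ms
#' (control). Asymptote medians/SDs for targets 2-4, which are not
#' reported, are linearly interpolated between targets 1 and 5.
#'
#' @param n_subjects Cohort size (16 stroke / 10 control by default).
#' @param ... Overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
stroke_cohort_config <- function(n_subjects = 16, ...) {
  defaults <- list(
    group = "stroke", n_subjects = n_subjects,
    median_A = 279, median_tau = 64, median_C = 1.11,
    median_D = interp_targets(328, 432),
    sdlog_A = iqr_dispersion(210, 455, log = TRUE),
    sdlog_tau = iqr_dispersion(44, 145, log = TRUE),
    sd_C = iqr_dispersion(0.57, 1.59),
    sd_D = interp_targets(iqr_dispersion(305, 366), iqr_dispersion(392, 445)),
    residual_sd = 76, retention_fraction = 0.8, retention_noise_sd = 15
  )
  do.call(cohort_config, modifyList(defaults, list(...)))
}

#' @rdname stroke_cohort_config
#' @export
control_cohort_config <- function(n_subjects = 10, ...) {
  defaults <- list(
    group = "control", n_subjects = n_subjects,
    median_A = 128, median_tau = 36, median_C = 0.12,
    median_D = interp_targets(227, 293),
    sdlog_A = iqr_dispersion(100, 151, log = TRUE),
    sdlog_tau = iqr_dispersion(24, 58, log = TRUE),
    sd_C = iqr_dispersion(0.07, 0.16),
    sd_D = interp_targets(iqr_dispersion(212, 269), iqr_dispersion(266, 327)),
    residual_sd = 24, retention_fraction = 0.8, retention_noise_sd = 5
  )
  do.call(cohort_config, modifyList(defaults, list(...)))
}

#' Draw per-subject model parameters from a cohort configuration
#'
#' `A_i`, `tau_i` are log-normal with median equal to the configured
#' median; `C_i` and `D_ik` are normal, centred on the configured medians.
#' When the configured `D` medians are monotone, each subject's drawn
#' asymptotes are returned sorted into that order (per-subject
#' monotonicity across targets mirrors the workspace geometry).
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed.
#' @param subject_offset Integer added to subject numbers when labelling
#'   (so stroke and control cohorts get disjoint ids).
#' @return Data frame: `subject`, `group`, `A`, `tau`, `C`, `D1`..`D5`.
#' @export
draw_subject_params <- function(config, seed = NULL, subject_offset = 0L) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    n <- config$n_subjects
    A <- exp(rnorm(n, log(config$median_A), config$sdlog_A))
    tau <- exp(rnorm(n, log(config$median_tau), config$sdlog_tau))
    C <- rnorm(n, config$median_C, config$sd_C)
    D <- sapply(seq_len(config$n_targets), function(k) {
      rnorm(n, config$median_D[k], config$sd_D[k])
    })
    D <- matrix(D, nrow = n)
    dm <- diff(config$median_D)
    if (all(dm >= 0)) {
      D <- t(apply(D, 1L, sort))
    } else if (all(dm <= 0)) {
      D <- t(apply(D, 1L, sort, decreasing = TRUE))
    }
    colnames(D) <- paste0("D", seq_len(config$n_targets))
    out <- data.frame(
      subject = sprintf("%s%02d", if (config$group == "stroke") "S" else "C",
                        seq_len(n) + subject_offset),
      group = config$group, A = A, tau = tau, C = C
    )
    cbind(out, as.data.frame(D))
  })
}

# One pseudo-random target sequence with exact per-target counts and,
# optionally, no immediate repeats. Sequential draws weighted by remaining
# counts; the rare dead end (only the previous target left) restarts.
target_sequence <- function(n_targets, trials_per_target, no_repeat = TRUE) {
  if (!no_repeat) {
    return(sample(rep(seq_len(n_targets), trials_per_target)))
  }
  for (attempt in 1:100) {
    remaining <- rep(trials_per_target, n_targets)
    seq_out <- integer(n_targets * trials_per_target)
    prev <- 0L
    ok <- TRUE
    for (i in seq_along(seq_out)) {
      allowed <- which(remaining > 0L)
      allowed <- allowed[allowed != prev]
      if (length(allowed) == 0L) { ok <- FALSE; break }
      nxt <- if (length(allowed) == 1L) allowed else {
        sample(allowed, 1L, prob = remaining[allowed])
      }
      seq_out[i] <- nxt
      remaining[nxt] <- remaining[nxt] - 1L
      prev <- nxt
    }
    if (ok) return(seq_out)
  }
  stop("could not build a no-repeat target sequence", call. = FALSE)
}

#' Generate a trial-level training session for every subject
#'
#' Each subject performs `n_targets * trials_per_target` movements in
#' pseudo-random target order with exact per-target counts. Observed MT is
#' the structural prediction plus Gaussian noise with the configured
#' residual SD, floored at 50 ms.
#'
#' @param params Subject parameter table from [draw_subject_params()].
#' @param config The generating [cohort_config()].
#' @param seed Optional integer seed.
#' @return Data frame of trial records: `subject`, `group`, `side`,
#'   `trial` (global index), `t` (per-target occurrence index, 1-based),
#'   `target`, `mt_ms`.
#' @export
generate_training_trials <- function(params, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    per_subject <- lapply(seq_len(nrow(params)), function(i) {
      p <- as_subject_params(params[i, c("A", "tau", "C",
                                         paste0("D", seq_len(config$n_targets)))])
      targets <- target_sequence(config$n_targets, config$trials_per_target,
                                 config$no_repeat)
      t_idx <- stats::ave(seq_along(targets), targets, FUN = seq_along)
      mu <- predict_mt(p, t_idx, targets)
      mt <- mu + rnorm(length(mu), 0, config$residual_sd)
      data.frame(
        subject = params$subject[i], group = params$group[i], side = "right",
        trial = seq_along(targets), t = t_idx, target = targets,
        mt_ms = pmax(mt, 50)
      )
    })
    do.call(rbind, per_subject)
  })
}

#' Generate pre-training and 1-month test-phase mean MTs
#'
#' A rested-state construct: test phases carry no fatigue term. The
#' pre-training mean is `mean_k(A_i + D_ik)` (nothing learned yet), the
#' 1-month mean is `mean_k(D_ik) + (1 - retention_fraction) * A_i`
#' (a `retention_fraction` of the learnable amplitude consolidated), each
#' plus Gaussian noise with `retention_noise_sd`. Long-term performance
#' change is `(pre1 - m1) / pre1`, so by construction it is driven by the
#' learning component.
#'
#' @inheritParams generate_training_trials
#' @return Data frame: `subject`, `group`, `mt_pre1`, `mt_1month`,
#'   `long_term_change`.
#' @export
generate_test_phases <- function(params, config, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(seed, {
    Dbar <- rowMeans(params[, paste0("D", seq_len(config$n_targets)),
                            drop = FALSE])
    n <- nrow(params)
    pre1 <- params$A + Dbar + rnorm(n, 0, config$retention_noise_sd)
    m1 <- Dbar + (1 - config$retention_fraction) * params$A +
      rnorm(n, 0, config$retention_noise_sd)
    data.frame(
      subject = params$subject, group = params$group,
      mt_pre1 = pre1, mt_1month = m1,
      long_term_change = (pre1 - m1) / pre1
    )
  })
}

#' Simulate a complete synthetic cohort
#'
#' Draws subject parameters, a trial-level training session and test-phase
#' summaries in one reproducible stream, keeping the generating parameters
#' for recovery checks.
#'
#' @param config A [cohort_config()] (or list of configs for a multi-group
#'   study; subject ids are kept disjoint).
#' @param seed Optional integer seed governing all draws.
#' @return A `synthetic_cohort` list: `params` (generating subject
#'   parameters), `trials`, `test_phases`, `config`, `seed`.
#' @examples
#' ch <- simulate_cohort(stroke_cohort_config(n_subjects = 4), seed = 1)
#' table(ch$trials$target) / 4
#' @export
simulate_cohort <- function(config, seed = NULL) {
  configs <- if (inherits(config, "cohort_config")) list(config) else config
  stopifnot(all(vapply(configs, inherits, TRUE, "cohort_config")))
  with_seed(seed, {
    offset <- 0L
    parts <- lapply(configs, function(cf) {
      params <- draw_subject_params(cf, subject_offset = offset)
      offset <<- offset + cf$n_subjects
      list(params = params,
           trials = generate_training_trials(params, cf),
           tests = generate_test_phases(params, cf))
    })
    structure(list(
      params = do.call(rbind, lapply(parts, `[[`, "params")),
      trials = do.call(rbind, lapply(parts, `[[`, "trials")),
      test_phases = do.call(rbind, lapply(parts, `[[`, "tests")),
      config = if (length(configs) == 1L) configs[[1L]] else configs,
      seed = seed
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic reach-training cohort\n")
  tab <- table(x$params$group)
  cat("  subjects:", paste(sprintf("%s (%d)", names(tab), tab),
                           collapse = ", "), "\n")
  cat("  trials:  ", nrow(x$trials), "rows\n")
  cat("  seed:    ", if (is.null(x$seed)) "<current stream>" else x$seed, "\n")
  invisible(x)
}

# ---- minimum-jerk trajectory fixture ---------------------------------------

# 5%-of-peak-speed crossings of the normalised minimum-jerk speed profile
# 30 s^2 (1-s)^2: closed form via s(1-s) = sqrt(threshold/30).
min_jerk_threshold_span <- function(frac = 0.05) {
  r <- sqrt(frac * 1.875 / 30)
  s1 <- (1 - sqrt(1 - 4 * r)) / 2
  c(onset = s1, offset = 1 - s1)
}

#' Generate a planar minimum-jerk reach trajectory
#'
#' A straight minimum-jerk reach from the home position `(0, 0)` to a
#' target `distance` cm away, with stationary padding on both sides and
#' optional isotropic sensor noise. The returned ground truth gives the
#' exact 5%-of-peak-speed crossing times of the underlying continuous
#' profile (span fraction 0.8811 of the movement duration), against which
#' sample-based movement-time extraction can be judged.
#'
#' @param duration_ms Duration of the minimum-jerk movement (ms).
#' @param distance Reach extent (cm), > 0.
#' @param sample_rate Sampling rate (Hz); must resolve the movement with
#'   at least 20 samples.
#' @param direction_deg Reach direction, degrees anticlockwise from +x.
#' @param pad_s Stationary padding before and after the movement (s).
#' @param noise_sd Isotropic positional noise SD (cm).
#' @param seed Optional integer seed for the noise draw.
#' @return List with `trajectory` (data frame `t_s`, `x_cm`, `y_cm`),
#'   `sample_rate`, and `truth` (`onset_s`, `offset_s`, `span_ms`,
#'   `peak_speed` of the noise-free continuous profile, plus the target
#'   endpoint).
#' @export
generate_trajectory <- function(duration_ms, distance, sample_rate = 120,
                                direction_deg = 0, pad_s = 0.25,
                                noise_sd = 0, seed = NULL) {
  if (duration_ms <= 0) stop("`duration_ms` must be > 0", call. = FALSE)
  if (distance <= 0) stop("`distance` must be > 0 (degenerate reach)",
                          call. = FALSE)
  T_s <- duration_ms / 1000
  if (sample_rate * T_s < 20) {
    stop("`sample_rate` too low: fewer than 20 samples within the movement",
         call. = FALSE)
  }
  dt <- 1 / sample_rate
  t <- seq(0, 2 * pad_s + T_s, by = dt)
  s <- pmin(pmax((t - pad_s) / T_s, 0), 1)
  pos <- distance * (10 * s^3 - 15 * s^4 + 6 * s^5)
  th <- direction_deg * pi / 180
  x <- pos * cos(th)
  y <- pos * sin(th)
  if (noise_sd > 0) {
    noise <- with_seed(seed, matrix(rnorm(2 * length(t), 0, noise_sd), ncol = 2))
    x <- x + noise[, 1]
    y <- y + noise[, 2]
  }
  span <- min_jerk_threshold_span(0.05)
  list(
    trajectory = data.frame(t_s = t, x_cm = x, y_cm = y),
    sample_rate = sample_rate,
    truth = list(
      onset_s = pad_s + span[["onset"]] * T_s,
      offset_s = pad_s + span[["offset"]] * T_s,
      span_ms = unname(diff(span)) * duration_ms,
      peak_speed = 1.875 * distance / T_s,
      target_x = distance * cos(th), target_y = distance * sin(th)
    )
  )
}
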