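# Population fitting of the learning-fatigue model by stochastic
# approximation EM (SAEM). Per-subject parameters are estimated on a
# transformed scale phi = (log A, log tau, C, D_1..D_5) with a diagonal
# Gaussian random-effect distribution; the E-step is a Metropolis random
# walk per subject with full-covariance proposals shaped by the posterior
# curvature (the model has strong A/tau/C/D trade-offs for slow learners
# and proposals must follow that ridge), the M-step a
# stochastic-approximation update of the Gaussian sufficient statistics.
# Random-effect variances are capped at the spread of the individual
# least-squares estimates (an upper bound on the true dispersion, since
# that spread includes estimation noise) — without the cap, a flat
# likelihood ridge lets the variance and the subject samples inflate each
# other. Empirical-Bayes subject estimates are posterior modes under the
# fitted population distribution.

# Parameter layout on the estimation scale, honouring the ablation flags.
make_pspec <- function(n_targets = 5L, drop_fatigue = FALSE,
                       drop_intercepts = FALSE) {
  n_D <- if (drop_intercepts) 1L else as.integer(n_targets)
  cols <- c("lA", "ltau", if (!drop_fatigue) "C", paste0("D", seq_len(n_D)))
  list(n_targets = as.integer(n_targets), has_C = !drop_fatigue, n_D = n_D,
       d_off = 2L + !drop_fatigue, d = length(cols), cols = cols)
}

#' SAEM fitting configuration
#'
#' @param n_burn Exploration iterations with step size 1 (default 300).
#' @param n_iter Averaging iterations with step size `1/m^step_exponent`
#'   (default 200).
#' @param step_exponent Step-size decay exponent in `(0.5, 1]` (default
#'   0.7).
#' @param mh_steps Metropolis steps per subject per iteration (default 2).
#' @param target_acceptance Acceptance rate targeted by the adaptive
#'   proposal scaling during burn-in (default 0.3).
#' @param tau_bounds Bounds on `tau` (trials) during estimation; `NULL`
#'   defaults to `[0.5, 10 * T]` where `T` is trials per target. Prevents
#'   exponential/linear aliasing on flat learners.
#' @param error_model `"pooled"` (one residual SD, the default) or
#'   `"by_group"` (one residual SD per group level in the data).
#' @param drop_fatigue Ablation: fix `C = 0` (no fatigue term).
#' @param drop_intercepts Ablation: one shared asymptote instead of
#'   per-target intercepts.
#' @param init `"two_stage"` (per-subject least squares, the default) or a
#'   precomputed list as returned by [initialize_two_stage()].
#' @param seed Integer seed making the fit reproducible (default 1).
#' @return A `fit_config` list.
#' @export
fit_config <- function(n_burn = 300L, n_iter = 200L, step_exponent = 0.7,
                       mh_steps = 2L, target_acceptance = 0.3,
                       tau_bounds = NULL,
                       error_model = c("pooled", "by_group"),
                       drop_fatigue = FALSE,
                       drop_intercepts = FALSE, init = "two_stage",
                       seed = 1L) {
  stopifnot(n_iter >= 1, n_burn >= 1, mh_steps >= 1)
  if (step_exponent <= 0.5 || step_exponent > 1) {
    stop("`step_exponent` must lie in (0.5, 1]", call. = FALSE)
  }
  structure(list(
    n_burn = as.integer(n_burn), n_iter = as.integer(n_iter),
    step_exponent = step_exponent, mh_steps = as.integer(mh_steps),
    target_acceptance = target_acceptance, tau_bounds = tau_bounds,
    error_model = match.arg(error_model),
    drop_fatigue = drop_fatigue, drop_intercepts = drop_intercepts,
    init = init, seed = as.integer(seed)
  ), class = "fit_config")
}

#' Population parameters of the learning-fatigue model
#'
#' Container for fixed effects, diagonal random-effect variances and the
#' residual SD(s) on the estimation scale (`log A`, `log tau`, `C`,
#' `D_1..D_5`). Natural-scale population medians are `exp()` of the `lA`
#' and `ltau` fixed effects.
#'
#' @param mu Named numeric of fixed effects on the estimation scale
#'   (names as in the fitted layout, e.g. `lA`, `ltau`, `C`, `D1`..`D5`).
#' @param omega2 Named numeric of random-effect variances (same layout),
#'   all `>= 0`.
#' @param sigma Residual SD in ms, `> 0`; a named vector when the error
#'   model is per-group.
#' @param pspec Internal parameter layout; defaults to the full model.
#' @return A `population_params` list.
#' @export
population_params <- function(mu, omega2, sigma, pspec = NULL) {
  pspec <- pspec %||% make_pspec()
  mu <- unlist(mu)[pspec$cols]
  omega2 <- unlist(omega2)[pspec$cols]
  if (any(!is.finite(mu)) || any(!is.finite(omega2))) {
    stop("`mu` and `omega2` must cover the model's parameters: ",
         paste(pspec$cols, collapse = ", "), call. = FALSE)
  }
  if (any(omega2 < 0)) stop("variances must be >= 0", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("`sigma` must be > 0", call. = FALSE)
  }
  structure(list(mu = mu, omega2 = omega2, sigma = sigma, pspec = pspec),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat("Population parameters (estimation scale):\n")
  print(round(rbind(mu = x$mu, omega2 = x$omega2), 4))
  cat("natural-scale medians: A =", round(exp(x$mu[["lA"]]), 1),
      "ms, tau =", round(exp(x$mu[["ltau"]]), 1), "trials\n")
  cat("residual SD (ms):", paste(sprintf("%s%.1f",
      if (is.null(names(x$sigma))) "" else paste0(names(x$sigma), " = "),
      x$sigma), collapse = ", "), "\n")
  invisible(x)
}

# Residual SD applying to one subject under a possibly per-group error
# model.
sigma_for <- function(pop, group) {
  s <- pop$sigma
  if (length(s) == 1L || is.null(names(s))) return(s[[1L]])
  if (group %in% names(s)) s[[group]] else mean(s)
}

# ---- data plumbing ---------------------------------------------------------

validate_trials <- function(trials, pspec) {
  need <- c("subject", "t", "target", "mt_ms")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(trials$mt_ms)) || any(trials$mt_ms <= 0)) {
    bad <- which(!is.finite(trials$mt_ms) | trials$mt_ms <= 0)[1L]
    stop("non-positive or non-finite MT at row ", bad, call. = FALSE)
  }
  if (any(trials$target < 1L | trials$target > pspec$n_targets)) {
    stop("target ids must lie in 1..", pspec$n_targets, call. = FALSE)
  }
  if (any(trials$t < 1L)) stop("per-target trial index must be >= 1",
                               call. = FALSE)
  invisible(trials)
}

# Split a trial table into per-subject lists with precomputed columns.
split_trials <- function(trials, pspec) {
  ids <- unique(trials$subject)
  lapply(ids, function(id) {
    tr <- trials[trials$subject == id, ]
    kd <- if (pspec$n_D == 1L) rep(1L, nrow(tr)) else as.integer(tr$target)
    list(subject = id,
         group = if ("group" %in% names(tr)) as.character(tr$group[1L]) else "all",
         t = as.numeric(tr$t), kd = kd, y = as.numeric(tr$mt_ms),
         n = nrow(tr))
  })
}

# Structural prediction for one subject at transformed parameters phi.
phi_predict <- function(phi, dat, pspec) {
  A <- exp(phi[1L])
  tau <- exp(phi[2L])
  C <- if (pspec$has_C) phi[3L] else 0
  D <- phi[pspec$d_off + dat$kd]
  A * exp(-dat$t / tau) + C * dat$t + D
}

phi_ss <- function(phi, dat, pspec) {
  r <- dat$y - phi_predict(phi, dat, pspec)
  sum(r * r)
}

# Gradient of the residual sum of squares wrt phi.
phi_ss_grad <- function(phi, dat, pspec) {
  A <- exp(phi[1L])
  tau <- exp(phi[2L])
  C <- if (pspec$has_C) phi[3L] else 0
  e <- exp(-dat$t / tau)
  f <- A * e + C * dat$t + phi[pspec$d_off + dat$kd]
  r <- dat$y - f
  g <- numeric(pspec$d)
  g[1L] <- -2 * sum(r * A * e)
  g[2L] <- -2 * sum(r * A * e * dat$t / tau)
  if (pspec$has_C) g[3L] <- -2 * sum(r * dat$t)
  for (j in seq_len(pspec$n_D)) {
    sel <- dat$kd == j
    if (any(sel)) g[pspec$d_off + j] <- -2 * sum(r[sel])
  }
  g
}

# Posterior curvature (negative log joint Hessian) for one subject, by
# central differences of the analytic gradient.
post_hessian <- function(phi, dat, pspec, sigma2, inv_o2) {
  d <- pspec$d
  H <- matrix(0, d, d)
  for (c in seq_len(d)) {
    eps <- 1e-5 * (abs(phi[c]) + 1e-3)
    up <- phi; up[c] <- up[c] + eps
    dn <- phi; dn[c] <- dn[c] - eps
    H[, c] <- (phi_ss_grad(up, dat, pspec) -
                 phi_ss_grad(dn, dat, pspec)) / (2 * eps)
  }
  (H + t(H)) / (2 * 2 * sigma2) + diag(inv_o2, nrow = d)
}

# ---- two-stage initialization ---------------------------------------------

# Per-subject least squares by profiling: for fixed tau the model is
# linear in (A, C, D_k); tau is found by grid + golden-section search on
# the profiled RSS over log tau. A is clamped to >= 1 ms (flat learners)
# with the linear terms refitted.
subject_nls <- function(dat, pspec, tau_lo, tau_hi, A_min = 1) {
  X_lin <- cbind(if (pspec$has_C) dat$t,
                 sapply(seq_len(pspec$n_D), function(j) as.numeric(dat$kd == j)))
  rss_at <- function(ltau) {
    X <- cbind(exp(-dat$t / exp(ltau)), X_lin)
    fit <- lm.fit(X, dat$y)
    sum(fit$residuals^2)
  }
  grid <- seq(log(tau_lo), log(tau_hi), length.out = 25L)
  vals <- vapply(grid, rss_at, numeric(1L))
  b <- which.min(vals)
  lo <- grid[max(1L, b - 1L)]
  hi <- grid[min(length(grid), b + 1L)]
  ltau <- if (lo < hi) optimize(rss_at, c(lo, hi))$minimum else grid[b]
  tau <- exp(ltau)
  X <- cbind(exp(-dat$t / tau), X_lin)
  fit <- lm.fit(X, dat$y)
  cf <- fit$coefficients
  A <- cf[1L]
  if (!is.finite(A) || A < A_min) {
    # exponential amplitude at (or below) the floor: fix A and refit the rest
    A <- A_min
    fit <- lm.fit(X_lin, dat$y - A * exp(-dat$t / tau))
    cf <- c(A, fit$coefficients)
  }
  C <- if (pspec$has_C) cf[2L] else 0
  D <- cf[(1L + pspec$has_C + 1L):length(cf)]
  D[!is.finite(D)] <- mean(dat$y)
  phi <- c(log(A), log(tau), if (pspec$has_C) C, D)
  names(phi) <- pspec$cols
  list(phi = phi, rss = sum(fit$residuals^2), n = dat$n)
}

#' Two-stage initialization of the population parameters
#'
#' Stage 1 fits each subject independently by profiled least squares
#' (`tau` bounded to `[1, 10 * T]`); stage 2 takes cross-subject medians
#' on the estimation scale as fixed effects and the pooled residual SD as
#' the residual noise. Random-effect variances are initialized at the
#' robust (MAD-based) spread of the individual estimates minus the
#' typical single-subject estimation variance (from the least-squares
#' curvature) — the raw spread conflates true between-subject dispersion
#' with estimation noise, which is substantial on this model's
#' amplitude/decay/fatigue ridge. Subjects whose individual fit fails are
#' excluded with a warning.
#'
#' @param trials Trial-record data frame (`subject`, `t`, `target`,
#'   `mt_ms`, optionally `group`).
#' @param n_targets,drop_fatigue,drop_intercepts Model layout (see
#'   [fit_config()]).
#' @param tau_bounds Bounds for `tau` in the individual fits; default
#'   `c(1, 10 * max(t))`.
#' @return List with `pop` (a [population_params()]), `phi` (matrix of
#'   per-subject estimates on the estimation scale), `omega2_cap` (raw
#'   estimate spread, an upper bound for the variance update), `subjects`
#'   (ids) and `failed` (excluded subject ids).
#' @export
initialize_two_stage <- function(trials, n_targets = 5L,
                                 drop_fatigue = FALSE,
                                 drop_intercepts = FALSE,
                                 tau_bounds = NULL) {
  pspec <- make_pspec(n_targets, drop_fatigue, drop_intercepts)
  validate_trials(trials, pspec)
  dats <- split_trials(trials, pspec)
  T_max <- max(trials$t)
  tb <- tau_bounds %||% c(1, 10 * T_max)
  fits <- lapply(dats, function(dat) {
    if (dat$n < pspec$d + 1L) return(NULL)
    tryCatch(subject_nls(dat, pspec, tb[1L], tb[2L]),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1L))
  if (!any(ok)) stop("individual least-squares failed for every subject",
                     call. = FALSE)
  if (any(!ok)) {
    warning("excluded from initialization: ",
            paste(vapply(dats[!ok], `[[`, "", "subject"), collapse = ", "),
            call. = FALSE)
  }
  phi <- do.call(rbind, lapply(fits[ok], `[[`, "phi"))
  rownames(phi) <- vapply(dats[ok], `[[`, "", "subject")
  # fixed effects must lie on the data-consistent manifold: the
  # componentwise median of estimates scattered along a curved
  # amplitude/decay/fatigue ridge falls inside the ridge's chord and can
  # fit the data badly. Anchor the decay rate at the cross-subject
  # median, then solve the conditionally linear terms on the pooled data.
  ltau_med <- median(phi[, 2L])
  pooled <- list(t = unlist(lapply(dats[ok], `[[`, "t")),
                 kd = unlist(lapply(dats[ok], `[[`, "kd")),
                 y = unlist(lapply(dats[ok], `[[`, "y")))
  Xp <- cbind(exp(-pooled$t / exp(ltau_med)),
              if (pspec$has_C) pooled$t,
              sapply(seq_len(pspec$n_D),
                     function(j) as.numeric(pooled$kd == j)))
  pfit <- lm.fit(Xp, pooled$y)
  cfp <- pfit$coefficients
  A_pool <- if (is.finite(cfp[1L]) && cfp[1L] > 1) cfp[1L] else 1
  Dp <- cfp[(1L + pspec$has_C + 1L):length(cfp)]
  Dp[!is.finite(Dp)] <- mean(pooled$y)
  mu <- setNames(c(log(A_pool), ltau_med,
                   if (pspec$has_C) cfp[1L + 1L], Dp), pspec$cols)
  # residual noise from the individual fits: pooled-fit residuals would
  # absorb the between-subject dispersion
  rss <- sum(vapply(fits[ok], `[[`, numeric(1L), "rss"))
  n_obs <- sum(vapply(fits[ok], `[[`, numeric(1L), "n"))
  sigma <- sqrt(max(rss / n_obs, 1e-12))
  floor_o2 <- omega2_floor(mu)
  if (nrow(phi) > 1L) {
    # dispersion calibration from restricted per-subject fits: with the
    # decay rate fixed at its anchor the remaining terms are linear, so
    # the estimates are stable (the unrestricted fits scatter along the
    # amplitude/decay/fatigue ridge and would inflate every variance) and
    # their exact estimation covariance is available for deconvolution
    phi_r <- t(vapply(dats[ok], function(dat) {
      Xr <- cbind(exp(-dat$t / exp(ltau_med)),
                  if (pspec$has_C) dat$t,
                  sapply(seq_len(pspec$n_D),
                         function(j) as.numeric(dat$kd == j)))
      cf <- lm.fit(Xr, dat$y)$coefficients
      cf[!is.finite(cf)] <- 0
      cf[1L] <- log(max(cf[1L], 1))
      c(cf[1L], ltau_med, cf[-1L])
    }, numeric(pspec$d)))
    colnames(phi_r) <- pspec$cols
    # estimation variance of the restricted estimates (common design)
    d1 <- dats[ok][[1L]]
    Xr <- cbind(exp(-d1$t / exp(ltau_med)),
                if (pspec$has_C) d1$t,
                sapply(seq_len(pspec$n_D),
                       function(j) as.numeric(d1$kd == j)))
    ev <- sigma^2 * diag(tryCatch(solve(crossprod(Xr)),
                                  error = function(e) diag(1e6, ncol(Xr))))
    # delta method for the log-amplitude coordinate
    ev_lA <- ev[1L] / exp(2 * median(phi_r[, 1L]))
    est_var <- c(ev_lA, NA, ev[-1L])
    spread2 <- apply(phi_r, 2L, stats::mad)^2
    # no stable individual decay-rate estimate exists; start its
    # dispersion at the log-amplitude dispersion (comparable relative
    # heterogeneity) and let SAEM refine it
    spread2[2L] <- max(spread2[1L], floor_o2[2L])
    est_var[2L] <- 0
    omega2 <- pmax(spread2 - est_var, 0.05 * spread2, floor_o2)
    omega2_cap <- pmax(4 * spread2, floor_o2)
    rownames(phi_r) <- rownames(phi)
    phi <- phi_r
  } else {
    omega2 <- setNames(pmax(rep(0, pspec$d), floor_o2), pspec$cols)
    omega2_cap <- omega2
  }
  list(pop = population_params(mu, omega2, sigma, pspec), phi = phi,
       omega2_cap = omega2_cap, subjects = rownames(phi),
       failed = vapply(dats[!ok], `[[`, "", "subject"))
}

# Variance floor keeping the random-effect prior proper without ever
# binding in realistically dispersed cohorts.
omega2_floor <- function(mu) {
  pmax(1e-10, 1e-8 * (abs(mu) + 1)^2)
}

# ---- SAEM ------------------------------------------------------------------

#' Fit the learning-fatigue nonlinear mixed-effects model by SAEM
#'
#' Maximizes the marginal likelihood of the model
#' `MT = A exp(-t/tau) + C t + D_k + eps` with log-normal random effects
#' on `A`, `tau` and normal random effects on `C`, `D_k` (diagonal
#' covariance), by stochastic-approximation EM: a per-subject Metropolis
#' chain with posterior-curvature-shaped proposals samples the random
#' effects, and exponential-family sufficient statistics are smoothed
#' with step size 1 during burn-in and `1/m^0.7` afterwards. Per-subject
#' empirical-Bayes modes, group RMSEs and a Laplace approximation of the
#' marginal log-likelihood are computed from the final population
#' estimate. Identical data, config and seed give an identical result.
#'
#' @param trials Trial-record data frame (`subject`, `t`, `target`,
#'   `mt_ms`, optionally `group`).
#' @param config A [fit_config()].
#' @return A `reach_fit` list: `pop` ([population_params()]), `subjects`
#'   (natural-scale empirical-Bayes parameter table), `rmse` (per group
#'   and overall), `trace` (per-iteration fixed effects and sigma),
#'   `loglik` (Laplace marginal log-likelihood at initialization and at
#'   the final estimate), `flags`, `config`.
#' @export
fit_nlme <- function(trials, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  pspec <- make_pspec(
    n_targets = max(5L, max(trials$target)),
    drop_fatigue = config$drop_fatigue,
    drop_intercepts = config$drop_intercepts
  )
  validate_trials(trials, pspec)
  dats <- split_trials(trials, pspec)
  N <- length(dats)
  T_max <- max(trials$t)
  tb <- config$tau_bounds %||% c(0.5, 10 * T_max)
  ltau_lim <- log(tb)

  set.seed(config$seed)

  init <- if (is.list(config$init)) config$init else {
    initialize_two_stage(trials, pspec$n_targets, config$drop_fatigue,
                         config$drop_intercepts, tau_bounds = c(1, 10 * T_max))
  }
  if (length(init$failed)) {
    # carry excluded subjects at the population means so every subject is
    # still sampled and reported
    miss <- setdiff(vapply(dats, `[[`, "", "subject"), rownames(init$phi))
    add <- matrix(rep(init$pop$mu, length(miss)), ncol = pspec$d, byrow = TRUE,
                  dimnames = list(miss, pspec$cols))
    init$phi <- rbind(init$phi, add)
  }
  ord <- match(vapply(dats, `[[`, "", "subject"), rownames(init$phi))
  phi <- init$phi[ord, , drop = FALSE]
  mu <- init$pop$mu
  omega2 <- init$pop$omega2
  o2_cap <- init$omega2_cap %||% pmax(4 * omega2, omega2_floor(mu))

  # start each subject at its empirical-Bayes mode under the initial
  # population: individual least-squares solutions on the aliasing ridge
  # would otherwise enter the sufficient statistics (and the chain) from
  # degenerate positions
  phi <- do.call(rbind, lapply(seq_len(N), function(i) {
    empirical_bayes_one(dats[[i]], init$pop, start = phi[i, ],
                        ltau_lim = log(tb))$phi
  }))
  rownames(phi) <- vapply(dats, `[[`, "", "subject")

  # error-model bookkeeping: one residual variance per error group
  subj_group <- vapply(dats, `[[`, "", "group")
  err_group <- if (config$error_model == "by_group") subj_group else
    rep("all", N)
  egs <- unique(err_group)
  eg_idx <- match(err_group, egs)
  n_obs_g <- vapply(egs, function(g) {
    sum(vapply(dats[err_group == g], `[[`, numeric(1L), "n"))
  }, numeric(1L))
  sigma2 <- setNames(rep(init$pop$sigma[[1L]]^2, length(egs)), egs)

  phi[, 2L] <- pmin(pmax(phi[, 2L], ltau_lim[1L]), ltau_lim[2L])

  ss_i <- vapply(seq_len(N), function(i) phi_ss(phi[i, ], dats[[i]], pspec),
                 numeric(1L))

  prop_chol <- function() {
    lapply(seq_len(N), function(i) {
      H <- post_hessian(phi[i, ], dats[[i]], pspec,
                        max(sigma2[eg_idx[i]], 1e-6), 1 / omega2)
      ch <- tryCatch(chol(solve(H)), error = function(e) NULL)
      if (is.null(ch)) diag(1 / sqrt(pmax(diag(H), 1e-12)), pspec$d) else ch
    })
  }
  Ls <- prop_chol()
  refresh_at <- unique(pmax(1L, c(floor(config$n_burn / 3),
                                  floor(2 * config$n_burn / 3),
                                  config$n_burn)))
  lambda <- rep(2.38 / sqrt(pspec$d), N)

  n_total <- config$n_burn + config$n_iter
  s1 <- colSums(phi)
  s2 <- colSums(phi^2)
  # residual statistic starts at the initializer's noise level, not at the
  # current states' SS (individual fits off the ridge would inflate it)
  s3 <- sigma2 * n_obs_g
  trace <- matrix(NA_real_, n_total, pspec$d + length(egs),
                  dimnames = list(NULL, c(pspec$cols, paste0("sigma_", egs))))
  ofloor <- omega2_floor(mu)

  for (m in seq_len(n_total)) {
    inv_o2 <- 1 / omega2
    osd <- sqrt(omega2)
    for (i in seq_len(N)) {
      s2i <- sigma2[eg_idx[i]]
      for (s in seq_len(config$mh_steps)) {
        if (s == 1L) {
          # independence kernel: propose from the current random-effect
          # distribution; acceptance reduces to the likelihood ratio
          prop <- mu + rnorm(pspec$d) * osd
          if (prop[2L] < ltau_lim[1L] || prop[2L] > ltau_lim[2L]) next
          ss_new <- phi_ss(prop, dats[[i]], pspec)
          dlog <- (ss_i[i] - ss_new) / (2 * s2i)
          if (is.finite(dlog) && log(runif(1L)) < dlog) {
            phi[i, ] <- prop
            ss_i[i] <- ss_new
          }
          next
        }
        prop <- phi[i, ] + lambda[i] * drop(rnorm(pspec$d) %*% Ls[[i]])
        if (prop[2L] < ltau_lim[1L] || prop[2L] > ltau_lim[2L]) next
        ss_new <- phi_ss(prop, dats[[i]], pspec)
        dlog <- (ss_i[i] - ss_new) / (2 * s2i) -
          0.5 * sum(((prop - mu)^2 - (phi[i, ] - mu)^2) * inv_o2)
        if (is.finite(dlog) && log(runif(1L)) < dlog) {
          phi[i, ] <- prop
          ss_i[i] <- ss_new
          if (m <= config$n_burn) {
            lambda[i] <- lambda[i] * exp(0.4 * (1 - config$target_acceptance) /
                                           config$mh_steps)
          }
        } else if (m <= config$n_burn) {
          lambda[i] <- lambda[i] * exp(-0.4 * config$target_acceptance /
                                         config$mh_steps)
        }
      }
    }
    if (!all(is.finite(ss_i))) {
      stop("non-finite likelihood contribution for subject ",
           dats[[which(!is.finite(ss_i))[1L]]]$subject, call. = FALSE)
    }
    gamma <- if (m <= config$n_burn) 1 else
      (m - config$n_burn)^(-config$step_exponent)
    s1 <- s1 + gamma * (colSums(phi) - s1)
    s2 <- s2 + gamma * (colSums(phi^2) - s2)
    s3 <- s3 + gamma * (vapply(egs, function(g) sum(ss_i[err_group == g]),
                               numeric(1L)) - s3)
    mu <- s1 / N
    o2_new <- pmin(pmax(s2 / N - mu^2, ofloor), o2_cap)
    omega2 <- if (m <= config$n_burn) {
      # annealing: during exploration the variance may shrink at most
      # geometrically, so the prior cannot collapse before the chain and
      # the fixed effects have settled
      pmin(pmax(o2_new, 0.95 * omega2), o2_cap)
    } else o2_new
    # residual variance is frozen during exploration: a transient
    # excursion of the chain must not flatten the likelihood via an
    # inflated noise term (the two-stage pooled residual SD is already a
    # consistent estimate)
    if (m > config$n_burn) sigma2 <- pmax(s3 / n_obs_g, 1e-12)
    trace[m, ] <- c(mu, sqrt(sigma2))
    if (m %in% refresh_at) Ls <- prop_chol()
  }

  pop <- population_params(mu, omega2, setNames(sqrt(sigma2), egs), pspec)

  eb <- lapply(seq_len(N), function(i) {
    empirical_bayes_one(dats[[i]], pop, start = phi[i, ], ltau_lim = ltau_lim)
  })
  phi_hat <- do.call(rbind, lapply(eb, `[[`, "phi"))
  eb_flagged <- vapply(eb, `[[`, logical(1L), "flagged")
  subjects <- eb_table(dats, phi_hat, pspec)
  rmse <- compute_rmse(trials, subjects)

  ll_final <- sum(vapply(seq_len(N), function(i) {
    laplace_loglik(phi_hat[i, ], dats[[i]], pop)
  }, numeric(1L)))
  init_pop <- init$pop
  ll_init <- sum(vapply(seq_len(N), function(i) {
    ph <- empirical_bayes_one(dats[[i]], init_pop,
                              start = init$phi[ord, , drop = FALSE][i, ],
                              ltau_lim = ltau_lim)$phi
    laplace_loglik(ph, dats[[i]], init_pop)
  }, numeric(1L)))

  structure(list(
    pop = pop, subjects = subjects, rmse = rmse, trace = trace,
    loglik = c(init = ll_init, final = ll_final),
    flags = list(
      improved = ll_final >= ll_init,
      eb_flagged = subjects$subject[eb_flagged],
      init_failed = init$failed
    ),
    config = config
  ), class = "reach_fit")
}

#' @export
print.reach_fit <- function(x, ...) {
  cat("Learning-fatigue NLME fit (SAEM),", nrow(x$subjects), "subjects\n")
  print(x$pop)
  cat("RMSE (ms):\n")
  print(x$rmse, row.names = FALSE)
  if (!x$flags$improved) {
    cat("note: marginal log-likelihood did not improve over initialization\n")
  }
  invisible(x)
}

# Natural-scale subject table from transformed-estimate rows.
eb_table <- function(dats, phi_hat, pspec) {
  out <- data.frame(
    subject = vapply(dats, `[[`, "", "subject"),
    group = vapply(dats, `[[`, "", "group"),
    A = exp(phi_hat[, 1L]),
    tau = exp(phi_hat[, 2L]),
    C = if (pspec$has_C) phi_hat[, 3L] else 0
  )
  D <- phi_hat[, pspec$d_off + seq_len(pspec$n_D), drop = FALSE]
  if (pspec$n_D == 1L) D <- D[, rep(1L, pspec$n_targets), drop = FALSE]
  colnames(D) <- paste0("D", seq_len(pspec$n_targets))
  cbind(out, as.data.frame(D))
}

# ---- empirical Bayes -------------------------------------------------------

empirical_bayes_one <- function(dat, pop, start = NULL, ltau_lim = NULL) {
  pspec <- pop$pspec
  sigma2 <- sigma_for(pop, dat$group)^2
  omega2 <- pmax(pop$omega2, omega2_floor(pop$mu))
  obj <- function(ph) {
    phi_ss(ph, dat, pspec) / (2 * sigma2) +
      0.5 * sum((ph - pop$mu)^2 / omega2)
  }
  grad <- function(ph) {
    phi_ss_grad(ph, dat, pspec) / (2 * sigma2) + (ph - pop$mu) / omega2
  }
  lower <- rep(-Inf, pspec$d)
  upper <- rep(Inf, pspec$d)
  if (!is.null(ltau_lim)) {
    lower[2L] <- ltau_lim[1L]
    upper[2L] <- ltau_lim[2L]
  }
  start <- start %||% pop$mu
  fit <- tryCatch(
    optim(start, obj, grad, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 500L)),
    error = function(e) NULL
  )
  flagged <- is.null(fit) || fit$convergence != 0L
  phi <- if (is.null(fit) || !all(is.finite(fit$par))) pop$mu else fit$par
  if (flagged && obj(phi) > obj(pop$mu)) phi <- pop$mu
  names(phi) <- pspec$cols
  list(phi = phi, flagged = flagged)
}

#' Empirical-Bayes estimate of one subject's parameters
#'
#' Posterior mode of a subject's transformed parameters given their trial
#' data and a fitted (or supplied) population distribution. With zero
#' random-effect variance, or with data carrying no information (huge
#' residual SD), the mode collapses to the population means. A
#' non-converged optimisation is flagged and the population means are
#' returned if they score better.
#'
#' @param trials Trial records for a single subject.
#' @param pop A [population_params()].
#' @return One-row data frame of natural-scale parameters (`subject`,
#'   `group`, `A`, `tau`, `C`, `D1`..), with attribute `"flagged"`.
#' @export
empirical_bayes <- function(trials, pop) {
  stopifnot(inherits(pop, "population_params"))
  validate_trials(trials, pop$pspec)
  if (length(unique(trials$subject)) != 1L) {
    stop("`empirical_bayes()` expects trials from exactly one subject",
         call. = FALSE)
  }
  dat <- split_trials(trials, pop$pspec)[[1L]]
  res <- empirical_bayes_one(dat, pop)
  out <- eb_table(list(dat), matrix(res$phi, 1L), pop$pspec)
  attr(out, "flagged") <- res$flagged
  out
}

# Laplace approximation of one subject's marginal log-likelihood at the
# posterior mode phi_hat; Hessian by central differences of the analytic
# gradient.
laplace_loglik <- function(phi_hat, dat, pop) {
  pspec <- pop$pspec
  sigma2 <- sigma_for(pop, dat$group)^2
  omega2 <- pmax(pop$omega2, omega2_floor(pop$mu))
  d <- pspec$d
  H <- post_hessian(phi_hat, dat, pspec, sigma2, 1 / omega2)
  ldet <- determinant(H, logarithm = TRUE)
  ldetH <- if (ldet$sign > 0) as.numeric(ldet$modulus) else
    sum(log(pmax(diag(H), 1e-12)))
  ll_joint <- -phi_ss(phi_hat, dat, pspec) / (2 * sigma2) -
    dat$n / 2 * log(2 * pi * sigma2) -
    0.5 * sum((phi_hat - pop$mu)^2 / omega2) -
    0.5 * sum(log(2 * pi * omega2))
  ll_joint + d / 2 * log(2 * pi) - 0.5 * ldetH
}

# ---- goodness of fit -------------------------------------------------------

#' Root-mean-square error of the fitted model
#'
#' RMSE of observed minus predicted MT over each group's trials and
#' overall, using per-subject parameter estimates.
#'
#' @param trials Trial-record data frame.
#' @param subjects Natural-scale subject parameter table (`subject`, `A`,
#'   `tau`, `C`, `D1`.., optionally `group`).
#' @return Data frame with columns `group`, `rmse`, `n` (rows per group
#'   plus `"overall"`).
#' @export
compute_rmse <- function(trials, subjects) {
  if (nrow(trials) == 0L) stop("empty trial table", call. = FALSE)
  idx <- match(trials$subject, subjects$subject)
  if (anyNA(idx)) {
    stop("no parameters for subject(s): ",
         paste(unique(trials$subject[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  n_targets <- sum(grepl("^D[0-9]+$", names(subjects)))
  Dmat <- as.matrix(subjects[, paste0("D", seq_len(n_targets)), drop = FALSE])
  pred <- subjects$A[idx] * exp(-trials$t / subjects$tau[idx]) +
    subjects$C[idx] * trials$t +
    Dmat[cbind(idx, as.integer(trials$target))]
  res <- trials$mt_ms - pred
  grp <- if ("group" %in% names(trials)) as.character(trials$group) else "all"
  groups <- unique(grp)
  out <- data.frame(
    group = c(groups, "overall"),
    rmse = c(vapply(groups, function(g) sqrt(mean(res[grp == g]^2)),
                    numeric(1L)),
             sqrt(mean(res^2))),
    n = c(vapply(groups, function(g) sum(grp == g), numeric(1L)), length(res))
  )
  rownames(out) <- NULL
  out
}
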