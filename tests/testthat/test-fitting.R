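test_that("SAEM matches the NLS oracle in the zero-noise, zero-dispersion limit", {
  skip_if_not_installed("minpack.lm")
  trials <- make_subject_trials("s1", stroke_true_params)
  fit <- fit_nlme(trials, fit_config(n_burn = 50, n_iter = 50, seed = 3))
  # independent oracle: Levenberg-Marquardt on the same data
  df <- data.frame(y = trials$mt_ms, t = trials$t, k = factor(trials$target))
  Xk <- stats::model.matrix(~ k - 1, df)
  or <- minpack.lm::nlsLM(
    y ~ A * exp(-t / tau) + C * t + Xk %*% c(D1, D2, D3, D4, D5),
    data = df,
    start = list(A = 200, tau = 50, C = 0.5, D1 = 300, D2 = 350, D3 = 380,
                 D4 = 400, D5 = 430))
  cf <- coef(or)
  expect_equal(exp(fit$pop$mu[["lA"]]), unname(cf["A"]), tolerance = 1e-3)
  expect_equal(exp(fit$pop$mu[["ltau"]]), unname(cf["tau"]), tolerance = 1e-3)
  expect_equal(fit$pop$mu[["C"]], unname(cf["C"]), tolerance = 1e-3)
  expect_equal(fit$pop$mu[["D5"]], unname(cf["D5"]), tolerance = 1e-3)
  expect_lt(fit$rmse$rmse[fit$rmse$group == "overall"], 1e-3)
})

test_that("two-stage initialization is exact on clean data and order-invariant", {
  set.seed(8)
  trials <- rbind(
    make_subject_trials("a", stroke_true_params),
    make_subject_trials("b", list(A = 200, tau = 40, C = 0.5,
                                  D = c(300, 320, 340, 360, 380))),
    make_subject_trials("c", list(A = 350, tau = 80, C = 1.5,
                                  D = c(350, 370, 390, 410, 430)))
  )
  init <- initialize_two_stage(trials)
  # noise-free: the pooled-anchor fixed effects must fit the data closely
  expect_equal(exp(init$pop$mu[["ltau"]]), 64, tolerance = 0.15)
  expect_lt(init$pop$sigma, 5)
  shuffled <- trials[rev(seq_len(nrow(trials))), ]
  init2 <- initialize_two_stage(shuffled)
  expect_equal(init$pop$mu, init2$pop$mu, tolerance = 1e-8)
  expect_equal(init$pop$omega2, init2$pop$omega2, tolerance = 1e-8)
})

test_that("flat learners (A near 0) initialize finitely without crashing", {
  set.seed(14)
  flat <- list(A = 0.001, tau = 64, C = 0.3, D = rep(400, 5))
  trials <- rbind(make_subject_trials("f1", flat, sigma = 40),
                  make_subject_trials("f2", flat, sigma = 40))
  init <- initialize_two_stage(trials)
  expect_true(all(is.finite(init$pop$mu)))
  expect_true(all(is.finite(unlist(init$phi))))
  expect_length(init$failed, 0)
})

test_that("empirical Bayes collapses to the population means without information", {
  ps <- population_params(
    mu = c(lA = log(279), ltau = log(64), C = 1.11,
           D1 = 328, D2 = 354, D3 = 380, D4 = 406, D5 = 432),
    omega2 = setNames(rep(0, 8), c("lA", "ltau", "C", paste0("D", 1:5))),
    sigma = 76)
  set.seed(5)
  trials <- make_subject_trials("x", list(A = 150, tau = 30, C = 0.2,
                                          D = rep(300, 5)), sigma = 76)
  eb <- empirical_bayes(trials, ps)
  expect_equal(eb$A, 279, tolerance = 5e-3)
  expect_equal(eb$tau, 64, tolerance = 5e-3)
  # huge residual SD: the data carry no information
  ps2 <- population_params(ps$mu, setNames(rep(0.25, 8), names(ps$mu)), 1e7)
  eb2 <- empirical_bayes(trials, ps2)
  expect_equal(eb2$A, 279, tolerance = 0.01)
})

test_that("empirical Bayes under a diffuse prior matches per-subject least squares", {
  trials <- make_subject_trials("x", stroke_true_params)
  mu <- c(lA = log(350), ltau = log(50), C = 0.5,
          D1 = 300, D2 = 330, D3 = 360, D4 = 390, D5 = 420)
  ps <- population_params(mu, setNames(rep(1e4, 8), names(mu)), sigma = 1)
  eb <- empirical_bayes(trials, ps)
  expect_equal(eb$A, 279, tolerance = 5e-3)
  expect_equal(eb$tau, 64, tolerance = 5e-3)
  expect_equal(eb$C, 1.11, tolerance = 5e-3)
  expect_equal(eb$D5, 432, tolerance = 5e-3)
})

test_that("RMSE computation is exact on hand-built residuals", {
  p <- list(A = 0, tau = 1, C = 0, D = rep(400, 5))
  trials <- data.frame(subject = "s", group = "g", t = c(1, 2), target = c(1L, 2L),
                       mt_ms = c(403, 396))
  subj <- data.frame(subject = "s", A = 0, tau = 1, C = 0,
                     D1 = 400, D2 = 400, D3 = 400, D4 = 400, D5 = 400)
  out <- compute_rmse(trials, subj)
  expect_equal(out$rmse[out$group == "overall"], sqrt(25 / 2), tolerance = 1e-9)
  perfect <- trials
  perfect$mt_ms <- c(400, 400)
  expect_equal(compute_rmse(perfect, subj)$rmse, c(0, 0))
  expect_error(compute_rmse(trials, subj[0, ]), "no parameters")
})

test_that("fitted RMSE is consistent with the generating residual SD", {
  ch <- simulate_cohort(control_cohort_config(n_subjects = 6), seed = 7)
  fit <- fit_nlme(ch$trials, fit_config(n_burn = 100, n_iter = 80, seed = 7))
  expect_equal(fit$rmse$rmse[fit$rmse$group == "control"], 24,
               tolerance = 0.1)
})

test_that("zero-dispersion cohorts yield near-zero random-effect variances", {
  cfg <- stroke_cohort_config(n_subjects = 8, sdlog_A = 0, sdlog_tau = 0,
                              sd_C = 0, sd_D = 0)
  ch <- simulate_cohort(cfg, seed = 19)
  fit <- fit_nlme(ch$trials, fit_config(n_burn = 150, n_iter = 100, seed = 19))
  expect_true(all(fit$pop$omega2 < 0.05 * fit$pop$mu^2))
})

test_that("the fatigue term earns its keep on fatigue-bearing data", {
  ch <- simulate_cohort(stroke_cohort_config(n_subjects = 6), seed = 23)
  full <- fit_nlme(ch$trials, fit_config(n_burn = 100, n_iter = 80, seed = 23))
  nofat <- fit_nlme(ch$trials, fit_config(n_burn = 100, n_iter = 80, seed = 23,
                                          drop_fatigue = TRUE))
  r_full <- full$rmse$rmse[full$rmse$group == "overall"]
  r_nofat <- nofat$rmse$rmse[nofat$rmse$group == "overall"]
  expect_lt(r_full, r_nofat)
})

test_that("identical seed, config and data give a bit-identical fit", {
  ch <- simulate_cohort(control_cohort_config(n_subjects = 4), seed = 2)
  f1 <- fit_nlme(ch$trials, fit_config(n_burn = 60, n_iter = 40, seed = 11))
  f2 <- fit_nlme(ch$trials, fit_config(n_burn = 60, n_iter = 40, seed = 11))
  expect_identical(f1$pop$mu, f2$pop$mu)
  expect_identical(f1$subjects, f2$subjects)
  expect_identical(f1$trace, f2$trace)
})

test_that("SAEM does not degrade the marginal likelihood of its initialization", {
  ok <- vapply(1:4, function(s) {
    ch <- simulate_cohort(stroke_cohort_config(n_subjects = 6), seed = s)
    fit_nlme(ch$trials, fit_config(n_burn = 100, n_iter = 80,
                                   seed = s))$flags$improved
  }, logical(1))
  expect_gte(mean(ok), 0.75)
})
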