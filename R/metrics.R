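# Per-subject learning and performance quantities derived from the fitted
# model: the decomposition that separates what was learned (the
# exponential drop) from how performance changed net of fatigue.

#' Derived learning and performance metrics for one subject
#'
#' With `model(t) = A exp(-t/tau) + C t + mean_k(D_k)` evaluated over the
#' per-target trial range `t = 1..T`:
#' * initial performance = `model(1)` (ms)
#' * amount of learning = `A (e^{-1/tau} - e^{-T/tau})` (ms), the drop of
#'   the exponential component over training
#' * normalized learning = amount of learning / initial performance
#' * final fatigue = `C * T` (ms), the linear worsening term at the last
#'   trial
#' * normalized performance change = `(model(1) - model(T)) / model(1)`,
#'   the net modelled change (learning minus fatigue accrual)
#' * half-life = `tau * ln 2` (trials)
#'
#' The identity `normalized performance change = normalized learning -
#' C (T - 1) / initial performance` holds exactly, which is why learning
#' and performance dissociate whenever `C > 0`.
#'
#' @param params Subject parameters as in [predict_mt()] (or a multi-row
#'   parameter table, giving one metrics row per subject).
#' @param T Trials per target in the session (default 120).
#' @return Data frame with columns `initial_performance`,
#'   `amount_of_learning`, `normalized_learning`, `final_fatigue`,
#'   `normalized_performance_change`, `half_life` (plus `subject`/`group`
#'   when present in `params`).
#' @examples
#' derive_metrics(list(A = 279, tau = 64, C = 1.11, D = rep(432, 5)))
#' @export
derive_metrics <- function(params, T = 120) {
  if (T < 2) stop("`T` must be >= 2", call. = FALSE)
  if (is.data.frame(params) && nrow(params) > 1L) {
    out <- do.call(rbind, lapply(seq_len(nrow(params)), function(i) {
      derive_metrics(params[i, ], T = T)
    }))
    rownames(out) <- NULL
    return(out)
  }
  p <- as_subject_params(params)
  if (p$tau <= 0) stop("`tau` must be strictly positive", call. = FALSE)
  Dbar <- mean(p$D)
  model_t <- function(t) p$A * exp(-t / p$tau) + p$C * t + Dbar
  initial <- model_t(1)
  if (initial <= 0) {
    stop("initial performance <= 0: normalized metrics undefined",
         call. = FALSE)
  }
  learning <- p$A * (exp(-1 / p$tau) - exp(-T / p$tau))
  out <- data.frame(
    initial_performance = initial,
    amount_of_learning = learning,
    normalized_learning = learning / initial,
    final_fatigue = p$C * T,
    normalized_performance_change = (initial - model_t(T)) / initial,
    half_life = p$tau * log(2)
  )
  lab <- params[intersect(c("subject", "group"), names(params))]
  if (length(lab)) out <- cbind(as.data.frame(lab), out)
  out
}

#' Long-term performance change from test-phase means
#'
#' `(MT_Pre1 - MT_1month) / MT_Pre1`: the relative change in mean MT
#' between the pre-training test and the 1-month retention test. Positive
#' values indicate improvement.
#'
#' @param mt_pre1 Mean MT in the pre-training test (ms), > 0; or a
#'   test-phase data frame with columns `mt_pre1`, `mt_1month`.
#' @param mt_1month Mean MT in the 1-month retention test (ms).
#' @return Unitless change (vectorised).
#' @examples
#' long_term_change(1000, 800) # 0.20, improved
#' long_term_change(900, 990)  # -0.10, worsened
#' @export
long_term_change <- function(mt_pre1, mt_1month = NULL) {
  if (is.data.frame(mt_pre1)) {
    mt_1month <- mt_pre1$mt_1month
    mt_pre1 <- mt_pre1$mt_pre1
  }
  if (any(mt_pre1 <= 0)) stop("`mt_pre1` must be > 0", call. = FALSE)
  (mt_pre1 - mt_1month) / mt_pre1
}

#' Half-life of the exponential learning component
#'
#' Number of trials for the learning component to halve: `tau * ln 2`.
#' Reports round to the nearest integer trial; full precision is kept
#' when `round = FALSE`.
#'
#' @param tau Decay rate in trials, > 0 (vectorised).
#' @param round Round to integer trials (default `TRUE`)?
#' @return Half-life in trials.
#' @examples
#' half_life(64) # 44
#' half_life(36) # 25
#' @export
half_life <- function(tau, round = TRUE) {
  if (any(tau <= 0)) stop("`tau` must be strictly positive", call. = FALSE)
  hl <- tau * log(2)
  if (round) base::round(hl) else hl
}
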