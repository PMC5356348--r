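# Structural model: MT(t, k) = A exp(-t/tau) + C t + D_k + noise.

N_TARGETS <- 5L

# Normalise subject parameters to a list(A, tau, C, D) with D of length 5.
# Accepts a list with D as a vector, or a list/one-row data.frame with
# columns D1..D5 (or D_1..D_5).
as_subject_params <- function(params) {
  if (is.data.frame(params)) {
    if (nrow(params) != 1L) {
      stop("expected parameters for exactly one subject", call. = FALSE)
    }
    params <- as.list(params)
  }
  if (!is.null(params$D)) {
    D <- as.numeric(params$D)
  } else {
    nm_plain <- paste0("D", seq_len(N_TARGETS))
    nm_us <- paste0("D_", seq_len(N_TARGETS))
    nms <- if (all(nm_plain %in% names(params))) nm_plain
      else if (all(nm_us %in% names(params))) nm_us
      else stop("subject parameters need `D` (length 5) or columns D1..D5",
                call. = FALSE)
    D <- as.numeric(unlist(params[nms], use.names = FALSE))
  }
  if (length(D) != N_TARGETS || any(!is.finite(D))) {
    stop("`D` must hold 5 finite per-target intercepts", call. = FALSE)
  }
  A <- as.numeric(params$A)
  tau <- as.numeric(params$tau)
  C <- as.numeric(params$C)
  if (length(A) != 1L || length(tau) != 1L || length(C) != 1L ||
      any(!is.finite(c(A, tau, C)))) {
    stop("`A`, `tau`, `C` must be single finite numbers", call. = FALSE)
  }
  list(A = A, tau = tau, C = C, D = D)
}

#' Predict movement time from subject-level model parameters
#'
#' Evaluates the deterministic part of the structural model,
#' `A * exp(-t / tau) + C * t + D_k`, for one subject. `t` is the
#' per-target trial index (1-based); `k` the target number (1..5).
#'
#' @param params Subject parameters: a list with elements `A` (ms), `tau`
#'   (trials), `C` (ms/trial) and `D` (numeric length 5, ms), or a one-row
#'   data frame with columns `A`, `tau`, `C`, `D1`..`D5`.
#' @param t Per-target trial index (vectorised), `t >= 1`.
#' @param k Target number in 1..5 (vectorised, recycled against `t`).
#' @return Predicted movement times in ms.
#' @examples
#' p <- list(A = 279, tau = 64, C = 1.11, D = c(328, 354, 380, 406, 432))
#' predict_mt(p, t = c(1, 120), k = 5)
#' @export
predict_mt <- function(params, t, k) {
  p <- as_subject_params(params)
  if (p$tau <= 0) stop("`tau` must be strictly positive", call. = FALSE)
  t <- as.numeric(t)
  k <- as.integer(k)
  if (any(t < 1)) stop("trial index `t` must be >= 1", call. = FALSE)
  if (any(k < 1L | k > N_TARGETS)) {
    stop("target `k` must be in 1..", N_TARGETS, call. = FALSE)
  }
  n <- max(length(t), length(k))
  t <- rep_len(t, n)
  k <- rep_len(k, n)
  p$A * exp(-t / p$tau) + p$C * t + p$D[k]
}

#' Simulate one noisy training movement time
#'
#' Adds homoscedastic Gaussian trial noise to [predict_mt()].
#'
#' @inheritParams predict_mt
#' @param sigma Residual noise SD in ms, `>= 0`.
#' @param seed Optional integer seed for a reproducible draw; `NULL` uses
#'   the current RNG stream.
#' @return Simulated movement times in ms (same length as `t`/`k`).
#' @export
simulate_trial <- function(params, t, k, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  }
  mu <- predict_mt(params, t, k)
  with_seed(seed, mu + rnorm(length(mu), 0, sigma))
}

# Internal vectorised predictor over rows of a trial table, used by the
# generator and the fitter. `theta` is the transformed-scale parameter
# vector/matrix; see fitting.R for the layout.
predict_rows <- function(A, tau, C, D_of_row, t) {
  A * exp(-t / tau) + C * t + D_of_row
}
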