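# Independent oracles and small builders shared across tests.

# Exhaustive-enumeration two-sided Mann-Whitney p: every assignment of
# the pooled ranks to the x sample, counted directly. Independent of the
# package's pwilcox/normal-approximation paths. Feasible up to ~ C(12,6).
mw_exact_enum <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(length(pooled), nx)
  Us <- apply(idx, 2L, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  # two-sided: double the smaller tail (cap at 1)
  lo <- mean(Us <= U_obs)
  hi <- mean(Us >= U_obs)
  min(1, 2 * min(lo, hi))
}

# 5%-of-peak crossing span of the continuous minimum-jerk speed profile,
# found by root-finding on 30 s^2 (1-s)^2 = 0.05 * 1.875.
min_jerk_span_oracle <- function(frac = 0.05) {
  f <- function(s) 30 * s^2 * (1 - s)^2 - frac * 1.875
  s1 <- uniroot(f, c(0, 0.5), tol = 1e-12)$root
  s2 <- uniroot(f, c(0.5, 1), tol = 1e-12)$root
  s2 - s1
}

# A small deterministic trial table from known subject parameters
# (noise-free unless sigma > 0).
make_subject_trials <- function(id, params, T = 120, n_targets = 5,
                                sigma = 0, group = "stroke") {
  tgt <- rep(seq_len(n_targets), each = T)
  t <- rep(seq_len(T), n_targets)
  mt <- predict_mt(params, t, tgt)
  if (sigma > 0) mt <- mt + rnorm(length(mt), 0, sigma)
  data.frame(subject = id, group = group, side = "right",
             trial = seq_along(t), t = t, target = tgt,
             mt_ms = pmax(mt, 50))
}

stroke_true_params <- list(A = 279, tau = 64, C = 1.11,
                           D = c(328, 354, 380, 406, 432))
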