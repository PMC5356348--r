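# The study's statistical battery: Shapiro-Wilk normality screening,
# median/IQR group contrasts by Mann-Whitney, Pearson correlation and
# simple regression, the demographics t-test, and the long-term-prediction
# regressions.

#' Shapiro-Wilk normality test
#'
#' Royston's W and p, for samples of 3 to 5000 finite values. Constant
#' samples are an error (W is undefined at zero variance).
#'
#' @param x Numeric sample.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || length(x) > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("Shapiro-Wilk is undefined for a constant sample", call. = FALSE)
  }
  ht <- shapiro.test(x)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Mann-Whitney rank-sum test with median/IQR summaries
#'
#' Two-sided test of `x` vs `y`. The p-value is exact (tail of the exact
#' U distribution) when the samples are tie-free and `n_x * n_y <= 400`;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. `method` can force either branch.
#'
#' @param x,y Numeric samples (non-empty).
#' @param method `"auto"` (default), `"exact"`, or `"approx"`.
#' @return List with `U` (statistic for `x`), `p`, `method` used, and
#'   `summary` (per-sample median and 25/75% quartiles).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4)) # exact p = 1/3
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  nx <- length(x)
  ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both samples must be non-empty",
                                 call. = FALSE)
  r <- rank(c(x, y))
  ties <- any(duplicated(c(x, y)))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (method == "auto") {
    method <- if (!ties && nx * ny <= 400) "exact" else "approx"
  }
  if (method == "exact") {
    if (ties) stop("exact Mann-Whitney p is unavailable with ties",
                   call. = FALSE)
    p <- if (U > nx * ny / 2) {
      2 * (1 - pwilcox(U - 1, nx, ny))
    } else {
      2 * pwilcox(U, nx, ny)
    }
    p <- min(1, p)
  } else {
    n <- nx + ny
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    s2 <- nx * ny / 12 * ((n + 1) - tie_term)
    mu <- nx * ny / 2
    z <- if (s2 > 0) (U - mu - sign(U - mu) * 0.5) / sqrt(s2) else 0
    p <- 2 * pnorm(-abs(z))
    p <- min(1, p)
  }
  qs <- function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    c(q25 = q[1L], median = q[2L], q75 = q[3L])
  }
  list(U = U, p = p, method = method,
       summary = rbind(x = qs(x), y = qs(y)))
}

#' Pearson correlation with simple linear regression
#'
#' Two-sided Pearson correlation between `x` and `y`, with the
#' least-squares line of `y` on `x`; `R^2` equals `r^2` exactly for the
#' simple regression.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, finite, each
#'   with positive variance.
#' @return List with `r`, `r_squared`, `p`, `n`, `slope`, `intercept`.
#' @export
pearson_and_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    stop("zero variance in `x` or `y`", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x),
       slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
}

#' Two-sample t-test
#'
#' Pooled-variance (default) or Welch two-sided t-test.
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @param equal_var Pool the variances (default `TRUE`)?
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(x, y, equal_var = TRUE) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples need at least 2 values", call. = FALSE)
  }
  if (equal_var && var(x) == 0 && var(y) == 0) {
    stop("zero pooled variance", call. = FALSE)
  }
  ht <- t.test(x, y, var.equal = equal_var)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Group contrasts of the model parameters
#'
#' For each model parameter (`A`, `tau`, `C`, `D1`..): a Shapiro-Wilk
#' normality screen per group, median and 25-75% IQR per group, and a
#' two-sided Mann-Whitney contrast. The nonparametric contrast is always
#' reported regardless of the normality screen (the screen's p-values are
#' recorded alongside). No multiple-testing correction is applied by
#' default; `adjust = "holm"` adds Holm-adjusted p-values.
#'
#' @param subjects Subject parameter table with a `group` column and the
#'   parameter columns.
#' @param parameters Which columns to contrast; defaults to `A`, `tau`,
#'   `C` and every `D<k>` column present.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Data frame, one row per parameter: group medians/IQRs,
#'   Shapiro-Wilk p per group, `U`, `p` (and `p_adj` if requested).
#' @export
contrast_parameters <- function(subjects, parameters = NULL,
                                adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  if (is.null(subjects$group)) stop("`subjects` needs a `group` column",
                                    call. = FALSE)
  groups <- unique(as.character(subjects$group))
  if (length(groups) != 2L) {
    stop("expected exactly 2 groups, got ", length(groups), call. = FALSE)
  }
  n_per <- table(subjects$group)
  if (any(n_per < 2L)) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  parameters <- parameters %||%
    intersect(c("A", "tau", "C", grep("^D[0-9]+$", names(subjects),
                                      value = TRUE)),
              names(subjects))
  rows <- lapply(parameters, function(pm) {
    v1 <- subjects[[pm]][subjects$group == groups[1L]]
    v2 <- subjects[[pm]][subjects$group == groups[2L]]
    sw <- function(v) tryCatch(shapiro_wilk(v)$p, error = function(e) NA_real_)
    mw <- mann_whitney(v1, v2)
    data.frame(
      parameter = pm,
      median_1 = mw$summary["x", "median"], q25_1 = mw$summary["x", "q25"],
      q75_1 = mw$summary["x", "q75"],
      median_2 = mw$summary["y", "median"], q25_2 = mw$summary["y", "q25"],
      q75_2 = mw$summary["y", "q75"],
      shapiro_p_1 = sw(v1), shapiro_p_2 = sw(v2),
      U = mw$U, p = mw$p, method = mw$method
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- groups
  if (adjust == "holm") out$p_adj <- stats::p.adjust(out$p, "holm")
  out
}

#' Regress long-term performance change on a training-derived predictor
#'
#' Tests whether what was learned during training (or the net performance
#' change) predicts the relative MT change between the pre-training test
#' and the 1-month retention test, via simple least-squares regression.
#' Subjects can be excluded by id (sensitivity variants).
#'
#' @param metrics Per-subject metrics table from [derive_metrics()]
#'   (needs `subject` and the predictor column).
#' @param test_phases Test-phase table with `subject`, `mt_pre1`,
#'   `mt_1month` (or a precomputed `long_term_change` column).
#' @param predictor `"normalized_learning"` (default) or
#'   `"normalized_performance_change"`.
#' @param exclude Character vector of subject ids to drop.
#' @return As [pearson_and_regression()], plus `predictor` and the
#'   subject ids used.
#' @export
predict_long_term <- function(metrics, test_phases,
                              predictor = c("normalized_learning",
                                            "normalized_performance_change"),
                              exclude = NULL) {
  predictor <- match.arg(predictor)
  if (is.null(test_phases$long_term_change)) {
    test_phases$long_term_change <- long_term_change(test_phases)
  }
  merged <- merge(metrics[, c("subject", predictor)],
                  test_phases[, c("subject", "long_term_change")],
                  by = "subject")
  merged <- merged[!(merged$subject %in% exclude), ]
  merged <- merged[complete.cases(merged), ]
  if (nrow(merged) < 3L) {
    stop("fewer than 3 matched subjects after merging/exclusion",
         call. = FALSE)
  }
  res <- pearson_and_regression(merged[[predictor]],
                                merged$long_term_change)
  res$predictor <- predictor
  res$subjects <- merged$subject
  res
}
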