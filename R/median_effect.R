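# Chou-Talalay median-effect fitting, CC50 determination and
# combination-index computation.

#' Fit the median-effect model to a dose-response series
#'
#' Linearizes the median-effect equation `fa/fu = (D/Dm)^m` as
#' `log10(fa/(1 - fa)) = m * log10(D) - m * log10(Dm)` and fits it by
#' ordinary least squares. `Dm` is the median-effect dose (the CC50 when
#' the response is cytotoxicity) and `m` the sigmoidicity coefficient.
#' Points with `fa` exactly 0 or 1 have an undefined logit and are
#' excluded with a warning; at least 2 interior points are required.
#'
#' @param series Data frame with columns `dose` (positive) and `fa`
#'   (fraction affected in \[0, 1\]).
#' @return Object of class `median_effect_fit` with elements `m`, `Dm`,
#'   `r_linearity` (correlation of the linearized fit),
#'   `se_log10_Dm` (standard error of `log10(Dm)` from the residual
#'   variance of the linear fit, delta method), `se_Dm`,
#'   `n_points_used`.
#' @examples
#' s <- data.frame(dose = c(1, 10, 100), fa = c(1/11, 1/2, 10/11))
#' fit_median_effect(s)  # m = 1, Dm = 10
#' @export
fit_median_effect <- function(series) {
  if (!all(c("dose", "fa") %in% names(series))) {
    stop("series must have columns 'dose' and 'fa'", call. = FALSE)
  }
  d <- series$dose
  fa <- series$fa
  .check_positive(d, "doses")
  if (anyNA(fa) || any(fa < 0 | fa > 1)) {
    stop("fa must lie in [0, 1]", call. = FALSE)
  }
  interior <- fa > 0 & fa < 1
  if (any(!interior)) {
    warning(sum(!interior),
            " point(s) with fa at 0 or 1 excluded (undefined logit)",
            call. = FALSE)
  }
  d <- d[interior]
  fa <- fa[interior]
  if (length(d) < 2L) {
    stop("insufficient data: need >= 2 points with fa strictly in (0, 1)",
         call. = FALSE)
  }
  x <- log10(d)
  y <- log10(fa / (1 - fa))
  if (stats::var(x) == 0) {
    stop("degenerate design: doses have zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  b <- stats::coef(fit)
  m <- unname(b[2L])
  log10_dm <- -unname(b[1L]) / m
  # delta method on g(b0, b1) = -b0/b1
  V <- suppressWarnings(stats::vcov(fit))  # noiseless data: sigma ~ 0
  grad <- c(-1 / m, unname(b[1L]) / m^2)
  se_log10_dm <- sqrt(max(0, drop(t(grad) %*% V %*% grad)))
  dm <- 10^log10_dm
  structure(list(m = m, Dm = dm, r_linearity = stats::cor(x, y),
                 se_log10_Dm = se_log10_dm,
                 se_Dm = dm * log(10) * se_log10_dm,
                 n_points_used = length(d)),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("<median-effect fit> m = %.4g, Dm (CC50) = %.4g +/- %.2g (s.e.), r = %.4f, n = %d\n",
              x$m, x$Dm, x$se_Dm, x$r_linearity, x$n_points_used))
  invisible(x)
}

#' Dose producing a given fractional effect
#'
#' Inverts the median-effect equation:
#' `Dx = Dm * (fa / (1 - fa))^(1/m)`.
#'
#' @param fit A [fit_median_effect()] result (or any list with `m` and
#'   `Dm`).
#' @param fa Fraction affected, strictly in (0, 1).
#' @return The dose `Dx`.
#' @export
dose_for_effect <- function(fit, fa) {
  if (anyNA(fa) || any(fa <= 0 | fa >= 1)) {
    stop("fa must lie strictly in (0, 1)", call. = FALSE)
  }
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Fraction affected at a given dose under a median-effect fit
#'
#' @param fit A [fit_median_effect()] result.
#' @param dose Positive dose(s).
#' @return Fraction affected `fa = 1 / (1 + (Dm/D)^m)`.
#' @export
fa_at_dose <- function(fit, dose) {
  .check_positive(dose, "dose")
  1 / (1 + (fit$Dm / dose)^fit$m)
}

#' Combination index at one observed fractional effect
#'
#' Mutually-exclusive (Loewe) form:
#' `CI = d1/Dx1(fa) + d2/Dx2(fa)`, where `Dx_i(fa)` is the single-drug
#' dose of drug i producing the observed effect. CI < 1 indicates
#' synergy, CI = 1 additivity, CI > 1 antagonism. The non-exclusive form
#' adds the geometric interaction term
#' `sqrt(d1 d2 / (Dx1 Dx2))`.
#'
#' @param fit1,fit2 Median-effect fits of the two single drugs.
#' @param d1,d2 Component doses of the combination point (non-negative,
#'   not both zero).
#' @param fa_observed Observed fraction affected, strictly in (0, 1).
#' @param exclusive Use the mutually-exclusive form (default TRUE).
#' @return List with `fa`, `d1`, `d2`, `Dx1`, `Dx2`, `ci`.
#' @export
combination_index <- function(fit1, fit2, d1, d2, fa_observed,
                              exclusive = TRUE) {
  if (anyNA(c(d1, d2)) || d1 < 0 || d2 < 0 || (d1 == 0 && d2 == 0)) {
    stop("component doses must be non-negative and not both zero",
         call. = FALSE)
  }
  if (is.na(fa_observed) || fa_observed <= 0 || fa_observed >= 1) {
    stop("fa_observed must lie strictly in (0, 1)", call. = FALSE)
  }
  dx1 <- dose_for_effect(fit1, fa_observed)
  dx2 <- dose_for_effect(fit2, fa_observed)
  ci <- d1 / dx1 + d2 / dx2
  if (!exclusive) ci <- ci + sqrt((d1 * d2) / (dx1 * dx2))
  list(fa = fa_observed, d1 = d1, d2 = d2, Dx1 = dx1, Dx2 = dx2, ci = ci)
}

#' Combination-index curve over a combination series
#'
#' One combination index per usable point (`fa` strictly inside (0, 1)),
#' sorted by `fa`; the series median CI is attached as attribute
#' `median_ci`.
#'
#' @param fit1,fit2 Median-effect fits of the two single drugs.
#' @param combo_series Data frame with columns `dose1`, `dose2`, `fa`.
#' @param exclusive Use the mutually-exclusive CI form (default TRUE).
#' @return Data frame with columns `fa`, `d1`, `d2`, `Dx1`, `Dx2`, `ci`.
#' @export
ci_curve <- function(fit1, fit2, combo_series, exclusive = TRUE) {
  if (!all(c("dose1", "dose2", "fa") %in% names(combo_series))) {
    stop("combo_series must have columns dose1, dose2, fa", call. = FALSE)
  }
  usable <- combo_series$fa > 0 & combo_series$fa < 1
  if (!any(usable)) {
    stop("insufficient data: no combination point with fa in (0, 1)",
         call. = FALSE)
  }
  s <- combo_series[usable, , drop = FALSE]
  s <- s[order(s$fa), , drop = FALSE]
  rows <- mapply(function(d1, d2, fa) {
    unlist(combination_index(fit1, fit2, d1, d2, fa, exclusive = exclusive))
  }, s$dose1, s$dose2, s$fa)
  out <- as.data.frame(t(rows))
  rownames(out) <- NULL
  attr(out, "median_ci") <- stats::median(out$ci)
  out
}

#' CC50 summary table for a set of conditions
#'
#' @param fits Named list of [fit_median_effect()] results, one per
#'   condition.
#' @return Data frame with `condition`, `cc50`, `se` (standard error of
#'   the CC50 propagated from the linearized fit's residuals), `m`,
#'   `r_linearity`.
#' @export
cc50_table <- function(fits) {
  stopifnot(length(fits) > 0L, !is.null(names(fits)))
  data.frame(condition = names(fits),
             cc50 = vapply(fits, function(f) f$Dm, numeric(1L)),
             se = vapply(fits, function(f) f$se_Dm, numeric(1L)),
             m = vapply(fits, function(f) f$m, numeric(1L)),
             r_linearity = vapply(fits, function(f) f$r_linearity,
                                  numeric(1L)),
             row.names = NULL, stringsAsFactors = FALSE)
}
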