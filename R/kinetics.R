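#' Eyring-Polanyi rate constant
#'
#' k = kappa (k_B T / h) exp(-dG / (R T)).
#'
#' @param delta_g_dagger activation free energy, kJ/mol.
#' @param temperature absolute temperature, K (> 0).
#' @param kappa transmission coefficient in [0, 1].
#' @return rate constant, 1/s.
#' @examples
#' eyring_rate(0, 300)    # k_B T / h at 300 K
#' @export
eyring_rate <- function(delta_g_dagger, temperature, kappa = 1) {
  if (any(temperature <= 0)) stop("temperature must be > 0")
  if (any(kappa < 0 | kappa > 1)) stop("kappa must be in [0, 1]")
  kappa * (mm_constants$KB * temperature / mm_constants$H) *
    exp(-delta_g_dagger / (mm_constants$R * temperature))
}

#' Convert an effective RT constant to a temperature (and back)
#'
#' T = RT / R with R = 8.3145e-3 kJ/(mol K). The effective temperatures
#' recovered by the correlation fits are not physical temperatures; they
#' absorb the non-quantitative scale of the computed interaction energies.
#'
#' @param rt effective RT, kJ/mol (> 0).
#' @return temperature, K.
#' @examples
#' rt_to_temperature(15.3)   # ~1840 K
#' @export
rt_to_temperature <- function(rt) {
  if (any(rt <= 0)) stop("rt must be > 0")
  rt / mm_constants$R
}

#' @rdname rt_to_temperature
#' @param temperature K (> 0).
#' @export
temperature_to_rt <- function(temperature) {
  if (any(temperature <= 0)) stop("temperature must be > 0")
  temperature * mm_constants$R
}

new_ie_fit <- function(model, data, type, slope_sign, degenerate = FALSE) {
  sl <- unname(stats::coef(model)[2])
  r2 <- if (degenerate) 0 else
    suppressWarnings(summary(model)$r.squared)
  if (is.nan(r2)) r2 <- 0
  rt <- if (sl == 0) NA_real_ else 1 / abs(sl)
  structure(list(
    model = model, data = data, type = type,
    slope = sl, intercept = unname(stats::coef(model)[1]),
    r_squared = r2, effective_rt = rt,
    effective_temperature = if (is.na(rt)) NA_real_ else rt_to_temperature(rt),
    expected_slope_sign = slope_sign,
    sign_consistent = !is.na(sl) && sign(sl) == slope_sign
  ), class = "ie_fit")
}

check_fit_data <- function(x, y, min_n) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_n)
    stop("need at least ", min_n, " complete observations")
  if (stats::var(x[ok]) == 0)
    stop("degenerate fit: predictor has zero variance")
  ok
}

zero_var_response <- function(y) {
  if (stats::var(y) == 0) {
    warning("response has zero variance; R^2 reported as 0")
    TRUE
  } else FALSE
}

#' Correlate ln K_M with the substrate interaction energy
#'
#' Ordinary least squares of ln(K_M) on IE_S. Within the
#' transition-state-analogue framework ln K_M = IE_S / (RT)_S + const, so the
#' slope estimates 1/(RT)_S; the effective RT (and temperature) is reported
#' alongside the fit. K_M must be in mM (unit choice shifts the intercept
#' only).
#'
#' @param data data frame with the interaction-energy and K_M columns.
#' @param ie_col,km_col column names.
#' @return an "ie_fit" object; see [tidy.ie_fit()], [glance.ie_fit()],
#'   [autoplot.ie_fit()].
#' @export
fit_ln_km <- function(data, ie_col = "ie_s", km_col = "km") {
  x <- data[[ie_col]]; y0 <- data[[km_col]]
  if (any(y0 <= 0, na.rm = TRUE)) stop("km must be strictly positive")
  y <- log(y0)
  ok <- check_fit_data(x, y, 3)
  d <- tibble::tibble(x = x[ok], y = y[ok])
  new_ie_fit(stats::lm(y ~ x, data = d), d, "ln_km", slope_sign = +1,
             degenerate = zero_var_response(d$y))
}

#' Correlate ln(k_cat/K_M) with the analogue interaction energy
#'
#' Ordinary least squares of ln(k_cat/K_M) on IE_TSA; within the framework
#' ln(k_cat/K_M) = -IE_TSA / (RT)_TSA + const, so the expected slope is
#' negative (variants binding the analogue more tightly are more efficient)
#' and the effective RT is 1/|slope|.
#'
#' @param data data frame.
#' @param ie_col,eff_col column names for IE_TSA and k_cat/K_M.
#' @return an "ie_fit" object.
#' @export
fit_ln_efficiency <- function(data, ie_col = "ie_tsa",
                              eff_col = "kcat_over_km") {
  x <- data[[ie_col]]; y0 <- data[[eff_col]]
  if (any(y0 <= 0, na.rm = TRUE)) stop("kcat_over_km must be strictly positive")
  y <- log(y0)
  ok <- check_fit_data(x, y, 3)
  d <- tibble::tibble(x = x[ok], y = y[ok])
  new_ie_fit(stats::lm(y ~ x, data = d), d, "ln_efficiency", slope_sign = -1,
             degenerate = zero_var_response(d$y))
}

#' Correlate ln k_cat with both interaction energies
#'
#' Least squares of ln(k_cat) on IE_TSA and IE_S jointly, under the model
#' ln k_cat = -IE_TSA/(RT)_TSA + IE_S/(RT)_S + const. The recovered
#' (RT)_TSA = -1/coef(IE_TSA) and (RT)_S = 1/coef(IE_S); both should be
#' positive for a physically sensible fit (flagged otherwise).
#'
#' @param data data frame with IE_S, IE_TSA and k_cat columns.
#' @param ie_s_col,ie_tsa_col,kcat_col column names.
#' @return list of class "kcat_fit": model, rt_s, rt_tsa, intercept,
#'   r_squared, physical (logical).
#' @export
fit_ln_kcat <- function(data, ie_s_col = "ie_s", ie_tsa_col = "ie_tsa",
                        kcat_col = "kcat") {
  xs <- data[[ie_s_col]]; xt <- data[[ie_tsa_col]]; y0 <- data[[kcat_col]]
  if (any(y0 <= 0, na.rm = TRUE)) stop("kcat must be strictly positive")
  y <- log(y0)
  ok <- is.finite(xs) & is.finite(xt) & is.finite(y)
  if (sum(ok) < 4) stop("need at least 4 complete observations")
  d <- tibble::tibble(ie_s = xs[ok], ie_tsa = xt[ok], y = y[ok])
  if (stats::var(d$ie_s) == 0 || stats::var(d$ie_tsa) == 0 ||
      abs(stats::cor(d$ie_s, d$ie_tsa)) > 1 - 1e-12)
    stop("degenerate fit: collinear or constant predictors")
  model <- stats::lm(y ~ ie_tsa + ie_s, data = d)
  co <- stats::coef(model)
  rt_tsa <- -1 / unname(co["ie_tsa"])
  rt_s <- 1 / unname(co["ie_s"])
  physical <- is.finite(rt_tsa) && is.finite(rt_s) && rt_tsa > 0 && rt_s > 0
  if (!physical)
    warning("recovered RT constants are not both positive")
  structure(list(model = model, data = d, rt_s = rt_s, rt_tsa = rt_tsa,
                 intercept = unname(co[1]),
                 r_squared = suppressWarnings(summary(model)$r.squared),
                 physical = physical),
            class = "kcat_fit")
}

#' Predicted kinetic shifts of a mutant relative to wild type
#'
#' Within the correlating framework:
#' delta ln K_M = (IE_S - IE_S,WT) / (RT)_S;
#' delta ln(k_cat/K_M) = -(IE_TSA - IE_TSA,WT) / (RT)_TSA;
#' delta ln k_cat = delta ln(k_cat/K_M) + delta ln K_M.
#'
#' @param mutant,wildtype lists or one-row data frames with `ie_s`, `ie_tsa`
#'   (kJ/mol).
#' @param rt_s,rt_tsa effective RT constants, kJ/mol.
#' @return one-row tibble with delta_ln_km, delta_ln_efficiency,
#'   delta_ln_kcat.
#' @export
predict_deltas <- function(mutant, wildtype, rt_s = 386.7, rt_tsa = 15.3) {
  need <- function(x, f) {
    v <- x[[f]]
    if (is.null(v) || !is.finite(v)) stop("missing ", f, " value")
    v
  }
  d_ie_s <- need(mutant, "ie_s") - need(wildtype, "ie_s")
  d_ie_tsa <- need(mutant, "ie_tsa") - need(wildtype, "ie_tsa")
  d_km <- d_ie_s / rt_s
  d_eff <- -d_ie_tsa / rt_tsa
  tibble::tibble(delta_ln_km = d_km, delta_ln_efficiency = d_eff,
                 delta_ln_kcat = d_eff + d_km)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an interaction-energy correlation fit
#'
#' @param x an "ie_fit".
#' @param ... unused.
#' @return tibble with term, estimate, std.error.
#' @exportS3Method generics::tidy
tidy.ie_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model)$coefficients)
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = s[, 1], std.error = s[, 2])
}

#' @rdname tidy.ie_fit
#' @exportS3Method generics::glance
glance.ie_fit <- function(x, ...) {
  tibble::tibble(type = x$type, r_squared = x$r_squared,
                 slope = x$slope, intercept = x$intercept,
                 effective_rt = x$effective_rt,
                 effective_temperature = x$effective_temperature,
                 sign_consistent = x$sign_consistent,
                 n = nrow(x$data))
}

#' @exportS3Method generics::tidy
tidy.kcat_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$model)$coefficients)
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @exportS3Method generics::glance
glance.kcat_fit <- function(x, ...) {
  tibble::tibble(rt_s = x$rt_s, rt_tsa = x$rt_tsa,
                 intercept = x$intercept, r_squared = x$r_squared,
                 physical = x$physical, n = nrow(x$data))
}

#' @export
print.ie_fit <- function(x, ...) {
  cat("<ie_fit ", x$type, ">  slope = ", signif(x$slope, 4),
      ", R^2 = ", signif(x$r_squared, 4),
      ", effective RT = ", signif(x$effective_rt, 4), " kJ/mol (T = ",
      signif(x$effective_temperature, 4), " K)\n", sep = "")
  invisible(x)
}

#' @export
print.kcat_fit <- function(x, ...) {
  cat("<kcat_fit>  (RT)_S = ", signif(x$rt_s, 4),
      " kJ/mol, (RT)_TSA = ", signif(x$rt_tsa, 4),
      " kJ/mol, R^2 = ", signif(x$r_squared, 4), "\n", sep = "")
  invisible(x)
}

#' Scatter plot of an interaction-energy correlation fit
#'
#' @param object an "ie_fit".
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ie_fit <- function(object, ...) {
  lab <- switch(object$type, ln_km = c("IE_S (kJ/mol)", "ln K_M (mM)"),
                ln_efficiency = c("IE_TSA (kJ/mol)", "ln k_cat/K_M"))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept, colour = "steelblue") +
    ggplot2::labs(x = lab[1], y = lab[2],
                  subtitle = sprintf("R^2 = %.3f, effective RT = %.1f kJ/mol",
                                     object$r_squared, object$effective_rt)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
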