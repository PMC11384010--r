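#' Product time course container
#'
#' @param time_s strictly increasing times (s)
#' @param product product concentration (M) or absorbance (see
#'   `absorbance`)
#' @param direction assay direction, `"forward"` or `"reverse"`
#' @param absorbance if TRUE, `product` is a 340 nm absorbance trace and is
#'   converted to molar NADH-equivalent concentration with the Beer-Lambert
#'   law (extinction coefficient 6220 M^-1 cm^-1, 1 cm path)
#' @return data.frame with columns `time_s`, `product_M`, class
#'   `ak_timecourse`
#' @export
ak_timecourse <- function(time_s, product, direction = c("reverse", "forward"),
                          absorbance = FALSE) {
  direction <- match.arg(direction)
  if (length(time_s) < 10L) stop("a time course needs at least 10 points")
  if (any(diff(time_s) <= 0)) stop("times must be strictly increasing")
  if (absorbance) product <- product / 6220   # 1 cm path, NADH at 340 nm
  structure(data.frame(time_s = time_s, product_M = product),
            class = c("ak_timecourse", "data.frame"),
            direction = direction)
}

#' Initial velocity by linear fit over an early window
#'
#' Least-squares slope of product concentration against time, restricted to
#' an early window where product inhibition has not yet bent the trace.
#' The default window is the first 10 percent of the time course or the
#' first 60 s, whichever is shorter. Product formation counts positive
#' regardless of which coupled signal was recorded.
#'
#' @param tc an [ak_timecourse]
#' @param window length-2 numeric, time window (s); default as above
#' @return initial velocity v0 (M s^-1)
#' @export
fit_initial_velocity_linear <- function(tc, window = NULL) {
  stopifnot(inherits(tc, "ak_timecourse"))
  if (is.null(window)) {
    tmax <- min(tc$time_s[1] + 0.1 * diff(range(tc$time_s)),
                tc$time_s[1] + 60)
    window <- c(tc$time_s[1], tmax)
  }
  keep <- tc$time_s >= window[1] & tc$time_s <= window[2]
  if (sum(keep) < 3L) stop("fewer than 3 points in the fitting window")
  fit <- lm(product_M ~ time_s, data = tc[keep, ])
  abs(unname(coef(fit)[2]))
}

#' Fit the product-inhibited reverse time course
#'
#' In the reverse reaction (ADP + ADP -> ATP + AMP) the product AMP acts as
#' a competitive inhibitor, so product accumulation is non-linear and
#' follows `[P](t) = (v0/eta) * (1 - exp(-eta t))`: the initial slope is
#' the true initial velocity `v0` and the factor `eta` quantifies the
#' inhibition-induced curvature (`eta -> 0` recovers a straight line of
#' slope `v0`).
#'
#' Nonlinear least squares with starting values from the early slope and
#' the late-time curvature. If the fitted curvature is indistinguishable
#' from zero (relative change of the late slope under `eta` below 1e-3
#' over the observed span) the linear fit is returned with `eta = 0` and
#' `eta_zero = TRUE`.
#'
#' @param tc an [ak_timecourse] with at least 10 points
#' @return list of class `ak_inhibition_fit`: `v0` (M s^-1), `eta` (s^-1),
#'   `eta_zero` flag, `residual_norm`, and the `nls` covariance when
#'   available
#' @export
fit_product_inhibition <- function(tc) {
  stopifnot(inherits(tc, "ak_timecourse"))
  if (nrow(tc) < 10L) stop("need at least 10 points")
  t <- tc$time_s - tc$time_s[1]
  P <- tc$product_M - tc$product_M[1]
  n_early <- max(3L, ceiling(length(t) * 0.15))
  v0_guess <- abs(coef(lm(P[1:n_early] ~ t[1:n_early]))[2])
  if (!is.finite(v0_guess) || v0_guess <= 0) v0_guess <- max(P) / max(t)
  # late plateau suggests P_inf = v0/eta
  eta_guess <- if (max(P) > 0) v0_guess / max(P) * 0.5 else 1 / max(t)
  dat <- data.frame(t = t, P = P)
  fit <- tryCatch(
    nls(P ~ (v0 / eta) * (1 - exp(-eta * t)), data = dat,
        start = list(v0 = v0_guess, eta = eta_guess),
        lower = c(v0 = v0_guess * 1e-4, eta = 1e-12),
        algorithm = "port",
        control = list(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  lin_v0 <- abs(coef(lm(P ~ t))[2])
  if (is.null(fit)) {
    return(structure(list(v0 = unname(lin_v0), eta = 0, eta_zero = TRUE,
                          residual_norm = NA_real_, cov = NULL),
                     class = "ak_inhibition_fit"))
  }
  cf <- coef(fit)
  # curvature negligible over the observed span -> fall back to the line
  if (cf[["eta"]] * max(t) < 1e-3) {
    return(structure(list(v0 = unname(lin_v0), eta = 0, eta_zero = TRUE,
                          residual_norm = sqrt(sum(residuals(fit)^2)),
                          cov = NULL),
                     class = "ak_inhibition_fit"))
  }
  cv <- tryCatch(vcov(fit), error = function(e) NULL)
  structure(list(v0 = cf[["v0"]], eta = cf[["eta"]], eta_zero = FALSE,
                 residual_norm = sqrt(sum(residuals(fit)^2)), cov = cv),
            class = "ak_inhibition_fit")
}

#' Michaelis-Menten fit of initial velocities
#'
#' Fits `v = v_max * S / (K_M + S)` by nonlinear least squares, optionally
#' weighted by supplied standard errors. Starting values come from a
#' Lineweaver-Burk regression. If the largest substrate concentration does
#' not reach `2 * K_M` the result carries `saturation_warning = TRUE`.
#'
#' @param points data.frame with columns `S` (M) and `v0`; an optional
#'   `sem` column provides weights `1/sem^2`
#' @return list of class `ak_mm_fit`: `v_max`, `K_M` (M), covariance,
#'   `saturation_warning`
#' @export
fit_michaelis_menten <- function(points) {
  stopifnot(is.data.frame(points), all(c("S", "v0") %in% names(points)))
  if (nrow(points) < 4L) stop("need at least 4 concentrations")
  w <- if ("sem" %in% names(points) && all(points$sem > 0)) 1 / points$sem^2
       else rep(1, nrow(points))
  lb <- lm(I(1 / v0) ~ I(1 / S), data = points[points$v0 > 0, ])
  vmax0 <- 1 / coef(lb)[1]
  km0 <- coef(lb)[2] * vmax0
  if (!is.finite(vmax0) || vmax0 <= 0) vmax0 <- max(points$v0) * 1.2
  if (!is.finite(km0) || km0 <= 0) km0 <- median(points$S)
  fit <- nls(v0 ~ v_max * S / (K_M + S), data = points, weights = w,
             start = list(v_max = vmax0, K_M = km0),
             lower = c(v_max = 0, K_M = 0), algorithm = "port",
             control = list(maxiter = 200, warnOnly = TRUE))
  cf <- coef(fit)
  structure(list(v_max = cf[["v_max"]], K_M = cf[["K_M"]],
                 cov = tryCatch(vcov(fit), error = function(e) NULL),
                 saturation_warning = max(points$S) < 2 * cf[["K_M"]]),
            class = "ak_mm_fit")
}

#' Fit a 1:1 binding isotherm to a titration
#'
#' Fits `f(L) = baseline + amplitude * L / (L + Kd)` as measured, e.g., by
#' microscale thermophoresis. Ligand depletion is not corrected (the
#' enzyme concentration is assumed far below Kd); a warning is attached if
#' `enzyme > Kd / 10`.
#'
#' @param points data.frame with columns `L` (M) and `f` (signal, fraction
#'   bound after normalization); optional `sem` column for weights
#' @param enzyme protein concentration (M) used only for the depletion
#'   check; default `NA` skips the check
#' @return list of class `ak_isotherm_fit`: `Kd` (M), `amplitude`,
#'   `baseline`, covariance, `monotone_warning`, `depletion_warning`
#' @export
fit_isotherm <- function(points, enzyme = NA_real_) {
  stopifnot(is.data.frame(points), all(c("L", "f") %in% names(points)))
  if (nrow(points) < 5L) stop("need at least 5 ligand concentrations")
  w <- if ("sem" %in% names(points) && all(points$sem > 0)) 1 / points$sem^2
       else rep(1, nrow(points))
  f_range <- diff(range(points$f))
  base0 <- min(points$f)
  amp0 <- if (f_range > 0) f_range else 1
  ord <- order(points$L)
  half <- base0 + amp0 / 2
  kd0 <- points$L[ord][which.min(abs(points$f[ord] - half))]
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- median(points$L)
  fit <- nls(f ~ baseline + amplitude * L / (L + Kd), data = points,
             weights = w,
             start = list(Kd = kd0, amplitude = amp0, baseline = base0),
             lower = c(Kd = min(points$L) * 1e-6, amplitude = 0,
                       baseline = -Inf),
             algorithm = "port", control = list(maxiter = 200, warnOnly = TRUE))
  cf <- coef(fit)
  # non-monotone beyond noise: residual sd of a monotone isotherm vs scatter
  sm <- stats::smooth.spline(log(points$L[ord]), points$f[ord], df = 4)
  mono_warn <- any(diff(predict(sm, log(sort(points$L)))$y) < -0.05 * amp0)
  structure(list(Kd = cf[["Kd"]], amplitude = cf[["amplitude"]],
                 baseline = cf[["baseline"]],
                 cov = tryCatch(vcov(fit), error = function(e) NULL),
                 monotone_warning = mono_warn,
                 depletion_warning = is.finite(enzyme) && enzyme > cf[["Kd"]] / 10),
            class = "ak_isotherm_fit")
}
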