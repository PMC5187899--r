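#' ACE inhibition rate from chromatographic peak areas
#'
#' The inhibition rate of a sample is the fractional loss of the hippuric
#' acid (HA) product peak relative to the uninhibited control:
#' \deqn{inhibition\ (\%) = 100 \times (A_{control} - A_{sample}) /
#'   A_{control}}
#'
#' @param A_control HA peak area of the negative control (> 0).
#' @param A_sample HA peak area with inhibitor (>= 0). Vectorised.
#' @return Inhibition in percent. A sample area above the control yields a
#'   negative rate (apparent activation) with a warning, not an error.
#' @examples
#' inhibition_rate(1000, 221.4)  # 77.86
#' @export
inhibition_rate <- function(A_control, A_sample) {
  if (any(A_control <= 0)) stop("A_control must be > 0")
  if (any(A_sample < 0)) stop("peak areas must be >= 0")
  if (any(A_sample > A_control))
    warning("A_sample exceeds A_control: negative inhibition (activation)")
  100 * (A_control - A_sample) / A_control
}

#' Fit a dose-response curve and recover the IC50
#'
#' Four-parameter logistic on log10 concentration,
#' \deqn{y = bottom + (top - bottom) / (1 + 10^{h (log_{10} IC50 - x)})}
#' with the asymptotes optionally fixed at 0 and 100%. The IC50 is the
#' concentration at which the fitted curve crosses 50% inhibition (for the
#' fixed-asymptote model this is the logistic midpoint). Fitting uses
#' Levenberg-Marquardt least squares.
#'
#' @param concentration Dose values (> 0, any consistent unit);
#'   zero-concentration controls must be excluded beforehand (they define
#'   `A_control`, not a fit point).
#' @param inhibition Observed inhibition in percent.
#' @param fix_asymptotes Fix bottom = 0 and top = 100 (two-parameter fit,
#'   the default); otherwise all four parameters are estimated with bottom
#'   and top bounded to \[0, 100\].
#' @return Object of class `"ic50_fit"` with elements `ic50`, `hill`,
#'   `bottom`, `top`, `fit` (the `nls` object), `data`, `se_log_ic50`,
#'   `conf_halfwidth` (95% half-width on the IC50, same unit as input).
#' @examples
#' conc <- 10^seq(0, 3, length.out = 8)
#' y <- 100 / (1 + (61.88 / conc))
#' fit_ic50(conc, y)$ic50
#' @export
fit_ic50 <- function(concentration, inhibition, fix_asymptotes = TRUE) {
  if (length(concentration) != length(inhibition))
    stop("concentration and inhibition must have equal length")
  if (any(concentration <= 0))
    stop("concentrations must be > 0 (log scale); drop zero-dose controls")
  if (length(concentration) < 4L)
    stop("at least 4 dose-response points are required")
  if (all(inhibition <= 50) || all(inhibition >= 50))
    stop("points must span both sides of 50% inhibition; ",
         "IC50 would be an extrapolation")
  x <- log10(concentration)
  y <- inhibition
  df <- data.frame(x = x, y = y)
  # starting values: midpoint from linear interpolation, slope 1
  ord <- order(x)
  mid0 <- tryCatch(approx(y[ord], x[ord], xout = 50, ties = mean)$y,
                   error = function(e) mean(x))
  if (is.na(mid0)) mid0 <- mean(x)
  if (fix_asymptotes) {
    fit <- minpack.lm::nlsLM(
      y ~ 100 / (1 + 10^(h * (m - x))), data = df,
      start = list(m = mid0, h = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    bottom <- 0; top <- 100
    m <- coef(fit)[["m"]]; h <- coef(fit)[["h"]]
    log_ic50 <- m
  } else {
    # start strictly inside the bounds; a boundary start can pin a parameter
    b0 <- min(max(min(y), 0.01), 45)
    t0 <- max(min(max(y), 99.9), 55)
    fit <- minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(h * (m - x))), data = df,
      start = list(bottom = b0, top = t0, m = mid0, h = 1),
      lower = c(0, 0, -Inf, 0.01), upper = c(100, 100, Inf, 100),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit)
    bottom <- cf[["bottom"]]; top <- cf[["top"]]
    m <- cf[["m"]]; h <- cf[["h"]]
    if (bottom >= 50 || top <= 50)
      stop("fitted curve does not cross 50% inhibition")
    # concentration where the curve crosses 50%
    log_ic50 <- m - log10((top - bottom) / (50 - bottom) - 1) / h
  }
  se <- tryCatch(summary(fit)$coefficients["m", "Std. Error"],
                 error = function(e) NA_real_)
  ic50 <- 10^log_ic50
  halfw <- if (is.na(se)) NA_real_ else
    (10^(log_ic50 + 1.96 * se) - 10^(log_ic50 - 1.96 * se)) / 2
  structure(list(ic50 = ic50, hill = h, bottom = bottom, top = top,
                 fit = fit, data = df, se_log_ic50 = se,
                 conf_halfwidth = halfw,
                 fix_asymptotes = fix_asymptotes),
            class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat("IC50 =", format(x$ic50, digits = 5),
      "(hill =", format(x$hill, digits = 3), ")\n")
  invisible(x)
}

#' @export
summary.ic50_fit <- function(object, ...) {
  cat("Dose-response fit (",
      if (object$fix_asymptotes) "2-parameter logistic, asymptotes 0/100"
      else "4-parameter logistic", ")\n", sep = "")
  cat("  IC50:", format(object$ic50, digits = 6),
      if (!is.na(object$conf_halfwidth))
        paste0("+/- ", format(object$conf_halfwidth, digits = 3)), "\n")
  cat("  hill slope:", format(object$hill, digits = 4), "\n")
  cat("  asymptotes:", format(object$bottom, digits = 3), "to",
      format(object$top, digits = 4), "%\n")
  invisible(object)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  c(ic50 = object$ic50, hill = object$hill,
    bottom = object$bottom, top = object$top)
}

#' @export
predict.ic50_fit <- function(object, concentration, ...) {
  x <- log10(concentration)
  m <- log10(object$ic50)
  if (!object$fix_asymptotes) {
    # invert back to the raw midpoint for prediction
    cf <- coef(object$fit)
    return(cf[["bottom"]] + (cf[["top"]] - cf[["bottom"]]) /
             (1 + 10^(cf[["h"]] * (cf[["m"]] - x))))
  }
  object$bottom + (object$top - object$bottom) /
    (1 + 10^(object$hill * (m - x)))
}

#' @export
plot.ic50_fit <- function(x, ...) {
  plot(x$data$x, x$data$y, xlab = "log10 concentration",
       ylab = "inhibition (%)", pch = 19, ...)
  xs <- seq(min(x$data$x), max(x$data$x), length.out = 200)
  lines(xs, predict(x, 10^xs), col = "steelblue")
  abline(h = 50, lty = 3)
  abline(v = log10(x$ic50), lty = 3)
}

#' @export
residuals.ic50_fit <- function(object, ...) {
  object$data$y - predict(object, 10^object$data$x)
}
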