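## DIC depth-profile regression used to infer juvenile habitat depth.

#' Linear regression of DIC Delta-14C on depth within a window
#'
#' Ordinary least squares of `d14c` on `depth_m` restricted to depths
#' inside the closed `window` (both ends inclusive). The 200--600 m
#' default is the outer-shelf / upper-slope band the species occupies.
#'
#' @param profile `data.frame` with columns `depth_m` and `d14c`
#'   (a `station` column is carried along if present).
#' @param window Length-2 numeric, closed depth window in metres.
#' @return A list of class `dic_regression`: `slope` (permil per m),
#'   `intercept`, `r_squared`, `p_value` (two-sided t-test on the slope),
#'   `n`, `slope_se`, and `window`.
#' @export
fit_depth_regression <- function(profile, window = c(200, 600)) {
  if (!all(c("depth_m", "d14c") %in% names(profile)))
    stop_domain("profile needs columns depth_m, d14c")
  if (any(profile$depth_m <= 0)) stop_domain("depths must be > 0")
  inw <- profile$depth_m >= window[1] & profile$depth_m <= window[2]
  if (sum(inw) < 3)
    stop_domain("insufficient data: < 3 points inside [",
                window[1], ", ", window[2], "] m")
  d <- profile[inw, , drop = FALSE]
  fit <- lm(d14c ~ depth_m, data = d)
  sm <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients["depth_m", "Pr(>|t|)"],
                 n = nrow(d),
                 slope_se = sm$coefficients["depth_m", "Std. Error"],
                 window = window),
            class = "dic_regression")
}

#' @export
print.dic_regression <- function(x, ...) {
  cat(sprintf(
    "DIC depth regression, %g-%g m (n = %d):\n  slope %.4g permil/m (SE %.3g), R^2 = %.3f, p = %.3g\n",
    x$window[1], x$window[2], x$n, x$slope, x$slope_se, x$r_squared, x$p_value))
  cat(sprintf("  = %.1f permil per 100 m of depth\n", slope_per_100m(x$slope)))
  invisible(x)
}

#' Convert a per-metre slope to permil per 100 m
#'
#' @param slope Slope in permil per metre.
#' @return Slope in permil per 100 m.
#' @export
#' @examples
#' slope_per_100m(-0.289)  # -28.9, i.e. about -29 permil per 100 m
slope_per_100m <- function(slope) {
  if (!is.numeric(slope) || any(!is.finite(slope)))
    stop_domain("slope must be finite")
  slope * 100
}
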