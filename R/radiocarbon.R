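## Bomb-radiocarbon age validation.
##
## The chronometer: fit a loess reference curve to coral / known-age
## otolith Delta-14C versus year of formation, place otolith-core values at
## their estimated birth years, test whether the residuals are consistent
## with zero, and profile the sum of squared residuals under purposeful
## age shifts.

#' Birth year (year of formation) from collection date and estimated age
#'
#' Year of formation equals the calendar year of collection minus the
#' estimated age; months are ignored.
#'
#' @param collection_date `Date`, date-parseable string, or numeric year.
#' @param age_years Integer age estimate (>= 0).
#' @return Integer calendar year.
#' @export
#' @examples
#' birth_year("2017-02-09", 59)  # 1958
birth_year <- function(collection_date, age_years) {
  if (any(age_years < 0)) stop_domain("age must be >= 0")
  yr <- if (is.numeric(collection_date)) collection_date
        else as.integer(format(parse_dates(collection_date), "%Y"))
  as.integer(yr - age_years)
}

# accepts ISO 8601 and MM/DD/YYYY
parse_dates <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  us <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)
  out[us] <- as.Date(x[us], format = "%m/%d/%Y")
  if (anyNA(out[!is.na(x)]))
    stop_domain("unparseable date(s): ",
                paste(unique(x[is.na(out) & !is.na(x)]), collapse = ", "))
  out
}

#' Read otolith-core radiocarbon samples and audit their birth years
#'
#' Reads a CSV with columns `sample_id, analysis_id, tl_mm, oto_mass_mg,
#' sample_date, year_of_formation, age_years, d13c, d14c, d14c_sd`
#' (`year_of_formation`, `analysis_id`, `d13c`, `oto_mass_mg` optional;
#' `"NM"`, `"--"` and empty cells are treated as missing). The year of
#' formation is always recomputed as collection year minus age; when the
#' file also carries a printed year of formation, rows whose printed year
#' disagrees with the recomputed one are flagged in `year_mismatch` --
#' they are never silently corrected.
#'
#' @param path CSV path.
#' @return A `data.frame` of samples with recomputed `year_of_formation`,
#'   a `printed_year` column when present, and logical `year_mismatch`.
#' @export
read_core_samples <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("NA", "NM", "--", ""))
  need <- c("sample_id", "sample_date", "age_years", "d14c", "d14c_sd")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_domain("core-sample CSV lacks column(s): ", paste(miss, collapse = ", "))
  if (any(raw$d14c_sd <= 0, na.rm = TRUE)) stop_domain("d14c_sd must be > 0")
  if (any(raw$age_years < 1, na.rm = TRUE)) stop_domain("age_years must be >= 1")
  printed <- if ("year_of_formation" %in% names(raw))
    as.integer(raw$year_of_formation) else NULL
  raw$collection_year <- as.integer(format(parse_dates(raw$sample_date), "%Y"))
  raw$year_of_formation <- birth_year(raw$collection_year, raw$age_years)
  if (!is.null(printed)) {
    raw$printed_year <- printed
    raw$year_mismatch <- !is.na(printed) & printed != raw$year_of_formation
  } else {
    raw$year_mismatch <- FALSE
  }
  raw
}

## loess reference curve -----------------------------------------------------

#' Fit the loess reference curve to a Delta-14C time series
#'
#' Local quadratic regression with tricube weights and
#' span = fraction-of-points bandwidth, computed exactly
#' (`surface = "direct"`), i.e. the classical loess of the reference
#' implementation in R. Defaults (degree 2, span 0.20) are the settings
#' used for coral-otolith reference series.
#'
#' @param series `data.frame` with columns `year` and `d14c` (>= 10 rows).
#' @param degree Local polynomial degree.
#' @param span Fraction of points in each local window.
#' @return An object of class `loess_fit` with elements `model`, `range`,
#'   `degree`, `span`.
#' @export
fit_loess <- function(series, degree = 2, span = 0.20) {
  if (!all(c("year", "d14c") %in% names(series)))
    stop_domain("series needs columns year, d14c")
  series <- series[is.finite(series$year) & is.finite(series$d14c), ]
  n <- nrow(series)
  if (n < 10) stop_domain("reference series needs >= 10 points")
  if (floor(span * n) < degree + 2)
    stop_domain("too few points per local window: need floor(span*n) >= degree+2")
  model <- loess(d14c ~ year, data = series, span = span, degree = degree,
                 family = "gaussian",
                 control = loess.control(surface = "direct"))
  structure(list(model = model, range = range(series$year),
                 degree = degree, span = span),
            class = "loess_fit")
}

#' Evaluate a fitted reference curve
#'
#' @param object A `loess_fit`.
#' @param years Years inside the fitted range (extrapolation is an error).
#' @param se Also return standard errors?
#' @param ... Unused.
#' @return Numeric vector of fitted Delta-14C, or a list with `fit`, `se`,
#'   `df` when `se = TRUE`.
#' @export
predict.loess_fit <- function(object, years, se = FALSE, ...) {
  if (any(years < object$range[1] - 1e-9 | years > object$range[2] + 1e-9))
    stop_domain("extrapolation: query year(s) outside the fitted range [",
                object$range[1], ", ", object$range[2], "]")
  p <- predict(object$model, data.frame(year = years), se = se)
  if (!se) as.numeric(p)
  else list(fit = as.numeric(p$fit), se = as.numeric(p$se.fit), df = p$df)
}

#' Bonferroni-corrected confidence band around the reference curve
#'
#' Pointwise t-intervals at per-comparison level `family_alpha / m`, so the
#' band holds simultaneously over the `m` comparisons at family level
#' `family_alpha`. `m` defaults to the number of years queried, the number
#' of otolith-core samples being compared.
#'
#' @param fit A `loess_fit`.
#' @param years Query years within the fitted range.
#' @param family_alpha Familywise error level.
#' @param m Number of comparisons (>= 1).
#' @return `data.frame` with `year`, `mean`, `lo`, `hi`.
#' @export
predict_with_bonferroni_ci <- function(fit, years, family_alpha = 0.05,
                                       m = length(years)) {
  if (m < 1) stop_domain("m must be >= 1")
  p <- predict(fit, years, se = TRUE)
  tcrit <- qt(1 - family_alpha / (2 * m), p$df)
  data.frame(year = years, mean = p$fit,
             lo = p$fit - tcrit * p$se, hi = p$fit + tcrit * p$se)
}

## residual analysis ---------------------------------------------------------

#' Test otolith-core values against the reference curve
#'
#' Residuals are observed core Delta-14C minus the curve at the estimated
#' birth year. Samples whose birth year falls outside the reference range
#' (e.g. pre-bomb birth years before the series starts) cannot be compared
#' and are reported separately, not dropped silently. The report carries a
#' Shapiro-Wilk normality p-value, a Levene p-value for homogeneity of
#' variance between early and late birth years (split at the median year),
#' and a one-sample t-test that the mean residual is zero; `consistent` is
#' the t-test verdict at `alpha`.
#'
#' @param fit A `loess_fit`.
#' @param samples `data.frame` with `year_of_formation` and `d14c`
#'   (e.g. from [read_core_samples()]).
#' @param alpha Significance level.
#' @return Object of class `radiocarbon_residual_test`: a list with
#'   `residuals`, `shapiro_p`, `levene_p`, `mean_zero_p`, `consistent`,
#'   `n`, and `excluded` (rows outside the reference range).
#' @export
residual_test <- function(fit, samples, alpha = 0.05) {
  if (!all(c("year_of_formation", "d14c") %in% names(samples)))
    stop_domain("samples need columns year_of_formation, d14c")
  inside <- samples$year_of_formation >= fit$range[1] &
    samples$year_of_formation <= fit$range[2]
  excluded <- samples[!inside, , drop = FALSE]
  comp <- samples[inside, , drop = FALSE]
  if (nrow(comp) < 3)
    stop_domain("insufficient data: < 3 samples within the reference range")
  res <- comp$d14c - predict(fit, comp$year_of_formation)
  grp <- factor(comp$year_of_formation > median(comp$year_of_formation),
                levels = c(FALSE, TRUE), labels = c("early", "late"))
  if (sd(res) == 0) {
    shapiro_p <- NA_real_
    levene_p <- NA_real_
    mean_zero_p <- if (isTRUE(all.equal(mean(res), 0))) 1 else 0
  } else {
    shapiro_p <- shapiro.test(res)$p.value
    levene_p <- if (nlevels(droplevels(grp)) == 2 && min(table(grp)) >= 2)
      car::leveneTest(res, grp)[1, "Pr(>F)"] else NA_real_
    mean_zero_p <- t.test(res, mu = 0)$p.value
  }
  structure(list(residuals = data.frame(year_of_formation = comp$year_of_formation,
                                        d14c = comp$d14c, residual = res),
                 shapiro_p = shapiro_p, levene_p = levene_p,
                 mean_zero_p = mean_zero_p, alpha = alpha,
                 consistent = mean_zero_p >= alpha,
                 n = nrow(comp), excluded = excluded),
            class = "radiocarbon_residual_test")
}

#' @export
print.radiocarbon_residual_test <- function(x, ...) {
  cat("Radiocarbon residual test (n =", x$n, "comparable samples)\n")
  cat(sprintf("  mean residual: %.2f permil\n", mean(x$residuals$residual)))
  cat(sprintf("  Shapiro-Wilk p = %.3f, Levene p = %.3f, mean-zero t p = %.3f\n",
              x$shapiro_p, x$levene_p, x$mean_zero_p))
  cat("  consistent with reference at alpha =", x$alpha, ":",
      x$consistent, "\n")
  if (nrow(x$excluded))
    cat("  excluded (birth year outside reference range):",
        nrow(x$excluded), "sample(s)\n")
  invisible(x)
}

## SSR age-bias profile ------------------------------------------------------

# invert the fitted curve on its monotone rise segment; values below the
# segment are assigned the rise-start year and flagged
invert_on_rise <- function(fit, d14c) {
  yrs <- seq(fit$range[1], fit$range[2], by = 0.05)
  f <- predict(fit, yrs)
  ipk <- which.max(f)
  imin <- which.min(f[seq_len(ipk)])
  yrs <- yrs[imin:ipk]
  f <- cummax(f[imin:ipk])  # enforce monotone rise for inversion
  keep <- !duplicated(f)
  year <- approx(f[keep], yrs[keep], xout = d14c, rule = 1)$y
  flagged <- d14c < f[1] | d14c > f[length(f)]
  year[d14c < f[1]] <- yrs[1]
  year[d14c > f[length(f)]] <- yrs[length(yrs)]
  list(year = year, flagged = flagged)
}

#' Sum-of-squared-residual profile under purposeful age shifts
#'
#' Ages are shifted by whole years (`shift` > 0 makes fish older, i.e.
#' moves the birth year earlier); the profile of SSR against shift should
#' be minimised at zero shift when ageing is unbiased. Two residual
#' definitions are computed: `"d14c"` (primary) sums squared differences
#' between observed core Delta-14C and the curve at the shifted birth
#' year; `"birth_year"` inverts the curve on its monotone rise segment and
#' sums squared differences between predicted and shifted birth years.
#' Shifted birth years outside the reference range are clipped to it.
#'
#' @param fit A `loess_fit`.
#' @param samples `data.frame` with `year_of_formation` and `d14c`.
#' @param shifts Integer age shifts, default -3:3.
#' @return Object of class `shift_profile`: `data.frame` with `shift`,
#'   `ssr_d14c`, `ssr_birth_year`, plus attributes `best_shift`
#'   (minimising `ssr_d14c`) and `n_inverse_flagged`.
#' @export
ssr_bias_profile <- function(fit, samples, shifts = -3:3) {
  if (!all(c("year_of_formation", "d14c") %in% names(samples)))
    stop_domain("samples need columns year_of_formation, d14c")
  inv <- invert_on_rise(fit, samples$d14c)
  rows <- lapply(shifts, function(s) {
    by_shift <- pmin(pmax(samples$year_of_formation - s, fit$range[1]),
                     fit$range[2])
    data.frame(shift = s,
               ssr_d14c = sum((samples$d14c - predict(fit, by_shift))^2),
               ssr_birth_year = sum((inv$year - by_shift)^2))
  })
  out <- do.call(rbind, rows)
  structure(out,
            best_shift = out$shift[which.min(out$ssr_d14c)],
            n_inverse_flagged = sum(inv$flagged),
            class = c("shift_profile", "data.frame"))
}
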