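## Synthetic-data generators.
##
## Every downstream stage of the package can be exercised on data produced
## here: a bomb-pulse radiocarbon reference series, a fished population
## sample drawn from the equilibrium catch composition, double age reads
## with reader error, and a DIC depth profile. All generators take explicit
## integer seeds and never touch the caller's RNG stream.

#' Configuration for the synthetic bomb-pulse reference curve
#'
#' The noiseless mean is flat at `prebomb_level` before `rise_start_year`,
#' rises monotonically to (`peak_year`, `peak_level`) and declines
#' monotonically to (`end_year`, `end_level`). Each monotone segment is a
#' cubic smoothstep, so the curve is C1 with zero slope at the anchors --
#' a convenient stand-in for the smooth rise and decline of marine
#' radiocarbon through the nuclear-testing era. Default anchor levels are
#' chosen so that pre-bomb, peak and decline values are consistent with
#' published Gulf of Mexico coral and known-age otolith series
#' (about -55 permil pre-bomb, +140 permil at the mid-1970s peak, declining
#' to about +45 permil by 2015).
#'
#' @param prebomb_level Pre-bomb plateau, permil.
#' @param rise_start_year Calendar year the rise begins.
#' @param peak_year Calendar year of the peak.
#' @param peak_level Peak Delta-14C, permil.
#' @param end_year Last year of the series.
#' @param end_level Delta-14C at `end_year`, permil.
#' @param noise_sd Gaussian observation noise, permil (>= 0).
#' @param n_points Number of (year, Delta-14C) points generated (>= 4).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return An object of class `bomb_curve_config`.
#' @export
bomb_curve_config <- function(prebomb_level = -55, rise_start_year = 1959,
                              peak_year = 1974, peak_level = 140,
                              end_year = 2015, end_level = 45,
                              noise_sd = 6, n_points = 150, seed = NULL) {
  if (!(rise_start_year < peak_year && peak_year < end_year))
    stop_domain("invalid year ordering: need rise_start_year < peak_year < end_year")
  if (noise_sd < 0) stop_domain("noise_sd must be >= 0")
  if (n_points < 4) stop_domain("n_points must be >= 4")
  structure(list(prebomb_level = prebomb_level,
                 rise_start_year = rise_start_year,
                 peak_year = peak_year, peak_level = peak_level,
                 end_year = end_year, end_level = end_level,
                 noise_sd = noise_sd, n_points = n_points, seed = seed),
            class = "bomb_curve_config")
}

# cubic smoothstep on [0, 1]
smoothstep <- function(u) u * u * (3 - 2 * u)

#' Noiseless mean of the synthetic bomb curve
#'
#' @param config A [bomb_curve_config()].
#' @param years Numeric vector of calendar years.
#' @return Mean Delta-14C (permil) at `years`.
#' @export
bomb_curve_mean <- function(config, years) {
  stopifnot(inherits(config, "bomb_curve_config"))
  out <- numeric(length(years))
  pre <- years <= config$rise_start_year
  out[pre] <- config$prebomb_level
  ris <- years > config$rise_start_year & years <= config$peak_year
  u <- (years[ris] - config$rise_start_year) /
    (config$peak_year - config$rise_start_year)
  out[ris] <- config$prebomb_level +
    (config$peak_level - config$prebomb_level) * smoothstep(u)
  dec <- years > config$peak_year
  u <- pmin((years[dec] - config$peak_year) /
              (config$end_year - config$peak_year), 1)
  out[dec] <- config$peak_level +
    (config$end_level - config$peak_level) * smoothstep(u)
  out
}

#' Generate a synthetic coral/otolith Delta-14C reference series
#'
#' Years are equally spaced from 14 years before the rise to `end_year`,
#' so the pre-bomb plateau is represented in the series as it is in the
#' coral record.
#'
#' @param config A [bomb_curve_config()].
#' @return A `data.frame` with columns `year`, `d14c`, `source`
#'   (here always `"synthetic"`), sorted by year.
#' @export
generate_reference_series <- function(config) {
  stopifnot(inherits(config, "bomb_curve_config"))
  years <- seq(config$rise_start_year - 14, config$end_year,
               length.out = config$n_points)
  mean_d14c <- bomb_curve_mean(config, years)
  d14c <- with_seed(config$seed,
                    mean_d14c + rnorm(length(years), 0, config$noise_sd))
  data.frame(year = years, d14c = d14c, source = "synthetic",
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic DIC depth profile
#'
#' The noiseless mean equals `surface_level` down to `mixed_layer_depth`
#' and declines linearly with `slope` below it. Default slope matches the
#' observed northern Gulf of Mexico decline of -0.289 permil per metre over
#' the 200--600 m band; defaults place 11 of the sampled depths inside that
#' band, mirroring the sampling design the regression is applied to.
#'
#' @param surface_level Mixed-layer Delta-14C, permil.
#' @param mixed_layer_depth Mixed-layer depth, m.
#' @param slope Decline below the mixed layer, permil per metre.
#' @param max_depth Deepest sampled depth, m.
#' @param noise_sd Gaussian noise, permil.
#' @param n_points Number of sampled depths (>= 8).
#' @param seed Integer seed or `NULL`.
#' @return An object of class `dic_profile_config`.
#' @export
dic_profile_config <- function(surface_level = 60, mixed_layer_depth = 200,
                               slope = -0.289, max_depth = 1248,
                               noise_sd = 5, n_points = 21, seed = NULL) {
  if (!(mixed_layer_depth < max_depth))
    stop_domain("mixed_layer_depth must be < max_depth")
  if (!is.finite(slope)) stop_domain("slope must be finite")
  if (noise_sd < 0) stop_domain("noise_sd must be >= 0")
  if (n_points < 8) stop_domain("n_points must be >= 8")
  structure(list(surface_level = surface_level,
                 mixed_layer_depth = mixed_layer_depth, slope = slope,
                 max_depth = max_depth, noise_sd = noise_sd,
                 n_points = n_points, seed = seed),
            class = "dic_profile_config")
}

#' Noiseless mean of the synthetic DIC profile
#'
#' @param config A [dic_profile_config()].
#' @param depth Numeric vector of depths, m.
#' @return Mean Delta-14C (permil) at `depth`.
#' @export
dic_profile_mean <- function(config, depth) {
  stopifnot(inherits(config, "dic_profile_config"))
  ifelse(depth <= config$mixed_layer_depth, config$surface_level,
         config$surface_level + config$slope * (depth - config$mixed_layer_depth))
}

# sampled depths: ~30% in the mixed layer, ~50% in the 200-600 m band the
# regression uses (11 of the default 21), remainder on the deep limb
dic_depths <- function(config) {
  n <- config$n_points
  n_win <- max(3L, round(0.52 * n))
  n_up <- max(2L, round(0.29 * n))
  n_deep <- n - n_win - n_up
  up <- seq(5, config$mixed_layer_depth - 25, length.out = n_up)
  win <- seq(config$mixed_layer_depth, 600, length.out = n_win)
  deep <- if (n_deep > 0)
    seq(650, config$max_depth, length.out = n_deep) else numeric(0)
  sort(c(up, win, deep))
}

#' Generate a synthetic DIC Delta-14C depth profile
#'
#' @param config A [dic_profile_config()].
#' @return A `data.frame` with columns `station`, `depth_m`, `d14c`.
#' @export
generate_dic_profile <- function(config) {
  stopifnot(inherits(config, "dic_profile_config"))
  depth <- dic_depths(config)
  d14c <- with_seed(config$seed,
                    dic_profile_mean(config, depth) +
                      rnorm(length(depth), 0, config$noise_sd))
  data.frame(station = "SYN-1", depth_m = depth, d14c = d14c,
             stringsAsFactors = FALSE)
}

#' Reader ageing-error model
#'
#' Reader error is Gaussian on the age scale with standard deviation
#' proportional to true age, rounded to whole opaque-zone counts and
#' floored at 1 y. `bias` is a systematic shift (years) applied to the
#' second reader.
#'
#' @param sd_per_year Error SD as a fraction of true age (>= 0).
#' @param bias Systematic shift, years, added to reader 2.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `reader_error_model`.
#' @export
reader_error_model <- function(sd_per_year = 0.08, bias = 0, seed = NULL) {
  if (sd_per_year < 0) stop_domain("sd_per_year must be >= 0")
  structure(list(sd_per_year = sd_per_year, bias = bias, seed = seed),
            class = "reader_error_model")
}

#' Generate double age reads with reader error
#'
#' @param true_ages Integer vector of true ages (all >= 1).
#' @param model A [reader_error_model()].
#' @return A `data.frame` with columns `read1`, `read2`, one row per fish
#'   (empty input gives an empty frame).
#' @export
generate_double_reads <- function(true_ages, model = reader_error_model()) {
  stopifnot(inherits(model, "reader_error_model"))
  if (length(true_ages) == 0)
    return(data.frame(read1 = integer(0), read2 = integer(0)))
  if (any(true_ages < 1)) stop_domain("true ages must be >= 1")
  n <- length(true_ages)
  sds <- model$sd_per_year * true_ages
  reads <- with_seed(model$seed, {
    r1 <- round(true_ages + rnorm(n, 0, sds))
    r2 <- round(true_ages + model$bias + rnorm(n, 0, sds))
    list(r1 = pmax(as.integer(r1), 1L), r2 = pmax(as.integer(r2), 1L))
  })
  data.frame(read1 = reads$r1, read2 = reads$r2)
}

#' Generate synthetic otolith-core radiocarbon samples
#'
#' Draws birth years spanning the rise and decline of the bomb curve,
#' assigns ages and collection dates consistent with them, and sets core
#' Delta-14C to the curve mean plus curve-level noise -- i.e. samples from
#' a population whose age estimates are unbiased, the null case of the
#' validation machinery.
#'
#' @param bomb_config A [bomb_curve_config()] describing the true curve.
#' @param n Number of cored otoliths.
#' @param seed Integer seed or `NULL`.
#' @return A `data.frame` with columns `sample_id`, `tl_mm`, `sample_date`,
#'   `age_years`, `year_of_formation`, `d14c`, `d14c_sd`.
#' @export
generate_core_samples <- function(bomb_config, n = 14, seed = NULL) {
  stopifnot(inherits(bomb_config, "bomb_curve_config"))
  if (n < 1) stop_domain("n must be >= 1")
  with_seed(seed, {
    by <- round(seq(bomb_config$rise_start_year + 1,
                    bomb_config$end_year - 10, length.out = n))
    age <- sample(3:50, n, replace = TRUE)
    cyear <- pmin(by + age, bomb_config$end_year)
    age <- cyear - by
    d14c <- bomb_curve_mean(bomb_config, by) +
      rnorm(n, 0, bomb_config$noise_sd)
    data.frame(sample_id = sprintf("SYN-CORE-%02d", seq_len(n)),
               tl_mm = round(500 + 25 * age + rnorm(n, 0, 100)),
               sample_date = sprintf("%d-06-15", cyear),
               age_years = age,
               year_of_formation = as.integer(by),
               d14c = round(d14c, 2),
               d14c_sd = round(runif(n, 1.9, 5.3), 1),
               stringsAsFactors = FALSE)
  })
}

#' Generate a fished population sample of aged fish
#'
#' Draws (age, length) pairs from the equilibrium catch composition implied
#' by `params` (see [catch_composition()]), i.e. the distribution a
#' size-selective fishery samples from, and dresses them as fish records
#' with collection dates and otolith masses. Otolith mass grows roughly
#' linearly with age with lognormal scatter, mimicking the strong
#' mass-at-age relationship used to pick old fish for coring.
#'
#' @param params A [growth_params()] object.
#' @param n Number of fish (>= 1).
#' @param seed Integer seed or `NULL`.
#' @param years Collection-year range to assign, default 1980:2017.
#' @return A `data.frame` with columns `fish_id`, `collection_date`,
#'   `tl_mm`, `oto_mass_mg`, `age_years`.
#' @export
generate_population_sample <- function(params, n, seed = NULL,
                                       years = 1980:2017) {
  stopifnot(inherits(params, "growth_params"))
  if (n < 1) stop_domain("n must be >= 1")
  catch <- simulate_catch(params, n, seed = seed)
  extras <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
    yr <- sample(years, n, replace = TRUE)
    doy <- sample(1:365, n, replace = TRUE)
    mass <- 0.033 * catch$age_years * exp(rnorm(n, 0, 0.15))
    list(yr = yr, doy = doy, mass = mass)
  })
  data.frame(fish_id = sprintf("SYN-%05d", seq_len(n)),
             collection_date = as.Date(extras$doy - 1,
                                       origin = paste0(extras$yr, "-01-01")),
             tl_mm = catch$tl_mm,
             oto_mass_mg = round(extras$mass, 3),
             age_years = catch$age_years,
             stringsAsFactors = FALSE)
}
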