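## Equilibrium growth/selectivity/mortality model.
##
## The population is represented by G growth-type groups: each group
## carries a persistent relative deviation from the mean von Bertalanffy
## length-at-age, survives under natural mortality plus size-selective
## fishing mortality, and contributes to the catch in proportion to its
## survivorship times its vulnerability. Binning the group lengths over a
## fixed age x length-bin grid gives the multinomial cell probabilities
## that length-age observations are fitted against.

PARAM_NAMES <- c("linf", "k", "t0", "cv_len", "l50", "sel_steepness",
                 "m_nat", "f_mort")

#' Growth, selectivity and mortality parameters
#'
#' The eight quantities of the model: von Bertalanffy `linf` (mm TL),
#' `k` (per year), `t0` (years), the CV of length at age `cv_len`,
#' logistic selectivity midpoint `l50` (mm TL) and spread `sel_steepness`
#' (mm), and instantaneous natural (`m_nat`) and fishing (`f_mort`)
#' mortality (per year). All must be strictly positive (the model works on
#' the log scale); `cv_len` must be < 1.
#'
#' @param linf,k,t0,cv_len,l50,sel_steepness,m_nat,f_mort See description.
#' @return Object of class `growth_params` (a named numeric vector).
#' @export
growth_params <- function(linf, k, t0, cv_len, l50, sel_steepness,
                          m_nat, f_mort) {
  p <- c(linf = linf, k = k, t0 = t0, cv_len = cv_len, l50 = l50,
         sel_steepness = sel_steepness, m_nat = m_nat, f_mort = f_mort)
  if (any(!is.finite(p)) || any(p <= 0))
    stop_domain("all eight parameters must be finite and strictly positive")
  if (p[["cv_len"]] >= 1) stop_domain("cv_len must be < 1")
  structure(p, class = "growth_params")
}

#' Log-normal prior specification
#'
#' One row per parameter: the natural-scale `median` and the standard
#' deviation `log_sd` of the log-parameter. Defaults are the priors used
#' for the northern Gulf of Mexico fit: weak (log-SD 2-5) priors on the
#' growth, length-CV and selectivity parameters, an informative prior on
#' natural mortality centred on the longevity-based estimate 0.069 / y
#' with log-SD 0.1, and a weak prior on fishing mortality.
#'
#' @param medians Named numeric of natural-scale medians (names as in
#'   [growth_params()]).
#' @param log_sds Named numeric of log-scale SDs (> 0).
#' @return `data.frame` of class `prior_spec` with columns `parameter`,
#'   `median`, `log_sd`.
#' @export
growth_priors <- function(medians = c(linf = 1618, k = 0.13, t0 = 0.2,
                                      cv_len = 0.12, l50 = 880,
                                      sel_steepness = 5, m_nat = 0.069,
                                      f_mort = 0.2),
                          log_sds = c(linf = 5, k = 2, t0 = 2, cv_len = 2,
                                      l50 = 5, sel_steepness = 2,
                                      m_nat = 0.1, f_mort = 2)) {
  medians <- medians[PARAM_NAMES]
  log_sds <- log_sds[PARAM_NAMES]
  if (anyNA(medians) || anyNA(log_sds))
    stop_domain("priors must name all eight parameters")
  if (any(log_sds <= 0)) stop_domain("log_sd must be > 0")
  if (any(medians <= 0)) stop_domain("prior medians must be > 0")
  structure(data.frame(parameter = PARAM_NAMES, median = unname(medians),
                       log_sd = unname(log_sds), stringsAsFactors = FALSE),
            class = c("prior_spec", "data.frame"))
}

#' Mean von Bertalanffy length at age
#'
#' mu_a = linf (1 - exp(-k (age - t0))), floored at 1 mm so lengths stay
#' positive below t0.
#'
#' @param params A [growth_params()] object.
#' @param age Age(s), years (> 0).
#' @return Mean length(s), mm TL.
#' @export
vbgf_mean_length <- function(params, age) {
  stopifnot(inherits(params, "growth_params"))
  if (any(age <= 0)) stop_domain("age must be > 0")
  pmax(params[["linf"]] * (1 - exp(-params[["k"]] * (age - params[["t0"]]))), 1)
}

#' Logistic gear selectivity
#'
#' V(l) = 1 / (1 + exp(-(l - l50) / gamma)) with spread gamma =
#' `sel_steepness` in mm; V(l50) = 0.5 and V is strictly increasing.
#'
#' @param params A [growth_params()] object.
#' @param length Length(s), mm TL (>= 0).
#' @return Selectivity in (0, 1).
#' @export
logistic_selectivity <- function(params, length) {
  stopifnot(inherits(params, "growth_params"))
  if (params[["sel_steepness"]] <= 0) stop_domain("sel_steepness must be > 0")
  if (any(length < 0)) stop_domain("length must be >= 0")
  1 / (1 + exp(-(length - params[["l50"]]) / params[["sel_steepness"]]))
}

#' Equilibrium catch-composition grid
#'
#' Builds the age x length-bin probability grid a size-selective fishery
#' samples from, assuming stable recruitment and mortality. G equal-weight
#' growth groups carry persistent deviations delta_g =
#' qnorm((g - 0.5) / G) * cv_len; group length at age is
#' mu_a (1 + delta_g), floored at 1 mm. Survivorship starts at 1 at age 1
#' and decays by exp(-(M + F V(l))) per year. Catch mass
#' w_g S_ga V(l_ga) is shared linearly between the two length bins whose
#' centres bracket l_ga, which keeps every cell probability continuous in
#' the parameters; a smoothing constant `eps` is then added to each cell
#' and the grid normalised.
#'
#' @param params A [growth_params()] object.
#' @param max_age Oldest modelled age A (ages 1..A).
#' @param bin_width Length-bin width, mm.
#' @param max_length Upper edge of the last bin, mm.
#' @param n_growth_groups Number of growth-type groups G.
#' @param eps Smoothing constant added to every cell.
#' @return Object of class `catch_composition`: the A x B probability
#'   matrix with attributes `ages`, `bin_mid`, `bin_width`, `params`.
#' @export
catch_composition <- function(params, max_age = 65L, bin_width = 50,
                              max_length = 2500, n_growth_groups = 21L,
                              eps = 1e-10) {
  stopifnot(inherits(params, "growth_params"))
  A <- as.integer(max_age)
  G <- as.integer(n_growth_groups)
  nb <- as.integer(round(max_length / bin_width))
  ages <- seq_len(A)
  mu <- vbgf_mean_length(params, ages)
  delta <- qnorm((seq_len(G) - 0.5) / G) * params[["cv_len"]]
  L <- pmax(outer(1 + delta, mu), 1)                       # G x A
  V <- 1 / (1 + exp(-(L - params[["l50"]]) / params[["sel_steepness"]]))
  cz <- apply(params[["m_nat"]] + params[["f_mort"]] * V, 1, cumsum)  # A x G
  S <- t(exp(-rbind(0, cz[-A, , drop = FALSE])))           # G x A
  C <- S * V / G
  pos <- pmin(pmax(L / bin_width + 0.5, 1), nb)  # bin-centre coordinates
  b0 <- pmin(floor(pos), nb - 1L)
  fr <- pos - b0
  P <- matrix(0, A, nb)
  # cell indices are unique within a growth group (one age, two distinct
  # bins), so accumulation can be vectorised per group
  for (g in seq_len(G)) {
    lo <- (b0[g, ] - 1L) * A + ages
    hi <- lo + A
    idx <- c(lo, hi)
    P[idx] <- P[idx] + c(C[g, ] * (1 - fr[g, ]), C[g, ] * fr[g, ])
  }
  P <- P + eps
  P <- P / sum(P)
  structure(P, ages = ages, bin_mid = (seq_len(nb) - 0.5) * bin_width,
            bin_width = bin_width, params = params,
            class = "catch_composition")
}

# observation (age, length) -> linear cell index of a composition grid
composition_cells <- function(grid, age, length) {
  A <- nrow(grid)
  nb <- ncol(grid)
  w <- attr(grid, "bin_width")
  if (any(age < 1 | age > A | age != round(age)))
    stop_domain("observation age(s) outside grid (integer 1..", A, ")")
  if (any(length <= 0 | length > nb * w))
    stop_domain("observation length(s) outside grid (0, ", nb * w, "]")
  bin <- pmin(pmax(ceiling(length / w), 1L), nb)
  (bin - 1L) * A + as.integer(age)
}

#' Multinomial log-likelihood of length-age observations
#'
#' Sum of log cell probabilities of the composition grid at the observed
#' (age, length-bin) cells.
#'
#' @param params A [growth_params()] object.
#' @param observations `data.frame` with columns `age_years` and `tl_mm`.
#' @param ... Grid settings passed to [catch_composition()].
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(params, observations, ...) {
  grid <- catch_composition(params, ...)
  cells <- composition_cells(grid, observations$age_years, observations$tl_mm)
  sum(log(grid[cells]))
}

#' Log-normal log-prior density
#'
#' Sum over the eight parameters of the normal log-density of
#' log(theta) at mean log(median) and SD log_sd. Non-positive parameter
#' values have log-prior -Inf.
#'
#' @param params A [growth_params()] object (or named positive vector).
#' @param priors A [growth_priors()] spec.
#' @return Log-prior (scalar; `-Inf` for non-positive parameters).
#' @export
log_prior <- function(params, priors = growth_priors()) {
  stopifnot(inherits(priors, "prior_spec"))
  th <- unclass(params)[PARAM_NAMES]
  if (any(!is.finite(th)) || any(th <= 0)) return(-Inf)
  sum(dnorm(log(th), log(priors$median), priors$log_sd, log = TRUE))
}

#' Simulate length-age catch samples from the composition grid
#'
#' Cells are drawn multinomially with the grid probabilities; length is
#' drawn uniformly within the drawn bin.
#'
#' @param params A [growth_params()] object.
#' @param n Number of fish (>= 1).
#' @param seed Integer seed or `NULL`.
#' @param ... Grid settings passed to [catch_composition()].
#' @return `data.frame` with columns `age_years`, `tl_mm`.
#' @export
simulate_catch <- function(params, n, seed = NULL, ...) {
  if (n < 1) stop_domain("n must be >= 1")
  grid <- catch_composition(params, ...)
  A <- nrow(grid)
  w <- attr(grid, "bin_width")
  with_seed(seed, {
    cells <- sample.int(length(grid), n, replace = TRUE, prob = as.vector(grid))
    age <- ((cells - 1L) %% A) + 1L
    bin <- ((cells - 1L) %/% A) + 1L
    data.frame(age_years = age, tl_mm = (bin - 1L) * w + runif(n) * w)
  })
}

#' Longevity-based natural mortality (Hewitt-Hoenig)
#'
#' M = 4.22 / t_max, the longevity estimator regression constant applied
#' to maximum observed age; reported to three decimals.
#'
#' @param t_max Maximum observed age, years (>= 1).
#' @return M in per year, rounded to 3 decimals.
#' @export
#' @examples
#' hewitt_hoenig_m(61)  # 0.069
hewitt_hoenig_m <- function(t_max) {
  if (!is.numeric(t_max) || any(t_max <= 0)) stop_domain("t_max must be > 0")
  round(4.22 / t_max, 3)
}

#' Total mortality and the overfishing ratio
#'
#' Z = F + M and the F:M ratio (reported to one decimal), the standard
#' overfishing indicator (F > M suggests overfishing).
#'
#' @param f_mort Instantaneous fishing mortality, per year (>= 0).
#' @param m_nat Instantaneous natural mortality, per year (> 0 for the
#'   ratio).
#' @return List with `z`, the exact `f_to_m` ratio, and `f_to_m_reported`
#'   (ratio rounded to one decimal).
#' @export
#' @examples
#' mortality_summary(0.34, 0.066)$z  # 0.406
mortality_summary <- function(f_mort, m_nat) {
  if (f_mort < 0 || m_nat < 0) stop_domain("mortality rates must be >= 0")
  if (m_nat == 0) stop_domain("F:M undefined for m_nat = 0")
  r <- f_mort / m_nat
  list(z = f_mort + m_nat, f_to_m = r, f_to_m_reported = round(r, 1))
}

#' Least-squares von Bertalanffy fit
#'
#' Plain nonlinear least squares of length on age under the VBGF with t0
#' unconstrained. On severely right-truncated age data this is expected to
#' produce biologically implausible estimates (strongly negative t0,
#' inflated linf) -- the failure mode that motivates the Bayesian
#' composition model. Non-convergence is reported, not raised.
#'
#' @param observations `data.frame` with `age_years` and `tl_mm`
#'   (>= 4 distinct ages).
#' @return List of class `vbgf_ls_fit`: `linf`, `k`, `t0`, `rss`,
#'   `converged`.
#' @export
fit_vbgf_least_squares <- function(observations) {
  age <- observations$age_years
  len <- observations$tl_mm
  if (length(unique(age)) < 4)
    stop_domain("need >= 4 distinct ages for a 3-parameter fit")
  start <- list(linf = max(len) * 1.05, k = 0.1, t0 = 0)
  fit <- try(minpack.lm::nlsLM(len ~ linf * (1 - exp(-k * (age - t0))),
                               start = start,
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    return(structure(list(linf = NA_real_, k = NA_real_, t0 = NA_real_,
                          rss = NA_real_, converged = FALSE),
                     class = "vbgf_ls_fit"))
  cf <- coef(fit)
  structure(list(linf = unname(cf["linf"]), k = unname(cf["k"]),
                 t0 = unname(cf["t0"]),
                 rss = sum(residuals(fit)^2),
                 converged = fit$convInfo$isConv),
            class = "vbgf_ls_fit")
}
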