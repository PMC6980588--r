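## Adaptive Metropolis-Hastings estimation of the composition model.
##
## All eight parameters are sampled on the log scale. Each chain starts
## from the posterior mode found by a multistart quasi-Newton/simplex
## search seeded from crude data-driven estimates (a catch-curve Z, a
## least-squares VBGF, and length quantiles), and proposes from a
## Roberts-Rosenthal mixture: with high probability a multivariate normal
## scaled by the chain's running covariance estimate, otherwise a small
## fixed diagonal kick that lets a chain escape local micro-modes. The
## global proposal scale follows a Robbins-Monro recursion towards a
## target acceptance rate; adaptation diminishes as 1/iteration, so late
## draws are effectively from a fixed kernel.

#' MCMC configuration
#'
#' Defaults mirror a production run (4 chains, 5,000 burn-in, 200,000
#' retained draws per chain). Tests and examples use far fewer draws.
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param burn_in Burn-in iterations per chain.
#' @param n_samples Retained draws per chain.
#' @param target_accept Robbins-Monro target acceptance rate.
#' @param mix_prob Probability of the fixed-kick proposal component.
#' @param kick_sd SD (log scale) of the fixed-kick component.
#' @param n_starts Starts for the multistart mode search.
#' @param seed Master integer seed; chain c uses `seed + c`.
#' @return Object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, burn_in = 5000L, n_samples = 200000L,
                        target_accept = 0.3, mix_prob = 0.05, kick_sd = 0.05,
                        n_starts = 6L, seed = 1L) {
  if (n_chains < 1) stop_domain("n_chains must be >= 1")
  if (burn_in < 0) stop_domain("burn_in must be >= 0")
  if (n_samples < 1) stop_domain("n_samples must be >= 1")
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 n_samples = as.integer(n_samples),
                 target_accept = target_accept, mix_prob = mix_prob,
                 kick_sd = kick_sd, n_starts = as.integer(n_starts),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# log posterior factory; observations = NULL gives a prior-only target
make_log_posterior <- function(observations, priors, ...) {
  lmed <- log(priors$median)
  lsd <- priors$log_sd
  if (is.null(observations)) {
    return(function(lth) {
      if (any(!is.finite(lth))) return(-Inf)
      sum(dnorm(lth, lmed, lsd, log = TRUE))
    })
  }
  grid0 <- catch_composition(do.call(growth_params, as.list(exp(lmed))), ...)
  cells <- composition_cells(grid0, observations$age_years, observations$tl_mm)
  cnt <- tabulate(cells, length(grid0))
  occ <- which(cnt > 0)
  cocc <- cnt[occ]
  function(lth) {
    th <- exp(lth)
    # reject numerically hopeless proposals before building the grid
    if (any(!is.finite(th)) || th[1] > 1e5 || th[4] >= 1 || th[3] > 60)
      return(-Inf)
    grid <- catch_composition(structure(setNames(th, PARAM_NAMES),
                                        class = "growth_params"), ...)
    sum(cocc * log(grid[occ])) + sum(dnorm(lth, lmed, lsd, log = TRUE))
  }
}

# crude data-driven starting values (log scale)
smart_start <- function(observations, priors) {
  age <- observations$age_years
  len <- observations$tl_mm
  linf0 <- as.numeric(quantile(len, 0.99))
  vb <- try(suppressWarnings(
    nls(len ~ li * (1 - exp(-kk * (age - tt))),
        start = list(li = linf0, kk = 0.15, tt = 0),
        control = nls.control(warnOnly = TRUE))), silent = TRUE)
  k0 <- 0.15; t00 <- 0.5
  if (!inherits(vb, "try-error")) {
    cf <- coef(vb)
    k0 <- min(max(cf[["kk"]], 0.02), 1)
    t00 <- max(cf[["tt"]], 0.25)
    linf0 <- max(cf[["li"]], as.numeric(quantile(len, 0.9)))
  }
  mu <- pmax(linf0 * (1 - exp(-k0 * (age - t00))), 1)
  cv0 <- min(max(sd(len / mu - 1), 0.05), 0.5)
  tab <- tabulate(age)
  amode <- which.max(tab)
  right <- which(tab > 0 & seq_along(tab) > amode)
  z0 <- if (length(right) >= 3)
    max(-coef(lm(log(tab[right]) ~ right))[[2]], 0.05) else 0.3
  m0 <- priors$median[priors$parameter == "m_nat"]
  f0 <- max(z0 - m0, 0.05)
  l500 <- median(len[age <= amode])
  g0 <- max(sd(len) / 4, 10)
  log(c(linf0, k0, t00, cv0, l500, g0, m0, f0))
}

# alternating BFGS / Nelder-Mead polish until the objective stabilises
polish_mode <- function(start, log_post, max_cycles = 4) {
  cur <- start
  lp <- log_post(cur)
  for (i in seq_len(max_cycles)) {
    o1 <- try(optim(cur, function(p) -log_post(p), method = "BFGS",
                    control = list(maxit = 500)), silent = TRUE)
    if (!inherits(o1, "try-error") && -o1$value > lp) {
      cur <- o1$par; lp <- -o1$value
    }
    o2 <- optim(cur, function(p) -log_post(p), method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-10))
    improved <- -o2$value > lp + 0.5
    if (-o2$value > lp) { cur <- o2$par; lp <- -o2$value }
    if (!improved) break
  }
  list(par = cur, lp = lp)
}

# starting value profiled over a fixed asymptotic length: re-fit k and t0
# so the growth curve stays aligned with the data at that linf
profile_start <- function(base, linf, observations) {
  st <- base
  st[1] <- log(linf)
  vb <- try(suppressWarnings(
    nls(tl_mm ~ linf * (1 - exp(-kk * (age_years - tt))),
        data = observations, start = list(kk = 0.15, tt = 0.5),
        control = nls.control(warnOnly = TRUE))), silent = TRUE)
  if (!inherits(vb, "try-error")) {
    cf <- coef(vb)
    st[2] <- log(min(max(cf[["kk"]], 0.02), 1))
    st[3] <- log(max(cf[["tt"]], 0.25))
  }
  st
}

# posterior-mode search: the likelihood surface has multiple basins that
# differ mainly in asymptotic length, so starts combine (i) the crude
# data-driven estimate, (ii) a deterministic profile of linf values
# spanning the plausible range with k and t0 re-aligned at each, and
# (iii) random jitters; the incumbent is then kicked and re-polished
find_posterior_mode <- function(observations, priors, log_post,
                                n_starts = 6L, seed = 1L) {
  jitter_sd <- c(0.15, 0.3, 0.5, 0.2, 0.1, 0.5, 0.05, 0.3)
  if (is.null(observations)) {
    base <- log(priors$median)
    starts <- with_seed(seed, c(list(base),
      lapply(seq_len(max(n_starts - 1L, 0L)),
             function(i) base + rnorm(8, 0, jitter_sd))))
    modes <- lapply(starts, polish_mode, log_post = log_post)
    return(modes[[which.max(vapply(modes, `[[`, numeric(1), "lp"))]])
  }
  base <- smart_start(observations, priors)
  q99 <- as.numeric(quantile(observations$tl_mm, 0.99))
  profile <- lapply(exp(seq(log(0.95), log(1.40), length.out = 7)),
                    function(f) profile_start(base, q99 * f, observations))
  starts <- with_seed(seed, {
    c(list(base), profile,
      lapply(seq_len(max(n_starts - 1L, 0L)),
             function(i) base + rnorm(8, 0, jitter_sd)))
  })
  modes <- lapply(starts, polish_mode, log_post = log_post)
  best <- modes[[which.max(vapply(modes, `[[`, numeric(1), "lp"))]]
  kicks <- with_seed(seed + 7919L,
                     lapply(1:2, function(i) best$par + rnorm(8, 0, jitter_sd / 2)))
  for (st in kicks) {
    md <- polish_mode(st, log_post)
    if (md$lp > best$lp) best <- md
  }
  best
}

run_one_chain <- function(log_post, start, config, chain_seed) {
  d <- length(start)
  n_iter <- config$burn_in + config$n_samples
  with_seed(chain_seed, {
    cur <- start + rnorm(d, 0, 0.05)
    curlp <- log_post(cur)
    if (!is.finite(curlp))
      stop_domain("initialization error: non-finite posterior at chain start (",
                  paste(signif(exp(cur), 4), collapse = ", "), ")")
    lsc <- log(0.05)
    mu <- cur
    Sig <- diag(d) * 1e-3
    ch <- chol(Sig)
    draws <- matrix(NA_real_, n_iter, d)
    nacc <- 0L
    for (i in seq_len(n_iter)) {
      prop <- if (runif(1) < config$mix_prob)
        cur + rnorm(d, 0, config$kick_sd)
      else cur + exp(lsc) * drop(rnorm(d) %*% ch)
      plp <- log_post(prop)
      a <- if (is.finite(plp)) min(1, exp(plp - curlp)) else 0
      if (runif(1) < a) {
        cur <- prop; curlp <- plp
        if (i > config$burn_in) nacc <- nacc + 1L
      }
      draws[i, ] <- cur
      # diminishing adaptation: Robbins-Monro scale + running covariance
      lsc <- lsc + (a - config$target_accept) / max(1, i / 50)^0.6
      g <- 1 / (i + 20)
      mu <- mu + g * (cur - mu)
      Sig <- Sig + g * (tcrossprod(cur - mu) - Sig)
      if (i %% 200 == 0) ch <- chol(Sig + diag(d) * 1e-10)
    }
    list(draws = draws[(config$burn_in + 1):n_iter, , drop = FALSE],
         acceptance = nacc / config$n_samples)
  })
}

#' Fit the composition model by adaptive Metropolis-Hastings
#'
#' Runs `config$n_chains` chains on the 8 log-parameters. With
#' `observations = NULL` the likelihood is dropped and the chains sample
#' the prior -- useful for validating the sampler.
#'
#' @param observations `data.frame` with `age_years`, `tl_mm` (>= 50 rows),
#'   or `NULL` for a prior-only run.
#' @param priors A [growth_priors()] spec.
#' @param config An [mcmc_config()].
#' @param ... Grid settings passed to [catch_composition()].
#' @return Object of class `mcmc_result`: list with `chains` (list of
#'   draw matrices, log scale, named columns), `posterior` (`data.frame`
#'   with natural-scale posterior `mean` and `sd_log`), `acceptance`,
#'   `mode` (log-scale posterior mode), `config`, `priors`.
#' @export
run_mcmc <- function(observations, priors = growth_priors(),
                     config = mcmc_config(), ...) {
  stopifnot(inherits(priors, "prior_spec"), inherits(config, "mcmc_config"))
  if (!is.null(observations) && nrow(observations) < 50)
    stop_domain("need >= 50 observations (or NULL for a prior-only run)")
  log_post <- make_log_posterior(observations, priors, ...)
  mode <- find_posterior_mode(observations, priors, log_post,
                              n_starts = config$n_starts,
                              seed = config$seed)
  chains <- lapply(seq_len(config$n_chains), function(cidx)
    run_one_chain(log_post, mode$par, config, config$seed + cidx))
  draws <- lapply(chains, function(x) {
    colnames(x$draws) <- PARAM_NAMES
    x$draws
  })
  all <- do.call(rbind, draws)
  posterior <- data.frame(parameter = PARAM_NAMES,
                          mean = colMeans(exp(all)),
                          sd_log = apply(all, 2, sd),
                          row.names = NULL)
  structure(list(chains = draws,
                 posterior = posterior,
                 acceptance = vapply(chains, `[[`, numeric(1), "acceptance"),
                 mode = setNames(mode$par, PARAM_NAMES),
                 mode_lp = mode$lp,
                 config = config, priors = priors),
            class = "mcmc_result")
}

#' @export
print.mcmc_result <- function(x, ...) {
  cat("Adaptive MH fit:", length(x$chains), "chains x",
      nrow(x$chains[[1]]), "draws (acceptance",
      paste(sprintf("%.2f", x$acceptance), collapse = "/"), ")\n")
  print(transform(x$posterior, mean = signif(mean, 4),
                  sd_log = signif(sd_log, 2)), row.names = FALSE)
  invisible(x)
}

#' Convergence diagnostics for an MCMC fit
#'
#' Per-parameter Gelman-Rubin potential scale reduction factor (PSRF,
#' needs >= 2 chains), Geweke z (first 10% vs last 50% of each chain,
#' reported for chain 1), and the Heidelberger-Welch stationarity test.
#' Overall pass requires PSRF < 1.1, |z| < 2 and all stationarity tests
#' passing.
#'
#' @param result An `mcmc_result` (or list of draw matrices).
#' @return List of class `mcmc_diagnostics`: `psrf`, `geweke_z`,
#'   `heidel_pass`, `pass`.
#' @export
convergence_diagnostics <- function(result) {
  draws <- if (inherits(result, "mcmc_result")) result$chains else result
  if (length(draws) < 2)
    stop_domain("PSRF unavailable: need >= 2 chains")
  if (nrow(draws[[1]]) < 100)
    stop_domain("need >= 100 post-burn-in draws")
  ml <- coda::mcmc.list(lapply(draws, coda::mcmc))
  psrf <- coda::gelman.diag(ml, autoburnin = FALSE,
                            multivariate = FALSE)$psrf[, 1]
  gz <- coda::geweke.diag(ml[[1]], frac1 = 0.1, frac2 = 0.5)$z
  hw <- coda::heidel.diag(ml[[1]])
  heidel_pass <- setNames(hw[, "stest"] == 1, colnames(draws[[1]]))
  structure(list(psrf = psrf, geweke_z = gz, heidel_pass = heidel_pass,
                 pass = all(psrf < 1.1) && all(abs(gz) < 2) &&
                   all(heidel_pass)),
            class = "mcmc_diagnostics")
}

#' @export
print.mcmc_diagnostics <- function(x, ...) {
  cat("Convergence diagnostics (pass =", x$pass, ")\n")
  print(data.frame(parameter = names(x$psrf), psrf = round(x$psrf, 3),
                   geweke_z = round(x$geweke_z, 2),
                   heidel = x$heidel_pass, row.names = NULL),
        row.names = FALSE)
  invisible(x)
}
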