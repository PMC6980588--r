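# shared fixtures and independent oracles

# estimated parameter values for the northern Gulf of Mexico stock,
# used as simulation truth throughout the suite
true_params <- function() growth_params(1533, 0.14, 1.82, 0.17,
                                        812, 78.8, 0.066, 0.34)

# brute-force local weighted quadratic regression with tricube weights,
# independent of stats::loess: q nearest neighbours, bandwidth = q-th
# smallest distance
loess_oracle <- function(x0, xs, ys, span, degree = 2) {
  n <- length(xs)
  q <- floor(n * span)
  d <- abs(xs - x0)
  h <- sort(d)[q]
  w <- pmax(0, (1 - pmin(d / h, 1)^3))^3
  X <- outer(xs - x0, 0:degree, "^")
  drop(solve(t(X) %*% (w * X), t(X) %*% (w * ys)))[1]
}

# closed-form simple-regression OLS oracle
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  c(intercept = a, slope = b)
}

# merge low-expectation cells and return the chi-square GOF p-value
gof_pvalue <- function(observed, prob, min_exp = 5) {
  n <- sum(observed)
  exp_cnt <- n * prob
  keep <- exp_cnt >= min_exp
  obs <- c(observed[keep], sum(observed[!keep]))
  expd <- c(exp_cnt[keep], sum(exp_cnt[!keep]))
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = length(obs) - 1, lower.tail = FALSE)
}
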