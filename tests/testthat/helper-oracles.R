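# Independent oracles: deliberately plain, loop-based reimplementations of
# the quantities under test.  They share only published constants (the
# Symlet-16 filter bank) with the package code and never call its fast
# paths.

# one periodized DWT step by the definition: y[k] = sum_j h[j] x[(2k-j) mod n]
oracle_dwt_step <- function(x) {
  lo <- pupilload:::sym16_filters()$lo
  L <- length(lo)
  hi <- numeric(L)
  for (k in seq_len(L)) hi[k] <- (-1)^k * lo[L - k + 1]
  n <- length(x)
  if (n %% 2 == 1) {
    x <- x[-n]
    n <- n - 1
  }
  half <- n %/% 2
  a <- d <- numeric(half)
  for (k in 0:(half - 1)) {
    sa <- sd_ <- 0
    for (j in 0:(L - 1)) {
      xi <- x[((2 * k - j) %% n) + 1]
      sa <- sa + lo[j + 1] * xi
      sd_ <- sd_ + hi[j + 1] * xi
    }
    a[k + 1] <- sa
    d[k + 1] <- sd_
  }
  list(approx = a, detail = d)
}

# exhaustive index-by-index modulus-maxima scan
oracle_modmax <- function(coeffs) {
  n <- length(coeffs)
  m <- abs(coeffs)
  out <- numeric(n)
  for (i in seq_len(n)) {
    left_ok <- if (i == 1) TRUE else m[i] > m[i - 1]
    right_ok <- if (i == n) TRUE else m[i] >= m[i + 1]
    if (left_ok && right_ok && m[i] > 0) out[i] <- coeffs[i]
  }
  out
}

# full IPA chain, stage by stage, mirroring the declared algorithm
oracle_ipa <- function(d, fs, threshold_factor = 0.8) {
  x <- d - mean(d)
  s1 <- oracle_dwt_step(x)
  s2 <- oracle_dwt_step(s1$approx)
  detail <- s2$detail / 2
  maxima <- oracle_modmax(detail)
  n <- length(maxima)
  sigma <- sqrt(sum((maxima - mean(maxima))^2) / n)
  lambda <- threshold_factor * sigma * sqrt(2 * log(n))
  count <- sum(abs(maxima) >= lambda & maxima != 0)
  list(event_count = count, ipa = count / (length(d) / fs))
}

# Monte-Carlo marginal-likelihood estimate of the two-sided JZS BF
oracle_bf_mc <- function(differences, r = 1, n_draws = 1e6) {
  n <- length(differences)
  t_stat <- mean(differences) / (sd(differences) / sqrt(n))
  draws <- rcauchy(n_draws, 0, r)
  old <- options(warn = -1)
  on.exit(options(old))
  num <- mean(dt(t_stat, df = n - 1, ncp = sqrt(n) * draws))
  num / dt(t_stat, df = n - 1)
}

# importance-sampling estimate of the posterior of the effect size
# (heavy-tailed t proposal around the sample effect)
oracle_posterior_is <- function(t_stat, n, r = 1, direction = "two_sided",
                                n_draws = 1e6) {
  center <- t_stat / sqrt(n)
  scale <- sqrt((1 + center^2 / 2) / n) * 1.5
  z <- rt(n_draws, df = 3)
  delta <- center + scale * z
  old <- options(warn = -1)
  lw <- dt(t_stat, df = n - 1, ncp = sqrt(n) * delta, log = TRUE) +
    dcauchy(delta, 0, r, log = TRUE) -
    dt((delta - center) / scale, df = 3, log = TRUE) + log(scale)
  options(old)
  if (direction == "greater") lw[delta < 0] <- -Inf
  if (direction == "less") lw[delta > 0] <- -Inf
  w <- exp(lw - max(lw[is.finite(lw)]))
  w <- w / sum(w)
  ord <- order(delta)
  cw <- cumsum(w[ord])
  qs <- sapply(c(0.025, 0.975), function(p) delta[ord][which(cw >= p)[1]])
  list(es_mean = sum(w * delta), es_ci = qs,
       es_sd = sqrt(sum(w * delta^2) - sum(w * delta)^2))
}
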