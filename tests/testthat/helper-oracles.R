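# Independent closed-form oracles used across tests.

# Moment-matched log-normal parameters for a target arithmetic mean/SD.
lnorm_from_moments <- function(m, s) {
  s2 <- log(1 + s^2 / m^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# Two-boundary Wiener absorption probability / mean exit time, written out
# independently of the package's absorption_oracle().
wiener_oracle <- function(v, a, w, s) {
  if (abs(v) < 1e-12) {
    c(p = w / a, t = w * (a - w) / s^2)
  } else {
    th <- 2 * v / s^2
    p <- (1 - exp(-th * w)) / (1 - exp(-th * a))
    c(p = p, t = (a * p - w) / v)
  }
}

# Expected value of the SAMPLE Spearman statistic for a bivariate normal
# copula targeting population rank correlation rho_s (classical closed form;
# the sample statistic is biased toward zero at small n).
expected_sample_spearman <- function(rho_s, n) {
  rp <- 2 * sin(pi * rho_s / 6)
  (6 / (pi * (n + 1))) * ((n - 2) * asin(rp / 2) + asin(rp))
}

# Equal-variance Gaussian observer: signal N(dprime, 1), noise N(0, 1),
# respond "intact" when evidence exceeds the criterion (placed at
# dprime / 2 + c). Brute-force oracle for the SDT index tests.
simulate_observer <- function(n, dprime, criterion) {
  sig <- rnorm(n, dprime, 1)
  noi <- rnorm(n, 0, 1)
  k <- dprime / 2 + criterion
  tibble::tibble(
    stimulus_hand = rep(c("intact", "missing"), each = n),
    response_hand = ifelse(c(sig, noi) > k, "intact", "missing")
  )
}
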