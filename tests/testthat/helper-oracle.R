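# Literal, self-contained transcription of the one-step update equations,
# kept independent of the package's filter implementation so trajectories
# can be cross-checked against it.
oracle_hgf_filter <- function(u, kappa2, omega2, theta, mu2_0, sigma2_0,
                              mu3_0, sigma3_0, m3 = 1, phi3 = 0.1,
                              mean_reverting = FALSE) {
  n <- length(u)
  out <- data.frame(muhat1 = numeric(n), muhat2 = numeric(n),
                    muhat3 = numeric(n), mu2 = numeric(n),
                    sigma2 = numeric(n), mu3 = numeric(n),
                    sigma3 = numeric(n), delta1 = numeric(n),
                    delta2 = numeric(n))
  mu2 <- mu2_0; sigma2 <- sigma2_0; mu3 <- mu3_0; sigma3 <- sigma3_0
  for (k in seq_len(n)) {
    muhat2 <- mu2
    muhat3 <- if (mean_reverting) mu3 + phi3 * (m3 - mu3) else mu3
    muhat1 <- 1 / (1 + exp(-muhat2))
    v2 <- exp(kappa2 * mu3 + omega2)
    pihat2 <- 1 / (sigma2 + v2)
    delta1 <- u[k] - muhat1
    pi2 <- pihat2 + muhat1 * (1 - muhat1)
    mu2_new <- muhat2 + delta1 / pi2
    sigma2_new <- 1 / pi2
    pihat3 <- 1 / (sigma3 + theta)
    w2 <- v2 * pihat2
    delta2 <- (sigma2_new + (mu2_new - muhat2)^2) * pihat2 - 1
    pi3 <- pihat3 + (kappa2^2 / 2) * w2 * (w2 + (2 * w2 - 1) * delta2)
    stopifnot(pi2 > 0, pi3 > 0)
    mu3_new <- muhat3 + (kappa2 / 2) * (w2 / pi3) * delta2
    out[k, ] <- c(muhat1, muhat2, muhat3, mu2_new, sigma2_new,
                  mu3_new, 1 / pi3, delta1, delta2)
    mu2 <- mu2_new; sigma2 <- sigma2_new
    mu3 <- mu3_new; sigma3 <- 1 / pi3
  }
  out
}

# Brute-force fixed-point iteration for the random-effects model-selection
# scheme, written directly from its defining equations.
oracle_rfx <- function(L, alpha0 = 1, n_iter = 200) {
  K <- ncol(L)
  alpha <- rep(alpha0, K)
  for (i in seq_len(n_iter)) {
    u <- exp(sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), `+`))
    u <- u / rowSums(u)
    alpha <- alpha0 + colSums(u)
  }
  list(alpha = alpha, freq = alpha / sum(alpha), u = u)
}

# Small simulated dataset from given parameter objects on a short schedule.
make_subject <- function(pparams = perceptual_params(),
                         rparams = response_params(),
                         schedule = default_schedule(), seed = 1) {
  rec <- realize_inputs(schedule, seed = seed)
  simulate_agent(rec, pparams, rparams, seed = seed + 1)
}
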