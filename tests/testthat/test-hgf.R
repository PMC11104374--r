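test_that("sigmoid is exact at anchors and saturates without overflow", {
  expect_equal(hgf_sigmoid(0), 0.5)
  expect_equal(hgf_sigmoid(-1.5), 0.18243, tolerance = 1e-4)
  expect_equal(hgf_sigmoid(1e4), 1)
  expect_equal(hgf_sigmoid(-1e4), 0)
  expect_false(any(is.nan(hgf_sigmoid(c(-750, 750)))))
})

test_that("trial-1 update at the empirical prior means matches the hand derivation", {
  tr <- hgf_filter(1L, perceptual_params())
  expect_equal(tr$muhat1[1], 0.5, tolerance = 1e-5)
  expect_equal(tr$pihat2[1], 0.81757, tolerance = 1e-5)
  expect_equal(tr$mu2[1], 0.46835, tolerance = 1e-5)
  expect_equal(1 / tr$sigma2[1], 1.06757, tolerance = 1e-5)
  expect_equal(tr$delta2[1], -0.05484, tolerance = 1e-3)
  expect_equal(1 / tr$sigma3[1], 0.67162, tolerance = 1e-5)
  expect_equal(tr$mu3[1], 0.99628, tolerance = 1e-5)
})

test_that("filter matches the literal transcription of the update equations", {
  set.seed(7)
  u <- rbinom(20, 1, 0.7)
  cases <- list(
    list(p = perceptual_params(), mr = FALSE),
    list(p = perceptual_params(kappa2 = 0.8, omega2 = -1, mu3_0 = 0.5),
         mr = FALSE),
    list(p = perceptual_params(m3 = 3, variant = "mean_reverting"), mr = TRUE),
    list(p = perceptual_params(kappa2 = 0.2, omega2 = -3, m3 = -2,
                               variant = "mean_reverting"), mr = TRUE))
  for (cs in cases) {
    p <- cs$p
    tr <- hgf_filter(u, p)
    or <- oracle_hgf_filter(u, p$kappa2, p$omega2, p$theta, p$mu2_0,
                            p$sigma2_0, p$mu3_0, p$sigma3_0, p$m3, p$phi3,
                            mean_reverting = cs$mr)
    for (col in c("muhat1", "muhat2", "muhat3", "mu2", "sigma2", "mu3",
                  "sigma3", "delta1", "delta2"))
      expect_equal(tr[[col]], or[[col]], tolerance = 1e-10)
  }
})

test_that("zero coupling freezes the volatility level (standard variant)", {
  u <- c(1, 0, 1, 1, 0, 1)
  tr <- hgf_filter(u, perceptual_params(kappa2 = 0))
  expect_equal(tr$mu3, rep(1, length(u)))
})

test_that("mean reversion without coupling is geometric relaxation to m3", {
  p <- perceptual_params(kappa2 = 0, mu3_0 = 1, m3 = 2, phi3 = 0.1,
                         variant = "mean_reverting")
  tr <- hgf_filter(c(1, 0), p)
  expect_equal(tr$mu3, c(1.1, 1.19))
})

test_that("variants coincide when the drift is inert", {
  set.seed(1)
  u <- rbinom(40, 1, 0.6)
  # phi3 = 0: drift disabled entirely
  a <- hgf_filter(u, perceptual_params(kappa2 = 0.6, variant = "standard"))
  b <- hgf_filter(u, perceptual_params(kappa2 = 0.6, phi3 = 0,
                                       variant = "mean_reverting"))
  for (col in names(a)) expect_equal(a[[col]], b[[col]], tolerance = 1e-12)
  # m3 at the (kappa2 = 0) fixed point: mu3 constant in both variants
  c1 <- hgf_filter(u, perceptual_params(kappa2 = 0))
  c2 <- hgf_filter(u, perceptual_params(kappa2 = 0, m3 = 1, phi3 = 0.1,
                                        variant = "mean_reverting"))
  expect_equal(c1$mu3, c2$mu3)
})

test_that("trajectory invariants hold on valid runs", {
  set.seed(11)
  for (i in 1:5) {
    p <- perceptual_params(kappa2 = runif(1), omega2 = rnorm(1, -2, 1),
                           mu3_0 = rnorm(1, 1, 0.5),
                           m3 = rnorm(1, 1, 1.5),
                           variant = sample(c("standard", "mean_reverting"), 1))
    u <- rbinom(80, 1, 0.7)
    tr <- try(hgf_filter(u, p), silent = TRUE)
    if (inherits(tr, "try-error")) next
    expect_true(all(tr$muhat1 > 0 & tr$muhat1 < 1))
    expect_true(all(tr$sigma2 > 0 & tr$sigma3 > 0))
    expect_true(all(tr$pihat2 > 0 & tr$pihat3 > 0))
    # sigma * pi = 1 by construction at both levels
    expect_equal(tr$sigma2 * (1 / tr$sigma2), rep(1, 80))
  }
})

test_that("empty input preserves the initial state", {
  tr <- hgf_filter(integer(0), perceptual_params())
  expect_equal(nrow(tr), 0)
})

test_that("invalid parameter regimes are rejected with the failing trial", {
  # very large kappa2 * mu3 growth can push pi3 <= 0
  p <- perceptual_params(kappa2 = 1, omega2 = 6, mu3_0 = 6, sigma3_0 = 1)
  u <- rep(c(1, 0), 40)
  err <- tryCatch(hgf_filter(u, p), error = function(e) conditionMessage(e))
  if (is.character(err)) {
    expect_match(err, "invalid trajectory")
    tr <- hgf_filter(u, p, check = FALSE)
    expect_lt(attr(tr, "valid_until"), length(u))
  } else {
    succeed("parameter regime happened to stay valid")
  }
})

test_that("average learning rate increases with the drift equilibrium m3", {
  rec <- realize_inputs(default_schedule(), seed = 3)
  curve <- m3_effect_curve(rec, m3_grid = -4:4)
  # the valid range must cover the grid from the stabilising end upward;
  # very high equilibria may be rejected as degenerate
  expect_true(all(curve$valid[1:6]))
  ok <- curve$valid
  expect_true(all(diff(curve$mean_lr1[ok]) >= -1e-10))
  expect_true(all(diff(curve$mean_volatile_update[ok]) >= -1e-10))
})

test_that("update step matches the filter trial by trial", {
  p <- perceptual_params(kappa2 = 0.7, omega2 = -1.5)
  u <- c(1, 1, 0)
  tr <- hgf_filter(u, p)
  st <- list(mu2 = p$mu2_0, sigma2 = p$sigma2_0,
             mu3 = p$mu3_0, sigma3 = p$sigma3_0)
  for (k in seq_along(u)) {
    step <- hgf_update_step(st, u[k], p)
    expect_equal(step$mu2, tr$mu2[k])
    expect_equal(step$mu3, tr$mu3[k])
    st <- list(mu2 = step$mu2, sigma2 = step$sigma2,
               mu3 = step$mu3, sigma3 = step$sigma3)
  }
})

test_that("input-optimised parameters beat the prior means on their own objective", {
  set.seed(5)
  u <- rbinom(120, 1, 0.85)
  bo <- fit_bayes_optimal(u, "standard", restarts = 2)
  expect_true(is.finite(attr(bo, "objective")))
  priors <- prior_spec("standard")
  free <- priors$param[!priors$fixed & priors$block == "perceptual"]
  start <- to_estimation_space(setNames(as.list(
    priors$native_mean[match(free, priors$param)]), free), priors, free)
  at_prior <- advicehgf:::input_log_joint(start, u, free, priors, "standard")
  expect_gte(attr(bo, "objective"), at_prior)
})

test_that("all-helpful input raises the predicted accuracy above the prior trajectory", {
  u <- rep(1L, 150)
  bo <- fit_bayes_optimal(u, "standard", restarts = 2)
  all_p <- modifyList(list(kappa2 = 0.5, omega2 = -2, mu2_0 = 0, mu3_0 = 1),
                      lapply(bo, identity))
  fitted <- hgf_filter(u, perceptual_params(kappa2 = all_p$kappa2,
                                            omega2 = all_p$omega2,
                                            mu2_0 = all_p$mu2_0,
                                            mu3_0 = all_p$mu3_0))
  at_prior <- hgf_filter(u, perceptual_params())
  expect_gt(mean(fitted$muhat1), mean(at_prior$muhat1))
})

test_that("on stationary input the fitted drift equilibrium stays near the prior", {
  set.seed(9)
  u <- rbinom(170, 1, 0.8)
  bo <- fit_bayes_optimal(u, "mean_reverting", restarts = 2)
  expect_lt(abs(bo$m3 - 1), 2)
})
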