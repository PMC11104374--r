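test_that("identical evidence columns give uniform frequencies and attributions", {
  L <- matrix(rnorm(30), 15, 2)
  L <- cbind(L[, 1], L[, 1])
  fit <- rfx_bms(L)
  expect_equal(unname(fit$freq), c(0.5, 0.5), tolerance = 1e-10)
  expect_true(all(abs(fit$attribution - 0.5) < 1e-10))
})

test_that("the fixed point matches a brute-force iteration of the defining equations", {
  set.seed(3)
  L <- matrix(rnorm(60, sd = 2), 20, 3)
  fit <- rfx_bms(L, tol = 1e-12)
  or <- oracle_rfx(L)
  expect_equal(unname(fit$alpha), unname(or$alpha), tolerance = 1e-8)
  expect_equal(unname(fit$attribution), unname(or$u), tolerance = 1e-8)
  # single-subject case against the same oracle
  L1 <- matrix(c(log(2), 0), 1, 2)
  expect_equal(unname(rfx_bms(L1)$alpha),
               unname(oracle_rfx(L1)$alpha), tolerance = 1e-8)
})

test_that("per-subject constant shifts leave the selection unchanged", {
  set.seed(4)
  L <- matrix(rnorm(40), 20, 2)
  L2 <- L + rnorm(20) # one constant per subject row
  a <- rfx_bms(L); b <- rfx_bms(L2)
  expect_equal(a$alpha, b$alpha, tolerance = 1e-8)
})

test_that("simplex invariants hold for all outputs", {
  set.seed(5)
  L <- matrix(rnorm(80, sd = 3), 20, 4)
  res <- bms(L, n_samples = 1e5)
  expect_equal(sum(res$freq), 1)
  expect_equal(sum(res$xp), 1, tolerance = 1e-12)
  expect_equal(sum(res$pxp), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(res$attribution)), rep(1, 20))
  K <- 4
  expect_true(all(res$pxp >= res$bor / K - 1e-12))
  expect_true(all(res$pxp <= 1 - res$bor * (K - 1) / K + 1e-12))
})

test_that("exceedance probabilities match the Beta closed form", {
  expect_equal(unname(exceedance_prob(c(1, 1))), c(0.5, 0.5))
  xp <- exceedance_prob(c(8, 2))
  expect_equal(unname(xp[1]), pbeta(0.5, 8, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(unname(xp[1]), 0.9805, tolerance = 1e-4)
  # permutation equivariance
  expect_equal(unname(exceedance_prob(c(2, 8))), unname(rev(xp)))
  # Monte Carlo within 3 SE of the exact value at 1e6 draws
  mc <- exceedance_prob(c(8, 2), n_samples = 1e6, seed = 2, force_mc = TRUE)
  se <- sqrt(xp[1] * (1 - xp[1]) / 1e6)
  expect_lt(abs(mc[1] - xp[1]), 3 * se)
})

test_that("omnibus risk reaches its defining limits", {
  set.seed(6)
  base <- rnorm(20)
  Lsame <- cbind(base, base)
  fit <- rfx_bms(Lsame)
  bor_same <- omnibus_risk(Lsame, fit)
  expect_gt(bor_same, 0.5)
  Lstrong <- cbind(base + 10, base)
  bor_strong <- omnibus_risk(Lstrong, rfx_bms(Lstrong))
  expect_lt(bor_strong, 0.01)
  expect_true(bor_same >= 0 && bor_same <= 1)
})

test_that("protection interpolates between exceedance and chance", {
  xp <- c(0.98, 0.02)
  expect_equal(protected_xp(xp, 0), xp)
  expect_equal(protected_xp(xp, 1), c(0.5, 0.5))
  expect_equal(protected_xp(xp, 0.1), c(0.932, 0.068))
  expect_error(protected_xp(c(0.5, 0.4), 0.1), "sum to 1")
})

test_that("a dominant-model cohort recovers its frequency split", {
  # 95/5 split with strong per-subject evidence
  set.seed(8)
  n <- 40
  truth <- rbinom(n, 1, 0.05) + 1 # model 1 for ~95% of subjects
  L <- t(sapply(truth, function(m) {
    l <- c(0, 0); l[m] <- 8; l + rnorm(2, sd = 0.5)
  }))
  res <- bms(L)
  expect_gt(res$freq[1], 0.85)
  expect_gt(res$pxp[1], 0.95)
  expect_lt(res$bor, 0.05)
})

test_that("group splits preserve the simplex structure", {
  set.seed(9)
  L <- rbind(matrix(rnorm(20, mean = c(2, 0)), 10, 2, byrow = TRUE),
             matrix(rnorm(20, mean = c(0, 2)), 10, 2, byrow = TRUE))
  all <- bms(L)
  g1 <- bms(L[1:10, ]); g2 <- bms(L[11:20, ])
  for (r in list(all, g1, g2)) {
    expect_equal(sum(r$freq), 1)
    expect_equal(sum(r$pxp), 1, tolerance = 1e-12)
  }
})
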