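test_that("default schedule reproduces the task anchors", {
  s <- default_schedule()
  expect_equal(s$n_trials, 170)
  expect_equal(which(s$phase_labels == "volatile")[1], 68)
  expect_true(all(s$phase_labels[1:67] == "stable"))
  expect_equal(unique(s$advice_accuracy_prob[1:67]), 0.85)
  expect_equal(unique(s$advice_accuracy_prob[120:136]), 0.55)
  expect_true(all(s$advice_accuracy_prob[68:119] %in% c(0.9, 0.1)))
  # phase partition exhaustive and contiguous
  expect_equal(sort(unique(s$phase_labels)), c("stable", "volatile"))
  expect_equal(rle(s$phase_labels)$values, c("stable", "volatile"))
})

test_that("schedules are built directly from block specifications", {
  s <- make_schedule(data.frame(len = c(10, 10), accuracy = c(0.9, 0.1)),
                     stable_trials = 10)
  expect_equal(s$advice_accuracy_prob, rep(c(0.9, 0.1), each = 10))
  s1 <- make_schedule(data.frame(len = 20, accuracy = 1), stable_trials = 5)
  expect_equal(unique(s1$advice_accuracy_prob), 1)
  expect_error(make_schedule(data.frame(len = 10, accuracy = 0.5),
                             stable_trials = 10), "stable_trials")
  expect_error(make_schedule(data.frame(len = 10, accuracy = 1.2),
                             stable_trials = 5), "accuracy")
})

test_that("realised inputs are seed-deterministic and match the schedule rates", {
  s <- default_schedule()
  a <- realize_inputs(s, seed = 4)
  b <- realize_inputs(s, seed = 4)
  expect_identical(a, b)
  expect_true(all(a$u %in% 0:1))
  expect_true(all(a$c %in% s$cue_levels))
  # deterministic schedule: accuracy 1 forces u = 1
  s1 <- make_schedule(data.frame(len = 50, accuracy = 1), stable_trials = 10)
  expect_true(all(realize_inputs(s1, seed = 9)$u == 1))
  # binomial oracle at accuracy 0.85 over many trials
  s2 <- make_schedule(data.frame(len = 10000, accuracy = 0.85),
                      stable_trials = 100)
  u <- realize_inputs(s2, seed = 12)$u
  expect_lt(abs(mean(u) - 0.85), 3 * sqrt(0.85 * 0.15 / 10000))
})

test_that("an advice-blind agent's behaviour is invariant to the advice stream", {
  # kappa2 = 0 freezes the volatility prediction, so with zeta = 0 neither
  # the integrated belief nor the decision temperature can depend on u
  rec <- realize_inputs(default_schedule(), seed = 6)
  pp <- perceptual_params(kappa2 = 0)
  rp <- response_params(zeta = 0)
  a <- simulate_agent(rec, pp, rp, seed = 42)
  rec_perm <- rec
  set.seed(99)
  rec_perm$u <- sample(rec$u)
  b <- simulate_agent(rec_perm, pp, rp, seed = 42)
  expect_identical(a$y, b$y)
})

test_that("the noise-free advice-blind limit follows the cue alone", {
  sch <- default_schedule(cue_levels = c(0.35, 0.65))
  rec <- realize_inputs(sch, seed = 7)
  a <- simulate_agent(rec, perceptual_params(kappa2 = 0),
                      response_params(zeta = 0, nu = 1e9), seed = 1)
  expect_identical(a$y, as.integer(rec$c > 0.5))
})

test_that("a high-m3 agent updates its advice predictions more in the volatile phase", {
  rec <- realize_inputs(default_schedule(), seed = 8)
  curve <- m3_effect_curve(rec, m3_grid = c(-4, 2))
  expect_true(all(curve$valid))
  expect_gt(curve$mean_volatile_update[2], curve$mean_volatile_update[1])
})

test_that("cohort generation stores ground truth and respects group specs", {
  spec <- cohort_spec(list(
    hc_like = list(n = 3, model = "HI"),
    fep_like = list(n = 2, model = "HII", mean = list(m3 = 3))),
    schedule = default_schedule())
  ch <- generate_cohort(spec, seed = 5)
  expect_equal(nrow(ch$trials), 5 * 170)
  expect_equal(sum(ch$truth$model == "HII"), 2)
  expect_equal(ch$truth$group[ch$truth$model == "HII"],
               rep("fep_like", 2))
  expect_true(all(c("m3", "omega2", "zeta") %in% names(ch$truth)))
  # m3 recorded only for the mean-reverting group
  expect_true(all(is.na(ch$truth$m3[ch$truth$model == "HI"])))
  # determinism
  ch2 <- generate_cohort(spec, seed = 5)
  expect_identical(ch$trials, ch2$trials)
  # empty group allowed
  spec0 <- cohort_spec(list(a = list(n = 0, model = "HI"),
                            b = list(n = 2, model = "HI")))
  ch0 <- generate_cohort(spec0, seed = 1)
  expect_equal(length(unique(ch0$trials$subject_id)), 2)
})

test_that("zero parameter spread yields identical ground-truth draws", {
  spec <- cohort_spec(list(g = list(n = 3, model = "HI")), spread_scale = 0)
  ch <- generate_cohort(spec, seed = 2)
  est <- ch$truth[, c("kappa2", "omega2", "mu2_0", "mu3_0", "zeta", "nu")]
  expect_true(all(apply(est, 2, function(x) diff(range(x)) == 0)))
})
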