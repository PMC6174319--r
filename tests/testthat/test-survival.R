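test_that("left-truncated KM matches the hand-worked example", {
  rec <- survival_records(80, c(81, 83, 84, 86), c(TRUE, TRUE, FALSE, TRUE))
  cv <- km_left_truncated(rec)
  expect_equal(cv$age, c(81, 83, 86))
  expect_equal(cv$survival, c(0.75, 0.5, 0))
  expect_equal(cv$n_risk, c(4, 3, 1))
  # single record with an event: step from 1 to 0
  one <- km_left_truncated(survival_records(0, 5, TRUE))
  expect_equal(curve_survival_at(one, c(4.9, 5)), c(1, 0))
})

test_that("KM equals brute-force risk-set enumeration on small record sets", {
  set.seed(21)
  for (rep in 1:60) {
    n <- sample(1:10, 1)
    entry <- sample(c(0, 0, 80, 82, 85), n, replace = TRUE)
    exit <- entry + sample(1:12, n, replace = TRUE)
    event <- sample(c(TRUE, TRUE, FALSE), n, replace = TRUE)
    if (!any(event)) event[1] <- TRUE
    cv <- suppressWarnings(km_left_truncated(
      survival_records(entry, exit, event)))
    oracle <- bf_km(entry, exit, event)
    expect_equal(cv$age, oracle$age)
    expect_equal(cv$survival, oracle$survival, tolerance = 1e-12)
  }
})

test_that("late entrants join the risk set only after entry", {
  # entries staggered: the age-82 entrant misses the first death at 81
  rec <- survival_records(c(80, 80, 82), c(81, 85, 86), c(TRUE, TRUE, TRUE))
  cv <- km_left_truncated(rec)
  expect_equal(cv$n_risk, c(2, 2, 1))
  expect_equal(cv$survival, c(0.5, 0.25, 0))
})

test_that("with entry zero and no censoring KM is the empirical survival", {
  set.seed(31)
  for (rep in 1:4) {
    n <- sample(3:20, 1)
    t <- sample(1:50, n, replace = TRUE)
    cv <- km_left_truncated(survival_records(0, t, TRUE))
    for (tt in sort(unique(t))) {
      expect_equal(curve_survival_at(cv, tt), mean(t > tt))
    }
  }
})

test_that("conditioning rescales a curve and preserves its invariants", {
  rec <- survival_records(80, c(85, 90, 92, 95), c(TRUE, TRUE, FALSE, TRUE))
  cv <- km_left_truncated(rec)
  # conditioning at the support start is the identity
  same <- condition_curve(cv, attr(cv, "start_age"))
  expect_equal(same$survival, cv$survival)
  cnd <- condition_curve(cv, 85)
  s85 <- curve_survival_at(cv, 85)
  expect_equal(cnd$survival, cv$survival[cv$age > 85] / s85)
  expect_true(all(diff(cnd$survival) <= 0))
  expect_true(all(cnd$survival >= 0 & cnd$survival <= 1))
  # S(90 | 80) is the ratio of unconditional survivals
  crafted <- km_left_truncated(
    survival_records(70, c(80, 90, 91, 92), c(TRUE, TRUE, FALSE, TRUE)))
  s80 <- curve_survival_at(crafted, 80)
  cnd2 <- condition_curve(crafted, 80)
  expect_equal(curve_survival_at(cnd2, 90),
               curve_survival_at(crafted, 90) / s80)
})

test_that("conditioning equals re-estimating on records truncated at that age", {
  set.seed(41)
  entry <- rep(80, 30)
  exit <- entry + sample(1:15, 30, replace = TRUE)
  event <- sample(c(TRUE, TRUE, FALSE), 30, replace = TRUE)
  cv <- condition_curve(km_left_truncated(survival_records(entry, exit, event)),
                        85)
  keep <- exit > 85
  cv2 <- km_left_truncated(
    survival_records(pmax(entry[keep], 85), exit[keep], event[keep]))
  expect_equal(cv$age, cv2$age)
  expect_equal(cv$survival, cv2$survival, tolerance = 1e-12)
})

test_that("log-rank matches the hand-computed two-group table", {
  a <- survival_records(0, c(1, 2), TRUE, "a")
  b <- survival_records(0, c(3, 4), TRUE, "b")
  lr <- logrank(a, b)
  expect_equal(round(lr$statistic, 4), 2.8824)
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-12)
  expect_equal(lr$df, 1L)
  expect_equal(round(lr$p_value, 4), 0.0896)
  # label symmetry and identical-group null
  expect_equal(logrank(b, a)$statistic, lr$statistic)
  same <- logrank(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # no events anywhere: statistic 0, p 1, with a warning
  expect_warning(none <- logrank(survival_records(0, 5, FALSE),
                                 survival_records(0, 6, FALSE)), "no events")
  expect_equal(none$p_value, 1)
})

test_that("log-rank agrees with survdiff on right-censored data", {
  set.seed(51)
  for (rep in 1:10) {
    na <- sample(5:25, 1); nb <- sample(5:25, 1)
    ta <- rexp(na, 0.1); tb <- rexp(nb, 0.07)
    va <- runif(na) < 0.8; vb <- runif(nb) < 0.8
    if (!any(va) && !any(vb)) va[1] <- TRUE
    lr <- logrank(survival_records(0, ta, va), survival_records(0, tb, vb))
    sd <- survival::survdiff(
      survival::Surv(c(ta, tb), c(va, vb)) ~ rep(c("a", "b"), c(na, nb)))
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-8)
  }
})

test_that("restricted mean survival integrates the step curve exactly", {
  flat <- km_left_truncated(survival_records(80, rep(90, 3), FALSE))
  # no events: S = 1 throughout the window
  expect_equal(rmst(flat, 80, 90), 10)
  # one death at 85 among two subjects: S = 1 then 0.5
  step <- km_left_truncated(
    survival_records(80, c(85, 90), c(TRUE, FALSE)))
  expect_equal(rmst(step, 80, 90), 5 + 0.5 * 5)
  expect_error(rmst(step, 80, 99), "outside")
  expect_error(rmst(step, 85, 85), "below")
})

test_that("rmst is monotone under pointwise curve dominance", {
  set.seed(61)
  for (rep in 1:5) {
    base <- sort(runif(6, 81, 94))
    s_hi <- cummin(runif(6, 0.5, 1))
    s_lo <- s_hi * runif(6, 0.3, 1)   # dominated pointwise
    mk <- function(s) structure(
      data.frame(age = base, survival = s, n_risk = 6:1, n_event = 1),
      start_age = 80, end_age = 95,
      class = c("survival_curve", "data.frame"))
    expect_gte(rmst(mk(s_hi), 80, 95), rmst(mk(s_lo), 80, 95))
  }
})
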