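test_that("the concordance index matches its worked example and boundary cases", {
  # worked example: 5 comparable pairs, 4 concordant
  expect_equal(c_index(c(2, 4, 5, 7), c(1, 1, 0, 1), c(0.9, 0.5, 0.6, 0.2)), 0.8)
  # perfect ordering without censoring
  t <- 1:10
  expect_equal(c_index(t, rep(1, 10), 10:1), 1.0)
  expect_equal(c_index(t, rep(1, 10), 1:10), 0.0)
  # constant risks: every comparable pair ties at 0.5
  expect_equal(c_index(t, rep(1, 10), rep(2, 10)), 0.5)
  expect_error(c_index(t, rep(0, 10), 1:10), "no events")
})

test_that("c_index agrees exactly with the brute-force pairwise oracle", {
  set.seed(14)
  for (i in 1:60) {
    n <- sample(10:40, 1)
    time <- round(rexp(n, 0.1), 1)        # induces some ties
    event <- rbinom(n, 1, 0.7)
    risk <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # tied risks too
    if (!any(event == 1 & time < max(time))) next
    expect_identical(c_index(time, event, risk), c_index_oracle(time, event, risk))
  }
})

test_that("c_index agrees with the survival package on tie-free data", {
  skip_if_not_installed("survival")
  set.seed(2)
  n <- 300
  time <- rexp(n); event <- rbinom(n, 1, 0.6); risk <- rnorm(n)
  cc <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)
  expect_equal(c_index(time, event, risk), unname(cc$concordance),
               tolerance = 1e-12)
})

test_that("complementing the risks complements the index", {
  set.seed(3)
  time <- rexp(50); event <- rbinom(50, 1, 0.8); risk <- rnorm(50)
  expect_equal(c_index(time, event, risk) + c_index(time, event, -risk), 1)
})

test_that("accuracy counts exact matches", {
  expect_equal(accuracy(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(accuracy(c(1, 0, 1), c(0, 1, 0)), 0)
  expect_equal(accuracy(c(1, 0, 1, 0), c(1, 0, 1, 1)), 0.75)
  expect_error(accuracy(c(1, 0), c(1, 0, 1)), "length")
})

test_that("stratified splits partition the cohort and reproduce under a seed", {
  set.seed(10)
  event <- rbinom(1000, 1, 0.65)
  folds <- split_and_cv(event, k = 5, seed = 3)
  tests <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(tests)), 1:1000)           # disjoint union
  for (f in folds) {
    expect_identical(sort(c(f$train, f$val, f$test)), 1:1000)
    expect_lt(abs(length(f$test) - 200), 2.5)             # 20%
    expect_lt(abs(length(f$val) - 200), 2.5)              # 20%
    expect_lt(abs(length(f$train) - 600), 4.5)            # 60%
    # stratification: event rate preserved in each part
    expect_lt(abs(mean(event[f$train]) - mean(event)), 0.05)
    expect_lt(abs(mean(event[f$test]) - mean(event)), 0.05)
  }
  expect_identical(folds, split_and_cv(event, k = 5, seed = 3))
  expect_false(identical(folds, split_and_cv(event, k = 5, seed = 4)))
  expect_error(split_and_cv(c(rep(1, 100), 0), k = 5), "too few")
})

test_that("bootstrap comparison is calibrated at its edges", {
  set.seed(21)
  n <- 80
  time <- rexp(n); event <- rbinom(n, 1, 0.7)
  r1 <- rnorm(n)
  # identical models: p = 1 and identical CIs
  out <- bootstrap_compare(list(a = r1, b = r1), time, event,
                           n_boot = 200, seed = 5)
  expect_equal(out$comparisons$p_adjusted, 1)
  expect_identical(out$ci$ci_low[1], out$ci$ci_low[2])
  # determinism
  out2 <- bootstrap_compare(list(a = r1, b = r1), time, event,
                            n_boot = 200, seed = 5)
  expect_identical(out$boot, out2$boot)
  # a genuinely better model is detected
  coh_risk <- time * -1  # oracle risk: earlier death = higher risk
  out3 <- bootstrap_compare(list(oracle = coh_risk, noise = rnorm(n)),
                            time, event, n_boot = 300, seed = 6)
  expect_lt(out3$comparisons$p_adjusted, 0.05)
  expect_gt(out3$comparisons$delta, 0)
})

test_that("bootstrap percentile intervals cover a known truth", {
  # truth: the large-sample concordance of an exponential proportional-hazards
  # risk score, estimated once on a very large sample
  set.seed(31)
  big_lp <- rnorm(20000)
  big_t <- rexp(20000, exp(big_lp))
  truth <- c_index(big_t, rep(1, 20000), big_lp)
  cover <- 0
  reps <- 40
  for (r in 1:reps) {
    lp <- rnorm(150)
    tt <- rexp(150, exp(lp))
    boot <- replicate(200, {
      idx <- sample.int(150, replace = TRUE)
      c_index(tt[idx], rep(1, 150), lp[idx])
    })
    ci <- stats::quantile(boot, c(0.025, 0.975))
    if (truth >= ci[1] && truth <= ci[2]) cover <- cover + 1
  }
  expect_gte(cover / reps, 0.90)
})

test_that("cross-validated evaluation reports per-fold concordance", {
  coh <- tiny_cohort(n = 150, seed = 17, effect = 1.5)
  cv <- evaluate_cv(coh, tiny_config(epochs = 2), k = 5, seed = 17)
  expect_length(cv$per_fold, 5L)
  expect_true(all(cv$per_fold >= 0 & cv$per_fold <= 1))
  expect_equal(cv$mean, mean(cv$per_fold))
})
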