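test_that("discrete survival loss matches hand-computed likelihood terms", {
  # certain event in the only bin -> loss 0
  expect_equal(survival_loss(matrix(1, 1, 1), 1L, 1L), 0, tolerance = 1e-10)
  # censored with zero hazards -> certain survival, loss 0
  expect_equal(survival_loss(matrix(0, 1, 3), 3L, 0L), 0, tolerance = 1e-10)

  # 3-patient toy, hand-computed negative log-likelihood
  h <- rbind(c(0.2, 0.5, 0.1),
             c(0.3, 0.4, 0.6),
             c(0.05, 0.1, 0.2))
  bin <- c(2L, 1L, 3L)
  event <- c(1L, 0L, 1L)
  ll1 <- log(1 - 0.2) + log(0.5)          # event in bin 2: survive 1, die 2
  ll2 <- log(1 - 0.3)                      # censored in bin 1
  ll3 <- log(1 - 0.05) + log(1 - 0.1) + log(0.2)
  expect_equal(survival_loss(h, bin, event), -(ll1 + ll2 + ll3) / 3,
               tolerance = 1e-12)
  expect_error(survival_loss(h, c(1L, 4L, 1L), event), "bin index")
})

test_that("cox partial likelihood and gradient match brute force", {
  set.seed(8)
  n <- 25
  time <- rexp(n); event <- rbinom(n, 1, 0.7); risk <- rnorm(n)
  # brute-force Breslow negative partial log-likelihood
  npl <- function(r) {
    s <- 0
    for (i in which(event == 1))
      s <- s + r[i] - log(sum(exp(r[time >= time[i]])))
    -s / sum(event)
  }
  cl <- cox_partial_loss(risk, time, event)
  expect_equal(cl$loss, npl(risk), tolerance = 1e-10)
  eps <- 1e-6
  for (k in c(1, 7, 20)) {
    r2 <- risk; r2[k] <- r2[k] + eps
    expect_equal(cl$grad[k], (npl(r2) - npl(risk)) / eps, tolerance = 1e-4)
  }
})

test_that("fitting is reproducible and predictions deterministic", {
  coh <- tiny_cohort(n = 90, seed = 4)
  f1 <- fit_tiny(coh, epochs = 2, seed = 3)
  f2 <- fit_tiny(coh, epochs = 2, seed = 3)
  expect_identical(f1$params, f2$params)
  expect_identical(predict_risk(f1, coh), predict_risk(f2, coh))
  p1 <- predict(f1, coh, type = "risk")
  expect_identical(p1, predict(f1, coh, type = "risk"))
  expect_true(all(is.finite(p1)))
})

test_that("risk is the stated monotone functional of the hazards", {
  coh <- tiny_cohort(n = 60, seed = 6)
  fit <- fit_tiny(coh, epochs = 1, seed = 6)
  h <- predict(fit, coh, type = "hazard")
  S <- predict(fit, coh, type = "survival")
  expect_equal(S, t(apply(1 - h, 1, cumprod)), tolerance = 1e-12)
  risk <- predict(fit, coh, type = "risk")
  expect_equal(risk, 1 - rowMeans(S), tolerance = 1e-12)
  # all-zero hazards give minimal risk; raising every hazard raises risk
  expect_equal(1 - mean(cumprod(1 - rep(0, 5))), 0)
  r_lo <- 1 - mean(cumprod(1 - h[1, ]))
  r_hi <- 1 - mean(cumprod(1 - pmin(1, h[1, ] + 0.05)))
  expect_gt(r_hi, r_lo)
})

test_that("checkpoints round-trip to identical predictions", {
  coh <- tiny_cohort(n = 70, seed = 12)
  fit <- fit_tiny(coh, epochs = 2, seed = 12)
  path <- withr::local_tempfile(fileext = ".rds")
  save_privsurv(fit, path)
  back <- load_privsurv(path)
  expect_identical(predict_risk(back, coh), predict_risk(fit, coh))
})

test_that("the cox head is rejected for private training", {
  coh <- tiny_cohort(n = 60, seed = 1)
  expect_error(privsurv(coh, tiny_config(head = "cox"),
                        privacy = privacy_config()),
               "not per-sample separable")
})

test_that("a noiseless step equals the epsilon -> infinity private step; clinical is untouched", {
  coh <- tiny_cohort(n = 80, seed = 13, miss = 0)
  base <- fit_tiny(coh, epochs = 1, seed = 13)
  batch <- 1:64
  scores <- feature_relevance(base, coh)
  huge <- allocate_budgets(scores, global_epsilon = 1e12, seed = 1)
  plain <- noisy_gradient_step(base, coh, batch, allocation = NULL,
                               learning_rate = 0.05, model_seed = 99)
  priv <- noisy_gradient_step(base, coh, batch, allocation = huge,
                              clip_bound = 1e4, learning_rate = 0.05,
                              model_seed = 99, noise_seed = 7)
  # clinical branch bit-identical between private and noiseless paths
  expect_identical(priv$model$params$clinical, plain$model$params$clinical)
  expect_identical(priv$model$params$fusion, plain$model$params$fusion)
  expect_identical(priv$model$params$head, plain$model$params$head)
  # protected encoders agree in the zero-noise limit
  for (m in c("mRNA", "miRNA", "CNV"))
    expect_equal(priv$model$params$encoders[[m]]$layers,
                 plain$model$params$encoders[[m]]$layers, tolerance = 1e-6)
  expect_identical(nrow(plain$ledger), 0L)
  expect_gt(nrow(priv$ledger), 0)

  bad <- huge
  bad$modalities$mRNA$eps_groups[1] <- -1
  expect_error(noisy_gradient_step(base, coh, batch, allocation = bad),
               "nonpositive")
})

test_that("finite noise perturbs only the protected encoders", {
  coh <- tiny_cohort(n = 80, seed = 13, miss = 0)
  base <- fit_tiny(coh, epochs = 1, seed = 13)
  scores <- feature_relevance(base, coh)
  alloc <- allocate_budgets(scores, global_epsilon = 0.8, seed = 1)
  plain <- noisy_gradient_step(base, coh, 1:64, learning_rate = 0.05,
                               model_seed = 99)
  priv <- noisy_gradient_step(base, coh, 1:64, allocation = alloc,
                              clip_bound = 1, learning_rate = 0.05,
                              model_seed = 99, noise_seed = 7)
  expect_identical(priv$model$params$clinical, plain$model$params$clinical)
  expect_false(isTRUE(all.equal(priv$model$params$encoders$mRNA$layers,
                                plain$model$params$encoders$mRNA$layers)))
  # ledger records every group of every protected modality once; the joint
  # release per modality spends the maximum group budget
  expect_identical(nrow(priv$ledger), 3L * (4L + 1L))
  expect_equal(accountant_report(priv$ledger, 0.8)$per_release_total, 0.8,
               tolerance = 1e-9)
})

test_that("the status classifier separates separable labels and not permuted ones", {
  set.seed(5)
  n <- 300
  x <- cbind(rnorm(n), rnorm(n))
  y <- as.integer(x[, 1] + 0.3 * x[, 2] > 0)
  cls <- classify_status(x, y, hidden = c(16, 8), epochs = 300, seed = 2)
  expect_equal(cls$accuracy, 1.0, tolerance = 0.02)
  # permuted labels: held-out accuracy is at chance
  yp <- sample(y)
  cls_null <- classify_status(x, yp, hidden = c(16, 8), epochs = 150,
                              test_idx = 201:300, seed = 2)
  expect_lt(abs(cls_null$accuracy - 0.5), 0.15)
  expect_error(classify_status(x, rep(1, n)), "both classes")
})

test_that("training history is recorded and the loss decreases on strong signal", {
  coh <- tiny_cohort(n = 150, seed = 20, effect = 1.5)
  fit <- fit_tiny(coh, epochs = 6, seed = 20)
  expect_length(fit$history, 6L)
  expect_lt(fit$history[6], fit$history[1])
})

test_that("prediction aligns external cohorts to the training features", {
  coh <- tiny_cohort(n = 100, seed = 30)
  fit <- fit_tiny(coh, epochs = 2, seed = 30)
  ref <- predict_risk(fit, coh)
  # same patients with shuffled feature columns: alignment restores order
  shuffled <- coh
  for (m in names(shuffled$blocks)) {
    b <- shuffled$blocks[[m]]
    perm <- sample(ncol(b$values))
    shuffled$blocks[[m]] <- modality_block(m, b$values[, perm, drop = FALSE],
                                           b$missing_mask)
  }
  expect_equal(predict_risk(fit, shuffled), ref, tolerance = 1e-12)
})
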