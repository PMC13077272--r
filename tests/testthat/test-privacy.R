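test_that("interval partition puts top scores in T_1 with quantile cuts", {
  scores <- 1:100
  part <- partition_intervals(scores, 4)
  expect_identical(part$n, 4L)
  expect_equal(part$cuts, c(25, 50, 75))
  expect_true(all(part$assignment[scores > 75] == 1L))   # T_1 = (75, 100]
  expect_true(all(part$assignment[scores <= 25] == 4L))  # T_4 = [1, 25]
  expect_identical(unname(part$assignment[75]), 2L)      # boundary closed below
  # partition property: every feature in exactly one interval
  expect_true(all(part$assignment %in% 1:4))
  expect_identical(length(part$assignment), 100L)

  expect_warning(p1 <- partition_intervals(rep(3, 10), 4), "distinct")
  expect_identical(p1$n, 1L)
  expect_error(partition_intervals(numeric(0), 4), "nonempty")
})

test_that("the budget map is the stated linear interpolation with monotone jitter", {
  expect_equal(eta_map(1:5, 5, Delta = 0), c(0.5, 0.4, 0.3, 0.2, 0.1))
  expect_equal(eta_map(1, 5, Delta = 0), 0.5)   # eps_max at the top interval
  expect_equal(eta_map(5, 5, Delta = 0), 0.1)   # eps_min at the bottom
  for (s in 1:100) {
    e <- eta_map(1:4, 4, Delta = 0.4 * (0.5 - 0.1) / 3, seed = s)
    expect_true(all(diff(e) < 0))
    expect_true(all(e >= 0.1 - 1e-12 & e <= 0.5 + 1e-12))
  }
  expect_error(eta_map(1:4, 4, Delta = 0.07), "monotonicity")
})

test_that("budget allocation composes exactly to the global epsilon", {
  scores <- list(mRNA = runif(50), miRNA = runif(30), CNV = runif(40))
  alloc <- allocate_budgets(scores, global_epsilon = 0.8, seed = 3)
  # each jointly clipped modality release spends its maximum group budget
  per_mod <- vapply(alloc$modalities, function(m) max(m$eps_groups), 1.0)
  expect_equal(unname(per_mod), rep(0.8 / 3, 3), tolerance = 1e-12)
  expect_equal(sum(per_mod), 0.8, tolerance = 1e-9)
  for (m in alloc$modalities) {
    ints <- m$eps_groups[seq_len(length(m$eps_groups) - 1L)]
    expect_true(all(diff(ints) < 0))  # strictly decreasing over intervals
  }
  # identical relevance distributions give identical allocations
  same <- list(mRNA = 1:20 / 20, miRNA = 1:20 / 20, CNV = 1:20 / 20)
  al2 <- allocate_budgets(same, seed = 4)
  expect_identical(al2$modalities$mRNA$eps_groups, al2$modalities$miRNA$eps_groups)
  expect_identical(al2$modalities$mRNA$intervals$assignment,
                   unname(al2$modalities$CNV$intervals$assignment))
  # uniform ablation: equal groups, identical joint-release guarantee
  alu <- allocate_budgets(scores, uniform = TRUE, seed = 3)
  g <- alu$modalities$mRNA$eps_groups
  expect_true(all(abs(g - g[1]) < 1e-15))
  expect_equal(max(g), 0.8 / 3, tolerance = 1e-12)
  expect_error(allocate_budgets(scores[c("mRNA", "CNV")]), "missing")
})

test_that("higher relevance intervals receive larger budgets hence less noise", {
  scores <- list(mRNA = 1:40, miRNA = 1:40, CNV = 1:40)
  alloc <- allocate_budgets(scores, seed = 1)
  m <- alloc$modalities$mRNA
  eps_by_interval <- m$eps_groups[1:4]
  noise_scale <- 2 / eps_by_interval  # proportional to the Laplace scale
  expect_true(all(diff(noise_scale) > 0))  # T_1 least noisy
  top_feature <- which.max(scores$mRNA)
  expect_equal(unname(m$intervals$assignment[top_feature]), 1L)
  expect_equal(unname(m$eps_feature[top_feature]), m$eps_groups[1])
})

test_that("per-sample clipping bounds the L1 norm and preserves direction", {
  g <- c(3, -4, 2, -1)  # L1 norm 10
  cg <- clip_per_sample_gradient(g, 1)
  expect_equal(sum(abs(cg)), 1, tolerance = 1e-12)
  expect_equal(cg / sqrt(sum(cg^2)), g / sqrt(sum(g^2)), tolerance = 1e-12)
  small <- c(0.2, -0.3)  # norm 0.5
  expect_identical(clip_per_sample_gradient(small, 1), small)
  expect_error(clip_per_sample_gradient(g, 0), "positive")
})

test_that("laplace sampling is seeded, centred, and has the right spread", {
  a <- laplace_sample(1, 1000, seed = 5)
  expect_identical(a, laplace_sample(1, 1000, seed = 5))
  x <- laplace_sample(1, 1e5, seed = 6)
  expect_lt(abs(mean(x)), 0.02)
  expect_lt(abs(stats::var(x) / 2 - 1), 0.02)  # Var = 2 b^2
  expect_error(laplace_sample(0, 10), "positive")
})

test_that("the accountant sums per-release spends and labels naive composition", {
  ledger <- do.call(rbind, lapply(1:4, function(s)
    data.frame(step = s, modality = rep(c("mRNA", "miRNA", "CNV"), each = 2),
               group = c("T1", "T2"), epsilon = rep(c(0.8 / 3, 0.1), 3),
               noise_scale = 1)))
  rep1 <- accountant_report(ledger, 0.8)
  expect_equal(rep1$per_release_total, 0.8, tolerance = 1e-12)
  expect_equal(unname(rep1$per_modality), rep(0.8 / 3, 3))
  expect_true(rep1$within_budget)
  expect_equal(rep1$naive_total, 4 * 0.8, tolerance = 1e-12)
  # doubling the steps doubles the naive figure, not the per-release one
  rep2 <- accountant_report(rbind(ledger, transform(ledger, step = step + 4)), 0.8)
  expect_equal(rep2$naive_total, 2 * rep1$naive_total)
  expect_equal(rep2$per_release_total, rep1$per_release_total)
  # empty protected set
  empty <- accountant_report(NULL, 0.8)
  expect_equal(empty$per_release_total, 0)
})
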