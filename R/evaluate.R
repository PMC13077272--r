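#' Concordance index for right-censored data
#'
#' The proportion of concordant pairs among all comparable pairs. A pair is
#' comparable iff the strictly earlier follow-up time carries an event; the
#' patient with the earlier event time should have the higher risk. Tied risks
#' on a comparable pair count 0.5 (tied event times are not comparable).
#'
#' @param time follow-up times.
#' @param event event indicators (1 death, 0 censored).
#' @param risk predicted risk scores (higher = worse prognosis).
#' @return the concordance index in `[0, 1]`; errors when no pair is
#'   comparable (e.g. all-censored input).
#' @export
c_index <- function(time, event, risk) {
  n <- length(time)
  if (length(event) != n || length(risk) != n) stopf("length mismatch")
  if (!any(event == 1)) stopf("no events: no comparable pairs")
  # comparable: t_i < t_j and e_i = 1; evaluated in row blocks so large
  # cohorts never materialize an n x n matrix
  n_comp <- 0; conc <- 0
  block <- max(1L, min(n, as.integer(2^22 / n)))
  for (start in seq(1L, n, by = block)) {
    i <- start:min(n, start + block - 1L)
    comp <- outer(time[i], time, "<") & (event[i] == 1)
    dr <- outer(risk[i], risk, "-")
    n_comp <- n_comp + sum(comp)
    conc <- conc + sum(comp & (dr > 0)) + 0.5 * sum(comp & (dr == 0))
  }
  if (n_comp == 0) stopf("no comparable pairs")
  conc / n_comp
}

#' Classification accuracy
#'
#' @param labels binary reference labels.
#' @param predictions binary predictions.
#' @return fraction of exact matches.
#' @export
accuracy <- function(labels, predictions) {
  if (length(labels) != length(predictions)) stopf("length mismatch")
  mean(labels == predictions)
}

#' Stratified 60/20/20 splits with 5-fold disjoint test sets
#'
#' Partitions the cohort into `k` event-stratified test sets of 20% each
#' (disjoint; their union is the cohort); for every fold the remaining 80% is
#' split 60/20 (of the cohort) into training and validation, again stratified
#' by event status. Fixed seed gives identical folds.
#'
#' @param event event indicator vector (stratification variable).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of `k` folds, each a list with `train`, `val`, `test` integer
#'   indices.
#' @export
split_and_cv <- function(event, k = 5L, seed = 1L) {
  n <- length(event)
  if (min(table(event)) < k) stopf("too few patients in a stratum for %d folds", k)
  with_seed(seed, function() {
    fold_of <- integer(n)
    for (g in unique(event)) {
      idx <- sample(which(event == g))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
    lapply(seq_len(k), function(f) {
      test <- which(fold_of == f)
      rest <- which(fold_of != f)
      val <- integer(0)
      for (g in unique(event)) {
        idx <- sample(rest[event[rest] == g])
        n_val <- round(0.25 * length(idx))  # 20% of cohort = 25% of the rest
        val <- c(val, idx[seq_len(n_val)])
      }
      val <- sort(val)
      list(train = sort(setdiff(rest, val)), val = val, test = sort(test))
    })
  })
}

#' Cross-validated evaluation of the survival model
#'
#' Fits the model on each fold's training set and reports the concordance
#' index on the disjoint test sets.
#'
#' @param cohort a `privsurv_cohort`.
#' @param config a [privsurv_config()].
#' @param privacy optional [privacy_config()].
#' @param preprocess a [preprocess_config()].
#' @param k folds (default 5).
#' @param seed integer seed (splits and fits).
#' @return list with `per_fold` C-indexes, `mean`, `sd`, and the folds.
#' @export
evaluate_cv <- function(cohort, config = privsurv_config(), privacy = NULL,
                        preprocess = preprocess_config(variance_threshold = numeric(0)),
                        k = 5L, seed = 1L) {
  folds <- split_and_cv(cohort$outcomes$event, k = k, seed = seed)
  ci <- vapply(seq_along(folds), function(f) {
    tr <- cohort_subset(cohort, folds[[f]]$train)
    te <- cohort_subset(cohort, folds[[f]]$test)
    fit <- privsurv(tr, config, privacy = privacy, preprocess = preprocess,
                    seed = seed + f)
    c_index(te$outcomes$time, te$outcomes$event, predict_risk(fit, te))
  }, 1.0)
  list(per_fold = ci, mean = mean(ci), sd = stats::sd(ci), folds = folds)
}

#' Bootstrap paired comparison of survival models
#'
#' Draws bootstrap resamples of the test patients, recomputes each model's
#' C-index per resample, and compares models pairwise. The paired bootstrap
#' distribution of the difference estimates the sampling standard error of the
#' observed difference; the two-sided p-value uses `z = mean(diff) / sd(diff)`
#' against the normal reference (resamples are not independent observations,
#' so the bootstrap sd is used as the SE of the difference, not divided by
#' `sqrt(n_boot)`), with Bonferroni multiplication across comparisons.
#' Percentile 95% confidence intervals are reported per model. Resamples with
#' no comparable pair are redrawn (and counted).
#'
#' @param risks named list of per-model risk score vectors on a common test set.
#' @param time,event test-set outcomes.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @return list with `comparisons` (data frame: `model_a`, `model_b`, `delta`,
#'   `p_adjusted`, `ci_low`, `ci_high` of the difference), `ci` (per-model
#'   percentile CIs and point estimates), `boot` (n_boot x models C-index
#'   matrix), `n_redrawn`.
#' @export
bootstrap_compare <- function(risks, time, event, n_boot = 1000L, seed = 1L) {
  if (length(risks) < 2L) stopf("need at least two models to compare")
  if (is.null(names(risks))) names(risks) <- sprintf("model%d", seq_along(risks))
  n <- length(time)
  models <- names(risks)
  point <- vapply(risks, function(r) c_index(time, event, r), 1.0)
  boot <- matrix(NA_real_, n_boot, length(models),
                 dimnames = list(NULL, models))
  n_redrawn <- 0L
  with_seed(seed, function() {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        ok <- any(event[idx] == 1 & time[idx] < max(time[idx]))
        if (ok) break
        n_redrawn <<- n_redrawn + 1L
      }
      for (m in models) boot[b, m] <<- c_index(time[idx], event[idx], risks[[m]][idx])
    }
  })
  pairs <- utils::combn(models, 2L, simplify = FALSE)
  n_cmp <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    d <- boot[, pr[1L]] - boot[, pr[2L]]
    md <- mean(d); sdd <- stats::sd(d)
    p <- if (sdd == 0) { if (abs(md) < .Machine$double.eps^0.5) 1 else 0 }
         else 2 * stats::pnorm(-abs(md / sdd))
    data.frame(model_a = pr[1L], model_b = pr[2L], delta = md,
               p_adjusted = min(1, p * n_cmp),
               ci_low = unname(stats::quantile(d, 0.025, type = 7)),
               ci_high = unname(stats::quantile(d, 0.975, type = 7)),
               stringsAsFactors = FALSE)
  })
  ci <- data.frame(model = models, c_index = unname(point),
                   ci_low = apply(boot, 2L, stats::quantile, 0.025),
                   ci_high = apply(boot, 2L, stats::quantile, 0.975),
                   stringsAsFactors = FALSE, row.names = NULL)
  list(comparisons = do.call(rbind, rows), ci = ci, boot = boot,
       n_redrawn = n_redrawn)
}
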