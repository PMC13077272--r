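#' Partition relevance scores into threshold intervals
#'
#' Divides the score range into `n` nonoverlapping intervals at nearest-rank
#' quantile cut points, ordered so that `T_1` holds the features with the
#' highest relevance scores. Every feature is assigned to exactly one
#' interval. When the scores carry fewer distinct cut points than requested
#' (heavy ties, or `n` above the number of distinct scores), the interval
#' count is reduced with a warning.
#'
#' @param scores numeric vector of relevance scores (names preserved).
#' @param n requested interval count (at least 2).
#' @return an object of class `budget_intervals`: `n` (effective count),
#'   `cuts` (ascending cut points), `assignment` (interval index per feature,
#'   1 = highest scores).
#' @export
partition_intervals <- function(scores, n) {
  if (!length(scores)) stopf("scores must be nonempty")
  if (n < 2L) stopf("n must be at least 2")
  n <- as.integer(n)
  n_distinct <- length(unique(scores))
  if (n > n_distinct) {
    warnf("n = %d exceeds the %d distinct score(s); reducing", n, n_distinct)
    n <- max(1L, n_distinct)
  }
  cuts <- if (n > 1L) unique(nearest_rank(scores, seq_len(n - 1L) / n * 100)) else numeric(0)
  if (length(cuts) + 1L < n) {
    warnf("tied scores collapse the partition to %d interval(s)", length(cuts) + 1L)
    n <- length(cuts) + 1L
  }
  above <- vapply(scores, function(s) sum(s > cuts), 0L)
  assignment <- n - above
  names(assignment) <- names(scores)
  structure(list(n = n, cuts = cuts, assignment = assignment),
            class = "budget_intervals")
}

#' Map an interval index to its privacy parameter
#'
#' The strictly monotone budget map: linear interpolation from `eps_max` (the
#' highest-relevance interval, `k = 1`, least noise) down to `eps_min`
#' (`k = n`), plus a bounded uniform perturbation `delta_k ~ U(-Delta, Delta)`
#' that preserves strict monotonicity, clamped to `[eps_min, eps_max]`.
#'
#' @param k interval index or vector of indices in `1..n`.
#' @param n interval count.
#' @param eps_max,eps_min permissible budget range (defaults 0.5 and 0.1).
#' @param Delta perturbation bound; must be below half the deterministic
#'   spacing `(eps_max - eps_min)/(n - 1)` so the sequence stays strictly
#'   decreasing.
#' @param seed integer seed for the perturbation draws.
#' @return `eps_k` values, strictly decreasing in `k`.
#' @export
eta_map <- function(k, n, eps_max = 0.5, eps_min = 0.1, Delta = 0, seed = 1L) {
  if (any(k < 1L) || any(k > n)) stopf("k must lie in 1..n")
  if (eps_max <= eps_min) stopf("eps_max must exceed eps_min")
  if (n == 1L) return(rep(eps_max, length(k)))
  spacing <- (eps_max - eps_min) / (n - 1)
  if (Delta < 0) stopf("Delta must be nonnegative")
  if (Delta >= spacing / 2)
    stopf("Delta = %g does not guarantee strict monotonicity (needs < %g)", Delta, spacing / 2)
  delta <- if (Delta > 0)
    with_seed(seed, function() stats::runif(n, -Delta, Delta)) else rep(0, n)
  eps <- eps_min + (eps_max - eps_min) * (n - k) / (n - 1) + delta[k]
  pmin(eps_max, pmax(eps_min, eps))
}

#' Allocate the global privacy budget from relevance scores
#'
#' Splits the global budget equally across the three protected genomic
#' modalities. Within a modality, input-feature relevance scores are
#' partitioned into intervals, each interval receives a raw budget from the
#' monotone [eta_map()] (higher relevance, higher budget, less noise), and the
#' modality's remaining protected parameters (deeper layers, biases, batch
#' norm) form one extra group at the mean raw interval budget. Group budgets
#' are rescaled so the modality's composed spend per gradient release equals
#' its share of the global budget: because every per-sample gradient is
#' L1-clipped jointly across the whole modality, one release perturbed with
#' per-group scales `2C/(|L| eps_k)` has privacy loss at most
#' `(2C/|L|) * max_k (1/b_k) = max_k eps_k`, so the modality spend is the
#' maximum group budget and the top interval receives the full share.
#'
#' @param relevance a [feature_relevance()] map, or a named list of per-feature
#'   score vectors for `mRNA`, `miRNA`, `CNV`.
#' @param global_epsilon global privacy budget (default 0.8).
#' @param n_intervals requested interval count (default 4).
#' @param eps_max,eps_min raw budget range (defaults 0.5, 0.1).
#' @param Delta perturbation bound; default `0.4 * (eps_max - eps_min) / (n - 1)`.
#' @param seed integer seed for the budget perturbation.
#' @param uniform logical: ignore relevance and give every group the same
#'   budget (the uniform-noise ablation at identical global epsilon).
#' @return an object of class `budget_allocation`.
#' @export
allocate_budgets <- function(relevance, global_epsilon = 0.8, n_intervals = 4L,
                             eps_max = 0.5, eps_min = 0.1, Delta = NULL,
                             seed = 1L, uniform = FALSE) {
  scores <- if (inherits(relevance, "relevance_map")) relevance$input else relevance
  protected <- c("mRNA", "miRNA", "CNV")
  miss <- setdiff(protected, names(scores))
  if (length(miss))
    stopf("relevance scores missing for protected modalit%s: %s",
          if (length(miss) > 1) "ies" else "y", paste(miss, collapse = ", "))
  if (is.null(Delta)) Delta <- 0.4 * (eps_max - eps_min) / max(1L, n_intervals - 1L)
  share <- global_epsilon / length(protected)
  mods <- list()
  for (i in seq_along(protected)) {
    m <- protected[i]
    part <- partition_intervals(scores[[m]], n_intervals)
    n_eff <- part$n
    raw <- if (n_eff > 1L)
      eta_map(seq_len(n_eff), n_eff, eps_max, eps_min,
              min(Delta, 0.49 * (eps_max - eps_min) / (n_eff - 1)),
              seed = seed)
    else eps_max
    raw <- c(raw, mean(raw))  # remainder group: deeper layers / biases
    # uniform ablation: every group at the full modality share (identical
    # joint-release guarantee, no relevance guidance)
    eps_groups <- if (uniform) rep(share, length(raw))
                  else raw * share / max(raw)
    eps_feature <- eps_groups[part$assignment]
    names(eps_feature) <- names(scores[[m]])
    mods[[m]] <- list(intervals = part, eps_groups = eps_groups,
                      eps_feature = eps_feature)
  }
  structure(list(modalities = mods, global_epsilon = global_epsilon,
                 n_intervals = n_intervals, eps_max = eps_max,
                 eps_min = eps_min, Delta = Delta, seed = seed,
                 uniform = uniform),
            class = "budget_allocation")
}

#' @export
print.budget_allocation <- function(x, ...) {
  cat(sprintf("Privacy budget allocation (global epsilon %.3g%s)\n",
              x$global_epsilon, if (x$uniform) ", uniform" else ", adaptive"))
  for (m in names(x$modalities)) {
    g <- x$modalities[[m]]$eps_groups
    cat(sprintf("  %-6s %d interval group(s) + remainder: %s (joint release %.6f)\n",
                m, length(g) - 1L, paste(sprintf("%.4f", g), collapse = ", "),
                max(g)))
  }
  invisible(x)
}

#' Clip a per-sample gradient to an L1 bound
#'
#' Rescales the gradient so its L1 norm is at most `C`; gradients already
#' within the bound are returned unchanged (direction is always preserved).
#'
#' @param g numeric vector/matrix gradient.
#' @param C positive L1 bound.
#' @return the clipped gradient, same shape as `g`.
#' @export
clip_per_sample_gradient <- function(g, C) {
  if (C <= 0) stopf("C must be positive")
  nrm <- sum(abs(g))
  if (nrm <= C) g else g * (C / nrm)
}

#' Draw Laplace noise
#'
#' I.i.d. draws from the Laplace distribution with location 0 and scale `b`,
#' by inverse-CDF transform of uniforms.
#'
#' @param b positive scale.
#' @param n number of draws.
#' @param seed optional integer seed; when `NULL`, draws from the current RNG.
#' @return numeric vector of length `n`.
#' @export
laplace_sample <- function(b, n, seed = NULL) {
  if (b <= 0) stopf("Laplace scale must be positive")
  draw <- function() {
    u <- stats::runif(n, -0.5, 0.5)
    -b * sign(u) * log(1 - 2 * abs(u))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw)
}

#' Summarize a privacy ledger
#'
#' Reports, per protected modality, the budget spent per gradient release:
#' since each release is one jointly-clipped vector with per-group Laplace
#' scales, the modality's formal epsilon-DP guarantee per release is the
#' maximum group budget. Modality spends compose by summation (the three
#' releases see the same batch), giving the global per-release total — the
#' guarantee the mechanism is calibrated to, constant within a
#' relevance-refresh period. The naive basic-composition total across every
#' release of the whole training run is reported separately and clearly
#' labelled.
#'
#' @param ledger a data frame with columns `step`, `modality`, `group`,
#'   `epsilon`, `noise_scale`, as recorded by private training.
#' @param global_epsilon optional global budget to audit against.
#' @return list with `per_modality` (per-release spend by modality),
#'   `per_release_total`, `naive_total` (across-training basic composition),
#'   `n_releases`, and `within_budget`.
#' @export
accountant_report <- function(ledger, global_epsilon = NULL) {
  if (is.null(ledger) || nrow(ledger) == 0L) {
    return(list(per_modality = numeric(0), per_release_total = 0,
                naive_total = 0, n_releases = 0L, within_budget = TRUE))
  }
  steps <- sort(unique(ledger$step))
  first <- ledger[ledger$step == steps[1L], ]
  template <- tapply(first$epsilon, first$modality, max)
  per_step <- vapply(steps, function(s) {
    sub <- ledger[ledger$step == s, ]
    tapply(sub$epsilon, sub$modality, max)
  }, template)
  per_modality <- if (is.matrix(per_step)) rowMeans(per_step) else mean(per_step)
  per_release_total <- sum(per_modality)
  naive_total <- if (is.matrix(per_step)) sum(colSums(per_step)) else sum(per_step)
  within <- if (is.null(global_epsilon)) TRUE
            else per_release_total <= global_epsilon + 1e-9
  list(per_modality = per_modality,
       per_release_total = per_release_total,
       naive_total = naive_total,
       n_releases = length(steps),
       within_budget = within)
}
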