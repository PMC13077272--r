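#' Model configuration
#'
#' Architecture and optimization settings for [privsurv()]. The defaults
#' follow the reference experimental settings: Adam with a fixed learning rate
#' of 0.001, batch size 256, 100 training epochs, representation length 128.
#'
#' @param head survival head: `"discrete"` (discrete-time likelihood over
#'   `time_bins` conditional hazards, the default) or `"cox"` (Cox partial
#'   likelihood, non-private only).
#' @param time_bins number of discrete time bins (equal-quantile edges from
#'   the training times).
#' @param d representation length (divisible by `H`).
#' @param H attention head count.
#' @param hidden_widths named list of hidden FC widths per genomic modality.
#' @param dropout_rate dropout probability (training mode only).
#' @param use_batchnorm batch normalization in the genomic encoders.
#' @param embedding_dims named embedding widths for the clinical fields.
#' @param optimizer `"adam"` or `"sgd"` (heavy-ball momentum; set
#'   `momentum = 0` for the plain update).
#' @param momentum SGD momentum coefficient.
#' @param learning_rate step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param lambda L2 regularization weight added to the gradient.
#' @param relevance_refresh recompute relevance-guided budgets every this many
#'   epochs during private training.
#' @param stabilizer LRP stabilizer.
#' @param verbose print a line per epoch while fitting.
#' @return an object of class `privsurv_config`.
#' @export
privsurv_config <- function(head = c("discrete", "cox"),
                            time_bins = 20L,
                            d = 128L,
                            H = 4L,
                            hidden_widths = NULL,
                            dropout_rate = 0.1,
                            use_batchnorm = TRUE,
                            embedding_dims = NULL,
                            optimizer = c("adam", "sgd"),
                            momentum = 0.9,
                            learning_rate = 0.001,
                            batch_size = 256L,
                            epochs = 100L,
                            lambda = 0,
                            relevance_refresh = 5L,
                            stabilizer = 1e-6,
                            verbose = FALSE) {
  head <- match.arg(head)
  optimizer <- match.arg(optimizer)
  d <- as.integer(d); H <- as.integer(H)
  if (d %% H != 0L) stopf("d = %d must be divisible by H = %d", d, H)
  if (is.null(hidden_widths))
    hidden_widths <- list(mRNA = c(512L, 128L), miRNA = c(256L, 128L),
                          CNV = c(512L, 128L))
  structure(list(head = head, time_bins = as.integer(time_bins), d = d, H = H,
                 hidden_widths = hidden_widths, dropout_rate = dropout_rate,
                 use_batchnorm = isTRUE(use_batchnorm),
                 embedding_dims = embedding_dims,
                 optimizer = optimizer, momentum = momentum,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 lambda = lambda, relevance_refresh = as.integer(relevance_refresh),
                 stabilizer = stabilizer, verbose = isTRUE(verbose)),
            class = "privsurv_config")
}

#' Privacy configuration
#'
#' Settings of the relevance-guided adaptive Laplace mechanism applied to the
#' genomic encoders' training gradients. The clinical branch and the fusion
#' layer are never perturbed.
#'
#' @param global_epsilon global privacy budget composed across the three
#'   protected modalities per gradient release (default 0.8).
#' @param clip_bound per-sample L1 gradient bound `C` per protected modality.
#' @param n_intervals relevance interval count (default 4).
#' @param eps_max,eps_min raw budget range of the interval map.
#' @param Delta budget perturbation bound; see [eta_map()].
#' @param uniform logical: the uniform-noise ablation (same global budget,
#'   equal group budgets, no relevance guidance).
#' @param reference_size number of training patients in the fixed reference
#'   batch used for relevance refreshes.
#' @return an object of class `privacy_config`.
#' @export
privacy_config <- function(global_epsilon = 0.8, clip_bound = 1.0,
                           n_intervals = 4L, eps_max = 0.5, eps_min = 0.1,
                           Delta = NULL, uniform = FALSE,
                           reference_size = 512L) {
  if (global_epsilon <= 0) stopf("global_epsilon must be positive")
  if (clip_bound <= 0) stopf("clip_bound must be positive")
  structure(list(global_epsilon = global_epsilon, clip_bound = clip_bound,
                 n_intervals = as.integer(n_intervals), eps_max = eps_max,
                 eps_min = eps_min, Delta = Delta, uniform = isTRUE(uniform),
                 reference_size = as.integer(reference_size)),
            class = "privacy_config")
}

PROTECTED_MODALITIES <- c("mRNA", "miRNA", "CNV")

# ---- parameter initialisation -------------------------------------------------

build_model_params <- function(prep, config, seed) {
  enc_cfgs <- list()
  encoders <- list()
  i <- 0L
  for (m in names(prep$blocks)) {
    i <- i + 1L
    cfg <- encoder_config(m, hidden_widths = config$hidden_widths[[m]],
                          rep_length = config$d,
                          dropout_rate = config$dropout_rate,
                          use_batchnorm = config$use_batchnorm)
    encoders[[m]] <- build_encoder(cfg, ncol(prep$blocks[[m]]$values),
                                   seed = seed + i)
    enc_cfgs[[m]] <- cfg
  }
  clin_cfg <- encoder_config("clinical", rep_length = config$d,
                             dropout_rate = config$dropout_rate,
                             embedding_dims = config$embedding_dims)
  n_levels <- vapply(prep$clinical_enc$vocab$levels, length, 1L)
  clinical <- build_clinical_encoder(clin_cfg, n_levels,
                                     n_continuous = ncol(prep$clinical_enc$cont),
                                     seed = seed + 101L)
  fusion <- fusion_params(config$d, config$H, config$dropout_rate,
                          seed = seed + 202L)
  k_out <- if (config$head == "discrete") config$time_bins else 1L
  head <- with_seed(seed + 303L, function() {
    h <- init_linear(config$d, k_out)
    h$type <- config$head
    h
  })
  list(clinical = clinical, encoders = encoders, fusion = fusion, head = head)
}

# ---- forward / backward -------------------------------------------------------

# prep: list(blocks, clinical_enc). Returns output logits plus all caches
# needed for the backward pass and for LRP.
model_forward <- function(params, prep, mode = c("eval", "train"), rng = NULL) {
  mode <- match.arg(mode)
  clin <- encode_clinical_branch(params$clinical, prep$clinical_enc$cat,
                                 prep$clinical_enc$cont, mode, rng)
  reps <- list(clinical = clin$out)
  enc_caches <- list()
  for (m in names(params$encoders)) {
    ef <- encoder_forward(params$encoders[[m]], prep$blocks[[m]]$values, mode, rng)
    reps[[m]] <- ef$out
    enc_caches[[m]] <- ef$cache
    params$encoders[[m]] <- ef$encoder  # running BN stats
  }
  bundle <- stack_representations(reps)
  fw <- fuse_forward(bundle, params$fusion, mode, rng)
  o <- fw$F_drop %*% params$head$W + rep(params$head$b, each = nrow(fw$F_drop))
  list(o = o, fuse = fw, bundle = bundle,
       caches = list(clinical = clin$cache, encoders = enc_caches),
       params = params)
}

# d_o rows are per-sample gradients of the per-patient loss w.r.t. the output
# logits. Returns the averaged gradient tree plus the raw per-sample encoder
# factors needed for privacy clipping.
model_backward <- function(params, fwd, d_o) {
  n <- nrow(d_o)
  g_head <- list(W = crossprod(fwd$fuse$F_drop, d_o) / n, b = colMeans(d_o))
  d_F <- d_o %*% t(params$head$W)
  fb <- fuse_backward(fwd$fuse, params$fusion, d_F)
  mods <- attr(fwd$bundle, "modality_order")
  grads <- list(head = g_head, fusion = list(W = fb$g_W, q = fb$g_q),
                encoders = list())
  enc_bwd <- list()
  for (i in seq_along(mods)) {
    m <- mods[i]
    if (m == "clinical") {
      grads$clinical <- clinical_backward(params$clinical,
                                          fwd$caches$clinical, fb$d_tok[[i]])
    } else {
      bwd <- encoder_backward(params$encoders[[m]],
                              fwd$caches$encoders[[m]], fb$d_tok[[i]])
      enc_bwd[[m]] <- bwd
      grads$encoders[[m]] <- list(layers = encoder_grads(bwd))
    }
  }
  list(grads = grads, enc_bwd = enc_bwd)
}

# ---- survival losses ----------------------------------------------------------

#' Discrete-time right-censored survival loss
#'
#' Negative log-likelihood of a discrete-time survival model with per-bin
#' conditional hazards: a patient with an event in bin `k` contributes the
#' hazard at `k` and survival through the earlier bins; a censored patient
#' contributes survival through bin `k` inclusive. Returns the mean
#' per-patient negative log-likelihood.
#'
#' @param hazards matrix (patients x bins) of conditional hazards in `[0, 1]`.
#' @param bin integer bin index per patient (1-based).
#' @param event event indicator (1 death, 0 censored).
#' @return scalar loss.
#' @export
survival_loss <- function(hazards, bin, event) {
  hazards <- as.matrix(hazards)
  n <- nrow(hazards); K <- ncol(hazards)
  if (length(bin) != n || length(event) != n) stopf("length mismatch")
  if (any(bin < 1L | bin > K)) stopf("bin index outside 1..%d", K)
  log_h <- log(pmax(hazards, 1e-12))
  log_s <- log(pmax(1 - hazards, 1e-12))
  cols <- matrix(seq_len(K), n, K, byrow = TRUE)
  lt <- cols < bin
  eq <- cols == bin
  ll <- rowSums(log_s * lt) + event * log_h[cbind(seq_len(n), bin)] +
    (1 - event) * log_s[cbind(seq_len(n), bin)]
  -mean(ll)
}

# Gradient of the per-patient discrete loss w.r.t. the logits o (rows are
# per-sample gradients; hazards = sigmoid(o)).
discrete_loss_grad <- function(hazards, bin, event) {
  n <- nrow(hazards); K <- ncol(hazards)
  cols <- matrix(seq_len(K), n, K, byrow = TRUE)
  lt <- cols < bin
  eq <- cols == bin
  d <- hazards * lt + eq * (hazards - event)
  d
}

#' Cox negative partial log-likelihood (Breslow ties)
#'
#' @param risk linear risk score per patient.
#' @param time follow-up times (positive).
#' @param event event indicator.
#' @return list with `loss` (mean over events) and `grad` (per-patient).
#' @export
cox_partial_loss <- function(risk, time, event) {
  if (any(time <= 0)) stopf("nonpositive times")
  n <- length(risk)
  if (sum(event) == 0L) stopf("no events: partial likelihood undefined")
  er <- exp(risk - max(risk))
  # risk-set sums: patients with t_j >= t_i
  ord <- order(time)
  er_ord <- er[ord]
  rev_cum <- rev(cumsum(rev(er_ord)))  # sum over t_j >= t_(i), Breslow
  # map each event time to its risk-set sum (ties share the full tied set)
  t_ord <- time[ord]
  first_at <- match(t_ord, t_ord)      # first index of each tied block
  S_i <- rev_cum[first_at]
  ev_ord <- event[ord] == 1L
  loss <- -sum((risk[ord][ev_ord] - max(risk)) - log(S_i[ev_ord])) / sum(event)
  # gradient: -e_k + exp(r_k) * sum over events i with t_i <= t_k of 1/S_i
  cum_inv <- cumsum(ifelse(ev_ord, 1 / S_i, 0))
  last_at <- length(t_ord) + 1L - match(t_ord, rev(t_ord))  # last index of tied block
  g_ord <- -as.numeric(ev_ord) + er_ord * cum_inv[last_at]
  g <- numeric(n)
  g[ord] <- g_ord / sum(event)
  list(loss = loss, grad = g)
}

# ---- parameter tree walking ---------------------------------------------------

get_path <- function(x, path) { for (p in path) x <- x[[p]]; x }

set_path <- function(x, path, value) {
  if (length(path) == 1L) { x[[path[[1L]]]] <- value; return(x) }
  x[[path[[1L]]]] <- set_path(x[[path[[1L]]]], path[-1L], value)
  x
}

# Enumerate trainable parameter slots: list(path, modality or NA, first_W flag)
param_slots <- function(params) {
  slots <- list()
  add <- function(path, modality = NA_character_, first_W = FALSE)
    slots[[length(slots) + 1L]] <<- list(path = path, modality = modality,
                                         first_W = first_W)
  for (f in params$clinical$fields) add(list("clinical", "emb", f))
  add(list("clinical", "W")); add(list("clinical", "b"))
  for (m in names(params$encoders)) {
    enc <- params$encoders[[m]]
    for (l in seq_along(enc$layers)) {
      add(list("encoders", m, "layers", l, "W"), m, first_W = (l == 1L))
      add(list("encoders", m, "layers", l, "b"), m)
      if (!is.null(enc$layers[[l]]$gamma)) {
        add(list("encoders", m, "layers", l, "gamma"), m)
        add(list("encoders", m, "layers", l, "beta"), m)
      }
    }
  }
  add(list("fusion", "W")); add(list("fusion", "q"))
  add(list("head", "W")); add(list("head", "b"))
  slots
}

# Map a slot path from the params tree to the grads tree (identical nesting).
grad_at <- function(grads, path) get_path(grads, path)

# ---- optimizer ----------------------------------------------------------------

init_opt_state <- function(slots) {
  list(t = 0L, m = vector("list", length(slots)), v = vector("list", length(slots)))
}

apply_update <- function(params, grads, slots, opt, state, lr, lambda,
                         momentum = 0.9) {
  state$t <- state$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (s in seq_along(slots)) {
    path <- slots[[s]]$path
    g <- grad_at(grads, path)
    if (is.null(g)) next
    th <- get_path(params, path)
    if (lambda > 0) g <- g + lambda * th
    if (opt == "adam") {
      if (is.null(state$m[[s]])) { state$m[[s]] <- g * 0; state$v[[s]] <- g * 0 }
      state$m[[s]] <- b1 * state$m[[s]] + (1 - b1) * g
      state$v[[s]] <- b2 * state$v[[s]] + (1 - b2) * g^2
      mhat <- state$m[[s]] / (1 - b1^state$t)
      vhat <- state$v[[s]] / (1 - b2^state$t)
      th <- th - lr * mhat / (sqrt(vhat) + eps)
    } else if (momentum > 0) {
      if (is.null(state$m[[s]])) state$m[[s]] <- g * 0
      state$m[[s]] <- momentum * state$m[[s]] + g
      th <- th - lr * state$m[[s]]
    } else {
      th <- th - lr * g
    }
    params <- set_path(params, path, th)
  }
  list(params = params, state = state)
}

# ---- privacy step internals ---------------------------------------------------

# Replace a protected modality's averaged gradients with clipped per-sample
# aggregates and add Laplace noise per group; appends ledger rows.
privatize_modality_grads <- function(grads, enc_bwd, m, alloc_m, C, nb,
                                     rng_noise, step, ledger) {
  bwd <- enc_bwd[[m]]
  norms <- encoder_grad_l1(bwd)
  scale_i <- pmin(1, C / pmax(norms, 1e-300))
  clipped <- encoder_grads(bwd, w = scale_i / nb)
  eps_groups <- alloc_m$eps_groups
  n_int <- length(eps_groups) - 1L
  eps_rest <- eps_groups[n_int + 1L]
  assignment <- alloc_m$intervals$assignment
  lay1 <- clipped[[1L]]
  for (k in seq_len(n_int)) {
    rows <- which(assignment == k)
    b_k <- 2 * C / (nb * eps_groups[k])
    if (length(rows)) {
      noise <- rng_eval(rng_noise, function()
        laplace_sample(b_k, length(rows) * ncol(lay1$W)))
      lay1$W[rows, ] <- lay1$W[rows, , drop = FALSE] +
        matrix(noise, length(rows), ncol(lay1$W))
    }
    ledger$rows[[length(ledger$rows) + 1L]] <-
      data.frame(step = step, modality = m, group = sprintf("T%d", k),
                 epsilon = eps_groups[k], noise_scale = b_k,
                 stringsAsFactors = FALSE)
  }
  clipped[[1L]] <- lay1
  b_rest <- 2 * C / (nb * eps_rest)
  for (l in seq_along(clipped)) {
    for (nm in names(clipped[[l]])) {
      if (l == 1L && nm == "W") next
      g <- clipped[[l]][[nm]]
      noise <- rng_eval(rng_noise, function() laplace_sample(b_rest, length(g)))
      clipped[[l]][[nm]] <- g + if (is.null(dim(g))) noise else
        matrix(noise, nrow(g), ncol(g))
    }
  }
  ledger$rows[[length(ledger$rows) + 1L]] <-
    data.frame(step = step, modality = m, group = "rest",
               epsilon = eps_rest, noise_scale = b_rest,
               stringsAsFactors = FALSE)
  grads$encoders[[m]]$layers <- clipped
  grads
}

ledger_df <- function(ledger) {
  if (!length(ledger$rows)) {
    return(data.frame(step = integer(0), modality = character(0),
                      group = character(0), epsilon = numeric(0),
                      noise_scale = numeric(0)))
  }
  do.call(rbind, ledger$rows)
}

# ---- time bins ----------------------------------------------------------------

make_time_bins <- function(time, K) {
  inner <- unique(stats::quantile(time, probs = seq_len(K - 1L) / K,
                                  type = 7, names = FALSE))
  list(edges = inner, K = length(inner) + 1L)
}

assign_bins <- function(time, bins) {
  vapply(time, function(t) 1L + sum(t > bins$edges), 1L)
}

# ---- training -----------------------------------------------------------------

#' Fit the multimodal attention survival model
#'
#' End-to-end fit on a multimodal cohort: per-modality preprocessing (fitted
#' on this cohort and frozen into the model), first-layer encoders, multihead
#' attention fusion, and a survival head, trained by minibatch gradient
#' descent on the right-censored likelihood. With a [privacy_config()], the
#' genomic encoders' per-sample gradients are L1-clipped and perturbed with
#' relevance-guided adaptive Laplace noise; budgets are refreshed from
#' layer-wise relevance propagation every `relevance_refresh` epochs and every
#' release is recorded in the privacy ledger.
#'
#' @param cohort a `privsurv_cohort` (treated as the training set).
#' @param config a [privsurv_config()].
#' @param privacy a [privacy_config()], or `NULL` for non-private training.
#' @param preprocess a [preprocess_config()]; by default no variance screening
#'   is applied (thresholds are data-scale specific) and features are min-max
#'   normalized.
#' @param seed integer seed controlling initialization, batching and dropout;
#'   privacy noise uses an independent stream derived from the same seed.
#' @return an object of class `privsurv` with elements `params`, `config`,
#'   `privacy`, `prep` (frozen statistics, vocabulary, feature lists), `bins`,
#'   `history` (per-epoch loss), `ledger`, `allocation`, `seed`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 120,
#'   dims = c(mRNA = 15, miRNA = 10, CNV = 12),
#'   n_informative = c(mRNA = 2, miRNA = 1, CNV = 2), seed = 3))
#' fit <- privsurv(coh, privsurv_config(d = 16, H = 2,
#'   hidden_widths = list(mRNA = 8, miRNA = 8, CNV = 8),
#'   time_bins = 5, epochs = 2, batch_size = 64), seed = 3)
#' head(predict(fit))
#' @export
privsurv <- function(cohort, config = privsurv_config(), privacy = NULL,
                     preprocess = preprocess_config(variance_threshold = numeric(0)),
                     seed = 1L) {
  stopifnot(inherits(cohort, "privsurv_cohort"))
  if (!is.null(privacy) && config$head == "cox")
    stopf("the Cox partial-likelihood head is not per-sample separable; use the discrete head for private training")
  prep_fit <- preprocess_cohort(cohort, preprocess)
  prep <- list(blocks = prep_fit$blocks, clinical_enc = prep_fit$clinical_enc)
  n <- nrow(cohort$outcomes)
  time <- cohort$outcomes$time
  event <- cohort$outcomes$event
  if (any(time <= 0)) stopf("nonpositive survival times")

  bins <- if (config$head == "discrete") make_time_bins(time, config$time_bins) else NULL
  bin_idx <- if (!is.null(bins)) assign_bins(time, bins) else NULL
  cfg <- config
  if (!is.null(bins)) cfg$time_bins <- bins$K

  params <- build_model_params(prep, cfg, seed)
  if (cfg$head == "discrete") {
    # initialize the output bias at the cohort's baseline per-bin hazard so
    # training starts from the marginal survival curve
    K <- bins$K
    at_risk <- vapply(seq_len(K), function(j) sum(bin_idx >= j), 1)
    ev <- vapply(seq_len(K), function(j) sum(bin_idx == j & event == 1), 1)
    base_h <- pmin(0.95, pmax(0.005, ev / pmax(at_risk, 1)))
    params$head$b <- stats::qlogis(base_h)
  }
  slots <- param_slots(params)
  opt_state <- init_opt_state(slots)
  rng_model <- rng_stream(seed + 1000L)
  rng_noise <- rng_stream(seed + 2000L)
  ledger <- new.env(parent = emptyenv()); ledger$rows <- list()
  allocation <- NULL

  ref_idx <- if (!is.null(privacy)) seq_len(min(privacy$reference_size, n)) else NULL
  refresh_allocation <- function(params) {
    ref_prep <- subset_prep(prep, ref_idx)
    fwd <- model_forward(params, ref_prep, mode = "eval")
    rel <- relevance_from_forward(params, fwd, cfg$stabilizer)
    allocate_budgets(rel, global_epsilon = privacy$global_epsilon,
                     n_intervals = privacy$n_intervals,
                     eps_max = privacy$eps_max, eps_min = privacy$eps_min,
                     Delta = privacy$Delta, seed = seed + 3000L,
                     uniform = privacy$uniform)
  }

  history <- numeric(0)
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    if (!is.null(privacy) && ((epoch - 1L) %% cfg$relevance_refresh == 0L))
      allocation <- refresh_allocation(params)
    ord <- rng_eval(rng_model, function() sample.int(n))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      step <- step + 1L
      bprep <- subset_prep(prep, bt)
      fwd <- model_forward(params, bprep, mode = "train", rng = rng_model)
      params <- fwd$params
      if (cfg$head == "discrete") {
        h <- stats::plogis(fwd$o)
        loss <- survival_loss(h, bin_idx[bt], event[bt])
        d_o <- discrete_loss_grad(h, bin_idx[bt], event[bt])
      } else {
        cl <- cox_partial_loss(as.vector(fwd$o), time[bt], event[bt])
        loss <- cl$loss
        d_o <- matrix(cl$grad, ncol = 1L)
      }
      if (!is.finite(loss)) stopf("training diverged (nonfinite loss) at step %d", step)
      bwd <- model_backward(params, fwd, d_o)
      grads <- bwd$grads
      if (!is.null(privacy)) {
        for (m in intersect(PROTECTED_MODALITIES, names(params$encoders)))
          grads <- privatize_modality_grads(grads, bwd$enc_bwd, m,
                                            allocation$modalities[[m]],
                                            privacy$clip_bound, length(bt),
                                            rng_noise, step, ledger)
      }
      upd <- apply_update(params, grads, slots, cfg$optimizer, opt_state,
                          cfg$learning_rate, cfg$lambda, cfg$momentum)
      params <- upd$params
      opt_state <- upd$state
      ep_loss <- ep_loss + loss * length(bt)
    }
    history <- c(history, ep_loss / n)
    if (cfg$verbose)
      message(sprintf("epoch %3d/%d  loss %.4f", epoch, cfg$epochs, ep_loss / n))
  }

  structure(list(params = params, config = cfg, privacy = privacy,
                 prep = prep_fit, bins = bins,
                 history = history, ledger = ledger_df(ledger),
                 allocation = allocation, seed = seed,
                 n_train = n),
            class = "privsurv")
}

# Subset the preprocessed inputs by patient index.
subset_prep <- function(prep, idx) {
  list(blocks = lapply(prep$blocks, function(b)
         modality_block(b$name, b$values[idx, , drop = FALSE], b$missing_mask[idx])),
       clinical_enc = list(cat = prep$clinical_enc$cat[idx, , drop = FALSE],
                           cont = prep$clinical_enc$cont[idx, , drop = FALSE]))
}

# Resolve `inputs` to a preprocessed batch using the model's frozen pipeline.
resolve_inputs <- function(model, inputs) {
  if (is.null(inputs)) stopf("supply a cohort (or preprocessed inputs)")
  if (inherits(inputs, "privsurv_cohort")) {
    pf <- preprocess_cohort(inputs, model$prep$config, fitted = model$prep)
    list(blocks = pf$blocks, clinical_enc = pf$clinical_enc)
  } else inputs
}

#' Perform one (optionally private) gradient step
#'
#' A single training update on an initialized or fitted model: forward and
#' backward over the given batch, per-sample L1 clipping and adaptive Laplace
#' perturbation of the protected genomic encoder gradients when an allocation
#' is supplied, then a plain SGD update. Clinical-branch and fusion parameters
#' are never perturbed, so with the same `model_seed` their update is
#' identical bit for bit whether or not privacy is on.
#'
#' @param model a fitted [privsurv()] object (its current parameters are the
#'   starting point).
#' @param cohort the cohort supplying the batch.
#' @param batch integer indices of the batch patients.
#' @param allocation a [allocate_budgets()] result, or `NULL` for a noiseless
#'   step.
#' @param clip_bound per-sample L1 bound `C` (ignored when `allocation` is
#'   `NULL`).
#' @param learning_rate SGD step size.
#' @param lambda L2 regularization weight.
#' @param model_seed seed for batching/dropout randomness.
#' @param noise_seed seed of the independent privacy-noise stream.
#' @return list with `model` (updated parameters), `loss`, and `ledger`
#'   (the release's rows, empty for a noiseless step).
#' @export
noisy_gradient_step <- function(model, cohort, batch, allocation = NULL,
                                clip_bound = 1.0, learning_rate = 0.01,
                                lambda = 0, model_seed = 1L, noise_seed = 2L) {
  stopifnot(inherits(model, "privsurv"))
  if (!is.null(allocation)) {
    for (m in intersect(PROTECTED_MODALITIES, names(model$params$encoders)))
      if (any(allocation$modalities[[m]]$eps_groups <= 0))
        stopf("nonpositive group epsilon for modality '%s'", m)
  }
  prep <- resolve_inputs(model, cohort)
  bprep <- subset_prep(prep, batch)
  rng_model <- rng_stream(model_seed)
  rng_noise <- rng_stream(noise_seed)
  params <- model$params
  time <- cohort$outcomes$time[batch]
  event <- cohort$outcomes$event[batch]
  fwd <- model_forward(params, bprep, mode = "train", rng = rng_model)
  params <- fwd$params
  h <- stats::plogis(fwd$o)
  bin_idx <- assign_bins(time, model$bins)
  loss <- survival_loss(h, bin_idx, event)
  d_o <- discrete_loss_grad(h, bin_idx, event)
  bwd <- model_backward(params, fwd, d_o)
  grads <- bwd$grads
  ledger <- new.env(parent = emptyenv()); ledger$rows <- list()
  if (!is.null(allocation)) {
    for (m in intersect(PROTECTED_MODALITIES, names(params$encoders)))
      grads <- privatize_modality_grads(grads, bwd$enc_bwd, m,
                                        allocation$modalities[[m]],
                                        clip_bound, length(batch),
                                        rng_noise, 1L, ledger)
  }
  slots <- param_slots(params)
  upd <- apply_update(params, grads, slots, "sgd", init_opt_state(slots),
                      learning_rate, lambda, momentum = 0)
  model$params <- upd$params
  list(model = model, loss = loss, ledger = ledger_df(ledger))
}

# ---- prediction and methods ---------------------------------------------------

#' Predict from a fitted multimodal survival model
#'
#' Deterministic evaluation-mode forward pass. The default risk score for the
#' discrete head is one minus the mean predicted survival probability across
#' the time bins (higher = worse prognosis); the Cox head returns the linear
#' risk score.
#'
#' @param object a fitted [privsurv()] model.
#' @param newdata a `privsurv_cohort`; the training preprocessing (frozen
#'   statistics, vocabulary, feature alignment) is applied. Defaults to the
#'   training inputs stored in the model.
#' @param type `"risk"` (default), `"survival"` (patients x bins survival
#'   probabilities), `"hazard"` (per-bin conditional hazards), or `"fused"`
#'   (patients x d fused features).
#' @param ... unused.
#' @return a numeric vector or matrix according to `type`.
#' @export
predict.privsurv <- function(object, newdata = NULL,
                             type = c("risk", "survival", "hazard", "fused"),
                             ...) {
  type <- match.arg(type)
  prep <- if (is.null(newdata))
    list(blocks = object$prep$blocks, clinical_enc = object$prep$clinical_enc)
  else resolve_inputs(object, newdata)
  fwd <- model_forward(object$params, prep, mode = "eval")
  if (type == "fused") return(fwd$fuse$M)
  if (object$config$head == "cox") {
    if (type != "risk") stopf("the Cox head provides type = \"risk\" only")
    return(as.vector(fwd$o))
  }
  h <- stats::plogis(fwd$o)
  if (type == "hazard") return(h)
  S <- t(apply(1 - h, 1L, cumprod))
  if (type == "survival") return(S)
  1 - rowMeans(S)
}

#' Risk scores from a fitted model
#'
#' Convenience wrapper around `predict(model, cohort, type = "risk")`.
#'
#' @param model a fitted [privsurv()] model.
#' @param cohort a `privsurv_cohort`.
#' @return numeric risk score per patient; higher means worse prognosis.
#' @export
predict_risk <- function(model, cohort = NULL) predict(model, cohort, type = "risk")

#' @export
print.privsurv <- function(x, ...) {
  cat("Multimodal attention survival model\n")
  cat(sprintf("  head: %s%s | d = %d, H = %d heads\n", x$config$head,
              if (x$config$head == "discrete")
                sprintf(" (%d bins)", x$config$time_bins) else "",
              x$config$d, x$config$H))
  cat(sprintf("  trained %d epochs on %d patients; final loss %.4f\n",
              length(x$history), x$n_train,
              if (length(x$history)) x$history[length(x$history)] else NA))
  if (!is.null(x$privacy)) {
    rep <- accountant_report(x$ledger, x$privacy$global_epsilon)
    cat(sprintf("  private: global epsilon %.3g per release (%s), %d releases, naive composed total %.1f\n",
                rep$per_release_total,
                if (x$privacy$uniform) "uniform" else "adaptive",
                rep$n_releases, rep$naive_total))
  } else cat("  non-private training\n")
  invisible(x)
}

#' @export
summary.privsurv <- function(object, ...) {
  slots <- param_slots(object$params)
  n_par <- sum(vapply(slots, function(s) length(get_path(object$params, s$path)), 1))
  out <- list(config = object$config, n_parameters = n_par,
              n_train = object$n_train, history = object$history,
              privacy = object$privacy,
              accountant = if (!is.null(object$privacy))
                accountant_report(object$ledger, object$privacy$global_epsilon))
  class(out) <- "summary.privsurv"
  out
}

#' @export
print.summary.privsurv <- function(x, ...) {
  cat(sprintf("privsurv model: %d trainable parameters, %d training patients\n",
              x$n_parameters, x$n_train))
  cat(sprintf("  optimizer %s, lr %g, batch %d, %d epochs\n",
              x$config$optimizer, x$config$learning_rate, x$config$batch_size,
              length(x$history)))
  if (length(x$history))
    cat(sprintf("  loss: first %.4f -> last %.4f\n", x$history[1L],
                x$history[length(x$history)]))
  if (!is.null(x$accountant)) {
    cat(sprintf("  privacy: per-release composed epsilon %.4f (budget %.4f)\n",
                x$accountant$per_release_total, x$privacy$global_epsilon))
    cat(sprintf("  naive across-training composition: %.2f over %d releases\n",
                x$accountant$naive_total, x$accountant$n_releases))
  }
  invisible(x)
}

#' @export
coef.privsurv <- function(object, ...) {
  list(head = object$params$head[c("W", "b")],
       fusion = object$params$fusion[c("W", "q")],
       encoders = lapply(object$params$encoders, function(e)
         lapply(e$layers, function(l) l[intersect(names(l), c("W", "b", "gamma", "beta"))])),
       clinical = object$params$clinical[c("emb", "W", "b")])
}

#' @export
plot.privsurv <- function(x, ...) {
  plot(seq_along(x$history), x$history, type = "l", xlab = "epoch",
       ylab = "training loss", main = "privsurv training loss", ...)
  invisible(x)
}

#' Save / load a fitted model
#'
#' Checkpoints round-trip to bit-identical predictions.
#'
#' @param model a fitted [privsurv()] model.
#' @param path file path.
#' @return `save_privsurv` returns `path` invisibly; `load_privsurv` the model.
#' @export
save_privsurv <- function(model, path) {
  stopifnot(inherits(model, "privsurv"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_privsurv
#' @export
load_privsurv <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "privsurv")) stopf("'%s' is not a saved privsurv model", path)
  model
}
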