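#' Affine message of layer-wise relevance propagation
#'
#' The contribution a lower-layer neuron `e` sends to an upper neuron `q`:
#' its activation times the connecting weight, plus an equal share of the
#' upper neuron's bias split among the `fan_in` contributing neurons.
#'
#' @param v_e activation of neuron `e`.
#' @param w_eq weight from `e` to `q`.
#' @param u_q bias of neuron `q`.
#' @param fan_in number of neurons feeding `q`.
#' @return the message value `v_e * w_eq + u_q / fan_in`.
#' @export
affine_message <- function(v_e, w_eq, u_q = 0, fan_in = 1L) {
  v_e * w_eq + u_q / fan_in
}

# sign() with sign(0) = +1, the stabilizer convention.
sign1 <- function(x) ifelse(x >= 0, 1, -1)

#' Propagate relevance backward through one affine layer
#'
#' Epsilon-rule decomposition: the relevance of lower neuron `e` is the sum
#' over upper neurons `q` of `upper_q * message(e -> q) / (sum_e' message(e' -> q)
#' + sign(denominator) * stabilizer)`. The denominator equals the upper
#' neuron's pre-activation, so with a vanishing stabilizer and zero biases the
#' total relevance is conserved layer to layer.
#'
#' @param upper_relevance matrix (patients x upper width) or vector.
#' @param activations lower-layer activations (patients x lower width).
#' @param weights weight matrix (lower width x upper width).
#' @param biases upper-layer bias vector (default zero).
#' @param stabilizer small positive real added with the denominator's sign.
#' @return lower-layer relevance (patients x lower width).
#' @export
lrp_backward_layer <- function(upper_relevance, activations, weights,
                               biases = NULL, stabilizer = 1e-6) {
  if (stabilizer <= 0) stopf("stabilizer must be positive")
  if (is.vector(activations)) activations <- matrix(activations, nrow = 1L)
  if (is.vector(upper_relevance))
    upper_relevance <- matrix(upper_relevance, nrow = nrow(activations))
  p <- ncol(activations)
  if (is.null(biases)) biases <- rep(0, ncol(weights))
  denom <- activations %*% weights + rep(biases, each = nrow(activations))
  denom_st <- denom + sign1(denom) * stabilizer
  C <- upper_relevance / denom_st
  lower <- activations * (C %*% t(weights)) +
    rowSums(sweep(C, 2L, biases, "*")) / p
  if (!all(is.finite(lower))) stopf("nonfinite relevance encountered during propagation")
  lower
}

#' Feature relevance of a fitted model by layer-wise propagation
#'
#' Runs a deterministic evaluation-mode forward pass, initializes the output
#' relevance from the pre-activation survival output (summing across the
#' output head's bins), and propagates it backward: through the output layer
#' to the fused features, to the modality tokens via the attention weighted
#' value sum (weights treated as fixed coefficients), and down each genomic
#' encoder's FC stack (batch normalization folded into the adjacent affine,
#' ReLU passed through) to the input features. Per-feature scores are the
#' mean absolute per-patient relevance.
#'
#' @param model a fitted [privsurv()] model.
#' @param inputs a `privsurv_cohort` or a preprocessed input list; defaults to
#'   the model's stored reference batch when omitted.
#' @param stabilizer epsilon-rule stabilizer (default `1e-6`).
#' @return an object of class `relevance_map`: per-modality input scores
#'   (`input`), per-layer per-neuron scores (`layers`, mean absolute relevance,
#'   output layer first), and the stabilizer used.
#' @export
feature_relevance <- function(model, inputs = NULL, stabilizer = 1e-6) {
  if (!inherits(model, "privsurv")) stopf("model must be a fitted privsurv object")
  prep <- resolve_inputs(model, inputs)
  fwd <- model_forward(model$params, prep, mode = "eval")
  relevance_from_forward(model$params, fwd, stabilizer)
}

# Core LRP pass over cached forward activations; shared with the training loop.
relevance_from_forward <- function(params, fwd, stabilizer = 1e-6) {
  if (is.null(fwd$caches)) stopf("model forward pass did not cache activations")
  mods <- attr(fwd$bundle, "modality_order")
  d <- params$fusion$d
  H <- params$fusion$H
  dh <- d %/% H

  # Output relevance: pre-activation output value per bin, one row per patient.
  R_out <- fwd$o
  # Output layer (F -> o); eval mode so the post-dropout F equals M.
  R_F <- lrp_backward_layer(R_out, fwd$fuse$M, params$head$W, params$head$b,
                            stabilizer)
  # Attention value aggregation: M[, c in head h] = sum_i A[p,h,i] tok_i[p,c];
  # weights are coefficients of a per-patient linear map, so the epsilon rule
  # applies directly with denominator M itself.
  n <- nrow(R_F)
  m <- length(mods)
  denom <- fwd$fuse$M + sign1(fwd$fuse$M) * stabilizer
  R_tok <- vector("list", m)
  for (i in seq_len(m)) {
    R_i <- matrix(0, n, d)
    for (h in seq_len(H)) {
      idx <- (h - 1L) * dh + seq_len(dh)
      contrib <- fwd$fuse$A[, h, i] * fwd$fuse$toks[[i]][, idx, drop = FALSE]
      R_i[, idx] <- R_F[, idx, drop = FALSE] * contrib / denom[, idx, drop = FALSE]
    }
    R_tok[[i]] <- R_i
  }
  names(R_tok) <- mods

  layers <- list()
  input <- list()
  out_scores <- colMeans(abs(R_out))
  for (mod in intersect(c("mRNA", "miRNA", "CNV"), mods)) {
    enc <- params$encoders[[mod]]
    cache <- fwd$caches$encoders[[mod]]
    R <- R_tok[[mod]]
    layer_scores <- list(output = out_scores,
                         token = colMeans(abs(R)))
    for (l in rev(seq_along(enc$layers))) {
      lay <- enc$layers[[l]]
      cc <- cache[[l]]
      if (enc$config$use_batchnorm) {
        scale <- lay$gamma / sqrt(lay$run_var + BN_EPS)
        W_eff <- sweep(lay$W, 2L, scale, "*")
        u_eff <- (lay$b - lay$run_mean) * scale + lay$beta
      } else {
        W_eff <- lay$W
        u_eff <- lay$b
      }
      R <- lrp_backward_layer(R, cc$X, W_eff, u_eff, stabilizer)
      nm <- if (l == 1L) "input" else sprintf("layer%d", l - 1L)
      layer_scores[[nm]] <- colMeans(abs(R))
    }
    feats <- colMeans(abs(R))
    names(feats) <- colnames(cache[[1L]]$X) %||%
      sprintf("%s_f%04d", mod, seq_along(feats))
    input[[mod]] <- feats
    layers[[mod]] <- layer_scores
  }
  structure(list(input = input, layers = layers, stabilizer = stabilizer),
            class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat("Layer-wise relevance map\n")
  for (m in names(x$input))
    cat(sprintf("  %-6s %d input features, top score %.4g\n",
                m, length(x$input[[m]]), max(x$input[[m]])))
  invisible(x)
}

#' Percentile summary of per-layer relevance scores
#'
#' Summarizes each layer's relevance distribution at the 25th, 50th, 75th and
#' 100th percentiles (nearest-rank definition), the layout used to heatmap
#' layer-feature association strength per modality.
#'
#' @param map a [feature_relevance()] result.
#' @return data frame with columns `modality`, `layer`, `p25`, `p50`, `p75`,
#'   `p100`; values are nondecreasing across the percentile columns.
#' @export
percentile_summary <- function(map) {
  stopifnot(inherits(map, "relevance_map"))
  rows <- list()
  for (m in names(map$layers)) {
    for (lname in names(map$layers[[m]])) {
      s <- map$layers[[m]][[lname]]
      if (!length(s)) stopf("layer '%s' of modality '%s' has no scores", lname, m)
      v <- nearest_rank(s, c(25, 50, 75, 100))
      rows[[length(rows) + 1L]] <- data.frame(
        modality = m, layer = lname,
        p25 = v[1L], p50 = v[2L], p75 = v[3L], p100 = v[4L],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export input-feature relevance as a tidy table
#'
#' @param map a [feature_relevance()] result.
#' @return data frame with columns `modality`, `feature_name`, `score`.
#' @export
relevance_table <- function(map) {
  stopifnot(inherits(map, "relevance_map"))
  do.call(rbind, lapply(names(map$input), function(m)
    data.frame(modality = m, feature_name = names(map$input[[m]]),
               score = unname(map$input[[m]]), stringsAsFactors = FALSE)))
}
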