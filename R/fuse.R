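#' Fusion parameters for multihead attention over modality tokens
#'
#' The second-layer fusion treats each patient's modality representations as a
#' small set of tokens. Keys are `K = relu(dropout(B W))` with `W` a trainable
#' d x d matrix initialized from a standard Gaussian; values are the tokens
#' themselves (identity); the query is a single learnable d-vector shared
#' across patients, initialized uniformly on `(-1/sqrt(d), 1/sqrt(d))`. Query,
#' keys and values are split into `H` blocks of width `d/H`, each head applies
#' scaled dot-product attention over the tokens, the head outputs are
#' concatenated, and a final projection vector `w_last` maps the multihead
#' output to the fused feature `Y`.
#'
#' @param d representation length (must be divisible by `H`).
#' @param H head count.
#' @param dropout_rate dropout probability (training mode only).
#' @param seed integer seed; initialization is reproducible.
#' @return an object of class `fusion_params` with elements `W`, `q`,
#'   `w_last`, `H`, `d`, `dropout_rate`.
#' @export
fusion_params <- function(d, H = 4L, dropout_rate = 0.1, seed = 1L) {
  d <- as.integer(d); H <- as.integer(H)
  if (d %% H != 0L) stopf("d = %d is not divisible by H = %d", d, H)
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must lie in [0, 1)")
  with_seed(seed, function() {
    structure(list(
      W = matrix(stats::rnorm(d * d), d, d),
      q = stats::runif(d, -1 / sqrt(d), 1 / sqrt(d)),
      w_last = stats::runif(d, -1 / sqrt(d), 1 / sqrt(d)),
      H = H, d = d, dropout_rate = dropout_rate
    ), class = "fusion_params")
  })
}

#' Project modality tokens to attention keys
#'
#' `K = relu(dropout(B W))`; dropout is the identity in evaluation mode, so
#' repeated evaluation-mode calls are deterministic.
#'
#' @param B_tokens numeric matrix (tokens x d).
#' @param W key projection matrix (d x d).
#' @param dropout_rate dropout probability.
#' @param mode `"train"` or `"eval"`.
#' @param rng internal RNG stream (training mode).
#' @return list with `K` (tokens x d) and `keep` (dropout mask or `NULL`).
#' @export
project_keys <- function(B_tokens, W, dropout_rate = 0, mode = c("eval", "train"),
                         rng = NULL) {
  mode <- match.arg(mode)
  if (!all(is.finite(B_tokens))) stopf("token input contains nonfinite values")
  P <- B_tokens %*% W
  if (mode == "train" && dropout_rate > 0) {
    keep <- rng_eval(rng, function()
      matrix(stats::runif(length(P)) >= dropout_rate, nrow(P), ncol(P)))
    P <- P * keep / (1 - dropout_rate)
  } else keep <- NULL
  list(K = pmax(P, 0), keep = keep)
}

#' Split an embedding-dimension object into head blocks
#'
#' Splits columns (or a vector) into `H` contiguous blocks of width `d/H`;
#' concatenating the blocks in order reconstructs the input exactly.
#'
#' @param x numeric vector of length `d` or matrix with `d` columns.
#' @param H head count; `d` must be divisible by `H`.
#' @return list of `H` blocks.
#' @export
split_heads <- function(x, H) {
  d <- if (is.matrix(x)) ncol(x) else length(x)
  if (d %% H != 0L) stopf("width %d is not divisible by H = %d", d, H)
  dh <- d %/% H
  lapply(seq_len(H), function(h) {
    idx <- (h - 1L) * dh + seq_len(dh)
    if (is.matrix(x)) x[, idx, drop = FALSE] else x[idx]
  })
}

#' Scaled dot-product attention for one head
#'
#' Weights are the softmax over tokens of `q_h . K_h` scaled by
#' `1/sqrt(d/H)`; the head output is the weight-weighted sum of the value rows
#' (values are the untransformed token block).
#'
#' @param q_h query block (length `d/H`).
#' @param K_h key block (tokens x `d/H`).
#' @param V_h value block (tokens x `d/H`).
#' @return list with `output` (length `d/H`) and `weights` (per-token,
#'   nonnegative, summing to 1).
#' @export
attention_head <- function(q_h, K_h, V_h) {
  stopifnot(ncol(K_h) == length(q_h), all(dim(K_h) == dim(V_h)))
  scores <- as.vector(K_h %*% q_h) / sqrt(length(q_h))
  w <- exp(scores - max(scores))
  w <- w / sum(w)
  list(output = as.vector(crossprod(V_h, w)), weights = w)
}

#' Multihead attention fusion over a representation bundle
#'
#' For every patient: keys from [project_keys()], values equal to the tokens,
#' query/key/value head-split, per-head scaled dot-product attention over the
#' modality tokens, concatenation of head outputs, dropout (training only) and
#' final projection by `w_last` yielding the fused feature `Y`.
#'
#' @param bundle a [stack_representations()] bundle (patients x tokens x d).
#' @param params a [fusion_params()] object.
#' @param mode `"eval"` or `"train"`.
#' @param rng internal RNG stream (training mode).
#' @return an object of class `attention_output`: list with `Y` (fused feature
#'   per patient), `M` (patients x d multihead output), and `weights`
#'   (patients x H x tokens array; each head's weights are nonnegative and sum
#'   to 1 per patient).
#' @export
multihead_fuse <- function(bundle, params, mode = c("eval", "train"), rng = NULL) {
  mode <- match.arg(mode)
  dims <- dim(bundle)
  n <- dims[1L]; m <- dims[2L]; d <- dims[3L]
  if (d != params$d) stopf("bundle width %d does not match fusion d = %d", d, params$d)
  H <- params$H; dh <- d %/% H
  A <- array(0, dim = c(n, H, m))
  M <- matrix(0, n, d)
  B <- unclass(bundle)
  q_heads <- split_heads(params$q, H)
  for (p in seq_len(n)) {
    tokens <- matrix(B[p, , ], m, d)
    K <- project_keys(tokens, params$W, params$dropout_rate, mode, rng)$K
    K_heads <- split_heads(K, H)
    V_heads <- split_heads(tokens, H)
    for (h in seq_len(H)) {
      att <- attention_head(q_heads[[h]], K_heads[[h]], V_heads[[h]])
      A[p, h, ] <- att$weights
      M[p, (h - 1L) * dh + seq_len(dh)] <- att$output
    }
  }
  if (mode == "train" && params$dropout_rate > 0) {
    keepF <- rng_eval(rng, function()
      matrix(stats::runif(length(M)) >= params$dropout_rate, n, d))
    F_drop <- M * keepF / (1 - params$dropout_rate)
  } else F_drop <- M
  structure(list(Y = as.vector(F_drop %*% params$w_last),
                 M = M, weights = A),
            class = "attention_output")
}

# Vectorized fusion forward shared by multihead_fuse() and the full model.
# tokens: n x m x d array; returns M (n x d), A (n x H x m), plus caches.
fuse_forward <- function(bundle, params, mode = c("eval", "train"), rng = NULL) {
  mode <- match.arg(mode)
  dims <- dim(bundle)
  n <- dims[1L]; m <- dims[2L]; d <- dims[3L]
  if (d != params$d) stopf("bundle width %d does not match fusion d = %d", d, params$d)
  H <- params$H; dh <- d %/% H
  toks <- lapply(seq_len(m), function(i) {
    t_i <- unclass(bundle)[, i, , drop = FALSE]
    dim(t_i) <- c(n, d)
    t_i
  })
  keys <- vector("list", m)
  keeps <- vector("list", m)
  P_raw <- vector("list", m)
  for (i in seq_len(m)) {
    pk <- project_keys(toks[[i]], params$W, params$dropout_rate, mode, rng)
    keys[[i]] <- pk$K
    keeps[i] <- list(pk$keep)  # may be NULL; keep the slot
    P_raw[[i]] <- pk$K  # relu output; sign recoverable from K > 0
  }
  A <- array(0, dim = c(n, H, m))
  M <- matrix(0, n, d)
  S_list <- vector("list", H)
  for (h in seq_len(H)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    qh <- params$q[idx]
    S <- matrix(0, n, m)
    for (i in seq_len(m)) S[, i] <- (keys[[i]][, idx, drop = FALSE] %*% qh) / sqrt(dh)
    Smax <- apply(S, 1L, max)
    E <- exp(S - Smax)
    Ah <- E / rowSums(E)
    A[, h, ] <- Ah
    S_list[[h]] <- S
    head_out <- matrix(0, n, dh)
    for (i in seq_len(m)) head_out <- head_out + Ah[, i] * toks[[i]][, idx, drop = FALSE]
    M[, idx] <- head_out
  }
  if (mode == "train" && params$dropout_rate > 0) {
    keepF <- rng_eval(rng, function()
      matrix(stats::runif(length(M)) >= params$dropout_rate, n, d))
    F_drop <- M * keepF / (1 - params$dropout_rate)
  } else {
    keepF <- NULL; F_drop <- M
  }
  list(M = M, F_drop = F_drop, A = A, S = S_list, toks = toks, keys = keys,
       keeps = keeps, keepF = keepF, n = n, m = m, d = d)
}

# Backward through the fusion given per-sample gradients d_F (n x d) at the
# post-dropout multihead output. Returns gradients for W and q, and per-token
# per-sample input gradients (list of n x d matrices, one per modality token).
fuse_backward <- function(fw, params, d_F) {
  n <- fw$n; m <- fw$m; d <- fw$d
  H <- params$H; dh <- d %/% H
  if (!is.null(fw$keepF)) d_M <- d_F * fw$keepF / (1 - params$dropout_rate)
  else d_M <- d_F
  d_tok <- lapply(seq_len(m), function(i) matrix(0, n, d))
  d_K <- lapply(seq_len(m), function(i) matrix(0, n, d))
  g_q <- rep(0, d)
  for (h in seq_len(H)) {
    idx <- (h - 1L) * dh + seq_len(dh)
    d_head <- d_M[, idx, drop = FALSE]
    Ah <- matrix(fw$A[, h, ], n, m)
    d_A <- matrix(0, n, m)
    for (i in seq_len(m)) {
      d_tok[[i]][, idx] <- d_tok[[i]][, idx] + Ah[, i] * d_head  # value path
      d_A[, i] <- rowSums(d_head * fw$toks[[i]][, idx, drop = FALSE])
    }
    d_S <- Ah * (d_A - rowSums(d_A * Ah))  # softmax backward per patient
    qh <- params$q[idx]
    for (i in seq_len(m)) {
      g_q[idx] <- g_q[idx] + as.vector(crossprod(fw$keys[[i]][, idx, drop = FALSE],
                                                 d_S[, i])) / sqrt(dh)
      d_K[[i]][, idx] <- d_K[[i]][, idx] + outer(d_S[, i], qh) / sqrt(dh)
    }
  }
  g_W <- matrix(0, d, d)
  for (i in seq_len(m)) {
    d_P <- d_K[[i]] * (fw$keys[[i]] > 0)
    if (!is.null(fw$keeps[[i]]))
      d_P <- d_P * fw$keeps[[i]] / (1 - params$dropout_rate)
    g_W <- g_W + crossprod(fw$toks[[i]], d_P)
    d_tok[[i]] <- d_tok[[i]] + d_P %*% t(params$W)
  }
  list(g_W = g_W / n, g_q = g_q / n, d_tok = d_tok)
}

#' Export per-patient attention weights as a tidy table
#'
#' @param weights the `weights` array of an [multihead_fuse()] output.
#' @param patient_ids optional patient identifiers.
#' @param modalities optional modality names (token order).
#' @return data frame with columns `patient_id`, `head`, `modality`, `weight`.
#' @export
attention_weights_table <- function(weights, patient_ids = NULL, modalities = NULL) {
  dims <- dim(weights)
  patient_ids <- patient_ids %||% sprintf("P%05d", seq_len(dims[1L]))
  modalities <- modalities %||% sprintf("token%d", seq_len(dims[3L]))
  expand <- expand.grid(patient = seq_len(dims[1L]), head = seq_len(dims[2L]),
                        modality = seq_len(dims[3L]))
  data.frame(patient_id = patient_ids[expand$patient],
             head = expand$head,
             modality = modalities[expand$modality],
             weight = weights[cbind(expand$patient, expand$head, expand$modality)],
             stringsAsFactors = FALSE)
}
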