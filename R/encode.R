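#' Encoder configuration
#'
#' Describes one modality-specific first-layer encoder. Genomic modalities
#' (mRNA, miRNA, CNV) use a stack of fully connected layers with ReLU
#' activation and batch normalization: `hidden_widths` gives the hidden layer
#' widths (1 to 3 of them) and a final projection maps to the representation
#' length `d`, so the total FC layer count is between 2 and 4. The clinical
#' encoder embeds the four categorical fields, concatenates the normalized
#' continuous values, and applies a single FC layer to width `d`.
#'
#' @param modality one of `"clinical"`, `"mRNA"`, `"miRNA"`, `"CNV"`.
#' @param hidden_widths integer vector of hidden FC widths (genomic only).
#' @param rep_length representation length `d`.
#' @param dropout_rate dropout probability in `[0, 1)`, applied in training
#'   mode only (to embedded vectors for the clinical branch, after each
#'   activation for genomic branches).
#' @param use_batchnorm logical; batch normalization after each affine, before
#'   activation (genomic branches).
#' @param embedding_dims named integer vector of embedding widths per
#'   categorical field (clinical only).
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(modality,
                           hidden_widths = switch(modality,
                             mRNA = c(512L, 128L), CNV = c(512L, 128L),
                             miRNA = c(256L, 128L), clinical = integer(0)),
                           rep_length = 128L,
                           dropout_rate = 0.1,
                           use_batchnorm = TRUE,
                           embedding_dims = NULL) {
  if (!modality %in% c("clinical", "mRNA", "miRNA", "CNV"))
    stopf("unknown modality '%s'", modality)
  if (modality != "clinical") {
    n_fc <- length(hidden_widths) + 1L  # hidden layers plus projection to d
    if (n_fc < 2L || n_fc > 4L)
      stopf("genomic encoders use 2-4 FC layers; got %d for '%s'", n_fc, modality)
    if (any(hidden_widths <= 0L)) stopf("all hidden widths must be positive")
  }
  if (rep_length <= 0L) stopf("rep_length must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must lie in [0, 1)")
  if (modality == "clinical" && is.null(embedding_dims))
    embedding_dims <- c(cancer_type = 8L, gender = 2L, race = 3L, histological_type = 8L)
  structure(list(modality = modality,
                 hidden_widths = as.integer(hidden_widths),
                 rep_length = as.integer(rep_length),
                 dropout_rate = dropout_rate,
                 use_batchnorm = isTRUE(use_batchnorm),
                 embedding_dims = embedding_dims),
            class = "encoder_config")
}

# He-normal weight init for ReLU stacks.
init_linear <- function(p_in, p_out) {
  list(W = matrix(stats::rnorm(p_in * p_out, sd = sqrt(2 / p_in)), p_in, p_out),
       b = rep(0, p_out))
}

#' Build a modality encoder
#'
#' Initializes the parameterized transform mapping (patients x features) input
#' to (patients x d) representations. Parameters are drawn from a seeded
#' generator, so the same seed yields identical initial parameters.
#'
#' @param config an [encoder_config()] for a genomic modality.
#' @param n_features input feature count.
#' @param seed integer seed for initialization.
#' @return an object of class `privsurv_encoder`.
#' @seealso [encoder_forward()]
#' @export
build_encoder <- function(config, n_features, seed = 1L) {
  stopifnot(inherits(config, "encoder_config"))
  if (config$modality == "clinical")
    stopf("use build_clinical_encoder() for the clinical branch")
  widths <- c(config$hidden_widths, config$rep_length)
  with_seed(seed, function() {
    layers <- list()
    p <- n_features
    for (w in widths) {
      lay <- init_linear(p, w)
      if (config$use_batchnorm) {
        lay$gamma <- rep(1, w); lay$beta <- rep(0, w)
        lay$run_mean <- rep(0, w); lay$run_var <- rep(1, w)
      }
      layers[[length(layers) + 1L]] <- lay
      p <- w
    }
    structure(list(config = config, n_features = n_features, layers = layers),
              class = "privsurv_encoder")
  })
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

#' Run an encoder forward
#'
#' Evaluation mode is deterministic: dropout is disabled and batch
#' normalization uses its running inference statistics. In training mode,
#' batch statistics are used (and treated as constants in the backward pass so
#' per-sample gradients stay well defined for privacy clipping).
#'
#' @param encoder a [build_encoder()] object.
#' @param X numeric matrix (patients x features).
#' @param mode `"eval"` or `"train"`.
#' @param rng an internal RNG stream for dropout (training mode).
#' @return list with `out` (patients x d), `cache` (activations for the
#'   backward pass), and `encoder` (with updated running statistics in
#'   training mode).
#' @export
encoder_forward <- function(encoder, X, mode = c("eval", "train"), rng = NULL) {
  mode <- match.arg(mode)
  if (!all(is.finite(X))) stopf("encoder input contains nonfinite values")
  if (ncol(X) != encoder$n_features)
    stopf("input has %d features but the encoder expects %d", ncol(X), encoder$n_features)
  cfg <- encoder$config
  cache <- list()
  h <- X
  for (l in seq_along(encoder$layers)) {
    lay <- encoder$layers[[l]]
    a <- h %*% lay$W + rep(lay$b, each = nrow(h))
    if (cfg$use_batchnorm) {
      if (mode == "train") {
        mu <- colMeans(a)
        va <- colMeans(a^2) - mu^2
        lay$run_mean <- BN_MOMENTUM * lay$run_mean + (1 - BN_MOMENTUM) * mu
        lay$run_var <- BN_MOMENTUM * lay$run_var + (1 - BN_MOMENTUM) * va
        encoder$layers[[l]] <- lay
      } else {
        mu <- lay$run_mean
        va <- lay$run_var
      }
      sd_ <- sqrt(va + BN_EPS)
      xhat <- sweep(sweep(a, 2L, mu), 2L, sd_, "/")
      z <- sweep(sweep(xhat, 2L, lay$gamma, "*"), 2L, lay$beta, "+")
    } else {
      sd_ <- NULL; xhat <- NULL; z <- a
    }
    r <- pmax(z, 0)
    if (mode == "train" && cfg$dropout_rate > 0) {
      keep <- rng_eval(rng, function()
        matrix(stats::runif(length(r)) >= cfg$dropout_rate, nrow(r), ncol(r)))
      out <- r * keep / (1 - cfg$dropout_rate)
    } else {
      keep <- NULL; out <- r
    }
    cache[[l]] <- list(X = h, sd = sd_, xhat = xhat, z = z, keep = keep)
    h <- out
  }
  list(out = h, cache = cache, encoder = encoder)
}

# Backward pass through a genomic encoder. `delta` holds per-sample gradients
# of the per-patient loss w.r.t. the encoder output (rows = patients). Returns
# per-layer per-sample factors (input X and delta matrices) from which both the
# plain averaged gradient and clipped per-sample aggregates are assembled, plus
# the gradient w.r.t. the encoder input.
encoder_backward <- function(encoder, cache, delta) {
  cfg <- encoder$config
  per_layer <- vector("list", length(encoder$layers))
  d <- delta
  for (l in rev(seq_along(encoder$layers))) {
    lay <- encoder$layers[[l]]
    cc <- cache[[l]]
    if (!is.null(cc$keep)) d <- d * cc$keep / (1 - cfg$dropout_rate)
    d_z <- d * (cc$z > 0)
    if (cfg$use_batchnorm) {
      d_a <- sweep(d_z, 2L, lay$gamma / cc$sd, "*")  # stop-gradient batch stats
    } else {
      d_a <- d_z
    }
    per_layer[[l]] <- list(X = cc$X, d_a = d_a,
                           d_z = if (cfg$use_batchnorm) d_z else NULL,
                           xhat = cc$xhat)
    d <- d_a %*% t(lay$W)
  }
  list(per_layer = per_layer, delta_input = d)
}

# Averaged (optionally per-sample weighted) gradients of an encoder from the
# backward factors. `w` is a per-sample weight vector (clipping scales divided
# by the aggregation count); defaults to plain mean.
encoder_grads <- function(bwd, w = NULL) {
  n <- nrow(bwd$per_layer[[1L]]$X)
  if (is.null(w)) w <- rep(1 / n, n)
  lapply(seq_along(bwd$per_layer), function(l) {
    pl <- bwd$per_layer[[l]]
    g <- list(W = crossprod(pl$X * w, pl$d_a),
              b = colSums(pl$d_a * w))
    if (!is.null(pl$d_z)) {
      g$gamma <- colSums(pl$xhat * pl$d_z * w)
      g$beta <- colSums(pl$d_z * w)
    }
    g
  })
}

# Per-sample L1 norms of the full per-sample encoder gradient (all layers,
# weights + biases + batchnorm scale/shift). Parameters are disjoint across
# layers, and the per-sample weight gradient is the outer product x_i d_i^T,
# whose L1 norm factorizes as ||x_i||_1 ||d_i||_1.
encoder_grad_l1 <- function(bwd) {
  n <- nrow(bwd$per_layer[[1L]]$X)
  total <- rep(0, n)
  for (pl in bwd$per_layer) {
    da_l1 <- rowSums(abs(pl$d_a))
    total <- total + rowSums(abs(pl$X)) * da_l1 + da_l1
    if (!is.null(pl$d_z)) {
      dz_l1 <- rowSums(abs(pl$d_z))
      total <- total + rowSums(abs(pl$xhat * pl$d_z)) + dz_l1
    }
  }
  total
}

#' Build the clinical encoder branch
#'
#' Embedding tables for the categorical fields (one reserved row for unknown
#' levels) plus a single FC layer from the concatenated embeddings and
#' continuous values to width `d`.
#'
#' @param config an [encoder_config()] with `modality = "clinical"`.
#' @param n_levels named integer vector of vocabulary sizes per field.
#' @param n_continuous number of continuous fields.
#' @param seed integer seed.
#' @return an object of class `privsurv_clinical_encoder`.
#' @export
build_clinical_encoder <- function(config, n_levels, n_continuous = 1L, seed = 1L) {
  stopifnot(inherits(config, "encoder_config"), config$modality == "clinical")
  fields <- names(config$embedding_dims)
  miss <- setdiff(fields, names(n_levels))
  if (length(miss)) stopf("n_levels lacks field(s): %s", paste(miss, collapse = ", "))
  with_seed(seed, function() {
    emb <- lapply(fields, function(f) {
      k <- config$embedding_dims[[f]]
      matrix(stats::rnorm((n_levels[[f]] + 1L) * k, sd = 0.1), n_levels[[f]] + 1L, k)
    })
    names(emb) <- fields
    p <- sum(config$embedding_dims) + n_continuous
    structure(c(list(config = config, fields = fields, emb = emb,
                     n_levels = n_levels[fields], n_continuous = n_continuous),
                init_linear(p, config$rep_length)),
              class = "privsurv_clinical_encoder")
  })
}

#' Encode the clinical branch
#'
#' Embedding lookups for the categorical index matrix are concatenated with
#' the normalized continuous values and passed through one affine + ReLU layer
#' to width `d`. Dropout is applied to the embedded vectors in training mode
#' only, so evaluation-mode output is deterministic.
#'
#' @param encoder a [build_clinical_encoder()] object.
#' @param cat integer index matrix (patients x fields), as from
#'   [encode_clinical()].
#' @param cont continuous value matrix (patients x n_continuous).
#' @param mode `"eval"` or `"train"`.
#' @param rng internal RNG stream for dropout (training mode).
#' @return list with `out` (patients x d) and `cache`.
#' @export
encode_clinical_branch <- function(encoder, cat, cont, mode = c("eval", "train"),
                                   rng = NULL) {
  mode <- match.arg(mode)
  cfg <- encoder$config
  n <- nrow(cat)
  parts <- vector("list", length(encoder$fields))
  for (i in seq_along(encoder$fields)) {
    f <- encoder$fields[i]
    idx <- cat[, f]
    if (any(idx < 1L | idx > encoder$n_levels[[f]] + 1L))
      stopf("categorical index out of vocabulary range for field '%s'", f)
    parts[[i]] <- encoder$emb[[f]][idx, , drop = FALSE]
  }
  E_emb <- do.call(cbind, parts)
  if (mode == "train" && cfg$dropout_rate > 0) {
    keep <- rng_eval(rng, function()
      matrix(stats::runif(length(E_emb)) >= cfg$dropout_rate, nrow(E_emb), ncol(E_emb)))
    E_emb_d <- E_emb * keep / (1 - cfg$dropout_rate)
  } else {
    keep <- NULL; E_emb_d <- E_emb
  }
  E <- cbind(E_emb_d, cont)
  a <- E %*% encoder$W + rep(encoder$b, each = n)
  out <- pmax(a, 0)
  list(out = out,
       cache = list(E = E, a = a, keep = keep, cat = cat))
}

# Backward for the clinical branch; returns averaged gradients only (the
# clinical branch is never privacy-protected).
clinical_backward <- function(encoder, cache, delta) {
  cfg <- encoder$config
  n <- nrow(delta)
  d_a <- delta * (cache$a > 0)
  gW <- crossprod(cache$E, d_a) / n
  gb <- colMeans(d_a)
  d_E <- d_a %*% t(encoder$W)
  g_emb <- list()
  off <- 0L
  for (f in encoder$fields) {
    k <- cfg$embedding_dims[[f]]
    d_part <- d_E[, off + seq_len(k), drop = FALSE]
    if (!is.null(cache$keep))
      d_part <- d_part * cache$keep[, off + seq_len(k), drop = FALSE] / (1 - cfg$dropout_rate)
    g <- matrix(0, encoder$n_levels[[f]] + 1L, k)
    agg <- rowsum(d_part, group = cache$cat[, f]) / n
    g[as.integer(rownames(agg)), ] <- agg
    g_emb[[f]] <- g
    off <- off + k
  }
  list(W = gW, b = gb, emb = g_emb)
}

#' Stack per-modality representations into a bundle
#'
#' Assembles the representation matrix: a patients x modalities x d array in
#' the fixed modality order (clinical, mRNA, miRNA, CNV, restricted to those
#' supplied). Patients with an imputed all-zero modality still produce a
#' defined representation row.
#'
#' @param reps named list of (patients x d) matrices.
#' @return a 3-d array with a `modality_order` attribute, class
#'   `representation_bundle`.
#' @export
stack_representations <- function(reps) {
  order_all <- c("clinical", "mRNA", "miRNA", "CNV")
  mods <- order_all[order_all %in% names(reps)]
  if (!length(mods)) stopf("no recognized modalities in the representation list")
  d <- unique(vapply(reps[mods], ncol, 1L))
  if (length(d) != 1L)
    stopf("representation widths differ across modalities: %s",
          paste(vapply(reps[mods], ncol, 1L), collapse = ", "))
  n <- unique(vapply(reps[mods], nrow, 1L))
  if (length(n) != 1L) stopf("patient counts differ across modalities")
  B <- array(0, dim = c(n, length(mods), d))
  for (i in seq_along(mods)) B[, i, ] <- reps[[mods[i]]]
  if (!all(is.finite(B))) stopf("representation bundle contains nonfinite values")
  attr(B, "modality_order") <- mods
  class(B) <- "representation_bundle"
  B
}
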