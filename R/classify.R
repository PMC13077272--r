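#' Survival-status classifier on fused features
#'
#' The auxiliary evaluation model: a neural network with 3 fully connected
#' layers (two hidden ReLU layers and a sigmoid output) trained with binary
#' cross-entropy to classify survival status (deceased = 1, surviving = 0)
#' from the fused feature representation, reporting accuracy.
#'
#' @param x numeric feature matrix (patients x features), e.g.
#'   `predict(model, cohort, type = "fused")`.
#' @param labels binary status labels (1 deceased, 0 surviving).
#' @param hidden widths of the two hidden layers.
#' @param epochs full-batch training epochs.
#' @param learning_rate Adam step size.
#' @param test_idx optional indices evaluated for the reported accuracy
#'   (training then uses the remaining patients); by default the classifier is
#'   trained and evaluated on all of `x`.
#' @param seed integer seed.
#' @return an object of class `status_classifier`: list with `accuracy`,
#'   `probabilities` (on the evaluation set), `params`, `test_idx`.
#' @export
classify_status <- function(x, labels, hidden = c(64L, 32L), epochs = 200L,
                            learning_rate = 0.01, test_idx = NULL, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L)
    stopf("survival-status classification needs both classes present")
  if (length(labels) != nrow(x)) stopf("labels do not match the feature rows")
  train_idx <- if (is.null(test_idx)) seq_len(nrow(x))
               else setdiff(seq_len(nrow(x)), test_idx)
  eval_idx <- test_idx %||% seq_len(nrow(x))
  xt <- x[train_idx, , drop = FALSE]; yt <- labels[train_idx]

  params <- with_seed(seed, function() {
    p <- ncol(x)
    list(l1 = init_linear(p, hidden[1L]),
         l2 = init_linear(hidden[1L], hidden[2L]),
         l3 = init_linear(hidden[2L], 1L))
  })
  mstate <- lapply(1:3, function(i) NULL)
  vstate <- lapply(1:3, function(i) NULL)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- nrow(xt)
  for (t in seq_len(epochs)) {
    a1 <- xt %*% params$l1$W + rep(params$l1$b, each = n); r1 <- pmax(a1, 0)
    a2 <- r1 %*% params$l2$W + rep(params$l2$b, each = n); r2 <- pmax(a2, 0)
    o <- as.vector(r2 %*% params$l3$W) + params$l3$b
    pr <- stats::plogis(o)
    d_o <- matrix((pr - yt) / n, ncol = 1L)
    g3 <- list(W = crossprod(r2, d_o), b = sum(d_o))
    d_r2 <- d_o %*% t(params$l3$W) * (a2 > 0)
    g2 <- list(W = crossprod(r1, d_r2), b = colSums(d_r2))
    d_r1 <- d_r2 %*% t(params$l2$W) * (a1 > 0)
    g1 <- list(W = crossprod(xt, d_r1), b = colSums(d_r1))
    gs <- list(g1, g2, g3)
    for (i in 1:3) {
      lay <- params[[i]]
      for (nm in c("W", "b")) {
        g <- gs[[i]][[nm]]
        key <- paste0(i, nm)
        if (is.null(mstate[[i]])) { mstate[[i]] <- list(); vstate[[i]] <- list() }
        m_ <- (mstate[[i]][[nm]] %||% (g * 0)) * b1 + (1 - b1) * g
        v_ <- (vstate[[i]][[nm]] %||% (g * 0)) * b2 + (1 - b2) * g^2
        mstate[[i]][[nm]] <- m_; vstate[[i]][[nm]] <- v_
        lay[[nm]] <- lay[[nm]] - learning_rate * (m_ / (1 - b1^t)) /
          (sqrt(v_ / (1 - b2^t)) + eps)
      }
      params[[i]] <- lay
    }
  }
  prob_fn <- function(newx) {
    n2 <- nrow(newx)
    r1 <- pmax(newx %*% params$l1$W + rep(params$l1$b, each = n2), 0)
    r2 <- pmax(r1 %*% params$l2$W + rep(params$l2$b, each = n2), 0)
    stats::plogis(as.vector(r2 %*% params$l3$W) + params$l3$b)
  }
  pe <- prob_fn(x[eval_idx, , drop = FALSE])
  acc <- accuracy(labels[eval_idx], as.integer(pe >= 0.5))
  structure(list(accuracy = acc, probabilities = pe, params = params,
                 test_idx = test_idx, predict_prob = prob_fn),
            class = "status_classifier")
}

#' @export
print.status_classifier <- function(x, ...) {
  cat(sprintf("3-FC-layer survival-status classifier: accuracy %.3f%s\n",
              x$accuracy,
              if (is.null(x$test_idx)) " (training data)" else " (held-out)"))
  invisible(x)
}
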