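#' Preprocessing configuration
#'
#' Holds the screening and encoding choices applied before model fitting:
#' per-modality variance thresholds (the defaults, 7 for mRNA and 0.2 for CNV,
#' are the RNA-seq-scale values used on the reference cohort; set them to the
#' scale of your data), min-max normalization, and the clinical field lists.
#'
#' @param variance_threshold named nonnegative vector of per-modality variance
#'   thresholds; modalities not named are left unfiltered (miRNA by default).
#' @param normalize logical; min-max normalize continuous features to `[0, 1]`.
#' @param clinical_categorical_fields character vector of categorical fields.
#' @param clinical_continuous_fields character vector of continuous fields.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(variance_threshold = c(mRNA = 7, CNV = 0.2),
                              normalize = TRUE,
                              clinical_categorical_fields =
                                c("cancer_type", "gender", "race", "histological_type"),
                              clinical_continuous_fields = "age") {
  if (any(variance_threshold < 0)) stopf("variance thresholds must be nonnegative")
  structure(list(variance_threshold = variance_threshold,
                 normalize = isTRUE(normalize),
                 clinical_categorical_fields = clinical_categorical_fields,
                 clinical_continuous_fields = clinical_continuous_fields),
            class = "preprocess_config")
}

#' Screen features by variance
#'
#' Retains exactly the features whose population variance (computed over
#' patients with the modality present) exceeds `threshold`, preserving order.
#'
#' @param block a `modality_block`.
#' @param threshold nonnegative variance cutoff.
#' @return the filtered `modality_block` (possibly 0 features, with a warning).
#' @export
variance_filter <- function(block, threshold) {
  stopifnot(inherits(block, "modality_block"))
  if (threshold < 0) stopf("threshold must be nonnegative")
  obs <- block$values[!block$missing_mask, , drop = FALSE]
  v <- apply(obs, 2L, pop_var)
  keep <- which(v > threshold)
  if (length(keep) == 0L)
    warnf("variance filter at %g removed every feature of modality '%s'",
          threshold, block$name)
  modality_block(block$name, block$values[, keep, drop = FALSE], block$missing_mask)
}

#' Per-feature reference statistics
#'
#' Computes per-feature minimum, maximum and population variance on a reference
#' (training) cohort, excluding patients whose modality is missing. The frozen
#' statistics are reused to normalize external cohorts.
#'
#' @param block a `modality_block` (or numeric matrix).
#' @return an object of class `feature_stats` with `min`, `max`, `var`.
#' @export
feature_stats <- function(block) {
  if (inherits(block, "modality_block")) {
    m <- block$values[!block$missing_mask, , drop = FALSE]
  } else m <- as.matrix(block)
  structure(list(min = apply(m, 2L, min),
                 max = apply(m, 2L, max),
                 var = apply(m, 2L, pop_var),
                 feature_names = colnames(m)),
            class = "feature_stats")
}

#' Min-max normalize a modality block
#'
#' Applies `(x - min) / (max - min)` column-wise using reference statistics.
#' Reference-cohort values land in `[0, 1]`; external values are clipped into
#' `[0, 1]`. Constant columns (max equal to min) map to 0 with a warning so
#' feature shapes stay stable once statistics are frozen.
#'
#' @param block a `modality_block`.
#' @param stats a [feature_stats()] object; fitted from `block` when `NULL`.
#' @return the normalized `modality_block`. Missing rows are normalized like
#'   any others; run [impute_missing()] afterwards to re-zero them.
#' @export
minmax_normalize <- function(block, stats = NULL) {
  stopifnot(inherits(block, "modality_block"))
  if (is.null(stats)) stats <- feature_stats(block)
  v <- block$values
  rng <- stats$max - stats$min
  const <- rng <= 0
  if (any(const))
    warnf("%d constant feature(s) in modality '%s' mapped to 0", sum(const), block$name)
  for (j in seq_len(ncol(v))) {
    if (const[j]) v[, j] <- 0
    else v[, j] <- pmin(1, pmax(0, (v[, j] - stats$min[j]) / rng[j]))
  }
  modality_block(block$name, v, block$missing_mask)
}

#' Zero-vector imputation for missing modalities
#'
#' Replaces the rows of patients whose modality is absent with all-zero
#' vectors of the block's feature width; the mask is retained for bookkeeping.
#'
#' @param block a `modality_block`.
#' @return the imputed `modality_block`.
#' @export
impute_missing <- function(block) {
  stopifnot(inherits(block, "modality_block"))
  block$values[block$missing_mask, ] <- 0
  block
}

#' Fit the clinical categorical vocabulary
#'
#' Maps each categorical level to an integer index. Index `n_levels + 1` is
#' reserved for levels unseen at fitting time (external cohorts).
#'
#' @param clinical clinical data frame.
#' @param fields categorical field names.
#' @return an object of class `clinical_vocab`.
#' @export
clinical_vocab <- function(clinical,
                           fields = c("cancer_type", "gender", "race", "histological_type")) {
  miss <- setdiff(fields, names(clinical))
  if (length(miss)) stopf("clinical table lacks field(s): %s", paste(miss, collapse = ", "))
  vocab <- lapply(fields, function(f) sort(unique(as.character(clinical[[f]]))))
  names(vocab) <- fields
  structure(list(levels = vocab), class = "clinical_vocab")
}

#' Encode clinical fields as index and continuous matrices
#'
#' Categorical fields are mapped to integer level indices via the fitted
#' vocabulary (unknown levels at inference map to the reserved index, with a
#' warning); continuous fields are min-max normalized with the reference range
#' and clipped to `[0, 1]`.
#'
#' @param clinical clinical data frame.
#' @param vocab a [clinical_vocab()]; fitted from `clinical` when `NULL`.
#' @param cont_range named list of `c(min, max)` per continuous field; fitted
#'   from `clinical` when `NULL`.
#' @param continuous_fields continuous field names.
#' @return list with `cat` (patients x fields integer matrix), `cont`
#'   (patients x n_continuous matrix in `[0, 1]`), `vocab`, `cont_range`.
#' @export
encode_clinical <- function(clinical, vocab = NULL, cont_range = NULL,
                            continuous_fields = "age") {
  if (is.null(vocab)) vocab <- clinical_vocab(clinical)
  fields <- names(vocab$levels)
  cat <- matrix(0L, nrow(clinical), length(fields),
                dimnames = list(clinical$patient_id, fields))
  for (f in fields) {
    lev <- vocab$levels[[f]]
    idx <- match(as.character(clinical[[f]]), lev)
    unk <- is.na(idx)
    if (any(unk)) {
      warnf("%d value(s) of '%s' not in the fitted vocabulary; mapped to the reserved index",
            sum(unk), f)
      idx[unk] <- length(lev) + 1L
    }
    cat[, f] <- idx
  }
  if (is.null(cont_range)) {
    cont_range <- lapply(continuous_fields, function(f)
      c(min = min(clinical[[f]]), max = max(clinical[[f]])))
    names(cont_range) <- continuous_fields
  }
  cont <- matrix(0, nrow(clinical), length(continuous_fields),
                 dimnames = list(clinical$patient_id, continuous_fields))
  for (f in continuous_fields) {
    r <- cont_range[[f]]
    span <- r[["max"]] - r[["min"]]
    cont[, f] <- if (span <= 0) 0 else
      pmin(1, pmax(0, (clinical[[f]] - r[["min"]]) / span))
  }
  list(cat = cat, cont = cont, vocab = vocab, cont_range = cont_range)
}

#' Align an external cohort's features to a trained reference
#'
#' Reorders the block's columns to exactly the reference feature list;
#' features absent in the external cohort are filled with zeros (the same
#' convention as missing-modality imputation). Warns when fewer than half of
#' the reference features overlap.
#'
#' @param block a `modality_block`.
#' @param reference_feature_names character vector fixed by the trained model.
#' @return a `modality_block` with exactly the reference features in order.
#' @export
align_external_features <- function(block, reference_feature_names) {
  stopifnot(inherits(block, "modality_block"))
  hit <- match(reference_feature_names, block$feature_names)
  overlap <- mean(!is.na(hit))
  if (overlap < 0.5)
    warnf("only %.0f%% of reference features present in external modality '%s'",
          100 * overlap, block$name)
  v <- matrix(0, nrow(block$values), length(reference_feature_names),
              dimnames = list(rownames(block$values), reference_feature_names))
  present <- which(!is.na(hit))
  if (length(present)) v[, present] <- block$values[, hit[present], drop = FALSE]
  modality_block(block$name, v, block$missing_mask)
}

#' Preprocess a cohort for model fitting
#'
#' Applies the paper-style pipeline per genomic modality: variance screening,
#' min-max normalization fitted on this cohort (or with supplied frozen
#' statistics), and zero-vector imputation; the clinical table is encoded via
#' [encode_clinical()].
#'
#' @param cohort a `privsurv_cohort`.
#' @param config a [preprocess_config()].
#' @param fitted optional result of a previous call (its frozen statistics,
#'   vocabulary and feature lists are reused, as for external validation).
#' @return list with `blocks` (processed genomic blocks), `clinical_enc`,
#'   `stats`, `config`, and `feature_names` per modality.
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config(), fitted = NULL) {
  blocks <- list()
  stats <- list()
  for (m in names(cohort$blocks)) {
    b <- cohort$blocks[[m]]
    if (!is.null(fitted)) {
      b <- align_external_features(b, fitted$feature_names[[m]])
      s <- fitted$stats[[m]]
    } else {
      thr <- config$variance_threshold[m]
      if (!is.na(thr)) b <- variance_filter(b, thr)
      s <- feature_stats(b)
    }
    if (config$normalize) b <- minmax_normalize(b, s)
    blocks[[m]] <- impute_missing(b)
    stats[[m]] <- s
  }
  clin <- encode_clinical(cohort$clinical,
                          vocab = fitted$clinical_enc$vocab %||% NULL,
                          cont_range = fitted$clinical_enc$cont_range %||% NULL,
                          continuous_fields = config$clinical_continuous_fields)
  list(blocks = blocks, clinical_enc = clin, stats = stats, config = config,
       feature_names = lapply(blocks, function(b) b$feature_names))
}
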