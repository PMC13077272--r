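#' Specify a synthetic multimodal survival cohort
#'
#' Describes the shape of a simulated pan-cancer style cohort: one clinical
#' table (four categorical fields plus age) and three genomic feature blocks
#' (mRNA, miRNA, CNV), right-censored survival outcomes, per-patient missing
#' modalities, and a minority of planted prognostic features per modality.
#' Survival times follow an exponential proportional-hazards model whose
#' log-hazard is `effect_size` times the sum of the planted feature values
#' (plus a standardized age term and one cancer-type level), so the true risk
#' ordering is known in closed form. Defaults mirror the feature counts of the
#' TCGA-style cohort the model targets (743 miRNA, 1579 mRNA, 2711 CNV).
#'
#' @param n_patients number of patients.
#' @param dims named integer vector of feature counts for the genomic
#'   modalities (`mRNA`, `miRNA`, `CNV`).
#' @param n_informative named integer vector: planted prognostic features per
#'   genomic modality. Must not exceed `dims`.
#' @param effect_size log-hazard weight magnitude of each planted feature.
#' @param censor_rate target fraction of censored records in `[0, 1)`. The
#'   uniform censoring window is calibrated numerically to hit this rate.
#' @param missing_rate named vector of per-patient modality dropout
#'   probabilities for the genomic modalities.
#' @param n_categories named integer vector of level counts for the clinical
#'   categorical fields.
#' @param baseline_median baseline median survival time in days (hazard scale).
#' @param seed integer seed; generation is bitwise reproducible for a fixed
#'   seed and never touches the global RNG.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_patients = 1000L,
                        dims = c(mRNA = 1579L, miRNA = 743L, CNV = 2711L),
                        n_informative = c(mRNA = 15L, miRNA = 8L, CNV = 25L),
                        effect_size = 1.0,
                        censor_rate = 0.3,
                        missing_rate = c(mRNA = 0.031, miRNA = 0.097, CNV = 0.083),
                        n_categories = c(cancer_type = 33L, gender = 2L,
                                         race = 5L, histological_type = 20L),
                        baseline_median = 365,
                        seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 2L) stopf("n_patients must be at least 2")
  mods <- c("mRNA", "miRNA", "CNV")
  for (m in mods) {
    if (is.na(dims[m]) || dims[m] < 1L) stopf("dims must name %s with a positive count", m)
    if (is.na(n_informative[m])) n_informative[m] <- 0L
    if (n_informative[m] > dims[m])
      stopf("n_informative[%s] = %d exceeds dims[%s] = %d", m, n_informative[m], m, dims[m])
    if (is.na(missing_rate[m])) missing_rate[m] <- 0
    if (missing_rate[m] < 0 || missing_rate[m] >= 1) stopf("missing_rate[%s] must lie in [0, 1)", m)
  }
  if (censor_rate < 0 || censor_rate >= 1) stopf("censor_rate must lie in [0, 1)")
  if (any(n_categories < 2L)) stopf("every clinical categorical field needs at least 2 levels")
  structure(list(
    n_patients = n_patients,
    dims = vapply(dims[mods], as.integer, 1L),
    n_informative = vapply(n_informative[mods], as.integer, 1L),
    effect_size = effect_size,
    censor_rate = censor_rate,
    missing_rate = missing_rate[mods],
    n_categories = n_categories,
    baseline_median = baseline_median,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a synthetic multimodal survival cohort
#'
#' Draws genomic feature matrices from a standard normal distribution, plants
#' the prognostic features named by the spec, simulates exponential
#' proportional-hazards survival times with independent uniform censoring
#' calibrated to the target censoring rate, and applies per-patient modality
#' dropout (masked rows are stored as zero vectors, the missing-modality
#' convention used downstream).
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `privsurv_cohort`: a list with elements
#'   `clinical` (data frame), `blocks` (named list of `modality_block`s),
#'   `outcomes` (data frame with `patient_id`, `time`, `event`,
#'   `status_label`), and `truth` (planted feature indices and the true
#'   linear predictor per patient).
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 50,
#'   dims = c(mRNA = 20, miRNA = 10, CNV = 15),
#'   n_informative = c(mRNA = 2, miRNA = 1, CNV = 2), seed = 7))
#' coh
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stopf("spec must be a cohort_spec")
  with_seed(spec$seed, function() {
    n <- spec$n_patients
    ids <- sprintf("P%05d", seq_len(n))

    cat_fields <- names(spec$n_categories)
    clinical <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
    for (f in cat_fields) {
      lev <- sprintf("%s_%02d", f, seq_len(spec$n_categories[[f]]))
      clinical[[f]] <- sample(lev, n, replace = TRUE)
    }
    clinical$age <- round(runif(n, 30, 85), 1)

    mods <- names(spec$dims)
    blocks <- list()
    informative <- list()
    raw <- list()
    for (m in mods) {
      p <- spec$dims[[m]]
      v <- matrix(rnorm(n * p), n, p,
                  dimnames = list(ids, sprintf("%s_f%04d", m, seq_len(p))))
      informative[[m]] <- sort(sample.int(p, spec$n_informative[[m]]))
      raw[[m]] <- v
    }

    # True linear predictor: planted genomic features plus one continuous and
    # one categorical clinical signal, all at the same effect size.
    lp <- rep(0, n)
    for (m in mods) {
      if (length(informative[[m]]))
        lp <- lp + rowSums(raw[[m]][, informative[[m]], drop = FALSE])
    }
    age_std <- (clinical$age - mean(clinical$age)) / stats::sd(clinical$age)
    risk_level <- sprintf("%s_01", cat_fields[1L])
    lp <- spec$effect_size * (lp + age_std + as.numeric(clinical[[cat_fields[1L]]] == risk_level))

    lambda0 <- log(2) / spec$baseline_median
    t_true <- stats::rexp(n, rate = 1) / (lambda0 * exp(lp))

    if (spec$censor_rate > 0) {
      # Calibrate the uniform censoring window: with C ~ U(0, cmax) the
      # expected censored fraction is mean(min(T_i / cmax, 1)).
      f <- function(cmax) mean(pmin(t_true / cmax, 1)) - spec$censor_rate
      cmax <- stats::uniroot(f, lower = min(t_true) * 1e-6,
                             upper = max(t_true) * 1e6, tol = 1e-10)$root
      cens <- stats::runif(n, 0, cmax)
      event <- as.integer(t_true <= cens)
      time <- pmin(t_true, cens)
    } else {
      event <- rep(1L, n)
      time <- t_true
    }

    for (m in mods) {
      mask <- stats::runif(n) < spec$missing_rate[[m]]
      v <- raw[[m]]
      v[mask, ] <- 0
      blocks[[m]] <- modality_block(m, v, missing_mask = mask)
    }

    outcomes <- data.frame(patient_id = ids, time = time, event = event,
                           status_label = event, stringsAsFactors = FALSE)
    structure(list(
      clinical = clinical,
      blocks = blocks,
      outcomes = outcomes,
      truth = list(informative_indices = informative, true_linear_predictor = lp),
      spec = spec
    ), class = "privsurv_cohort")
  })
}

#' Construct a modality feature block
#'
#' @param name modality name, one of `"clinical"`, `"mRNA"`, `"miRNA"`, `"CNV"`.
#' @param values numeric matrix (patients x features) with row and column names.
#' @param missing_mask logical vector, `TRUE` where the modality is absent for
#'   a patient; such rows are represented by zero vectors.
#' @return an object of class `modality_block`.
#' @export
modality_block <- function(name, values, missing_mask = rep(FALSE, nrow(values))) {
  if (!name %in% c("clinical", "mRNA", "miRNA", "CNV"))
    stopf("unknown modality name '%s'", name)
  values <- as.matrix(values)
  if (length(missing_mask) != nrow(values))
    stopf("missing_mask length %d does not match %d patients", length(missing_mask), nrow(values))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("%s_f%04d", name, seq_len(ncol(values)))
  structure(list(name = name, values = values,
                 feature_names = colnames(values),
                 missing_mask = as.logical(missing_mask)),
            class = "modality_block")
}

#' @export
print.modality_block <- function(x, ...) {
  cat(sprintf("<modality_block '%s': %d patients x %d features, %d missing>\n",
              x$name, nrow(x$values), ncol(x$values), sum(x$missing_mask)))
  invisible(x)
}

#' @export
print.privsurv_cohort <- function(x, ...) {
  cat(sprintf("Multimodal survival cohort: %d patients\n", nrow(x$outcomes)))
  cat(sprintf("  events: %d (%.1f%% censored)\n", sum(x$outcomes$event),
              100 * mean(x$outcomes$event == 0)))
  for (b in x$blocks)
    cat(sprintf("  %-6s %5d features, %d patients missing\n",
                b$name, ncol(b$values), sum(b$missing_mask)))
  cat(sprintf("  clinical: %d categorical + 1 continuous field\n",
              ncol(x$clinical) - 2L))
  invisible(x)
}

#' Subset a cohort by patient index
#'
#' @param cohort a `privsurv_cohort`.
#' @param idx integer or logical patient index.
#' @return the subsetted cohort (ground truth subset alongside, if present).
#' @export
cohort_subset <- function(cohort, idx) {
  out <- cohort
  out$clinical <- cohort$clinical[idx, , drop = FALSE]
  out$outcomes <- cohort$outcomes[idx, , drop = FALSE]
  out$blocks <- lapply(cohort$blocks, function(b)
    modality_block(b$name, b$values[idx, , drop = FALSE], b$missing_mask[idx]))
  if (!is.null(cohort$truth))
    out$truth$true_linear_predictor <- cohort$truth$true_linear_predictor[idx]
  out
}

# Full-precision numeric formatting so CSV round-trips are bitwise faithful.
fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write a cohort to a directory of delimited text files
#'
#' Lays out one CSV per modality (missing-modality patients appear as absent
#' rows, not NA-filled cells), an outcomes table, the clinical table, and a
#' JSON manifest mapping modality to file. Numeric values are written at full
#' precision so [read_cohort()] round-trips exactly.
#'
#' @param cohort a `privsurv_cohort`.
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(n_patients = nrow(cohort$outcomes),
                   modalities = list(), outcomes = "outcomes.csv",
                   clinical = "clinical.csv")

  oc <- cohort$outcomes
  oc$time <- fmt_num(oc$time)
  utils::write.csv(oc, file.path(path, "outcomes.csv"), row.names = FALSE)

  cl <- cohort$clinical
  cl$age <- fmt_num(cl$age)
  utils::write.csv(cl, file.path(path, "clinical.csv"), row.names = FALSE)

  for (b in cohort$blocks) {
    f <- sprintf("%s.csv", b$name)
    keep <- !b$missing_mask
    df <- data.frame(patient_id = rownames(b$values)[keep], stringsAsFactors = FALSE)
    vals <- b$values[keep, , drop = FALSE]
    for (j in seq_len(ncol(vals))) df[[colnames(vals)[j]]] <- fmt_num(vals[, j])
    utils::write.csv(df, file.path(path, f), row.names = FALSE)
    manifest$modalities[[b$name]] <- f
  }
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(cohort$truth, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path directory containing a `manifest.json`.
#' @return a `privsurv_cohort`. Patients absent from a modality file are
#'   restored as zero rows with the missing mask set.
#' @export
read_cohort <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stopf("no manifest.json under '%s'", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)

  oc <- utils::read.csv(file.path(path, manifest$outcomes),
                        stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("patient_id", "time", "event"))
    if (!col %in% names(oc)) stopf("outcomes table is missing the '%s' column", col)
  outcomes <- data.frame(patient_id = oc$patient_id,
                         time = as.numeric(oc$time),
                         event = as.integer(oc$event),
                         stringsAsFactors = FALSE)
  outcomes$status_label <- if ("status_label" %in% names(oc))
    as.integer(oc$status_label) else outcomes$event
  if (any(!is.finite(outcomes$time)) || any(outcomes$time <= 0))
    stopf("outcomes table contains nonpositive or unreadable times")
  ids <- outcomes$patient_id

  clinical <- utils::read.csv(file.path(path, manifest$clinical),
                              stringsAsFactors = FALSE)
  if (!identical(clinical$patient_id, ids))
    stopf("clinical table patient ids do not match the outcomes table")
  if ("age" %in% names(clinical)) clinical$age <- as.numeric(clinical$age)

  blocks <- list()
  for (m in names(manifest$modalities)) {
    df <- utils::read.csv(file.path(path, manifest$modalities[[m]]),
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE)
    if (!"patient_id" %in% names(df)) stopf("modality table '%s' lacks patient_id", m)
    unknown <- setdiff(df$patient_id, ids)
    if (length(unknown))
      stopf("modality '%s' contains %d patients absent from the outcomes table", m, length(unknown))
    feats <- setdiff(names(df), "patient_id")
    vals <- matrix(0, length(ids), length(feats), dimnames = list(ids, feats))
    pres <- match(df$patient_id, ids)
    for (j in seq_along(feats)) vals[pres, j] <- as.numeric(df[[feats[j]]])
    mask <- !(ids %in% df$patient_id)
    blocks[[m]] <- modality_block(m, vals, missing_mask = mask)
  }

  truth <- NULL
  tf <- file.path(path, "truth.json")
  if (file.exists(tf)) {
    truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth$informative_indices <- lapply(truth$informative_indices, as.integer)
  }
  structure(list(clinical = clinical, blocks = blocks, outcomes = outcomes,
                 truth = truth),
            class = "privsurv_cohort")
}
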