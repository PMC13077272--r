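# Shared fixture builders for the test suite. Everything is generated in code
# under fixed seeds; no data files.

# A small multimodal cohort that fits every module test.
tiny_cohort <- function(n = 150, seed = 7, effect = 1, censor = 0.3,
                        miss = 0.1) {
  generate_cohort(cohort_spec(
    n_patients = n,
    dims = c(mRNA = 12L, miRNA = 8L, CNV = 10L),
    n_informative = c(mRNA = 2L, miRNA = 1L, CNV = 2L),
    effect_size = effect, censor_rate = censor,
    missing_rate = c(mRNA = miss, miRNA = miss, CNV = miss),
    n_categories = c(cancer_type = 4L, gender = 2L, race = 3L,
                     histological_type = 3L),
    seed = seed))
}

# A small model configuration that trains in a couple of seconds.
tiny_config <- function(epochs = 3, ...) {
  privsurv_config(d = 8L, H = 2L,
                  hidden_widths = list(mRNA = 6L, miRNA = 6L, CNV = 6L),
                  time_bins = 5L, batch_size = 64L, epochs = epochs,
                  use_batchnorm = FALSE, learning_rate = 0.01, ...)
}

fit_tiny <- function(cohort = tiny_cohort(), epochs = 3, seed = 1, ...) {
  privsurv(cohort, tiny_config(epochs = epochs, ...), seed = seed)
}

# Brute-force concordance oracle: the literal pairwise definition.
c_index_oracle <- function(time, event, risk) {
  conc <- 0; comp <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      comp <- comp + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}

# Population variance oracle.
pop_var_oracle <- function(x) mean((x - mean(x))^2)

# Closed-form Laplace CDF for distributional tests.
plaplace <- function(q, b) ifelse(q < 0, 0.5 * exp(q / b), 1 - 0.5 * exp(-q / b))
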