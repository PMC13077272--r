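# privsurv

Privacy-preserving multimodal survival prediction with attention fusion.

## The problem

Pan-cancer survival models increasingly combine clinical variables with
several genomic measurements per patient — mRNA expression, miRNA expression,
copy-number variation. Two practical obstacles dominate: (i) fusing
heterogeneous modalities so that the informative ones drive the prediction,
and (ii) the genomic data are highly identifying, so models trained on them
should limit what their gradients reveal about any one patient.

`privsurv` implements a bilayer architecture for right-censored survival
data:

1. **Modality encoders.** Each genomic block passes through 2–4 fully
   connected ReLU layers (optional batch normalization) to a fixed-length
   representation; the clinical branch embeds the categorical fields
   (cancer type, gender, race, histological type), concatenates age, and
   projects to the same length *d*. A patient is then a 4 × *d* token matrix
   *B*.
2. **Multihead attention fusion.** Keys *K* = relu(dropout(*B W*)), values
   are the tokens (identity), and a single learnable query *q* is shared
   across patients. *q*, *K*, *V* split into *H* blocks of width *d/H*; each
   head takes softmax(*q Kᵀ* / √(*d/H*)) weights over the modality tokens and
   averages the values; the concatenated head outputs feed a discrete-time
   survival head (per-bin conditional hazards; Cox partial likelihood
   optional).
3. **Relevance-guided adaptive differential privacy.** Layer-wise relevance
   propagation (epsilon rule, sign-matched stabilizer) scores every genomic
   input feature against the survival output. Scores are cut into quantile
   intervals T₁..Tₙ; a strictly monotone map assigns interval budgets from
   ε_max = 0.5 down to ε_min = 0.1 (plus bounded jitter), rescaled so each
   modality's jointly clipped gradient release satisfies ε/3-DP and the
   composed global guarantee per release is ε = 0.8. Per-sample gradients are
   L1-clipped at *C* and each group receives Laplace(2*C*/(|L| ε_k)) noise —
   the most relevant features get the largest ε_k, hence the least noise. A
   ledger records every release; `accountant_report()` audits the composed
   spend and separately reports the naive whole-training composition.

Evaluation tools include Harrell's concordance index (tested against a
brute-force oracle), event-stratified 60/20/20 splits with five disjoint test
folds, bootstrap paired model comparison with Bonferroni correction, and a
3-layer survival-status classifier for accuracy. A synthetic multimodal
cohort generator with planted prognostic features provides ground truth for
everything.

## Worked example

```r
library(privsurv)

coh <- generate_cohort(cohort_spec(
  n_patients = 600,
  dims = c(mRNA = 60, miRNA = 40, CNV = 50),
  n_informative = c(mRNA = 5, miRNA = 3, CNV = 4),
  effect_size = 1, censor_rate = 0.3, seed = 42))
coh
#> Multimodal survival cohort: 600 patients
#>   events: 417 (30.5% censored)
#>   mRNA      60 features, 24 patients missing
#>   miRNA     40 features, 53 patients missing
#>   CNV       50 features, 57 patients missing
#>   clinical: 4 categorical + 1 continuous field

folds <- split_and_cv(coh$outcomes$event, k = 5, seed = 42)
train <- cohort_subset(coh, folds[[1]]$train)
test  <- cohort_subset(coh, folds[[1]]$test)

cfg <- privsurv_config(d = 32, H = 4,
  hidden_widths = list(mRNA = 32, miRNA = 32, CNV = 32),
  use_batchnorm = FALSE, lambda = 1e-3,
  time_bins = 15, epochs = 60, batch_size = 128, learning_rate = 0.003)
fit <- privsurv(train, cfg, seed = 42)
fit
#> Multimodal attention survival model
#>   head: discrete (15 bins) | d = 32, H = 4 heads
#>   trained 60 epochs on 360 patients; final loss 1.7408
#>   non-private training

risk <- predict_risk(fit, test)
c_index(test$outcomes$time, test$outcomes$event, risk)
#> [1] 0.665
```

The test concordance of 0.665 means two-thirds of comparable patient pairs
(the earlier follow-up time carries an event) are ranked correctly by the
predicted risk; 0.5 would be chance, and the planted-signal oracle on this
small cohort sits near 0.9 — a 360-patient training set recovers part of it.
Feature relevance and its per-layer percentile summary (the heatmap layout):

```r
rel <- feature_relevance(fit, train)
head(percentile_summary(rel), 4)
#>   modality  layer       p25       p50       p75     p100
#> 1     mRNA output 2.3392041 2.6097648 2.8905239 3.671910
#> 2     mRNA  token 0.0270368 0.2071637 0.5660351 1.374197
#> 3     mRNA layer1 0.0382606 0.5074977 1.2932418 3.733421
#> 4     mRNA  input 1.2667999 1.5158569 1.9377052 5.719192
```

Private training at a global budget of ε = 0.8 per gradient release
(full-batch releases; adaptive allocation over four relevance intervals):

```r
pfit <- privsurv(train,
  privsurv_config(d = 32, H = 4,
    hidden_widths = list(mRNA = 32, miRNA = 32, CNV = 32),
    use_batchnorm = FALSE, lambda = 1e-3,
    time_bins = 15, epochs = 60, batch_size = 4096, learning_rate = 0.003),
  privacy = privacy_config(global_epsilon = 0.8, clip_bound = 1),
  seed = 42)
pfit
#> Multimodal attention survival model
#>   head: discrete (15 bins) | d = 32, H = 4 heads
#>   trained 60 epochs on 360 patients; final loss 2.2905
#>   private: global epsilon 0.8 per release (adaptive), 60 releases, naive composed total 48.0

c_index(test$outcomes$time, test$outcomes$event, predict_risk(pfit, test))
#> [1] 0.596
```

The drop from 0.665 to 0.596 is the price of the Laplace noise at this budget
and cohort size; the methods vignette
(`vignettes/multimodal-survival-privacy.Rmd`) quantifies why pure-ε noise at
sub-1 budgets is severe at desk scale, and what the accountant's per-release
versus naive whole-training figures mean.

A command-line interface wrapping these functions (simulate / train /
predict / relevance / evaluate / compare) is installed at
`system.file("cli", "privsurv", package = "privsurv")`.

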