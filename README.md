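# adex

Extraction of adverse drug events (ADEs) and related information from
clinical narrative, for NLP researchers and pharmacovigilance engineers
who need an end-to-end, fully reproducible entity-and-relation pipeline
in R.

Clinical notes mention drugs, their attributes, and the injuries drugs
cause, but spontaneous ADE-reporting systems are known to under-report;
extracting this information from text is therefore a two-step task. The
first step is **named entity recognition** over nine clinical types
(Medication, Indication, Frequency, Severity, Dosage, Duration, Route,
ADE, SSLIF); the second is **relation extraction** over seven typed
relations (Dosage-Medication, Route-Medication, Frequency-Medication,
Duration-Medication, Medication-Indication, Medication-ADE,
Severity-ADE). `adex` implements:

* a **BiLSTM-CRF sequence labeler** with word, initial-capital, POS, and
  character-CNN features over BMES-with-type tags (37 labels). With
  emissions $s(t, y)$ and learned transitions $A_{y,y'}$, a labeling
  $y_{1..n}$ scores
  $\;\Phi(y) = \sum_t s(t, y_t) + \sum_t A_{y_{t-1},y_t}$, trained by the
  exact CRF negative log-likelihood
  $-\log p(y) = \log Z - \Phi(y)$ (forward recursion in log space) and
  decoded by Viterbi;
* a **BiLSTM-Attention relation classifier** over candidate windows
  (word, POS, and two signed position-embedding channels; additive
  attention pooling $\alpha = \mathrm{softmax}(v^\top \tanh(WH))$,
  context $c = H^\top \alpha$) concatenated with entity-pair side
  features (entity words, entity types, bucketed token distance, bucketed
  between-entity count) into a softmax over 7 relation types + None —
  including **inter-sentence** candidates;
* three **multi-task couplings** of the two submodels: hard parameter
  sharing (shared BiLSTM beside task-private ones), soft sharing by L2
  regularisation of the comparable second recurrent layers
  ($\lambda\,\lVert p_2^{ner}-p_2^{re}\rVert^2$), and task relation
  learning (linear exchange layers between the task hidden spaces);
* a BRAT-style **standoff reader/writer**, a deterministic tokenizer and
  rule-based POS tagger, a seeded **synthetic corpus generator**
  emulating the annotation schema (10:1 SSLIF:ADE imbalance,
  inter-sentence relations, distractor phrasing), and **micro-averaged
  end-to-end evaluation** with exact span matching.

The neural layers run on a small reverse-mode autodiff tape included in
the package; gradients are finite-difference- and enumeration-checked in
the test suite. Everything is seeded: identical configuration and seed
reproduce corpora, models, and reports byte-for-byte.

## Worked example

Generate a small annotated corpus, train the uncoupled pipeline, and
evaluate it end-to-end on the held-out split:

```r
library(adex)

corpus <- generate_corpus(gen_config(n_docs = 60, seed = 13))
corpus
#> <ade_corpus> 48 train / 12 test documents (seed 13)

model <- train_multitask(corpus$train, mode = "pipeline",
                         ner_config = ade_small_ner_config(epochs = 8),
                         re_config = ade_small_re_config(epochs = 8),
                         seed = 1)
tail(tidy(model), 3)
#> # A tibble: 3 x 4
#>   epoch ner_loss re_loss penalty
#>   <int>    <dbl>   <dbl>   <dbl>
#> 1     6   0.0599      NA       0
#> 2     7   0.0461      NA       0
#> 3     8   0.0370      NA       0

pred <- lapply(corpus$test, function(d) {
  extract_relations(model$re, predict_entities(model$ner, d))
})
evaluate_extraction(corpus$test, pred) |>
  dplyr::filter(type == "ALL")
#> # A tibble: 2 x 8
#>   task     type     tp    fp    fn precision recall    f1
#>   <chr>    <chr> <int> <int> <int>     <dbl>  <dbl> <dbl>
#> 1 entity   ALL     201     0     0         1      1     1
#> 2 relation ALL      97     0     0         1      1     1
```

The `ner_loss` column is the mean CRF negative log-likelihood per
sentence (the RE task hit its early-stopping loss after epoch 3, hence
`NA` afterwards); the evaluation rows are micro-averaged
precision/recall/F1 under exact span matching — `entity` scores the
recognizer, `relation` scores end-to-end extraction, where entity
mistakes would surface as relation false positives/negatives. The
template corpus is learnable by construction, so near-perfect scores
indicate a correctly wired implementation, not clinical-grade
performance (see the methods vignette).

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/adex.R generate --out corpus_dir
Rscript inst/cli/adex.R run-all --mode hard --seed 1 --out run_dir
```

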