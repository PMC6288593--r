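---
title: "Extracting adverse drug events from clinical narrative: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting adverse drug events from clinical narrative: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(adex)
```

## The task

Adverse drug events (ADEs) — injuries caused by medical drug intervention —
are systematically under-captured by spontaneous reporting systems, which
makes clinical notes a valuable complementary surveillance source. Pulling
ADE information out of free-text notes is a two-step information-extraction
problem:

1. **Named entity recognition (NER).** Label text spans with one of nine
   types: `Medication`, `Indication`, `Frequency`, `Severity`, `Dosage`,
   `Duration`, `Route`, `ADE`, and `SSLIF` (any sign, symptom, or disease
   that is neither an ADE nor an Indication).
2. **Relation extraction (RE).** Decide, for each type-compatible entity
   pair, whether it bears one of seven relations — `Dosage-Medication`,
   `Route-Medication`, `Frequency-Medication`, `Duration-Medication`,
   `Medication-Indication`, `Medication-ADE`, `Severity-ADE` — or none.
   Each relation name fixes its argument types, so argument order is
   canonical throughout the package.

Because the second step consumes the first step's output, the package
evaluates both the RE stage in isolation (gold entities supplied) and the
full end-to-end pipeline, where entity errors propagate into relation
errors. All scores are micro-averaged precision/recall/F1 under exact span
matching: a predicted entity counts only if an unmatched gold entity has
the identical character span and type, and a predicted relation counts
only if its type and both argument spans match exactly. Exact matching is
the strictest reproducible convention; there is no partial credit.

## The sequence labeler

Entity recognition is a BMES-tagged sequence-labeling problem: a
multi-token span of type *t* becomes `B_t M_t ... E_t`, a single-token
span `S_t`, everything else `O` — 4 × 9 + 1 = 37 labels. Each token
contributes four features, embedded and concatenated:

* its lowercased **word** (default 100-d),
* whether its **initial character is a capital** (5-d),
* its **POS tag** (20-d) from a bundled deterministic rule-based tagger
  (closed-class lexicon plus suffix heuristics — e.g. the adjectival
  `-al` suffix tags "Renal" as `JJ`); any external tagger with the same
  vectorised signature can be plugged in,
* a **character representation** (30-d character embeddings convolved
  with width-3 kernels into 50 filters, tanh, max-pooled over positions),
  which captures sub-word shape such as drug-name morphology.

The concatenation passes through a bidirectional LSTM (200 units total,
100 per direction) and a linear projection to 37 per-token emission
scores. A linear-chain CRF with learned transition scores (including
virtual START/STOP) defines a globally normalised distribution over label
sequences; training minimises the exact negative log-likelihood computed
by the forward recursion in log space, and decoding is Viterbi with ties
broken toward the lowest label index so output is deterministic.
Transitions into structurally impossible BMES bigrams are *learned*, not
masked, by default; a config flag (`constrain_decoding`) adds a hard mask
at decode time for users who prefer the guarantee.

**Repairing ill-formed label output.** A decoder trained without the hard
mask can emit ill-formed sequences. `decode_bmes()` repairs them
deterministically, left to right: an `M`/`E` with no open run of its type
becomes `O`; an open `B (M)*` run interrupted before its `E` — by `O`, a
type switch, a new `B`, or the sentence end — is emitted as an entity
covering the tokens seen so far, so a lone `B` yields a single-token
entity. The rule is frozen by an exhaustive test against an independent
transcription on every label pattern up to length 4.

**Span snapping.** Entity annotations that cross token boundaries are
snapped outward to the smallest covering token span; the count of snapped
spans is reported (`snapped` attribute, and on fitted models), since real
clinical tokenisation is imperfect.

## The relation classifier

A relation candidate is an ordered entity pair (earlier entity first)
whose types match one of the seven signatures and whose sentence distance
is at most `max_sentence_gap` (default 3). The context window runs from
the first token of the earlier sentence to the last token of the later
one, so inter-sentence relations are first-class. Each window token is
embedded from its word, its POS tag, and **two position channels** — the
signed distance to the nearest boundary of each target entity (0 inside,
negative before, positive after, clipped at `max_position`). Character
features are deliberately absent from this submodel; they did not help
relation classification in this architecture family. A bidirectional LSTM
encodes the window and single-query additive attention (tanh projection,
learned scoring vector, softmax) pools it into a context vector.

Because attention context alone can miss pair-specific evidence, four
side features are embedded and concatenated before the output layer: the
words of the two target entities (mean of word embeddings for multi-word
entities — order-free and well-defined), the two entity types, the
bucketed token distance between the entities, and the bucketed count of
entities lying between them (buckets `{0, 1, 2, 3–5, 6–10, >10}`;
embedding a bucket is the natural vector representation of an integer
feature). A softmax over the seven relation types plus `None` closes the
model; an exact probability tie resolves conservatively to `None`, and
since an entity-type pair admits exactly one schema-compatible relation
type, a predicted label incompatible with the pair is likewise discarded
as `None` — emitted relations satisfy the schema by construction.
Negative (`None`) candidates can be down-sampled during training
(`neg_keep`); the default keeps all of them.

## The multi-task couplings

NER and RE are heterogeneous, loosely related tasks; the package
implements the three standard coupling families next to the uncoupled
pipeline baseline, under one alternating schedule (one NER mini-batch,
one RE mini-batch, cycling the shorter loader — 1:1 alternation is the
simplest defensible schedule and is config-visible):

* **Hard parameter sharing.** Each task keeps a private BiLSTM; both also
  feed a shared BiLSTM whose output is concatenated with the private one
  before the task decoder. The two tasks' token-feature widths differ, so
  each task reaches the shared layer through a small task-private linear
  adapter mapping its features to a common width — the same
  dimensionality obstacle that motivates regularising only comparable
  layers in the soft variant. The shared layer accumulates gradient from
  both tasks; private groups receive gradient only from their own task
  (the optimiser steps only parameters with gradient, so this contract is
  bitwise testable).
* **Soft sharing by regularisation.** Each task gets two stacked BiLSTMs.
  First layers have incomparable input widths, so the penalty
  `lambda * sum((p2_ner - p2_re)^2)` ties only the second-layer
  parameters, whose shapes match by construction. With `lambda = 0` the
  tasks decouple and the training trajectory reproduces the two-layer
  pipeline bit-for-bit under the same seeds — a strong correctness check
  that the package asserts in its tests.
* **Task relation learning.** Each task's pooled hidden representation
  (attention-pooled for RE, mean-pooled for NER windows) is mapped through
  a linear exchange layer into the other task's decoder input. The two
  directions use separate maps (`learn.W5.ner2re`, `learn.W5.re2ner`);
  nothing forces the two spaces to share one matrix. At inference the
  counterpart encoder runs on the same text — for an NER sentence the
  RE-side encoder sees neutral position channels (distance 0), since no
  target pair exists. Zeroed exchange maps reduce exactly to a
  no-exchange baseline with zero-widened decoder input.

No claim is made that any coupling beats the pipeline on the synthetic
data; which coupling helps is known to depend on the tasks and data, and
the synthetic corpus is deliberately easy enough for all variants to
learn.

## The synthetic corpus

The annotated clinical corpora this model family is built for are access-
restricted, so the package ships a seeded generator that emulates the
annotation schema and its difficulty profile rather than any real
patient language: closed invented lexicons (fake drug names such as
"Zalprex", invented indication terms), template sentences whose wording
determines the gold annotation, and three deliberate difficulty features
mirroring the error modes that matter in practice:

* **Class imbalance.** SSLIF dominates ADE by an order of magnitude. The
  default template mixture is derived analytically: SSLIF sentences
  (weight 0.48, 1.5 entities each) plus distractor sentences (rate 0.05)
  give 0.77 expected SSLIF per sentence slot, so an ADE-statement weight
  of 0.077 centres the configured ratio at 10:1.
* **Lexical confusability.** ADE and SSLIF draw from the same symptom
  lexicon; only context ("developed ... after starting" vs "history of")
  disambiguates, so the labeler must actually use context.
* **Distractors and distance.** Distractor sentences put relation-like
  wording ("stopped secondary to ...") next to pairs that bear no
  relation; a configurable fraction (default 0.1) of ADE/Indication
  statements is split across sentences with gaps up to
  `max_relation_gap` (default 2), and cross-sentence dosage templates
  create type-compatible `None` pairs whose resolution requires the
  position features.

Default study conditions: 250 documents (200 train / 50 test), 4–8
sentences each, seed 13. What the generator does **not** emulate: real
clinical spelling variation, abbreviation, negation scope, genuinely
ambiguous annotation, or long-tail vocabulary. Passing the package's
learnability checks therefore demonstrates that the implementation can
recover patterns it is trained on — a correctness property — and says
nothing about performance on real clinical notes.

## Numerical and engineering choices

* **Automatic differentiation.** The models run on a small reverse-mode
  tape over matrices included in the package. The two hot recurrences —
  the LSTM and the CRF log-partition — are fused single-tape nodes with
  hand-written backward passes (backpropagation through time, and
  forward–backward posterior marginals respectively). All gradients are
  validated against central finite differences through the full losses
  (relative error ~1e-8), and the CRF additionally against exhaustive
  path enumeration.
* **Optimisation.** Adam (1e-3 at full width; 8e-3 in the small profile)
  with per-parameter lazy steps: only parameters that received gradient
  on the current batch move. Besides making the sharing contracts exact,
  this keeps untouched embedding rows genuinely frozen.
* **Determinism.** One integer seed controls everything. Each stateful
  component (per-task initialisation, shuffling, dropout; corpus
  generation) owns an explicit RNG stream (a saved `.Random.seed` swapped
  in and out), so the two tasks' arithmetic is independent of scheduling
  and identical configurations reproduce reports byte-for-byte.
* **Degenerate inputs.** Empty text tokenises to zero tokens; documents
  without compatible pairs yield no candidates; `0/0` metric ratios are 0
  by convention; unknown words map to a reserved index, never an error;
  tokens shorter than the convolution kernel are padded.
* **Problem sizes.** The package's own experiments (tests and the
  acceptance script) use a documented small profile —
  `ade_small_ner_config()` / `ade_small_re_config()`, 24-d words, 32
  recurrent units, dropout 0.15, early stop on mean epoch loss — sized to
  the closed synthetic vocabularies, where full-width embeddings add
  nothing. The full-width defaults (`ner_config()` / `re_config()`)
  remain the configuration intended for real corpora.
* **Pretrained embeddings** (plain-text word2vec format) are optional;
  when supplied they seed the lookup table and are frozen by default —
  leaving domain embeddings untuned tends to generalise better in this
  setting, and freezing also guards against overfitting tiny corpora.

## Known limitations

* Discontiguous and overlapping entities are unsupported (the schema has
  neither).
* The rule-based POS tagger targets the generator's vocabulary and common
  English morphology; for real notes, plug in a trained tagger.
* Relations with sentence gaps beyond `max_sentence_gap` are structurally
  unreachable — the knob exposes the recall/efficiency trade-off; very
  long-distance relations require a different candidate strategy.
* Couplings trained with `train_multitask()` carry closures and are
  retrained from seed rather than checkpointed; plain pipeline submodels
  serialise to JSON checkpoints.
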