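---
title: "Soft prompt-tuning with automatic verbalizers: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft prompt-tuning with automatic verbalizers: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msprompt)
```

# The model

Short-text classification is recast as cloze filling. A text `x` is
embedded by a frozen masked language model and wrapped into the prompt
`T = {h_1..h_i, e(x), h_{i+1}..h_n, e([MASK])}`: `n` trainable soft
tokens, re-encoded by a BiLSTM, flank the input, and the mask slot sits
last. The backbone predicts a vocabulary distribution at the mask, and
class `y` is scored by the equal-weight mean probability of its label
words `V_y`. Three assumptions carry the method:

1. **The backbone already knows the domain.** The mask distribution of a
   class's texts concentrates on words that co-occur with that class —
   that is what masked-LM pretraining optimizes. The soft prompt only
   steers this distribution; it cannot create signal the backbone lacks.
2. **Label words are class-pure.** The mean in `g(y)` weights every word
   equally, so a word carrying probability for several classes is pure
   noise. This motivates removing cross-class duplicates outright during
   verbalizer merging.
3. **Short texts, single mask.** One mask position per text suffices for
   single-label classification of texts up to ~20 tokens.

## The training objective

The optimization target is stated as an argmin over the encoded soft
tokens without an explicit per-example loss. This package uses
cross-entropy over classes with class logits `log g(y)`: the per-example
loss is `-log( g(y*) / Σ_y g(y) )`. It is differentiable, and its argmin
agrees with the decision rule actually applied at prediction time; with
one label word per class it reduces to the familiar softmax
cross-entropy over label-word logits. Only the soft-token embeddings, the
BiLSTM and the output projection receive gradients; the frozen backbone
contributes constants (its parameter digest is asserted unchanged in the
tests).

## BiLSTM encoding

The published recurrence for `h_i` is loosely typeset; we implement the
standard reading: a forward LSTM over the raw soft tokens, a backward
LSTM over the reversed sequence, concatenation of the two hidden states
at each position, and an affine projection to the backbone embedding
dimension. Dropout (default 0.5) is applied to the encoded outputs
during training only, with inverted scaling, one mask per example per
batch.

# The reference backbone

No deep-learning framework is assumed: the packaged MLM is a small
encoder written in plain matrix algebra, with analytic gradients that the
test suite checks against numerical differentiation. Its architecture is
a *mean-context* predictor: to fill position `t`, the mean `c` of the
embeddings at all other positions is encoded as `u = tanh(Wc + b)` and
scored against the output table. Two observations justify the choice:

* In every consumer of the contract — cloze classification, masked-token
  loss, pseudo-log-likelihood windows — the masked position always
  carries the `[MASK]` embedding, so any information must come from the
  context; a bag-of-context encoder captures exactly that.
* The synthetic data are class-conditional unigram mixtures, for which
  context order carries no signal; a heavier sequence encoder would add
  cost without changing what the fixtures can test.

The backbone is pluggable: anything implementing
`mask_fill_distribution()` (and thereby `masked_token_loss()`) can be
swapped in, including the prescribed-distribution stub used throughout
the tests. Word-order-sensitive phenomena are out of reach of the
reference encoder — a real transformer backbone behind the same contract
is the intended production path.

Pretraining masks 15% of positions per sentence per epoch (at least
one), uniformly at random, and minimizes cross-entropy with Adam
(learning rate 0.005, 20–30 epochs at the shipped problem sizes). The
masking rate is the conventional value; nothing in the method depends on
it strongly.

# Verbalizer construction

**Concepts Retrieval.** Entities are matched by greedy longest-match
over token n-grams (no overlaps), concepts retrieved per entity are
ranked by membership probability (breadth `N_v = 50` per entity — the
retrieval breadth is not specified in the source method; 50 is wide
enough that the anchor-distance stage, not retrieval truncation, decides
the final set), merged keeping each concept's maximum probability, and
the `N_a = 15` closest to the class-name anchor are kept. Distance is
cosine distance on the backbone's input embeddings, mean-pooled for
multi-token strings; fully out-of-vocabulary candidates rank last via an
infinite sentinel. "Morphological derivations" of the class name are
excluded by a deliberately blunt token-level rule: equality, substring
containment either way, or character-bigram Jaccard ≥ 0.5 after
normalization.

**Context Information.** Candidates are the union over the class's
training texts of the top `K_cand = 50` mask-fill predictions (special
tokens excluded, lexicographic tie-break). Each candidate is placed at
the mask slot of each text's context window — half-size `c = 5`, so the
left context is the text tail and the right side is padding — and scored
by the average masked-token loss over included positions. Padding is
excluded from both the numerator and the denominator, a documented
deviation from the literal `1/(2c+1)` at text boundaries: averaging over
realizable positions keeps scores comparable between boundary and
interior windows. "Discarding words with higher loss" is realized as
truncation to the `N_a` lowest.

**Merging.** The final verbalizer is the unweighted set union of the two
lists with provenance retained. Words claimed by more than one class are
dropped from all of them (assumption 2 above); a class emptied by this
rule is a hard error naming the class. Passing one strategy alone gives
the CR-only / CI-only ablation verbalizers, and `singleton_verbalizer()`
(class name as the sole label word) is the no-expansion baseline.

Open choices resolved here: candidates are pooled per class across all
its training texts (not per text), and Context Information uses only the
K-shot training texts of the class — no unlabeled pool is assumed.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `n_soft`, `insert_index` | 4, 2 | soft tokens, how many precede the input; the template places soft tokens on both sides |
| `hidden_size` | 200 | BiLSTM width per direction |
| `dropout` | 0.5 | on encoded soft tokens, training only |
| `lr` | 3e-4 | AdamW step size |
| `weight_decay` | 0.01 | decoupled |
| `batch_size` | 64 | |
| `epochs` | 10 | per-dataset knob |
| `N_a` | 15 | label words kept per strategy per class |
| `N_v`, `K_cand` | 50, 50 | candidate breadths (CR / CI) |
| `c` (`half_size`) | 5 | context-window half-size |

The source method reports two incompatible learning rates (3e-4 in its
configuration, 3e-5 as its sensitivity optimum). The default here is
3e-4; `train_config(lr = "sensitivity_optimum")` selects the other.
Neither is asserted as canonical. Similarly its batch-size sensitivity
analysis is internally inconsistent (best accuracy at 64, conclusion
favoring 16); the default stays 64.

Numerical details: soft tokens initialize from N(0, 0.02²) (or from
sampled vocabulary embeddings via `init = "vocab"`); LSTM and projection
weights from N(0, 0.02²); backbone parameters from N(0, 0.05²) with the
`[PAD]` embedding pinned to zero. Argmax ties at prediction go to the
first class in sorted class order and set a tie flag. Verbalizer words
that are not single in-vocabulary tokens are skipped with a warning and
the averaging denominator shrinks accordingly — a zero-probability
treatment would punish classes for vocabulary coverage rather than
evidence. All ranking operations break ties by score then
lexicographically, which makes every pipeline stage deterministic given
its seed.

# The synthetic study conditions

The datasets the method was demonstrated on (crawled Chinese medical
inquiries) are not deposited, so the generators emulate their structure
rather than their content: 4 department-style classes, vocabulary 500,
texts of 5–20 tokens drawn from class-conditional unigram mixtures with
a `mixing` weight (default 0.9) against shared background tokens. Each
class's name is inserted into its own topic distribution at rank 10, so
the anchor word co-occurs with its class without dominating it — this is
what makes both the anchor-distance ranking and the singleton baseline
meaningful. The toy knowledge base links each topic word to its
classmates with probabilities decaying in rank plus low-probability
cross-class distractor edges, so retrieval ranking is nontrivial and
cross-class deduplication has work to do.

Episodes follow the K-per-class protocol for both train and test splits
(3 repetitions, `mean±std` reporting). A `--test-size`-style override is
deliberately absent from the harness: at desk scale the K-per-class test
split is the protocol.

What passing these conditions does **not** show: robustness to Chinese
orthography and real clinical vocabulary, to word-order effects (the
unigram generator has none), to entity linking harder than surface-form
matching, or to verbalizer noise from a web-scale knowledge base. The
fixtures validate the machinery — layout, gradients, ranking rules,
protocol — not clinical performance.

Problem sizes used by the shipped tests and the acceptance script (the
package's own choice of desk scale): pretraining corpus 200 texts/class,
20 epochs; evaluation pool 100 texts/class; K = 20, 3 episodes; the
smaller harness checks use 3 classes and a 120-token vocabulary. At
these sizes the full suite runs in well under a minute on one CPU. At
mixing 0.9 the synthetic benchmark sits near its ceiling — all
strategies, including the singleton baseline, can reach 100% on some
seeds — so the end-to-end assertions are recovery bars (≥ 0.85, merged ≥
singleton), not strategy separations.

# Known limitations

* The reference backbone is intentionally order-blind; it is a contract
  implementation, not a BERT substitute, and conclusions about real
  prompt-tuned transformers require plugging one in.
* The derivation filter is tuned for token-level English-like synthetic
  vocabularies; logographic scripts need a different rule.
* Soft-prompt training shares one dropout mask per example across the
  batch's encoded prompt (the encoding itself is example-independent);
  with `n_soft = 4` this is a negligible departure from per-position
  independence.
* `g(y)` uses full-vocabulary mask probabilities, not probabilities
  renormalized over the union of label words; with equal-size `V_y` the
  argmax is unaffected, with unequal sizes the choice matters and is
  documented here as the literal reading.
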