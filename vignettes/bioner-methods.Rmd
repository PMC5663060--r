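---
title: "Methods: a character-attentive BiLSTM-CRF tagger for biomedical NER"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a character-attentive BiLSTM-CRF tagger for biomedical NER}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bioner)
```

This vignette is the package's own account of the model it implements, the
choices that were genuinely open, and what its tests do and do not
establish.

## The task and the model

Biomedical named entity recognition is treated as sequence labeling over
pre-tokenized sentences under the BIEOS scheme: `B-`/`I-`/`E-` mark the
beginning, inside and end of a multi-token mention, `S-` a single-token
mention, `O` everything else. The tag inventory is
`{O} ∪ {B,I,E,S} × entity types`, so a two-type corpus has nine tags.

The scoring pipeline has four stages.

**Character attention.** Word-level normalization (lowercasing, digit
replacement) deliberately destroys orthography, yet orthography carries
signal in this domain (`IL-2`, `p53`, suffixes like *-ase*). The package
therefore builds a character-level representation per word: each character
embedding window of width 5 passes through a tanh layer, and attention
weights — one weight *per embedding dimension*, normalized over the word's
characters within each dimension — combine the character embeddings with a
Hadamard product into a vector `R_c` of the character dimension. The
per-dimension (vector-valued) reading is a deliberate interpretation: the
Hadamard product in the combination step only makes sense with a weight
per dimension, and the normalizing division is read elementwise. A scalar
per-character weight would be the alternative reading; it is not
implemented because the vector reading subsumes it (a scalar is a vector
weight with identical components).

One mathematical consequence documented here: the word-embedding term
`U_t e_w + b_t` inside the attention score is constant across the
characters of a word, and a per-dimension softmax is invariant to
constants, so `U_t` and `b_t` receive exactly zero gradient. They are kept
as parameters because the formulation lists them; the finite-difference
suite confirms the zero analytically and numerically.

**Word representation and context window.** The input to the recurrent
layer is the concatenation `R_i = R_c ⊕ e_w`, windowed as
`x_i = R_{i-2} ⊕ R_{i-1} ⊕ R_i ⊕ R_{i+1} ⊕ R_{i+2}` with zero vectors
beyond the sentence boundary. The character window uses the same zero-pad
convention (rather than learned boundary characters) for symmetry and
testability.

**Encoder.** A standard single-layer LSTM per direction — input, forget
and output gates with a tanh candidate, no peephole connections, zero
initial state — over the windowed inputs. The gate equations are not
printed in the formulation the package follows; the plain variant is the
minimal consistent choice. Forward and backward hidden states are combined
by one tanh layer, `h_t = tanh(W_f [h→; h←] + b_f)`; in unidirectional
mode the map acts on the forward state alone and no backward parameters
exist at all.

**CRF output layer.** Emissions `F` (tags × positions) come from an affine
map of `h_t`. A tag path scores
`S = Σ_t (A[y_{t-1}, y_t] + F[y_t, t])`. Because the path score references
a transition *into* the first tag, the transition matrix is augmented with
a learned START row and STOP column; `crf_start_stop = FALSE` pins both at
zero for a strictly minimal parameterization. The log-partition uses the
forward recursion entirely in log space; decoding is Viterbi with
deterministic lowest-index tie-breaking. The no-CRF ablation
(`decoder = "softmax"`) scores each position independently and never
touches the transition matrix, in training or decoding.

No hard BIEOS constraints are imposed at decode time — the CRF must learn
them. Invalid predicted sequences (possible under either decoder) are
repaired deterministically during span extraction: a stray `I-`/`E-` opens
a span as if `B-`, an incompatible continuation closes the open span at
that boundary. Evaluation is therefore total on any tag sequence; gold
sequences are validated strictly instead.

## Training

The per-sentence loss is `-log P(y|x) + (λ/2)‖Θ‖²` over the trainable
coordinates. As printed, the objective being *maximized* adds the ridge
term, which would reward large weights; the package treats this as a sign
typo and penalizes, while `ridge_sign = "bonus"` reproduces the printed
form for auditability.

Gradients are hand-derived backpropagation through every stage: CRF
expected-minus-observed sufficient statistics via forward–backward,
emission and combiner affine maps, backpropagation through time for both
LSTM directions, the window scatter, the per-dimension attention softmax,
and scatter-adds into both embedding tables. Frozen blocks
(`fine_tune_words = FALSE`, padding rows, disabled START/STOP, the
transition matrix under the softmax decoder) receive exactly zero
gradient and are excluded from the ridge. The test suite checks every
active coordinate against central finite differences (step `1e-5`,
relative error with a unit floor below `1e-4`; observed errors are near
`1e-10`).

Optimization is online AdaGrad exactly as printed: one update per sentence
in a freshly shuffled order per epoch, the accumulator includes the
current gradient, and there is no smoothing epsilon — a zero gradient with
an empty accumulator is guarded as a no-op. Defaults `α = 0.01`,
`λ = 1e-8`.

Model selection: after each epoch the development split is decoded and
span F1 recorded; the best-development parameters are returned. Stopping
occurs at `max_epochs` (default 100), after `patience` (default 10) epochs
without improvement, or — a package addition — as soon as development F1
reaches `early_stop_f1` (default 1.0). The last rule exists because the
synthetic corpora below are learned to a perfect development score within
one or two epochs, after which a patience rule alone would burn the whole
epoch budget; a perfect score cannot improve, so stopping is equivalent
under best-model selection. Tests that need a fixed number of epochs set
`early_stop_f1 = 2`. The epoch count, stopping rule and shuffle policy are
artifact choices; the source formulation states none of them. The whole
run is a deterministic, bit-reproducible function of (corpora, embeddings,
configuration, seed), and seeded routines restore the caller's RNG state.

## Pre-processing and embeddings

`normalize_token()` lowercases and replaces numeric content with the
literal `NUM`. Whether digit replacement applies inside alphanumeric
tokens or only to whole numeric tokens is underdetermined; both are
implemented, and the digit-run convention (`IL-2 → il-NUM`) is the default
because it maximizes embedding-vocabulary hits for exactly the token
shapes this domain produces. Character indexing uses the raw surface form
— the character model exists precisely to see what normalization removes.

Word embeddings load from word2vec text format (header optional); the
binary dialect is intentionally not parsed — convert with gensim's
`save_word2vec_format(..., binary = False)` — keeping I/O bit-auditable.
Out-of-vocabulary words map to an `UNKNOWN` row initialized
Glorot-uniform for the table's shape (the formulation marks words UNKNOWN
but never says what vector they get); the padding row is zero and never
updated. Character embeddings are uniform in `[0, 1)` with dimension 30;
all dense layers *and biases* are uniform in
`±sqrt(6/(rows + cols))` — biases included because the stated scheme
initializes `b` randomly with `W`.

## Synthetic corpora: what they emulate and what they do not

The seeded generator produces trigger/filler/entity token streams with the
structural statistics the model exploits: a span-length profile with 40%
single-token mentions, 45% of length 2–3, 15% of length 4–5 (matching the
published span statistics of a five-type shared-task corpus, used as
generator defaults, not as claims about real data); type-specific
morphological suffixes on entity head tokens (rate 0.9); type-specific
trigger words preceding entities (rate 0.7); digit qualifiers on some
entity tokens (rate 0.2) to exercise normalization; and a Zipf-like filler
distribution. Generated embeddings give tokens of one morpheme cluster a
shared latent direction, emulating the usefulness of pre-trained vectors.
Tokens are synthetic strings throughout — no real gene names, hence no
lexical leakage into tests.

Two engineered variants create the qualitative separations the ablation
tests check:

* **Transition-dependent.** A fraction (0.8) of entities have their gold
  type drawn at random while their interior tokens carry strong,
  independently drawn and therefore often conflicting class evidence; the
  remaining entities are cleanly typed. Per-token argmax decoding then
  mixes types inside a span — an invalid sequence that the repair rule
  fragments into several wrong spans — while Viterbi must commit to one
  type for the whole span because type-switching bigrams never occur in
  training. This is the designed mechanism, not an accident of training
  length: the ambiguity is irreducible, so more epochs do not close the
  gap. Earlier, simpler designs (length-coded types with token noise) were
  solved outright by the BiLSTM emissions and produced no separation; a
  linear chain also cannot express "exactly one entity somewhere in this
  window", which rules out existence-ambiguity designs.
* **Morphology-dependent.** Entity tokens are built on stems excluded from
  the embedding vocabulary (every one maps to `UNKNOWN`) and are typed
  solely by their character suffix; there are no context triggers. The
  word-only model can find boundaries but must guess types (F1 ≈ 0.5);
  the character-attentive model reads the suffix (F1 ≈ 1.0).

Passing these tests shows the implementation can exploit transition
structure and orthography when they are the only available signal. It does
not show performance on real biomedical text: the generator has no
syntax, no nested or discontinuous mentions, no annotation inconsistency,
and far smaller vocabularies.

## Numerical choices

* All partition-function and attention exponentials subtract the
  per-column (resp. per-dimension) maximum before `exp` — exact in real
  arithmetic, overflow-safe in floating point; a stress test drives scores
  to ±1000 and checks finiteness.
* Viterbi and per-token argmax break ties toward the lowest tag index;
  the all-zero instance decodes to the all-first-tag path by contract.
* Empty sentences are rejected at encoding; empty corpora at training.
* The finite-difference comparison uses
  `|a − f| / max(|a|, |f|, 1)`: losses here are O(1–10), and the floor
  keeps coordinates whose true gradient is exactly zero (see `U_t`)
  well-defined.

## Problem sizes used by the tests

Oracle equivalence enumerates all `K^T` paths for 220 random instances
with `K ≤ 4, T ≤ 6`. The gradient check runs a complete sweep over a
~1100-parameter model (dims 3–4) and spot-checks 200 coordinates per
architectural variant. Trainability checks use: 10 sentences × ≤ 50
epochs at the published hyperparameters (overfit capability); 2000
training sentences with an 8-epoch budget (learnability, F1 ≥ 0.95 —
in practice the development score is perfect after one epoch); and 400
sentences × 3 epochs per arm for the two ablation comparisons, sizes at
which the gaps are stable across seeds.

## Known limitations

* Desk-scale CPU execution only; no mini-batching, no GPU, single-layer
  LSTMs by scope.
* The CRF computes exactly the marginals training needs; no n-best lists
  or posterior exports.
* Character-offset (rather than token-span) evaluation formats are out of
  scope; alternative annotations are token-indexed.
* The `U_t`/`b_t` attention parameters are inert under the per-dimension
  softmax reading (see above); they are retained for fidelity, not
  function.
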