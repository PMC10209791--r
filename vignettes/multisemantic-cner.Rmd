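---
title: "Multisemantic character features for Chinese clinical NER: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multisemantic character features for Chinese clinical NER: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscner)
```

## The problem and the model

Clinical named entity recognition (CNER) over Chinese electronic medical
records is a character-level sequence labeling problem: each character of a
record receives a BIO tag (`B-X` opens an entity of category `X`, `I-X`
continues it, `O` is background), and contiguous tagged runs become entity
mentions — diseases, symptoms, anatomy, examinations, instruments,
medicines, operations. Chinese makes the problem hard in a specific way:
word boundaries are not marked, and a single character carries meaning
through several parallel systems — its composition (input-method codes),
its pronunciation, its ordered strokes, and its printed shape.

mscner implements a model that feeds all of these signals to one decoder.
Per character $x_i$ six feature vectors are concatenated:

$$v_i^{\text{input}} = \mathrm{Concat}\!\left(v_i^{\text{ctx}},\; v_i^{fc},\;
v_i^{zc},\; v_i^{pc},\; v_i^{sc},\; v_i^{if}\right)$$

* $v^{\text{ctx}}$ — a contextual vector from a transformer backbone with
  **dynamic layer fusion**: every backbone layer's representation $h_c$ is
  weighted by a learned non-negative weight $\alpha_c$ (softmax-normalized,
  $\sum_c \alpha_c = 1$), summed per position, and passed through a dense
  projection. Low layers carry surface information, middle layers syntax,
  top layers semantics; fusion lets the tagger draw on all of them instead
  of the top layer alone.
* $v^{fc}, v^{zc}$ — 32-dim vectors from 1D convolutional extractors over
  the one-hot **5-stroke (wubi)** and **Zheng** input-method codes (1–4
  lowercase letters each; the two systems compensate for each other's
  collisions).
* $v^{pc}$ — the same extractor architecture over the **phonological code**
  (pinyin), decomposed into (initial, final, tone digit) slots.
* $v^{sc}$ — the extractor over the one-hot **stroke-sequence code**
  (digits 1–5: horizontal, vertical, left-falling, right-falling, turning;
  padded/truncated to 24 positions). A switchable 5-dim stroke-type count
  vector can be appended (`stroke_counts`); it is too small to pass
  through the two pooling stages itself, so it joins after the extractor.
* $v^{if}$ — a 128-dim vector from a 2D convolutional extractor over the
  character rendered as a 14×14 black-and-white glyph image, capturing
  pictographic similarity.

Every extractor is "conv(kernel 3) → ReLU → 2-window max pool" twice, then
a dense layer (channels 32/32 for codes, 8/32 for the image). The
concatenated vectors feed a bidirectional LSTM
($h_i = [h_i^{\text{forward}}; h_i^{\text{backward}}]$), a linear emission
projection, and a linear-chain CRF whose probability of a tag sequence $y$
is

$$P(y \mid X) = \frac{\exp \sum_i \left(Z_{y_i, y_{i+1}} + P_{i+1, y_{i+1}}\right)}
{\sum_{\tilde y \in Y_X} \exp \sum_i \left(Z_{\tilde y_i, \tilde y_{i+1}} + P_{i+1, \tilde y_{i+1}}\right)}$$

with transition matrix $Z$ (extended by explicit START/STOP boundary
states) and emission scores $P$. Decoding is exact Viterbi; training
minimizes $-\log P(y \mid X)$ with AdamW, end to end through the fusion
weights, projection, all five extractors, the BiLSTM, the emission layer
and $Z$. The backbone itself stays frozen — fine-tuning a pretrained
encoder is out of scope here, and the bundled stand-in backbone is a fixed
random-weight encoder in any case.

Evaluation is entity-level exact match: a predicted span counts only when
both boundaries and the category agree with a gold span, and
$\text{precision} = TP/(TP+FP)$, $\text{recall} = TP/(TP+FN)$,
$F_1 = 2PR/(P+R)$, micro-averaged by pooling counts over categories.

## Parameters that matter

| Parameter | Default (`"paper"` profile) | Meaning |
|---|---|---|
| `dropout` | 0.5 | applied to the concatenated BiLSTM input and to $h$ before emission |
| `learning_rate` | 1e-4 | AdamW step size |
| `batch_size` | 32 | documents per update |
| `hidden` | 768 | BiLSTM hidden width per direction ($h$ is 1536) |
| `max_len` | 510 | longest sequence; longer documents are chunked |
| `proj_dim` | 768 | width of the fused contextual vector |
| code / image feature dims | 32 / 128 | dense outputs of the extractors |

The `"desk"` profile is the package's own scaled configuration for
from-scratch training on small synthetic corpora: stand-in backbone of 2
layers × width 32, `hidden = 64`, `proj_dim = 32`, `learning_rate = 1e-3`,
`dropout = 0.1`, `batch_size = 16`. The rationale: the reference
hyperparameters regularize a large pretrained encoder being fine-tuned on
tens of thousands of entities; a randomly initialized model a thousand
times smaller, trained on a few hundred synthetic sentences, needs a
larger step and less regularization to converge in a comparable number of
epochs. These values were fixed when the profile was designed and are not
tuned per run.

Two published values are knowingly ambiguous, and both are configuration
knobs here: the fused projection width is reported both as 512 (in the
fusion formula) and 768 (in the parameter table) — the default follows the
parameter table; and the "semantic feature dimension" is reported as 124
although four 32-dim code vectors total 128 — the default keeps 4 × 32,
with per-channel widths fixed by the conv-stack specs.

## The synthetic corpus generator

Real clinical corpora cannot be redistributed, so every pipeline stage is
exercised on generated data. `synth_generate()` emits one-sentence
documents over a closed set of ~65 characters: entity mentions (surface
forms of 2–6 characters drawn from per-category dictionaries) interleaved
with O-tagged connective runs. Category frequencies default to the
published per-category entity shares of the self-annotated benchmark
corpus — strongly imbalanced, with Instrument at about 1.5% — so the
rare-category regime is represented. Generation is fully deterministic
given the seed. `inject_noise()` corrupts exactly
$\lfloor \text{rate} \times \text{spans} \rfloor$ gold spans by category
flips, boundary shifts, or deletions, mirroring the standard annotation
error taxonomy.

What the generator does *not* emulate: real clinical syntax and
long-range discourse (documents are single template sentences), nested
entities (flat BIO cannot represent them), non-Chinese tokens inside
entities (lab abbreviations, numerals), and ambiguous surface forms that
belong to different categories in context. A model that passes the
overfit and ablation checks here has demonstrated that the architecture,
gradients and decoding work — not that it reaches any particular accuracy
on real records, which additionally requires a real pretrained backbone
and real annotated corpora.

Because no CJK font ships with the package (and none is assumed at test
time), the bundled 14×14 glyph bitmaps are procedurally generated
synthetic stand-ins (distinct, deterministic, binary, ink fractions
0.1–0.3), clearly labelled as such; `render_glyph()` rasterizes through a
real font when the user supplies one. Similarly, the bundled code table
carries the published codes verbatim for its six reference characters and
well-formed synthetic codes for the rest of the corpus character set.

## Numerical choices

* CRF arithmetic is entirely in log space with log-sum-exp stabilization;
  the forward recursion, forward-backward marginals and Viterbi are
  checked against exhaustive enumeration (tolerance 1e-8; Viterbi exact,
  ties broken toward the lowest tag index at each backtrack step).
* Convolutions use "same" zero padding, so the stated pooling arithmetic
  (4 → 2 → 1 positions for codes; 14 → 7 → 3 for glyphs) never empties the
  grid; pooling on odd lengths floors, discarding the trailing element,
  and pooling ties resolve to the earliest window element.
* The code extractors treat the one-hot matrix as a 1D signal: positions
  along the convolution axis, alphabet as input channels; "2×2 max
  pooling" on this 1D signal is window-2 pooling along positions.
* Unknown and non-Chinese characters map to all-zero one-hot inputs and an
  all-zero glyph, not to a learned UNK embedding; their feature vectors
  are then the bias-determined constants of the extractors.
* Fusion weights are stored unconstrained and softmax-normalized each
  forward pass (uniform at initialization); with dynamic fusion disabled,
  a fixed one-hot weight on the top layer reproduces the conventional
  "top layer only" encoder.
* Weight matrices initialize uniform scaled by fan-in under per-component
  seeds derived from `config$seed`; the forget-gate bias starts at 1.
  Training, generation and noise injection are deterministic given their
  seeds (single-threaded).
* The backward LSTM runs the forward machinery on each sequence reversed
  within its own length; in a padded batch the padded steps sit after all
  real steps and receive zero upstream gradient, so no masking is needed.
* Document chunking breaks at the last O-tagged position before a span
  that would straddle the boundary; a single entity longer than `max_len`
  is an error.
* Orphan `I-X` tags (no compatible predecessor) open a new span — the
  lenient repair policy; exact-boundary matching gives no partial credit.

## Scale of the shipped checks

The test suite and the acceptance script train only desk-profile models:
the overfit check uses a 200-sentence, 5-category corpus (up to 50
epochs, stopping once training-set micro-$F_1 \ge 0.95$, typically
reached around epoch 15); the ablation grid trains all eight
feature-combination variants for 3 epochs on a 100-sentence corpus and
compares the full model against the context-only baseline averaged over 3
seeds; CRF oracle equivalence runs 100 random instances with $K^n \le
10^4$. These sizes are the package's chosen verification scale: large
enough to separate learning from chance on the synthetic task, small
enough to run comfortably on one CPU.

## Known limitations

* The stand-in backbone is contextual but not linguistic: its
  representations come from fixed random weights. It verifies shapes,
  determinism and gradient flow through fusion, not transfer learning.
  The adapter interface accepts any function producing character-aligned
  layer stacks, so a real whole-word-masking encoder can be plugged in.
* Real wubi/Zheng/pinyin/stroke codes are bundled only for the six
  reference characters; broader coverage requires a user-supplied table
  (the TSV format is documented in `read_code_table()`).
* BIO hard constraints are off by default (the CRF learns transitions);
  enabling `bio_constraints` imposes $-\infty$ on invalid transitions.
* Flat BIO cannot represent nested entities; the generator does not emit
  them and the evaluator would treat them as boundary errors.
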