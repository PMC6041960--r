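---
title: "A dual-pathway connectionist model of exception-word reading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-pathway connectionist model of exception-word reading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Japanese two-kanji words form a quasiregular spelling-to-sound domain. About
a third of characters have a single legitimate pronunciation at a given word
position (*consistent*); the rest have several, one of which dominates by
type frequency (*typical*) while the others are exceptions (*atypical*).
Surface dyslexia — reading an exception word with the regular pronunciation
of its components — is the behavioral signature that item-specific knowledge
has been lost while the regular mapping survives. Triangle-style models of
reading locate that item-specific support in the semantic system: lesioning
semantics should selectively impair atypical-word reading and raise
regularization (surface) errors.

`kanjinet` implements the whole simulation pipeline: a synthetic quasiregular
lexicon with the statistics of the published two-kanji materials, a
continuous-time recurrent sigmoid network trained through a developmental
curriculum, a semantic-lesion battery, nearest-neighbor phonological
decoding with an error taxonomy, and the repeated-measures lesion ×
typicality analysis.

## Model

Four primary systems — visual input, phonetic input, semantic, phonetic
output — are connected bidirectionally through one hidden layer per adjacent
pair. The ventral pathway is visual ↔ hidden ↔ semantic ↔ hidden ↔ phonetic
output; the dorsal pathway is visual ↔ hidden ↔ phonetic input ↔ hidden ↔
phonetic output. Unit dynamics follow

$$ s_i = \sum_j w_{ji}\,a_j,\qquad
   x_{i,t} = x_{i,t-1} + \lambda\,(s_{i,t} - x_{i,t-1}),\qquad
   a_i = \frac{1}{1+e^{-g\,x_i}} $$

with gain $g = 1$, integration rate $\lambda = 0.1$, and 20 time steps per
trial. Inputs are clamped for the whole trial; all other units start from a
zero integrated input (activation 0.5). Training is online backpropagation
through the unrolled dynamics with cross-entropy error, no momentum, a
zero-error radius of 0.1 (units within 0.1 of their target contribute no
derivative, and a trial with no out-of-radius unit applies no update), and
weight decay. Error is assessed over the final 5 of the 20 steps: the
settled state is what nearest-neighbor decoding reads out, and forcing
binary targets earlier (we tested windows up to the last 15 steps) pushes
weights to overshoot before the integrated inputs can settle, collapsing
learning.

Four tasks share the network: reading (visual → phonetic output),
comprehension (visual → semantic), speaking (semantic → phonetic output) and
repetition (phonetic input → phonetic output).

### Curriculum

Preliteracy: each word is presented 19 times for speaking and once for
repetition per epoch (95%/5%). Afterwards the forward projections from the
semantic and phonetic-input layers to the phonetic output layer are frozen —
the production mappings acquired before literacy can no longer be unlearned.
We freeze only the forward directions: weights *into* a clamped layer
receive no gradient, so the feedback blocks are still at their random
initial values when freezing happens, and freezing them would fix noise
into the reading dynamics. A layer's bias freezes when all of its incoming
blocks are frozen.

Literacy: per epoch each word is presented 6 times for reading (30%), 12 for
comprehension (60%), once for speaking and once for repetition. After every
2 epochs a reading test is run on the test items; each failed item receives
20 extra reading trials whose error derivatives are *not*
frequency-scaled — the drilling that Japanese schooling applies to failed
kanji.

Error derivatives are scaled by the square root of the word's
occurrences-per-million frequency (`root_frequency()`), normalized by the
lexicon maximum. The normalization is deliberate: with raw per-million
scales (up to ~25 at the log-normal tail) online updates at this network
scale diverge within one epoch, and normalizers that allow single trials to
step beyond the nominal learning rate (we measured the mean-normalized
variant) destabilize training the same way. Dividing by the maximum keeps
the relative √f weighting between words — which is what produces
frequency-modulated division of labor — exactly proportional while bounding
every step by the learning rate.

Learning rate and weight decay start at 0.5 and 5·10⁻⁷ and drop by 0.05 and
5·10⁻⁸ per 10 preliteracy / 2 literacy epochs (the paper profile). The desk
profile scales the learning-rate schedule to one fifth (0.1 by 0.01):
measured at the desk network size, per-trial updates at 0.5 — and already at
0.2 — thrash (loss plateaus at the saturation ceiling and nothing is
learned), while 0.1 learns cleanly. The schedule's shape and intervals are
unchanged.

## Synthetic lexicon

The generator emulates the material statistics rather than the materials:

* characters carry binary visual codes (30 bits, ~50% density, concatenated
  by position — a stand-in for kanji bitmaps), 50-bit semantic prototypes
  with exactly 30 on-bits, and 1–2-mora pronunciations per position drawn
  from a 40-mora inventory with 10 binary distinctive features per mora
  (words occupy up to 6 mora slots, zero-padded);
* a word's semantics concatenates one fresh 20-bit exemplar per character
  (10 of the prototype's 30 on-bits switched off), so semantics is partially
  predictable from orthography but arbitrary with respect to phonology;
* pronunciation choices are sampled proportionally to type frequency, making
  a word's friends/neighbors ratio (the fraction of same-position,
  same-character words sharing its pronunciation) concentrate around the
  pronunciation's type-frequency share;
* word frequencies are log-normal: mean log₁₀ 1.0, sd 0.6 occurrences per
  million. Most words are genuinely low-frequency, and the test band (log₁₀
  within ±0.45 of 0.77) sits below the corpus mean, matching the
  "low-frequency items" of the human experiment. These values were fixed
  once, from corpus realism, before any acceptance measurement.

The test-set selector picks 20 words per condition from the low-frequency
band, requires every test word's characters to occur in at least two other
words, and targets the published condition means of the friends ratio
(1.00 / 0.71 / 0.33) by greedy swap selection; a draw that cannot reach the
bands (±0.05, and ±0.04 on the mean log-frequency) triggers a deterministic
regeneration from a derived seed. Condition labels are re-derivable from the
inventory: consistent = both characters single-pronunciation; typical /
atypical = both characters inconsistent with both pronunciations modal /
non-modal; everything else is filler.

What a green generator test establishes: the *statistics* reported for the
original two-kanji materials. What it does not establish: real kanji orthography,
Japanese phonotactics beyond mora slots, or a real corpus frequency
distribution.

## Lesioning and scoring

A lesion deactivates `round(fraction × 100)` semantic units — activation
clamped to 0 at every time step, weights untouched, mask reversible — with a
fresh mask per repetition (default 5%, 50 repetitions in the paper profile,
20 at the desk scale), held fixed across test words within a repetition.
Reading output is decoded as the lexicon word with the smallest Euclidean
distance to the settled phonetic-output vector (ties to the lowest word id).
Errors are classified with precedence correct → surface → semantic → other:
a *surface* error pronounces at least one target character with a different
legitimate pronunciation of that character (flagged as a regularization when
the substitute has the higher type frequency); a *semantic* error shares a
character with the target and exceeds the 95th percentile of random-pair
semantic overlap (a heuristic null, invented here — the source experiments report only a
human example). Accuracies and error rates are averaged over repetitions
within each simulation, then analyzed with a fully-within repeated-measures
ANOVA (simulation as the random unit), hand-rolled sums of squares checked
against both a frozen hand computation and `stats::aov`.

## Profiles, sizes, and what the desk run can show

Layer sizes: the published figure's unit counts are not recoverable from the
text, so hidden sizes are free parameters. The profiles use asymmetric
hidden layers — desk 80 (visual–semantic), 25 (visual–phonetic-input), 120
(semantic–output), 25 (phonetic-input–output); the paper profile scales
these up. The ventral pathway carries the item-specific, essentially
arbitrary mappings and is capacity-bound: in pilots, speaking accuracy after
six preliteracy epochs rose from 21% (40 hidden units) to 58% (100) to ~90%
(120) on the ventral output leg. The dorsal pathway transmits the
systematic, compositional structure and needs little capacity; keeping it
small is also what creates the capacity pressure that makes exception words
lean on semantics — the division-of-labor regime the full-scale model
operates in.

The desk profile (one CPU, CI budget) runs 6 preliteracy + 10 literacy
epochs on 1200 words over 300 characters with 5 simulations. The
specification's 8+8 sketch is arithmetically incompatible with its own
15-minute budget once the 20-step dynamics are costed (~1 ms/trial × 24k
trials/epoch × 16 epochs × 5 simulations ≈ 30+ min), so the budget was
honored instead and the epochs shifted toward literacy, where reading and
comprehension actually learn. Training arithmetic runs in single precision
(double precision is used for gradient checks and forward evaluation, and
frozen parameters are returned bit-identical), which roughly halves the
cost.

The desk run tests the qualitative lesion signature — a larger accuracy
drop for atypical words than for typical and consistent words, and an
increased surface-error rate for atypical words under lesion — averaged
over 5 simulations at partial training. Honest caveat: at desk depth this
direction is draw-dependent and the acceptance experiment's fixed-seed
aggregate currently lands on the wrong side. The mechanism, visible in the
training logs, is that with the vocabulary-wide mapping still immature,
test-item accuracy is carried largely by the drilling that immediately
precedes evaluation, and freshly drilled items — disproportionately the
atypical ones — are memorized across all free parameters rather than
specifically through semantics. Deeper training (22+ epochs in pilots)
restores the expected direction but does not fit a CI budget on one CPU.
The scaled-down profile therefore demonstrates the *machinery* (identity,
battery, analysis) and the full-scale regime is left to the paper profile
(`default_config("paper")`), which needs hours of CPU.

## Known limitations

* Mid-training performance oscillates with drill recency; the battery is run
  at the end of literacy (an even epoch, right after the final drill), the
  same position the original training procedure ends in.
* At desk scale, comprehension is only partially learned, so the semantic
  route's support is noisier than in a fully trained model; the lesion
  effect's direction is asserted on the 5-simulation aggregate, not per
  simulation.
* The semantic-error null threshold and the per-repetition (rather than
  per-word) lesion sampling are reasoned choices where the source is silent.
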