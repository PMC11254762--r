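---
title: "Methods: single-neuron semantic encoding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-neuron semantic encoding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semspike)
```

# The analysis problem

During natural speech, words arrive roughly every third of a second. A
neuron that participates in comprehension should modulate its firing within
a few hundred milliseconds of each word, and — if it encodes meaning rather
than sound — that modulation should track *what the word means*: words about
food, actions, or family should drive it differently, and homophones
(identical sound, different meaning) should drive it by meaning, not form.

`semspike` implements the full analysis chain for asking these questions of
word-aligned single-unit recordings:

1. **Semantic domains from word embeddings.** Every unique word is mapped to
   a pretrained embedding vector; spherical k-means on the unit sphere
   (cosine distance) groups the vocabulary into semantic domains, with the
   domain count chosen by a silhouette criterion and the partition quality
   summarized by purity and d′.
2. **Word-aligned firing rates.** Spike times are converted to rates in a
   400-ms window lagged 100 ms after each word onset.
3. **Per-neuron selectivity.** Rank-sum tests per domain with
   Benjamini–Hochberg false-discovery control, plus a selectivity index
   `SI = |FR_domain − FR_other| / (FR_domain + FR_other)`.
4. **Population decoding.** Linear support vector classifiers with balanced
   class weights predict each held-out word's domain from the selective
   population's rates, against label-permutation nulls.
5. **Context dependence.** Homophone contrasts, a sentence versus word-list
   selectivity comparison, and surprisal-conditioned decoding.
6. **The neuronal–semantic space.** Per-neuron ridge regressions onto the
   embedding dimensions, PCA of the stacked weights, word projections, and
   distance/cophenetic correlations between neural and embedding geometry.

Because real recordings of this kind are rare, the package ships a
synthetic-data generator that plants all of the structure the analyses are
designed to detect. Every analysis is exercised end to end on data whose
ground truth is known.

# The synthetic generator

`generator_config()` describes one recorded session. Defaults match the
scale of the study design this pipeline targets:

| parameter | default | meaning |
|---|---|---|
| `n_domains` | 9 | planted semantic domains |
| `words_per_domain` | 51 | sentence vocabulary of 459 unique words |
| `dim` | 300 | embedding dimension |
| `concentration` | 2.5 | within-domain spread of word vectors |
| `n_sentences`, `sentence_length` | 131, 8 | 1,048 sentence word tokens |
| `n_units`, `frac_selective` | 133, 0.15 | ~20 planted selective units |
| `baseline_rate`, `tuning_gain` | 4 Hz, 3.6 Hz | planted SI ≈ 0.31 |
| `context_attenuation` | 0.5 | word-list tuning multiplier γ |
| `word_interval` | 0.341 s (± 5 ms jitter) | inter-word onset interval |
| `response_lag`, `response_dur` | 0.1 s, 0.4 s | response window |
| `homophone_pairs`, `homophone_occurrences` | 10, 8 | cross-domain homophones |
| `story_unique`, `story_shared` | 70, 28 | story vocabulary split |

Key modelling decisions:

* **Embedding geometry.** Domain centroids are rows of a random orthonormal
  basis; each word vector is the normalized sum of its centroid and
  isotropic Gaussian noise with expected displacement `1/concentration`
  regardless of dimension. At the default concentration the domains are
  well separated (d′ ≈ 15), which is what the cluster-recovery tests
  require; weaker concentrations are available for stress-testing.
* **Rates, not spike trains.** Only windowed rates are analysed downstream,
  so spikes are generated per response window as Poisson counts at
  `baseline + tuning`, with spike times uniform in the window. The tuning
  term depends on the mode: a gain for preferred-domain words (`"domain"`),
  a gain scaled by the positive cosine between the word vector and the
  unit's preferred direction (`"geometry"`, used for the semantic-space
  recovery analyses), or a gain tied to phonetic identity (`"phonetic"`, a
  control under which the homophone analysis must *reject* meaning coding —
  and does).
* **Baseline and gain are calibrated to the selectivity index, not taken
  from any reported rate table**: `SI = g/(2b + g)`, so 4 Hz baseline and
  3.6 Hz gain plant SI ≈ 0.31 in selective units.
* **Word-list attenuation preserves engagement.** With γ < 1 the
  word-specific tuning term is multiplied by γ during word lists and the
  removed drive is returned as an unselective rate increase equal to the
  unit's average tuning. Selectivity therefore drops while the unit's mean
  rate is unchanged — mirroring the empirical signature that word lists
  reduce tuning without reducing overall firing, and making the companion
  rank-sum test on mean rates a true null.
* **Homophones are a designed sub-experiment.** Homophone mates are drawn
  from different domains and share a `phonetic_id`; mates are oversampled
  to ≥ 8 sentence occurrences, and two same-domain control words per pair
  are oversampled identically. The homophone analysis then compares
  occurrence-matched words, so estimator noise is equal between the
  homophone and control samples. Without this matching, differences in
  per-word event counts masquerade as rate differences.
* **Story condition.** The story reuses 28 sentence-vocabulary words and
  adds 42 novel words drawn from the same planted domains, so
  cross-material decoding can be evaluated on partially novel vocabulary.

What the generator does **not** emulate: syntax or any sequential structure
within sentences (word order is exchangeable), non-Poisson spiking
statistics (bursting, refractoriness, slow drift), correlated noise across
units, electrode instabilities, or realistic word frequency distributions.
A green test suite therefore shows that the *analyses* recover what was
planted under idealized noise — it does not certify performance on real
recordings, where all of the above violations are present.

# Statistical choices

**Selectivity and FDR.** Each unit's nine domain tests are BH-adjusted as
one family (`bh_scope = "unit"`, matching the described procedure; a pooled
scope is available). BH controls the false-discovery proportion *within the
family it adjusts*. The acceptance check of FDR control therefore measures
the mean per-family FDP: units with no planted tuning have all-null
families, so any selective call there is a family-level false discovery;
units with planted tuning have no true-null domain tests in a strict sense
(their non-preferred domains also differ distributionally from "all other
domains", because the complement contains the preferred domain). Across 50
seeded populations the mean FDP is ~0.04 at the nominal 0.05. The
population-level proportion of false *units* among selective calls is a
different quantity that per-unit adjustment does not control.

**Preferred-domain ties.** Smallest adjusted p, then the larger absolute
rate modulation, then the lower domain index.

**Undefined SI.** A 0/0 selectivity index (unit silent in both event sets)
propagates as `NA` and is excluded from group means.

**Decoding accuracy.** Class-balanced throughout (validation words are
bootstrap-resampled to equal per-domain counts; disabling the bootstrap
computes mean per-domain recall directly). Chance is exactly `1/k`, which
is why a nine-domain chance level of 11% is meaningful even though domains
have unequal word counts. Features are standardized with training-split
statistics only. The multiclass reduction is one-vs-rest (one-vs-one is a
flag).

**Permutation scope.** The default null shuffles domain labels at the
event level, which makes the null mean exactly `1/k`. Shuffling the
word→domain map instead (`scope = "word"`) keeps labels consistent within
a word; because words recur across training and validation sentences, the
classifier can exploit word identity and that null sits slightly above
`1/k` (~12% rather than 11.1% at the default scale). Both are available;
the event-level null is the default and is what the chance-level
calibration asserts against. Empirical p-values are reported with add-one
smoothing, `p = (1 + #{null ≥ obs}) / (1 + n_perm)`, keeping them in
(0, 1].

**Condition comparisons and selection bias.** Selecting units on the
sentence condition and then comparing their SI across conditions imports a
regression-to-the-mean artifact: borderline units enter with inflated
sentence SIs, so a paired test shows a "drop" even when both conditions
share one generative law. The package's calibration tests therefore use
the generator's planted ground-truth units for the γ = 1 null; empirical
analyses that select units on the same data should interpret small
attenuation effects with this caveat in mind (the planted γ = 0.5 effect
is an order of magnitude larger than the bias).

**Window overlap.** At 341 ms word spacing a 100–500 ms window overlaps
the next word's window, so adjacent events share spikes and their rates
are mildly dependent. This barely affects the rank-sum domain tests
(domains are interleaved; measured type-I ≈ 3.5–5%), but two-sample tests
between contiguous blocks can be anticonservative. The word/nonword null
calibration in the tests therefore widens the word interval past the
window; the robustness checks at 350 ms and 450 ms windows cover the
overlap sensitivity for real analyses.

**Surprisal.** The language-model interface is a single generic,
`conditional_prob(lm, word, prefix)`; any model (e.g. a neural LM for real
data) can stand behind it. The bundled default is an absolutely discounted
backoff bigram trained on the stimulus corpus (discount 0.5, add-one
unigram backoff with an unknown-word cell, sentence-start symbol).
Surprisal is `−log P` in natural-log units, capped at 30 for impossible
words. Decile splits are computed over all scored words, pooled; splits
with fewer than 10 words per decile widen to quintiles.

**Homophone test.** Pooled permutation test (10,000 permutations,
two-sided, mean-difference statistic) on per-unit-per-pair `|Δ rate|`
measurements, plus a one-tailed paired t on the per-unit scatter. Units
with no response over the tested words or beyond 2.5×IQR are excluded and
logged. Comparison pairs are same-domain, different-sound word pairs
matched in count and occurrence number to the homophone pairs. Single
sessions at the default scale are near the power threshold for the pooled
permutation test; a multi-session analysis (pooling units, as with
participants) is the intended design and is what the test suite checks.

**Semantic space.** Per-word responses are per-unit z-scored mean rates
("normalized firing rate" is interpreted as per-unit z-scoring). Ridge
solutions use the closed normal-equations form with λ = 1e-4 by default.
PCA reduces the units × 300 weight matrix along the neuronal dimension, so
components live in embedding space and words are projected by inner
product. Single-linkage clustering runs on cosine distances in the full
embedding space with words sorted lexicographically first, making tie
resolution deterministic. Pair statistics (258k pairs at the 459-word
scale) are percentile-binned (100 bins; per-session variants bin at 200
with 2.5×IQR outlier-bin exclusion) before the Pearson correlation, and
one-sided permutation p-values shuffle word identity.

# Reproducibility and problem sizes

Every stochastic stage takes a seed; `split_seed()` derives per-stage
sub-seeds from one master integer, and `run_pipeline()` is byte-identical
across runs at fixed configuration and seed. The repeated-seed suites run
at sizes chosen to keep the full test run in the tens of minutes on one
core: the cluster-recovery sweep uses 12 words per domain in 50 dimensions
with 20 silhouette repeats per seed (20 seeds), the selectivity-recovery
and type-I suites use the full 133-unit, 131-sentence sentence condition
over 50 seeds each, decoding calibrations use 150–200 permutations, and
the pair-distance permutation tests use 200–500 permutations. The
acceptance script reruns the full pipeline at the study-scale defaults.

# Known limitations

* The generator's exchangeable word order makes the bigram LM's surprisal
  nearly flat; the surprisal-conditioned decoding analyses plant their
  effect through the `gain_scale` hook rather than through linguistically
  structured stimuli.
* Orthogonal planted centroids make domain separation easier than in real
  embedding spaces, where domains share structure; purity and d′ on real
  data will be lower.
* The homophone permutation test treats unit-pair measurements as
  exchangeable; within-unit correlation across pairs is ignored by the
  pooled permutation (the paired per-unit t-test is the robust companion).
* `participant_dropout()` assumes the analysis statistic is comparable
  across dropout groups; it flags distributional shifts via one-way ANOVA
  only.
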