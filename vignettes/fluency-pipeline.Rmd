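---
title: "Characterizing phonemic fluency beyond the correct-word count"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing phonemic fluency beyond the correct-word count}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The phonemic ('S') fluency test asks a participant to produce as many
words starting with a given letter as possible in 60 seconds, without
proper nouns, inflectional variants of earlier responses, or repeats. The
test is usually summarized by a single number — the count of correct
words — which is sensitive to frontal-lobe damage but discards most of
what the response actually contains: *which* words were produced, what
kinds of rules were broken, how rare the chosen words are, and how the
sequence is organized in time. `fluencygraph` implements a layered
characterization of this richer structure: per-token qualitative scoring,
whole-sequence similarity modelling with community detection, and Bayesian
predictive modelling of lesion status, together with a synthetic cohort
generator that makes the entire pipeline testable without patient data.

## Single-word scoring

Every uttered token receives exactly one label. The precedence order is a
design choice the field leaves open, resolved here as: an exact repeat of
any earlier token is a **perseveration** regardless of the repeated word's
own category (a repetition is a repetition, whatever is repeated); then
membership in a profanity list (**inappropriate**), a proper-noun list
(**proper noun**); then a shared stem with an earlier token under an
ordered suffix-stripping rule list (**permutation**, e.g. "say, saying");
then an initial-letter violation (**wrong letter**); otherwise
**correct**. A perseveration is flagged *recurrent* when at least one
response intervenes since the nearest earlier occurrence ("sun, sea,
sun"), the variant associated with posterior rather than frontal lesions.
Manual annotations can override any automatic label.

Error metrics are percentages of the total number of uttered words. The
rule-break percentage counts inappropriate words, proper nouns and
permutations; wrong-letter words are tallied separately but excluded from
the rule-break total (they are too rare for meaningful analysis, and we
keep them in the denominator — a documented convention, since the
formula's denominator "number of words" is ambiguous on this point).

The suffix rules (`-ing, -ings, -ed, -er, -ers, -est, -en, -s, -es, -'s`,
first match stripped once, stems must be at least 3 characters) are
deliberately minimal and inflectional; derivational morphology is out of
scope and can be handled by manual annotation. Permutations are only
matched against *earlier* tokens, consistent with the observation that
such errors nearly always follow their source immediately.

**Word frequency.** Raw corpus frequencies in (0, 1] are transformed as
`log10(raw * 1e9)`, so 1e-9 maps to 0 and 1 maps to 9; words absent from
the lexicon become missing values. A word is *low-frequency* when its
transformed frequency falls **at or below** the cohort mean minus two
sample standard deviations. Two conventions are deliberate here. First,
the threshold pools transformed frequencies of all correct *tokens* across
the entire sample (patients and controls alike), making it
cohort-relative; token-level pooling rather than participant-mean pooling
is an assumption, documented because the alternative is defensible.
Second, the boundary is inclusive ("fell at least two standard deviations
below" means ≤), and absent words are never low-frequency but stay in the
correct-word denominator.

**Clustering and switching.** Following the Troyer convention, maximal
runs of consecutive words sharing their first two letters are clusters;
cluster size is run length minus one ("snore, snail, show" contains a
cluster of size 1), the mean is taken over all runs including singletons,
and the relative number of switches is `switches / (total words - 1) ×
100`. All uttered tokens participate, errors and repetitions included —
the inclusion convention is assumed rather than stated in the source
literature. Only the first-two-letters criterion is implemented; the full
phonemic rule set (rhymes, homonyms) is a known limitation.

## Whole-sequence analysis

Hosted large-language-model embedding services are a paid external
dependency, so the package's default backend is a deterministic local
feature-hashing embedder: tokens are joined with `", "` (the delimiter is
fixed because embeddings depend on it), character 2-4-grams and adjacent
word bigrams are hashed into `d` signed buckets with a seeded 64-bit hash,
and the vector is L2-normalized. This is order-sensitive, reproducible,
and captures lexical and sublexical overlap between sequences — but it is
*not* a semantic model: synonyms produced by different participants look
unrelated. Conclusions from the synthetic pipeline therefore transfer to
the real setting only insofar as sequence similarity is driven by shared
surface vocabulary; the backend interface (`embed_sequences()`'s
`backend` argument) is the integration point for an external service,
shipped as a stub that tests never call.

Pairwise cosine similarities between embeddings form a complete weighted
participant graph. Age and NART enter as standardized absolute-difference
*edge* covariates — the model covariates are described only loosely in the
source analyses, and the edge-difference encoding is our documented
choice, not an inference about anyone's intent. Mean transformed word
frequency is carried as a node attribute (the "rarity" colouring of the
graph figure).

### Community detection

Communities are inferred with a degree-corrected stochastic block model
fitted by description-length (DL) minimization. Edge weights are
discretized into `Q = 8` quantile bins treated as multigraph edge
multiplicities — a deliberate simplification that keeps the microcanonical
DL tractable while preserving the ordinal structure of the similarities;
`Q` trades resolution against noise sensitivity. The DL combines (a) the
partition-dependent part of the degree-corrected multigraph entropy,
(b) per-block-pair Gaussian marginal likelihoods
(normal-inverse-gamma prior, so every term is finite at any block size)
for each standardized edge covariate, and (c) explicit prior costs for the
partition and the block-level edge-count matrix, which penalize block
count and prevent overfitting. Degree correction is on by default,
matching the reference implementations of nested block models.

The search runs agglomerative merges from singletons down the full
block-count ladder (greedy best-merge among affinity-shortlisted
candidate pairs; the chosen state's DL is recomputed exactly at every
level so incremental errors cannot accumulate), selects the best-DL
level, and then polishes with single-node Metropolis sweeps that accept
DL increases with probability `exp(-dDL)`. The returned state is the best
visited; its DL is never worse than the one-block or all-singleton
partitions. The seed governs tie-breaks and proposals, and fits are
bit-reproducible under it. A second hierarchy level can be obtained by
refitting the model to the block-level multigraph; community profiling is
done at the first level. The number of communities is inferred, never
fixed.

Communities are characterized by group composition, median fluency, age
and NART, TF-IDF characteristic words (documents are community-level
token concatenations, `idf = log(n_communities / n_containing)`,
alphabetical tie-break), and one-versus-rest Mann-Whitney U tests with a
Bonferroni threshold of `alpha/40` by default — the divisor is
configurable since the implied family of 40 tests is not enumerated in
the source analyses.

## Predictive modelling

Three nested Bayesian logistic regressions predict frontal-lesion status
(frontal = 1 versus posterior and control = 0): *baseline* (age, NART,
fluency score), *errors* (plus rule-break %, low-frequency %, number of
switches, relative switches, mean cluster size) and *full* (plus sequence
embeddings reduced to 256 latent variables by a seeded Gaussian random
projection with entries `N(0, 1/k)`). Baseline and errors use a ridge
prior; the full model uses the horseshoe to promote sparsity across the
many embedding coordinates. Sampling is exact-likelihood Gibbs with
Polya-Gamma augmentation; half-Cauchy local/global scales are updated
through inverse-gamma auxiliaries. The intercept is unpenalized and
features are standardized internally.

Model fidelity is McFadden's pseudo-R², computed as `1 - mean_s
LL(draws)/LL0` with `LL0` the intercept-only log-likelihood at the
empirical rate — the specific pseudo-R² variant used by the original
MATLAB tooling is not documented, so McFadden's is our stated choice.
Parameter-count-adjusted fit is WAIC, `-2(lppd - p_waic)`, from the
pointwise posterior log-likelihood matrix. Effective sample size uses
Geyer's initial-positive-sequence truncation and is reported as a
fraction of retained draws.

The default desk-scale MCMC schedule is 10,000 burn-in + 10,000 samples
thinned by 5; analysis scripts and tests use shorter schedules (stated in
each script) chosen so a complete run stays in the minutes range on one
CPU, and the reference schedule of 100,000 + 100,000 with thinning 10 is
available through `default_model_specs()`. With ~260 horseshoe
coordinates the minimum ESS fraction can drop below 10% at short
schedules; the fit warns rather than fails, and rankings of pseudo-R² and
WAIC across the three models are stable across seeds at these schedules.

## The synthetic cohort generator

No patient data ship with the package; the generator emulates the
*group-level statistical structure* of a focal-lesion fluency study — five
groups (left/right frontal, left/right posterior, controls) with the
published group sizes, correct-word means and SDs, error-subtype
percentages, low-frequency-word percentages, and age/NART moments as
planted defaults.

Mechanisms, each the simplest process matching the published moments:

* **Correct-word count**: rounded normal truncated at zero (only means
  and SDs are published). Truncation raises the realized mean slightly
  (about 0.3 words for the most impaired group); recovery checks compare
  against the analytic truncated mean.
* **Errors**: each uttered slot is independently an error with the
  profile's total subtype probability (the per-word binomial family is an
  assumption — the source reports only group mean percentages), the
  subtype drawn multinomially; generation stops after the planted number
  of correct words. Pooled over a group, the token-level error rate is
  unbiased for the planted rate. Perseverations repeat a uniformly chosen
  earlier correct word with at least one intervening response (the
  recurrent form; an immediate-repeat mode is configurable); permutations
  append an inflectional suffix to the immediately preceding correct word;
  inappropriate words and proper nouns come from small packaged fixture
  lists (mild placeholder profanities; common S-names) standing in for
  unpublished supplementary lists. Error slots whose preconditions are
  not yet satisfiable are deferred, never silently dropped (except in
  degenerate zero-word transcripts).
* **Word choice**: frequency-weighted sampling without replacement from a
  synthetic Zipf lexicon of pronounceable-ish random 's' strings. Lexicon
  words never end in a strippable suffix, so distinct lexicon words can
  never be mistaken for permutations of each other — scorer and generator
  agree exactly on every planted label.
* **Low-frequency words**: with the profile's probability a draw comes
  from the lexicon's bottom-frequency decile. The lexicon scales that
  decile down by a further 4 decades (`rare_gap`): real corpus frequency
  distributions are effectively bimodal between everyday vocabulary and
  genuinely obscure words, and this gap is what makes the cohort-relative
  mean-minus-2SD rule well-posed — the threshold lands in the void between
  the modes, so the scored low-frequency percentage recovers the planted
  rate exactly up to sampling noise. With a pure unimodal Zipf lexicon the
  2-SD rule has no stable referent (the power-law tail leaks through any
  threshold), which is a property of the rule, not of the generator.
* **Word order**: a two-state Markov process — with probability
  `stay_prob` (default 0.4, a free parameter chosen so healthy-control
  mean cluster sizes land in a plausible range) the next word is drawn
  from the current first-two-letter neighbourhood, otherwise from a
  different one — makes cluster/switch statistics controllable.
* **Sequence style** (off by default): styled groups draw ordinary words
  preferentially from alternating lexicon ranks. This changes *which*
  words are produced while leaving frequencies, rarity, and cluster
  statistics unchanged in distribution — a planted sequence-level signal
  invisible to every scorecard metric, used to demonstrate the regime
  where embedding-based models outperform feature-based ones. The
  demonstration strength of 0.75 was fixed a priori as "strong but not
  separable".

What the generator does **not** emulate: semantic association structure,
real phonology, response timing, lesion anatomy, or any within-participant
correlation between error types beyond the shared total-word budget.
Passing tests therefore validate the pipeline's mechanics and its
statistical contracts on data with known truth — not clinical validity on
real transcripts.

## Numerical and testing conventions

Ratios with zero denominators are `NaN` (undefined markers), never
silently zero: a zero-word participant has undefined percentages, a
one-token transcript has undefined relative switches. Degenerate feature
values are imputed at the column mean only inside the model-comparison
design matrices, where rows must stay aligned across nested models. All
stochastic stages take explicit seeds and are bit-reproducible under
them; cohort generation, embedding, block-model fitting and MCMC each
consume independent seeds derived from the configured one. Problem sizes
in the test suite (e.g. planted-partition graphs of 90 nodes, horseshoe
recovery at n = 500, p = 50, model-ordering cohorts of 240, calibration
batteries of 1000 simulations) are the package's chosen desk-scale
defaults; they keep a complete run in the minutes range while leaving
every statistical check well-powered. Property tests with stochastic
pass-criteria state their binomial slack explicitly (e.g. requiring 17/20
successes as a test of a claimed 95% rate).

## Known limitations

* The hashing embedder models surface form, not meaning.
* Only the first-two-letter clustering criterion is implemented.
* The weighted-graph block model bins weights rather than modelling them
  continuously; very fine similarity gradations within a bin are lost.
* The one-vs-rest community battery assumes the `alpha/40` convention
  rather than deriving the test family.
* Printed group-level tables from the source study are planted means, not
  fitted quantities; the package makes no claim to reproduce patient-level
  numbers, which are not publicly deposited.
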