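---
title: "Methods: staged phonological network growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged phonological network growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonogrow)
```

## The model

phonogrow analyses how phonological neighbourhoods grow as a learner's
vocabulary expands through six proficiency stages (age-of-acquisition, AoA,
stages 1–6, the CEFR A1–C2 ladder).  The lexicon known at stage *s* is the
cumulative union of everything acquired at stages 1..*s*.  At each stage a
network is built: nodes are phonemic word forms, and an edge joins two forms
at segment-level Levenshtein distance exactly 1 (one substitution, deletion,
or addition — the classic phonological-neighbour relation).  Each edge
carries an integer similarity weight in [0, 100] derived from a
feature-weighted phonetic alignment (below), so `degree` is neighbourhood
density and `weighted_degree` aggregates phonetic proximity.

A word entering at stage *a* can undergo `7 − a` **growth spurts**: spurt 1
is the set of neighbours already present at its entry stage, and spurt
*j* > 1 the neighbours gained between stages *a + j − 2* and *a + j − 1*.
Three spurt-level outcomes are computed per word:

* **proportional degree gain** — neighbours added at the spurt divided by
  the degree the word finally reaches at stage 6 (so gains across a word's
  spurts sum to 100%);
* **saturation** — cumulative degree as a percentage of the word's
  neighbourhood density in a first-language (L1) reference lexicon, the
  benchmark for how much of the available neighbourhood has been learned;
* **average weighted degree** — the word's cumulative edge weight divided by
  its current neighbour count.  This is the published worked computation: a
  no-growth spurt automatically carries the previous per-neighbour average
  forward, and a word with 7 neighbours of summed weight 352 averages 50.3.
  An alternative "per new neighbour" reading (weight added ÷ neighbours
  added, 352/5 = 70.4 in the same expansion) is exposed via
  `avg_weighted_degree_new(..., method = "new")`; the two readings disagree
  whenever growth is non-uniform, and we default to the one the worked
  example actually computes.

Growing words acquired at stages 1–3 are classified by their post-entry gain
profile: *initial* (all growth in the entry spurt), *continuous* (growth at
every spurt), *delayed* (dormant for one or two post-entry spurts, then
growth at every remaining spurt), else *other*.  Dormancy longer than two
spurts falls into *other*: the two delayed templates (`X+0+1…`, `X+0+0+1…`)
are the defined patterns, and extending them silently would blur the
classification.

## Phonetic alignment and edge weights

Edge weights come from an ALINE-family dynamic-programming alignment:
segment pairs are scored as `c_sub − δ(p, q) − V(p) − V(q)`, where δ sums
salience-weighted differences over multivalued phonetic features (place 40,
manner 50, voicing/nasality/retroflexion/laterality 10, syllabicity, height,
backness, roundness and aspiration 5, length 1), `V` charges `c_vwl = 10`
per vowel, and one-against-two expansions score `c_exp = 45` minus all
pairwise deltas and vowel penalties.  Skips earn 0.  The optimal global
score *S* is normalised Dice-style,

\[ d(a, b) = 1 - \frac{2\,S(a,b)}{S(a,a) + S(b,b)} \in [0, 1], \]

and the edge weight is `round((1 − d) × 100)` (half up).

Two numerical choices deserve comment.  First, the normalisation: dividing
by the self-alignment of the longer word alone is tempting, but the
Dice-style denominator is what reproduces the published alineR reference
outputs exactly (/eɪ/–/deɪ/ = /eɪ/–/eɪt/ = 0.3684, /eɪ/–/aɪ/ = 0.1667 with
the default feature table), so it is the shipped behaviour.  Second, the
expansion score charges the vowel penalty of *all three* segments involved
rather than the maximum of the expanded pair; this guarantees the identity
alignment is optimal for every string, hence `d = 0` exactly and only for
identical segment sequences — a property the neighbour semantics rely on.

Transcriptions are strings of single-character segments: multi-character
symbols (affricates, long vowels) must be recoded to unique single
characters upstream, which is also what makes character-level and
segment-level edit distance coincide.  The default feature table
(`inst/extdata/aline_features.tsv`) covers an English-oriented IPA inventory
plus the ASCII symbols the synthetic generator emits, and is fully
overridable through `feature_table()`.

## Statistical models

The spurt-level table (one row per growing word per spurt) feeds three
models, each with linear predictor `Spurt + AoA + Frequency(log) + Length`,
Spurt and AoA as factors with treatment contrasts against level 1:

* two quasi-binomial logit GLMs for the proportional outcomes, fitted to
  Smithson–Verkuilen-squeezed proportions `(y(n−1)+0.5)/n`, with `n` the
  row count entering the model (recorded in the table's `sv_n` attribute —
  the saturation model has its own `n` because words without L1 neighbours
  are excluded from it);
* a zero-inflated negative binomial model for the rounded average weighted
  degree, whose zeros are spurts with an empty neighbourhood, with the same
  predictors in the count and zero-inflation components (glmmTMB,
  `nbinom2`).

Quasi-likelihoods have no true likelihood, so McFadden's pseudo-R² is
computed on the Bernoulli kernel `Σ y log μ + (1−y) log(1−μ)` at the fitted
versus intercept-only means — the only reading under which a quasi-binomial
fit can report an R² at all.  Standardised odds ratios scale continuous
covariates to unit SD before exponentiating and label magnitudes by the
Cohen-style thresholds 1.68 / 3.47 / 6.71, applied through the reciprocal
for ratios below 1.  Pairwise spurt contrasts are estimated marginal means
averaged over AoA, re-gridded to the response scale, with multivariate-t
(Tukey) family-wise adjustment.  Degenerate cells — e.g. a spurt level whose
zero-inflation cell is empty — produce the huge standard errors they
deserve; the fits report them rather than suppressing them.

## The synthetic generator

Real staged lexica are proprietary, so the generator builds what the
analysis assumes, with known ground truth.  A pool of CV(C…) forms over a
small inventory is the L1 reference: its neighbourhood graph defines each
word's L1 density, and because the staged lexicon samples *from* the pool,
saturation can never exceed 100%.  Words are drawn stage by stage with
selection weight

\[ w_i \propto e^{\text{ease}_s \cdot z_i} \left(1 + c\,M_i^{\gamma}\right),
\qquad M_i = \sum_{v \in N(i) \cap \text{present}} (1 + \text{age}_v)^{-\alpha}, \]

where `z_i` is a standardised short-and-frequent score whose scale decays
linearly across stages (`ease_strength`, default 1, reproducing the
early-words-are-shorter-and-more-frequent gradients), `γ` is the
preferential-attachment exponent (default 1: attachment linear in the
candidate's already-present neighbour count), and `α ≥ 0` is the aging
strength with a power-law kernel `(1 + age)^{-α}` — the standard form for
node-relevance decay.  `α = 0` means no obsolescence: a present neighbour
keeps attracting at a constant rate.  The attachment scale `c = 1` is a
fixed implementation constant, chosen so that the two regimes the generator
must exhibit are both realised: with homogeneous base rates
(`ease_strength = 0`), a large pool, and `α = 0`, the mean per-spurt share
of a stage-1 word's final degree is flat (within ±0.05 of 1/6 in
Monte-Carlo over 30 seeds); at `α = 2` the first spurt's mean share
strictly exceeds every later spurt's.

Two caveats on what passing tests show.  The ease gradient itself
front-loads neighbour arrivals (short words live in dense regions and are
picked early), so experiments that isolate the aging mechanism must switch
it off — that is why the obsolescence tests run at `ease_strength = 0`.
And the synthetic pool is far denser than a natural lexicon: hermit
(zero-neighbour) fractions come out near 2–3% versus the 27–66% typical of
real staged vocabularies, and correspondingly few words show purely
"initial" growth.  Qualitative network properties (positive degree
assortativity, first-spurt dominance, Zipf-like frequencies, length
gradients) transfer; absolute sparsity-dependent fractions do not.

Frequencies follow a Zipf law over pool ranks correlated with length; the
generator is deterministic given `seed`, emits the exact TSV schema the
reader ingests (round-trips with zero drops), and returns the generating
truth (entry stages, pool densities, per-spurt gains, pattern labels) so
end-to-end consistency is testable.

## Problem sizes and other choices

The generator's default `words_per_stage` (584, 899, 1345, 1657, 946, 936)
mirrors a realistic staged vocabulary.  Tests and the acceptance script use
smaller explicit configs — typically 40–270 words per stage with pool
inflation 3–8 — which exercise every code path while keeping simulation
studies (100-replicate parameter recovery at n = 2000; 30-seed Monte-Carlo
aging contrasts) comfortable on a single CPU.

Display conventions follow the worked examples: proportional degree gains
print as whole percents rounded half-up (68.75 → 69), saturations truncate
toward zero (4/15 → 26%, a conservative "reached at least" reading), means
print at one decimal rounded half-to-even (58.65 → 58.6).  Full precision
is carried everywhere internally.

Assortativity is the Pearson correlation of endpoint degrees with each
undirected edge counted in both orientations; a network with no edges or
constant endpoint degree raises an error rather than returning 0.  Hermit
fractions use the stage's uniquely acquired words as denominator, judged in
that stage's own network (pass the stage-6 network to ask instead which
words never connect).  Vocabulary accounting reports both raw and
post-filter counts — staged data sources disagree between cumulative sums
and printed totals, and the reader records dropped rows instead of guessing
which filtering order produced a given table.

## Limitations

Edge weights depend on the feature table; the shipped values are a
reasonable English-oriented default, not a phonetic ground truth, and exact
numerical agreement with other ALINE implementations is only guaranteed for
the normalisation documented above.  The generator does not model
phonotactics, semantics, or part of speech, and its words-within-stage
arrival order is an artefact of sequential sampling.  Statistical models
treat words as independent given covariates (no random effects); the
quasi-binomial McFadden R² is a pseudo-measure on a working likelihood.
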