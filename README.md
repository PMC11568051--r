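# phonogrow

Growth, saturation, and phonetic distance in staged phonological networks.

Second-language learners acquire vocabulary in stages (the CEFR ladder
A1–C2, treated as age-of-acquisition stages 1–6). At every stage, the known
word forms make up a **phonological network**: nodes are phonemic
transcriptions, and an edge joins two forms that differ by exactly one
segment (substitution, deletion, or addition — the classic phonological
neighbour). phonogrow is for researchers in psycholinguistics and cognitive
network science who want to ask how these networks *grow*: which growth
spurt adds most of a word's eventual neighbourhood, how close learners come
to the neighbourhood density the first language offers, and whether early
spurts recruit phonetically closer or more distant neighbours.

## What it computes

For a word entering at stage *a* (up to `7 − a` growth spurts, where spurt 1
comprises the neighbours already present at entry):

- **proportional degree gain** — neighbours added at spurt *j* as a share of
  the stage-6 degree: `gain_j / k_final × 100`, so a word's gains sum to
  100%;
- **saturation** — cumulative degree over the word's L1-reference
  neighbourhood density: `k_j / k_L1 × 100`;
- **average weighted degree** — cumulative edge weight over current degree,
  where edge weights are ALINE-style feature-weighted phonetic similarities,
  `w = round((1 − d) × 100)` with `d = 1 − 2S(a,b)/(S(a,a)+S(b,b))` from a
  dynamic-programming alignment over place/manner/voicing/… features;
- growth-pattern classification (*initial* / *continuous* / *delayed* /
  *other*), per-stage degree assortativity and hermit (zero-neighbour)
  fractions;
- three regressions on the spurt-level table,
  `DV ~ Spurt + AoA + Frequency + Length`: quasi-binomial logit GLMs for the
  two proportional outcomes (on Smithson–Verkuilen-squeezed proportions
  `(y(n−1)+0.5)/n`), and a zero-inflated negative binomial for the rounded
  weighted degree, with Tukey-adjusted pairwise spurt contrasts on the
  response scale, McFadden pseudo-R², and standardised odds ratios.

A synthetic staged-lexicon generator (`generate()`) produces pool-based
lexica with Zipf frequencies, length gradients, preferential attachment, and
a tunable node-aging strength `α` (power-law kernel `(1+age)^−α`), so the
entire pipeline is testable without proprietary vocabulary data.

## Worked example

The package ships a miniature fixture whose words reproduce the canonical
worked numbers through the ordinary pipeline:

```r
library(phonogrow)
lex  <- make_worked_example_fixture()
nets <- build_all_networks(lex, worked_example_features())
trs  <- compute_trajectories(nets, lex)
trs[["bad"]]
#> Growth trajectory for /bad/ (AoA 1, L1 density 20)
#>  spurt neighbors_added cumulative_degree added_weight cumulative_weight
#>      1               8                 8          638               638
#>      2               3                11          245               883
#>      3               2                13          148              1031
#>      4               2                15          166              1197
#>      5               1                16           92              1289
#>      6               0                16            0              1289
```

`/bad/` ends with 16 neighbours; its first spurt contributes 8 of them
(`proportional_degree_gain(trs[["bad"]], 1)` → 50%), the second 3 more
(cumulative 69%, spurt-2 gain 19%). `/lo/`, with an L1 density of 15, runs
through saturations 13% → 13% → 26% and tops out at 33%; `/hi/` starts with
7 neighbours of summed weight 352 (50.3 per neighbour, unchanged over its
dormant second spurt) and expands to 12 of summed weight 704 (58.7).

A full synthetic run:

```r
syn <- generate(generator_config(
  n_consonants = 12, n_vowels = 5,
  words_per_stage = c(100L, 150L, 220L, 270L, 160L, 160L),
  len_min = 2, len_max = 5, seed = 42))
run <- pg_run_all(syn$lexicon)
run
#> Per-stage networks:
#>  stage n_nodes n_edges assortativity hermit_fraction
#>      1     100     503         0.511           0.010
#>      ...
#>      6    1060    8996         0.423           0.025
#>
#> Mean outcomes by spurt (growing words):
#>  spurt prop_degree_gain avg_weighted_degree prop_saturation_gain
#>      1           0.6839                79.2               0.4009
#>      2           0.1912                79.5               0.1246
#>      ...
#> Degree-gain model McFadden R2: 0.288
```

The first spurt carries ~68% of eventual degree — the obsolescence
signature: networks grow by one large entry burst followed by shrinking
spurts. Assortativity is positive at every stage (dense neighbourhoods
attach to dense neighbourhoods), and the degree-gain model's Spurt factor
dominates its covariates.

## Layout

- `R/` — lexicon I/O, phonetics (edit distance, ALINE alignment), network
  construction, growth metrics, statistical models, synthetic generator,
  pipeline orchestration (`pg_run_all()`)
- `inst/extdata/aline_features.tsv` — default segment feature table
- `vignettes/phonogrow-methods.Rmd` — the methods vignette (model,
  parameters, numerical conventions, generator design, limitations)
- `tests/testthat/` — unit, property, and end-to-end acceptance tests
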