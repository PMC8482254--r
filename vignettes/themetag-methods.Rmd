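---
title: "Cross-platform thematic label transfer: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform thematic label transfer: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(themetag)
```

# The analysis

`themetag` implements an ecological analysis that carries weak thematic
labels from one social-media platform to another and from there to
area-level health outcomes. It has five stages:

1. **Weak-label corpus.** On a community platform, forums dedicated to one
   topic (here: alcohol) act as weak positive labels. Starting from one seed
   community, every community that its description page links to, or that
   links to it, is added when it holds at least `min_posts = 1000` posts.
   All titles from the expanded community set become positive examples; an
   equal number of titles sampled uniformly without replacement from all
   other communities become negatives. The corpus is split 0.8/0.1/0.1 by a
   seeded shuffle with floor allocation.
2. **Classifier.** A binary text classifier maps each post to a probability
   of being theme-related; the call is positive at probability ≥ 0.5
   (inclusive). The default model is an L2-regularized logistic regression
   on token counts; any external model — for instance a fine-tuned
   transformer — plugs in as a plain function from texts to probabilities,
   and the rest of the pipeline is unchanged.
3. **Hashtag enrichment.** Applied to an unlabeled hashtag-bearing tweet
   corpus, the classifier's calls define, for every hashtag, a 2×2 table of
   per-tweet presence against call. A Pearson chi-square without continuity
   correction, made one-sided in the *greater* (enrichment) direction by
   halving — valid at one degree of freedom — tests whether the hashtag is
   over-represented among positive calls. Hashtags with fewer than 5
   occurrences are excluded *before* testing (they never enter the
   Benjamini–Hochberg family); the survivors are selected by BH step-up at
   a 0.05 false discovery rate.
4. **Geographic prevalence.** Tweets carrying at least one selected hashtag
   and a geotag are assigned to areas by boundary-inclusive ray-casting
   point-in-polygon. An area's prevalence is its tweet count divided by the
   mean of its yearly population estimates (default 2013–2018), per 10,000
   persons. Areas enter the association analysis when they hold ≥ 1 tweet
   and mean population strictly > 1000.
5. **Association.** For each outcome the package reports the crude Spearman
   rank correlation (t-approximation p-value on n − 2 degrees of freedom)
   and the coefficient on prevalence from an ordinary least-squares
   regression of the outcome on prevalence plus seven area-level
   confounders (race/ethnicity composition, median income, two education
   rates, and the sex ratio), with a two-sided t-test p-value.

The analysis is ecological throughout: all associations are between
area-level aggregates and say nothing about individual-level exposure.

# The synthetic world

Real platform corpora of this kind are not redistributable, so the package
ships a generative model with planted ground truth; every stage above has a
recoverable target.

* **Posts.** Each community contributes titles of 1 + Poisson(8) tokens.
  In themed communities each token comes from a theme lexicon with
  probability `theme_token_rate` (default 0.3), otherwise from a background
  lexicon; background communities leak theme tokens at `leak_token_rate`
  (default 0.02). The two rates alone control classifier difficulty.
* **Link graph.** The seed themed community is linked (directions
  alternating) with every other themed community and with no background
  community, so one-hop expansion recovers exactly the themed set.
* **Tweets.** Each tweet draws a latent indicator z ~ Bernoulli(0.1), text
  from the same token mixture keyed by z, and 1 + Poisson(0.5) hashtags:
  each draw comes from the planted 15-hashtag set with probability
  q1 = 0.6 when z = 1 and q0 = 0.02 when z = 0, otherwise uniformly from
  185 null hashtags. Setting q1 = q0 produces a null world in which planted
  and null hashtags are indistinguishable by construction.
* **Geography.** Areas are axis-aligned unit grid cells (polygon-reader
  complexity is exercised through GeoJSON input, not the generator).
  Populations are log-normal (meanlog 9, sdlog 0.5), drawn once per area
  and jittered ±5% per year so the mean-of-years denominator is a real
  computation. Confounders are i.i.d. standard normal. Tweets are assigned
  to areas with probability proportional to population; a fraction
  `geotag_rate` carries coordinates drawn uniformly inside the cell.
* **Outcome.** With `activity_a` = the area's latent-positive tweet count
  per mean population × 10,000,

  y_a = β0 + β·activity_a + xᵀ_a γ + ε_a,  ε_a ~ N(0, σ²),

  with β = `true_beta` (default 2), γ = `confounder_effects` and σ =
  `noise_sd` (default 0.5). A second outcome generated from the confounders
  and noise alone provides a built-in negative control.

Determinism: a single integer seed fans out to independent sub-streams
(posts, tweets, geography, outcomes) by stable string hashing, so identical
configurations reproduce byte-identical corpora and enlarging the tweet
corpus does not perturb the geography.

**What the generator does not emulate** — and hence what green tests do not
show about real data: natural language (tokens are exchangeable lexicon
draws, so the classifier's task is easier than real slang-rich text),
user-level structure (no accounts, no per-user tweet dedup, no retweets),
temporal drift of hashtag meaning, irregular census polygons with shared
borders or holes, and spatial autocorrelation of outcomes.

# Parameter choices

| Parameter | Default | Why |
|---|---|---|
| `min_posts` | 1000 | canonical community-expansion threshold |
| split fractions | 0.8 / 0.1 / 0.1 | canonical; floor allocation, remainder to test |
| threshold | 0.5, inclusive | calls are positive at probability ≥ 0.5 |
| `min_count` | 5 | hashtags below 5 occurrences are never tested |
| `fdr` | 0.05 | BH step-up rate |
| scale | 10,000 | prevalence per 10,000 persons |
| inclusion | ≥ 1 tweet, population > 1000 (strict) | county-style inclusion rule |
| `l2` | 1.0 | ridge strength; no finer guidance exists, and results are insensitive on separable synthetic text |
| `posts_per_community` | 1200 | places every community above the 1000-post expansion threshold so the corpus stage is exercised non-trivially |
| `geotag_rate` | 0.5 | exposed rather than fixed: real platforms geotag far fewer posts (a few percent), but a desk-scale 20,000-tweet world needs a denser geotagged subset for area-level analysis; set 0.05 for realism studies |

Split-remainder convention: the three printed partition counts under floor
allocation (521,016 / 65,127 at n = 651,271) leave one example over; it goes
to the test partition.

# Numerical and procedural choices

* **One-sided p.** `p_one = p_two/2` in the enrichment direction,
  `1 − p_two/2` otherwise; a zero statistic gives 0.5. On every 2×2 table
  the statistic equals the squared two-proportion z, which the tests use as
  an independent oracle.
* **No Yates correction** by default (configurable): the 5-occurrence floor
  bounds small-sample distortion, and the correction is deliberately not
  part of the canonical settings.
* **Occurrences are per-tweet presence** (the row margin a+b of the table),
  not token counts: the contingency unit is the tweet, and a hashtag
  repeated inside one tweet counts once.
* **Degenerate tables** (a zero marginal — e.g. when a stub classifier
  calls every tweet positive) are excluded from testing, not failed.
* **Containment** is edge-inclusive; when areas share a border the
  lexicographically smallest `area_id` claims the point. Real polygon sets
  tile the plane with shared edges, so a deterministic rule is required;
  unassigned geotags are counted and their coordinates kept, never silently
  dropped.
* **Spearman p** uses the t-approximation, not an exact permutation: area
  counts in this design run from dozens to thousands, where the
  approximation is standard.
* **Regression** is unweighted OLS with the seven confounders entered raw:
  coefficients on prevalence are invariant to affine confounder rescaling
  (property-tested), so standardization is presentation-only and omitted.
  Rank-deficient designs raise an error naming the collinear columns. No
  multiple-testing correction is applied across association rows; p-values
  are reported per outcome.
* **Pairwise-complete deletion** per outcome: each association row reports
  its own n after inclusion filters and outcome availability.

# Validation design and problem sizes

The test suite validates each stage against independent brute-force oracles
(exhaustive neighbor scans, the z² identity, the literal BH step-up
definition, rank-and-correlate Spearman) on ≥ 1000 random instances each,
and the pipeline end-to-end on generated worlds:

* **Planted-hashtag recovery**: 20 seeds of the default world
  (20,000 tweets, 15 planted / 185 null hashtags, q1 = 0.6, q0 = 0.02),
  full weak-label → train → discover path; mean sensitivity ≥ 0.9 and mean
  empirical FDR ≤ 0.1.
* **Null calibration**: 100 seeds of a 4,000-tweet world with q1 = q0; the
  mean selected fraction must not exceed 0.05 plus 3 Monte-Carlo standard
  errors.
* **Effect recovery**: 200 replicate worlds of 2,000 tweets and 100 areas;
  the adjusted regression of the generated outcome on the generator's true
  activity covariate recovers `true_beta` within 2 Monte-Carlo standard
  errors with 95% CI coverage inside [0.92, 0.98]. The tweet count affects
  only the granularity of the activity covariate, not the estimator's bias,
  so replicate worlds are kept small. Note that regressing on the
  *estimated* hashtag prevalence instead of the true covariate is subject
  to classical attenuation — prevalence is a noisy proxy for latent
  activity — which is why parameter recovery is defined against the
  generator's own covariate while the pipeline's proxy path is validated
  for direction and significance.
* **Conservation and determinism**: assigned + unassigned = geotagged input
  on every run, and a repeated seed reproduces byte-identical artifacts.

# Known limitations

* The default classifier is a bag-of-tokens linear model; it cannot learn
  word order or subword structure. The adapter seam exists precisely so a
  transformer can replace it without touching the statistics.
* No per-user deduplication: a prolific account inflates its area's
  prevalence. The on-disk schema carries no user ids, so this is a
  documented analysis limitation.
* Hashtag semantics are treated as stationary across years.
* The enrichment test conditions on the classifier's calls; classifier bias
  propagates to hashtag selection and is not corrected for.
* Confounder adjustment is linear and additive; no spatial autocorrelation
  or causal identification is attempted.
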