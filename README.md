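# themetag

Cross-platform thematic label transfer and hashtag enrichment analysis.

## The problem

Health behaviors such as alcohol use leave traces on social media, but the
thematic structures that organize those traces differ by platform: one
platform has topic-dedicated communities (subreddits), another has
free-form hashtags. `themetag` implements a pipeline that transfers weak
labels across that divide and connects the result to area-level health
outcomes:

1. **Weak supervision** — posts from a seed themed community and its
   one-hop link neighborhood (communities with ≥ 1000 posts) become
   positive training labels; an equal number of random posts from all other
   communities become negatives (balanced by construction), split
   0.8/0.1/0.1.
2. **Classification** — a binary text classifier (default: L2-regularized
   logistic regression on token counts; any external model, e.g. a
   fine-tuned transformer, plugs in as a function from texts to
   probabilities) calls each tweet positive at probability ≥ 0.5.
3. **Hashtag enrichment** — for each hashtag h with ≥ 5 per-tweet
   occurrences, a 2×2 table crosses presence of h with the call, and a
   one-sided ("greater") Pearson chi-square

   χ² = n(ad − bc)² / [(a+b)(c+d)(a+c)(b+d)],  p₁ = p₂/2 in the enrichment direction,

   is corrected by Benjamini–Hochberg step-up at FDR 0.05 to yield the
   significant hashtag set.
4. **Geographic prevalence** — geotagged tweets carrying a significant
   hashtag are mapped to areas by point-in-polygon (boundary-inclusive,
   deterministic tie-break); an area's prevalence is tweets divided by its
   mean 2013–2018 population, per 10,000 persons. Areas with ≥ 1 tweet and
   population > 1000 are analyzed.
5. **Ecological association** — each outcome is reported with the crude
   Spearman ρ and the prevalence coefficient β from OLS adjusted for seven
   area-level confounders (race/ethnicity composition, median income,
   education, sex ratio).

Because the platform corpora behind such analyses are not redistributable,
the package ships a synthetic world generator with planted ground truth —
themed communities with an elevated theme-lexicon rate, tweets whose latent
theme indicator enriches a planted hashtag subset, and grid-cell areas
whose outcome is linear in latent activity plus confounders — so every
stage is testable offline against a recoverable target. The package also
ships the curated 18-community and 24-hashtag (14 beer, 5 wine, 3 liquor,
2 ambiguous) reference lists via `alcohol_subreddits()` and
`alcohol_hashtags()`.

## Worked example

```r
library(themetag)

cfg   <- world_config(seed = 42)          # 20,000 tweets, 15 planted hashtags
w     <- generate_world(cfg)

positives <- expand_seed_communities(w$graph, "c001", min_posts = 1000)
corpus    <- build_labeled_corpus(w$posts, positives, seed = 42)
split     <- split_corpus(corpus, seed = 42)          # 9600 / 1200 / 1200
model     <- train_classifier(split$train)

results <- discover_hashtags(w$tweets, model)         # FDR 0.05, min count 5
sig     <- significant_hashtags(results)
head(results[, c("hashtag", "occurrences", "statistic", "p_adjusted", "significant")], 3)
#>     hashtag occurrences statistic    p_adjusted significant
#> 1 alctag009         156  506.2732 4.102675e-110        TRUE
#> 2 alctag014         184  453.7861  5.409168e-99        TRUE
#> 3 alctag013         159  416.6242  4.416766e-91        TRUE

length(sig)                                   # 15 of 200 tested
all(w$truth$planted_hashtags %in% sig)        # TRUE — every planted hashtag found

suite <- run_association_suite(w$tweets, w$areas, list(all = sig),
                               min_population = 0)
print(suite, digits = 3)
#>           outcome  level category  n spearman_rho spearman_p    beta  beta_p
#> 1  drinking_index county      all 99        0.266    0.00767 0.95141 0.00151
#> 2 unrelated_index county      all 99        0.110    0.28035 0.00845 0.57277
```

Reading the output: all 15 planted hashtags are recovered with no false
discoveries among the 185 null hashtags; the outcome generated from latent
alcohol activity (`drinking_index`) shows a positive, significant adjusted
association with hashtag prevalence, while the confounder-only negative
control (`unrelated_index`) does not. (The β on the prevalence *proxy* is
attenuated relative to the generative effect, as expected for a noisy
exposure measure — see the methods vignette.)

A command-line wrapper with subcommands `simulate`, `build-corpus`,
`train`, `discover`, `prevalence`, `associate` and `run-all` is installed
at `system.file("cli", "themetag.R", package = "themetag")`; `run-all`
writes `model.json`, `hashtags.json`, `prevalence.csv`, `association.csv`
and a `manifest.json` recording the seed, settings and tweet funnel.

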