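# End-to-end orchestration: simulate (optional) -> build corpus -> train ->
# discover -> prevalence -> associate, under a single config whose defaults
# are the pipeline's canonical settings, with a manifest for reproducibility.

#' Pipeline configuration
#'
#' All stage thresholds live here, never as literals in stage code. The
#' defaults are the canonical settings of the analysis: community expansion
#' at >= 1000 posts, 0.8/0.1/0.1 split, 0.5 decision threshold (inclusive),
#' FDR 0.05 with a 5-occurrence minimum, prevalence per 10,000 persons, and
#' county inclusion at >= 1 tweet and mean population strictly > 1000.
#'
#' @param seed Global seed; per-stage streams are derived by stable hashing.
#' @param min_posts Community expansion post-count threshold.
#' @param fractions Train/validation/test fractions.
#' @param threshold Classifier decision threshold (inclusive).
#' @param fdr BH false discovery rate.
#' @param min_count Minimum hashtag occurrences before testing.
#' @param scale Per-capita normalization constant.
#' @param min_tweets,min_population Area inclusion filters.
#' @param years Population-estimate year range.
#' @param l2 Classifier L2 regularization strength.
#' @param seed_community Seed community id for corpus expansion.
#' @param world Optional [world_config()] used when simulating.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            min_posts = 1000,
                            fractions = c(0.8, 0.1, 0.1),
                            threshold = 0.5,
                            fdr = 0.05,
                            min_count = 5,
                            scale = 10000,
                            min_tweets = 1,
                            min_population = 1000,
                            years = 2013:2018,
                            l2 = 1,
                            seed_community = NULL,
                            world = NULL) {
  structure(
    list(seed = as.integer(seed), min_posts = min_posts,
         fractions = fractions, threshold = threshold, fdr = fdr,
         min_count = min_count, scale = scale, min_tweets = min_tweets,
         min_population = min_population, years = as.integer(years), l2 = l2,
         seed_community = seed_community, world = world),
    class = "pipeline_config"
  )
}

#' Run the full pipeline
#'
#' Executes every stage on an in-memory world (either supplied, read from
#' `input_dir`, or simulated when `simulate = TRUE`) and writes
#' `model.json`, `hashtags.json`, `prevalence.csv`, `association.csv` and
#' `manifest.json` to `output_dir`. Rerunning with the same config and seed
#' reproduces identical outputs.
#'
#' The manifest records the seed, the stage settings, and the tweet funnel:
#' total -> hashtag-bearing -> alcohol-filtered -> geotagged-alcohol ->
#' area-assigned (+ unassigned).
#'
#' @param config A [pipeline_config()].
#' @param output_dir Output directory (created if needed).
#' @param world Optional `theme_world` (takes precedence).
#' @param input_dir Optional directory of world files from [write_world()].
#' @param simulate Generate a world from `config$world` (or the default
#'   [world_config()] with the pipeline seed) when no input is given.
#' @return Invisibly, a list with `association`, `prevalence`, `hashtags`,
#'   `model` and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir,
                         world = NULL, input_dir = NULL, simulate = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(world)) {
    if (!is.null(input_dir)) {
      world <- read_world(input_dir)
    } else if (simulate) {
      wc <- if (is.null(config$world)) world_config(seed = config$seed)
            else config$world
      world <- generate_world(wc)
    } else {
      stop("no input: supply `world`, `input_dir`, or set `simulate = TRUE`",
           call. = FALSE)
    }
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  ## corpus ------------------------------------------------------------------
  seed_comm <- config$seed_community
  if (is.null(seed_comm)) seed_comm <- names(world$graph$communities)[1]
  positives <- expand_seed_communities(world$graph, seed_comm,
                                       min_posts = config$min_posts)
  corpus <- build_labeled_corpus(world$posts, positives, seed = config$seed)
  split <- split_corpus(corpus, fractions = config$fractions,
                        seed = config$seed)

  ## classifier --------------------------------------------------------------
  model <- train_classifier(split$train, l2 = config$l2,
                            threshold = config$threshold, seed = config$seed)
  write_classifier(model, file.path(output_dir, "model.json"))

  ## hashtag discovery -------------------------------------------------------
  results <- discover_hashtags(world$tweets, model, q = config$fdr,
                               min_count = config$min_count,
                               threshold = config$threshold)
  sig <- significant_hashtags(results)
  jsonlite::write_json(results, file.path(output_dir, "hashtags.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  ## prevalence --------------------------------------------------------------
  alcohol <- filter_alcohol_tweets(world$tweets, sig)
  geotagged <- alcohol[alcohol$geotagged, , drop = FALSE]
  prevalence <- compute_prevalence(geotagged, world$areas,
                                   years = config$years, scale = config$scale)
  utils::write.csv(prevalence, file.path(output_dir, "prevalence.csv"),
                   row.names = FALSE)

  ## association -------------------------------------------------------------
  association <- run_association_suite(
    world$tweets, world$areas, hashtag_sets = list(all = sig),
    years = config$years, scale = config$scale,
    min_tweets = config$min_tweets, min_population = config$min_population
  )
  utils::write.csv(association, file.path(output_dir, "association.csv"),
                   row.names = FALSE)

  ## manifest ----------------------------------------------------------------
  manifest <- list(
    seed = config$seed,
    settings = config[c("min_posts", "fractions", "threshold", "fdr",
                        "min_count", "scale", "min_tweets", "min_population",
                        "years", "l2")],
    counts = list(
      tweets_total = nrow(world$tweets),
      tweets_with_hashtags = sum(lengths(tweet_hashtag_sets(world$tweets)) > 0),
      corpus_examples = nrow(corpus),
      split = c(train = nrow(split$train), validation = nrow(split$validation),
                test = nrow(split$test)),
      hashtags_tested = nrow(results),
      hashtags_significant = length(sig),
      tweets_alcohol = nrow(alcohol),
      tweets_alcohol_geotagged = nrow(geotagged),
      tweets_assigned = sum(prevalence$tweet_count),
      tweets_unassigned = attr(prevalence, "n_unassigned"),
      areas = length(world$areas$features),
      areas_included = nrow(apply_inclusion_filters(
        prevalence, config$min_tweets, config$min_population))
    )
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(association = association, prevalence = prevalence,
                 hashtags = results, model = model, manifest = manifest))
}
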