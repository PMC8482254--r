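# Synthetic social-media world with planted ground truth.
#
# The generator emulates the data regime the pipeline is designed for:
# a community platform whose themed forums carry an elevated rate of
# theme-lexicon tokens, a microblogging platform whose tweets carry a latent
# theme indicator that enriches a planted hashtag subset, and a geography of
# grid-cell areas whose outcome is a linear function of latent theme activity
# plus confounders. Every downstream stage therefore has a recoverable target.

#' Confounder covariate names used throughout the package
#'
#' Seven area-level covariates mirroring the standard community-survey
#' adjustment set: race/ethnicity composition, income, education and sex
#' ratio.
#' @return Character vector of length 7.
#' @export
confounder_names <- function() {
  c("pct_white", "pct_black", "pct_hispanic", "median_income",
    "pct_hs", "pct_bachelor", "males_per_100_females")
}

#' Configuration of the synthetic world
#'
#' Parameterizes the data-generating process: a community corpus with themed
#' and background communities, a tweet corpus with a latent theme indicator
#' and planted hashtags, and a grid-cell geography with populations,
#' confounders and a linear outcome model.
#'
#' @param n_communities Total number of communities.
#' @param n_alcohol_communities Number of themed (alcohol-related)
#'   communities; the first one acts as the seed community whose description
#'   links reach all other themed communities.
#' @param posts_per_community Posts per community.
#' @param vocab_background_size,vocab_theme_size Lexicon sizes.
#' @param theme_token_rate Probability that a token in a themed-community post
#'   (or a latent-positive tweet) is drawn from the theme lexicon.
#' @param leak_token_rate Same probability for background communities and
#'   latent-negative tweets.
#' @param n_tweets Number of tweets.
#' @param latent_theme_rate Bernoulli rate of the latent theme indicator z.
#' @param n_planted_hashtags,n_null_hashtags Sizes of the planted (enriched)
#'   and null hashtag sets.
#' @param planted_rate_pos Probability q1 that a hashtag draw on a z = 1 tweet
#'   comes from the planted set.
#' @param planted_rate_neg Same probability q0 for z = 0 tweets. A recoverable
#'   world needs q1 > q0; q1 = q0 yields a null world where planted and null
#'   hashtags are statistically indistinguishable.
#' @param geotag_rate Fraction of tweets carrying latitude/longitude.
#' @param n_areas Number of grid-cell areas.
#' @param years Integer vector of population-estimate years.
#' @param true_beta Outcome effect of per-10,000 latent tweet activity.
#' @param confounder_effects Length-7 vector of confounder coefficients.
#' @param noise_sd Outcome noise standard deviation.
#' @param seed Integer seed; fully determines the generated world.
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_communities = 20,
                         n_alcohol_communities = 5,
                         posts_per_community = 1200,
                         vocab_background_size = 500,
                         vocab_theme_size = 50,
                         theme_token_rate = 0.3,
                         leak_token_rate = 0.02,
                         n_tweets = 20000,
                         latent_theme_rate = 0.1,
                         n_planted_hashtags = 15,
                         n_null_hashtags = 185,
                         planted_rate_pos = 0.6,
                         planted_rate_neg = 0.02,
                         geotag_rate = 0.5,
                         n_areas = 100,
                         years = 2013:2018,
                         true_beta = 2,
                         confounder_effects = c(0.5, -0.5, 0.3, 0.2, -0.3, 0.4, 0.1),
                         noise_sd = 0.5,
                         seed = 1L) {
  cfg <- list(
    n_communities = check_count(n_communities, "n_communities"),
    n_alcohol_communities = check_count(n_alcohol_communities, "n_alcohol_communities"),
    posts_per_community = check_count(posts_per_community, "posts_per_community"),
    vocab_background_size = check_count(vocab_background_size, "vocab_background_size"),
    vocab_theme_size = check_count(vocab_theme_size, "vocab_theme_size"),
    theme_token_rate = check_prob(theme_token_rate, "theme_token_rate"),
    leak_token_rate = check_prob(leak_token_rate, "leak_token_rate"),
    n_tweets = check_count(n_tweets, "n_tweets"),
    latent_theme_rate = check_prob(latent_theme_rate, "latent_theme_rate"),
    n_planted_hashtags = check_count(n_planted_hashtags, "n_planted_hashtags"),
    n_null_hashtags = check_count(n_null_hashtags, "n_null_hashtags"),
    planted_rate_pos = check_prob(planted_rate_pos, "planted_rate_pos"),
    planted_rate_neg = check_prob(planted_rate_neg, "planted_rate_neg"),
    geotag_rate = check_prob(geotag_rate, "geotag_rate"),
    n_areas = check_count(n_areas, "n_areas"),
    years = as.integer(years),
    true_beta = as.numeric(true_beta),
    confounder_effects = as.numeric(confounder_effects),
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  )
  if (cfg$n_alcohol_communities >= cfg$n_communities) {
    stop("`n_alcohol_communities` must be smaller than `n_communities`",
         call. = FALSE)
  }
  if (length(cfg$confounder_effects) != 7) {
    stop("`confounder_effects` must have length 7", call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  if (length(cfg$years) < 1) stop("`years` must be non-empty", call. = FALSE)
  class(cfg) <- "world_config"
  cfg
}

# Draw `n` documents: token count 1 + Poisson(mean_extra), each token from the
# theme lexicon with per-document probability `rate`, else background.
draw_documents <- function(n, rate, theme_vocab, background_vocab,
                           mean_extra = 8) {
  lens <- 1L + stats::rpois(n, mean_extra)
  total <- sum(lens)
  from_theme <- stats::runif(total) < rep.int(rate, lens)
  tokens <- character(total)
  n_theme <- sum(from_theme)
  if (n_theme > 0) tokens[from_theme] <- sample(theme_vocab, n_theme, replace = TRUE)
  if (n_theme < total) tokens[!from_theme] <- sample(background_vocab, total - n_theme, replace = TRUE)
  paste_docs(tokens, lens)
}

#' Generate a synthetic social-media world
#'
#' Generates (a) a community-post corpus whose themed communities draw tokens
#' from a theme lexicon at `theme_token_rate` (background communities leak at
#' `leak_token_rate`), (b) a community link graph connecting the seed themed
#' community to every other themed community and to no background community,
#' (c) a tweet corpus with latent indicator z ~ Bernoulli(`latent_theme_rate`)
#' whose hashtag draws come from a planted set with probability q1 (z = 1) or
#' q0 (z = 0) and otherwise uniformly from a null set, and (d) grid-cell areas
#' with log-normal populations, i.i.d. standard-normal confounders, tweets
#' allocated proportionally to population, and a linear-Gaussian outcome
#'
#'   y_a = beta0 + true_beta * activity_a + x_a' gamma + N(0, noise_sd),
#'
#' where activity_a is the area's latent-positive tweet count per mean
#' population, scaled per 10,000 persons.
#'
#' Independent RNG streams (posts, tweets, geography) are derived from the
#' seed by stable hashing, so changing one component's size does not perturb
#' the others.
#'
#' @param config A [world_config()].
#' @return A list of class `theme_world` with elements `posts`, `graph`,
#'   `tweets`, `areas` and `truth`. `truth` carries the planted hashtag set,
#'   `true_beta`, the per-area latent-tweet fraction and (in memory only) the
#'   exact activity covariate, tweet-level latent indicators and area
#'   assignments used to build the outcome.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  cfg <- config

  theme_vocab <- sprintf("alc%03d", seq_len(cfg$vocab_theme_size))
  background_vocab <- sprintf("bg%04d", seq_len(cfg$vocab_background_size))
  community_ids <- sprintf("c%03d", seq_len(cfg$n_communities))
  themed <- community_ids[seq_len(cfg$n_alcohol_communities)]
  seed_comm <- themed[1]

  ## --- community posts -----------------------------------------------------
  posts <- with_stream(cfg$seed, "posts", {
    n_posts <- cfg$n_communities * cfg$posts_per_community
    community <- rep(community_ids, each = cfg$posts_per_community)
    rate <- ifelse(community %in% themed, cfg$theme_token_rate, cfg$leak_token_rate)
    data.frame(
      post_id = sprintf("p%06d", seq_len(n_posts)),
      community = community,
      title = draw_documents(n_posts, rate, theme_vocab, background_vocab),
      stringsAsFactors = FALSE
    )
  })

  ## --- link graph: seed <-> other themed communities, directions alternate --
  others <- setdiff(themed, seed_comm)
  if (length(others) > 0) {
    out_edge <- seq_along(others) %% 2 == 0
    edges <- data.frame(
      src = ifelse(out_edge, seed_comm, others),
      dst = ifelse(out_edge, others, seed_comm),
      stringsAsFactors = FALSE
    )
  } else {
    edges <- data.frame(src = character(0), dst = character(0),
                        stringsAsFactors = FALSE)
  }
  graph <- community_graph(
    communities = stats::setNames(rep(cfg$posts_per_community, cfg$n_communities),
                                  community_ids),
    edges = edges
  )

  ## --- geography -----------------------------------------------------------
  geo <- with_stream(cfg$seed, "geography", {
    g <- ceiling(sqrt(cfg$n_areas))
    idx <- seq_len(cfg$n_areas)
    x0 <- (idx - 1) %% g
    y0 <- (idx - 1) %/% g
    base_pop <- stats::rlnorm(cfg$n_areas, meanlog = 9, sdlog = 0.5)
    pop <- sapply(cfg$years, function(yr) {
      base_pop * stats::runif(cfg$n_areas, 0.95, 1.05)
    })
    pop <- matrix(pop, nrow = cfg$n_areas)
    colnames(pop) <- as.character(cfg$years)
    conf <- matrix(stats::rnorm(cfg$n_areas * 7), ncol = 7,
                   dimnames = list(NULL, confounder_names()))
    list(x0 = x0, y0 = y0, pop = pop, conf = conf)
  })
  mean_pop <- rowMeans(geo$pop)

  ## --- tweets --------------------------------------------------------------
  planted <- sprintf("alctag%03d", seq_len(cfg$n_planted_hashtags))
  nulltags <- sprintf("tag%04d", seq_len(cfg$n_null_hashtags))

  tw <- with_stream(cfg$seed, "tweets", {
    n <- cfg$n_tweets
    z <- stats::runif(n) < cfg$latent_theme_rate
    body <- draw_documents(
      n, ifelse(z, cfg$theme_token_rate, cfg$leak_token_rate),
      theme_vocab, background_vocab
    )
    k <- 1L + stats::rpois(n, 0.5)
    total <- sum(k)
    q <- rep.int(ifelse(z, cfg$planted_rate_pos, cfg$planted_rate_neg), k)
    from_planted <- stats::runif(total) < q
    tags <- character(total)
    npl <- sum(from_planted)
    if (npl > 0) tags[from_planted] <- sample(planted, npl, replace = TRUE)
    if (npl < total) tags[!from_planted] <- sample(nulltags, total - npl, replace = TRUE)
    tag_sets <- lapply(
      split(tags, factor(rep.int(seq_len(n), k), levels = seq_len(n))),
      function(x) sort(unique(x))
    )
    area_idx <- sample.int(cfg$n_areas, n, replace = TRUE, prob = mean_pop)
    geotagged <- stats::runif(n) < cfg$geotag_rate
    u <- pmin(pmax(stats::runif(n), 1e-9), 1 - 1e-9)
    v <- pmin(pmax(stats::runif(n), 1e-9), 1 - 1e-9)
    lon <- geo$x0[area_idx] + u
    lat <- geo$y0[area_idx] + v
    lon[!geotagged] <- NA_real_
    lat[!geotagged] <- NA_real_
    year <- sample(cfg$years, n, replace = TRUE)
    text <- paste(
      body,
      vapply(tag_sets, function(h) paste0("#", h, collapse = " "), character(1))
    )
    list(z = z, tag_sets = unname(tag_sets), area_idx = area_idx,
         lon = lon, lat = lat, year = year, text = text)
  })

  tweets <- data.frame(
    tweet_id = sprintf("t%07d", seq_len(cfg$n_tweets)),
    text = tw$text,
    lat = tw$lat,
    lon = tw$lon,
    year = tw$year,
    stringsAsFactors = FALSE
  )
  tweets$hashtags <- tw$tag_sets

  ## --- outcomes ------------------------------------------------------------
  latent_count <- tabulate(tw$area_idx[tw$z], nbins = cfg$n_areas)
  assigned_count <- tabulate(tw$area_idx, nbins = cfg$n_areas)
  latent_rate <- ifelse(assigned_count > 0, latent_count / assigned_count, 0)
  activity <- latent_count / mean_pop * 1e4
  beta0 <- 1
  outcome <- with_stream(cfg$seed, "outcomes", {
    main <- beta0 + cfg$true_beta * activity +
      as.vector(geo$conf %*% cfg$confounder_effects) +
      stats::rnorm(cfg$n_areas, sd = cfg$noise_sd)
    unrelated <- as.vector(geo$conf %*% cfg$confounder_effects) +
      stats::rnorm(cfg$n_areas, sd = cfg$noise_sd)
    list(drinking_index = main, unrelated_index = unrelated)
  })

  area_ids <- sprintf("a%03d", seq_len(cfg$n_areas))
  features <- lapply(seq_len(cfg$n_areas), function(i) {
    ring <- cbind(
      lon = c(geo$x0[i], geo$x0[i] + 1, geo$x0[i] + 1, geo$x0[i], geo$x0[i]),
      lat = c(geo$y0[i], geo$y0[i], geo$y0[i] + 1, geo$y0[i] + 1, geo$y0[i])
    )
    list(
      area_id = area_ids[i],
      level = "county",
      rings = list(ring),
      population_by_year = stats::setNames(as.numeric(geo$pop[i, ]),
                                           colnames(geo$pop)),
      confounders = stats::setNames(as.numeric(geo$conf[i, ]),
                                    confounder_names()),
      outcomes = c(drinking_index = outcome$drinking_index[i],
                   unrelated_index = outcome$unrelated_index[i])
    )
  })
  areas <- structure(list(level = "county", features = features),
                     class = "geo_areas")

  truth <- list(
    planted_hashtags = planted,
    true_beta = cfg$true_beta,
    area_latent_rate = stats::setNames(latent_rate, area_ids),
    # in-memory extras used by tests and recovery analyses
    area_activity = stats::setNames(activity, area_ids),
    area_assigned = stats::setNames(assigned_count, area_ids),
    tweet_latent = tw$z,
    tweet_area = area_ids[tw$area_idx],
    beta0 = beta0
  )

  structure(
    list(config = cfg, posts = posts, graph = graph, tweets = tweets,
         areas = areas, truth = truth),
    class = "theme_world"
  )
}

#' @export
print.theme_world <- function(x, ...) {
  cat("<theme_world>\n")
  cat("  posts:   ", nrow(x$posts), " in ", length(x$graph$communities),
      " communities\n", sep = "")
  cat("  tweets:  ", nrow(x$tweets), " (",
      sum(!is.na(x$tweets$lat)), " geotagged)\n", sep = "")
  cat("  areas:   ", length(x$areas$features), "\n", sep = "")
  cat("  planted hashtags: ", length(x$truth$planted_hashtags), "\n", sep = "")
  invisible(x)
}
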