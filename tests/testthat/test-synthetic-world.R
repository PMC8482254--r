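test_that("world generation is deterministic and seed-stream isolated", {
  cfg <- small_world_config(seed = 11)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$posts, w2$posts)
  expect_identical(w1$tweets, w2$tweets)
  expect_identical(w1$areas, w2$areas)
  expect_identical(w1$truth$area_latent_rate, w2$truth$area_latent_rate)

  # changing the tweet count must not perturb posts or geography
  cfg_more <- small_world_config(seed = 11, n_tweets = 2000)
  w3 <- generate_world(cfg_more)
  expect_identical(w1$posts, w3$posts)
  expect_identical(
    lapply(w1$areas$features, `[[`, "population_by_year"),
    lapply(w3$areas$features, `[[`, "population_by_year")
  )
})

test_that("degenerate configurations are rejected with validation errors", {
  expect_error(world_config(n_tweets = 0), "n_tweets")
  expect_error(world_config(n_areas = 0), "n_areas")
  expect_error(world_config(n_communities = 3, n_alcohol_communities = 3),
               "n_alcohol_communities")
  expect_error(world_config(theme_token_rate = 1.2), "probability")
  expect_error(world_config(planted_rate_neg = -0.1), "probability")
  expect_error(world_config(noise_sd = 0), "noise_sd")
})

test_that("themed posts carry theme tokens at the configured rate", {
  cfg <- small_world_config(seed = 3, posts_per_community = 300)
  w <- generate_world(cfg)
  themed <- sprintf("c%03d", 1:3)
  toks <- unlist(tokenize(w$posts$title[w$posts$community %in% themed]))
  is_theme <- grepl("^alc", toks)
  rate <- mean(is_theme)
  mc_se <- sqrt(cfg$theme_token_rate * (1 - cfg$theme_token_rate) / length(toks))
  expect_lt(abs(rate - cfg$theme_token_rate), 3 * mc_se)

  # background leak rate likewise
  bg <- unlist(tokenize(w$posts$title[!w$posts$community %in% themed]))
  leak <- mean(grepl("^alc", bg))
  mc_se_bg <- sqrt(cfg$leak_token_rate * (1 - cfg$leak_token_rate) / length(bg))
  expect_lt(abs(leak - cfg$leak_token_rate), 3 * mc_se_bg)
})

test_that("link graph connects the seed to themed communities only", {
  w <- generate_world(small_world_config(seed = 5))
  edges <- w$graph$edges
  themed <- sprintf("c%03d", 1:3)
  expect_setequal(unique(c(edges$src, edges$dst)), themed)
  expect_true(all(edges$src == "c001" | edges$dst == "c001"))
})

test_that("tweet-area allocation conserves totals and geotags fall inside cells", {
  cfg <- small_world_config(seed = 9)
  w <- generate_world(cfg)
  expect_equal(sum(w$truth$area_assigned), cfg$n_tweets)
  geo <- !is.na(w$tweets$lat)
  assigned <- assign_area(w$tweets$lon[geo], w$tweets$lat[geo], w$areas)
  expect_false(anyNA(assigned))
  expect_identical(assigned, w$truth$tweet_area[geo])
})

test_that("planted hashtags are frequent and disjoint from the null set", {
  for (seed in 1:3) {
    w <- generate_world(world_config(seed = seed))
    occ <- table(unlist(w$tweets$hashtags))
    planted <- w$truth$planted_hashtags
    # Binomial(20000 * 1.5 draws, (0.1*0.6 + 0.9*0.02)/15) has mean ~156 per
    # planted hashtag; the < 5 tail is negligible, so every planted hashtag
    # must clear the 5-occurrence floor.
    expect_true(all(occ[planted] >= 5))
    expect_length(intersect(planted, grep("^tag", names(occ), value = TRUE)), 0)
  }
})

test_that("a written world round-trips losslessly through the readers", {
  w <- generate_world(small_world_config(seed = 21, n_tweets = 200))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  back <- read_world(dir)

  expect_equal(back$posts[order(back$posts$post_id), ],
               w$posts[order(w$posts$post_id), ], ignore_attr = TRUE)
  expect_identical(back$tweets$tweet_id, w$tweets$tweet_id)
  expect_identical(back$tweets$hashtags, w$tweets$hashtags)
  expect_equal(back$tweets$lat, w$tweets$lat, tolerance = 1e-12)
  expect_identical(sort(names(back$graph$communities)),
                   sort(names(w$graph$communities)))
  expect_equal(length(back$areas$features), length(w$areas$features))
  expect_identical(back$truth$planted_hashtags, w$truth$planted_hashtags)
  expect_equal(back$truth$area_latent_rate,
               w$truth$area_latent_rate, tolerance = 1e-12)
  expect_length(back$truth$planted_hashtags,
                w$config$n_planted_hashtags)

  # prevalence counts computed from disk equal the in-memory allocation
  geo <- !is.na(back$tweets$lat)
  prev <- compute_prevalence(back$tweets[geo, ], back$areas)
  in_mem <- table(factor(w$truth$tweet_area[geo],
                         levels = sort(unique(w$truth$tweet_area))))
  expect_equal(prev$tweet_count[match(names(in_mem), prev$area_id)],
               as.integer(in_mem))
})

test_that("areas.geojson is a valid FeatureCollection with n_areas features", {
  w <- generate_world(small_world_config(seed = 2, n_tweets = 50))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  gj <- jsonlite::read_json(file.path(dir, "areas.geojson"))
  expect_identical(gj$type, "FeatureCollection")
  expect_length(gj$features, 16)
  expect_identical(gj$features[[1]]$geometry$type, "Polygon")
})
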