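test_that("hashtag extraction case-folds, strips '#' and uses set semantics", {
  expect_identical(extract_hashtags("no tags here")[[1]], character(0))
  expect_identical(extract_hashtags("#ilovebeer")[[1]], "ilovebeer")
  expect_identical(extract_hashtags("Try #CraftBeer and #craftbeer! #beer#wine")[[1]],
                   c("beer", "craftbeer", "wine"))
})

test_that("tallies cross per-tweet presence with calls and conserve totals", {
  tw <- make_tweets(rep("x", 4),
                    hashtags = list("tag", "tag", character(0), character(0)))
  preds <- data.frame(item_id = tw$tweet_id,
                      call = c("positive", "negative", "positive", "negative"),
                      stringsAsFactors = FALSE)
  expect_identical(tally_hashtag(tw, preds, "tag"),
                   c(a = 1L, b = 1L, c = 1L, d = 1L))

  # a hashtag repeated within one tweet counts once
  tw2 <- make_tweets("#beer #beer cheers", lat = NULL)
  preds2 <- data.frame(item_id = tw2$tweet_id, call = "positive",
                       stringsAsFactors = FALSE)
  tab <- tally_hashtag(tw2, preds2, "beer")
  expect_identical(unname(tab["a"] + tab["b"]), 1L)

  # missing prediction coverage is an error
  expect_error(tally_hashtag(tw, preds[-1, ], "tag"), "exactly once")

  # conservation on a generated world: every table sums to the tweet count
  w <- generate_world(small_world_config(seed = 8, n_tweets = 400))
  stub <- function(x) ifelse(nchar(x) %% 2 == 0, 0.7, 0.2)
  preds_w <- predict_theme(stub, w$tweets$text, ids = w$tweets$tweet_id)
  for (h in w$truth$planted_hashtags[1:3]) {
    expect_equal(sum(tally_hashtag(w$tweets, preds_w, h)), 400)
  }
})

test_that("the one-sided chi-square matches hand-derived values", {
  r <- chi_square_one_sided(8, 2, 2, 8)
  expect_equal(r$statistic, 7.2)
  expect_equal(r$p_one_sided, 0.0036451790, tolerance = 1e-7)

  r0 <- chi_square_one_sided(5, 5, 5, 5)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_one_sided, 0.5)

  rdep <- chi_square_one_sided(2, 8, 8, 2)
  expect_equal(rdep$p_one_sided, 0.9963548210, tolerance = 1e-8)

  expect_error(chi_square_one_sided(0, 0, 3, 4), "degenerate")
})

test_that("chi-square agrees with the z^2 oracle and stats::chisq.test on random tables", {
  set.seed(123)
  checked <- 0
  while (checked < 1000) {
    tab <- matrix(rpois(4, lambda = sample(3:40, 1)) + 1, 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    got <- chi_square_one_sided(a, b, c, d)
    ora <- oracle_chisq_one_sided(a, b, c, d)
    expect_equal(got$statistic, ora$statistic, tolerance = 1e-9)
    expect_equal(got$p_one_sided, ora$p_one_sided, tolerance = 1e-9)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
    # two-sided consistency: 2 * min(p_one, 1 - p_one) = two-sided p
    expect_equal(2 * min(got$p_one_sided, 1 - got$p_one_sided),
                 ref$p.value, tolerance = 1e-9)
    checked <- checked + 1
  }
})

test_that("BH selection matches the brute-force step-up definition", {
  sel <- bh_select(c(0.01, 0.02, 0.03, 0.04, 0.2), q = 0.05)
  expect_identical(sel, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bh_select(rep(1, 10), q = 0.05)))
  expect_error(bh_select(0.1, q = 0), "\\(0, 1\\)")

  set.seed(99)
  for (rep in 1:1000) {
    m <- sample(1:40, 1)
    p <- round(runif(m)^sample(1:3, 1), sample(1:4, 1))  # induce ties
    q <- runif(1, 0.01, 0.3)
    expect_identical(bh_select(p, q), oracle_bh(p, q))
  }
})

test_that("BH selection is monotone in q and tie decisions are shared", {
  set.seed(5)
  for (rep in 1:50) {
    p <- sample(round(runif(8), 2), 20, replace = TRUE)
    s1 <- bh_select(p, 0.05)
    s2 <- bh_select(p, 0.2)
    expect_true(all(s2[s1]))           # enlarging q never shrinks the set
    for (v in unique(p)) {
      expect_length(unique(s1[p == v]), 1)  # ties: all-or-none
    }
  }
})

test_that("discovery composes stages, filters rare hashtags and sorts output", {
  # 40 tweets: 'hot' always on positive-called tweets, 'cold' on half of
  # each group (no association), 'rare' perfectly enriched but with only 4
  # occurrences so it must never be tested
  tags <- lapply(seq_len(40), function(i) {
    h <- if (i %% 2 == 0) "cold" else character(0)
    if (i <= 20) h <- c(h, "hot")
    if (i <= 4) h <- c(h, "rare")
    h
  })
  tw <- make_tweets(sprintf("txt%02d", 1:40), hashtags = tags)
  stub <- function(texts) {
    ifelse(as.integer(sub("txt", "", texts)) <= 20, 0.9, 0.1)
  }
  res <- suppressMessages(discover_hashtags(tw, stub, q = 0.05, min_count = 5))
  expect_setequal(res$hashtag, c("hot", "cold"))   # 'rare' excluded pre-test
  expect_true(res$significant[res$hashtag == "hot"])
  expect_false(res$significant[res$hashtag == "cold"])
  expect_identical(res$hashtag, res$hashtag[order(res$p_one_sided, res$hashtag)])

  # a constant-positive classifier degenerates every table: nothing tested
  expect_warning(
    res_deg <- suppressMessages(
      discover_hashtags(tw, function(x) rep(0.6, length(x)))
    ),
    "no testable"
  )
  expect_equal(nrow(res_deg), 0)
  expect_equal(attr(res_deg, "n_degenerate"), 3)
})

test_that("discovery results are invariant to tweet order", {
  w <- generate_world(small_world_config(seed = 31, n_tweets = 600))
  stub <- function(texts) ifelse(grepl("alc", texts), 0.8, 0.2)
  r1 <- discover_hashtags(w$tweets, stub)
  r2 <- discover_hashtags(w$tweets[rev(seq_len(600)), ], stub)
  expect_identical(r1$hashtag, r2$hashtag)
  expect_equal(r1$p_one_sided, r2$p_one_sided, tolerance = 1e-12)
  expect_identical(r1$significant, r2$significant)
})

test_that("tweets without hashtags are dropped with a logged count", {
  tw <- make_tweets(c("#beer good", "no tags", "also none"),
                    hashtags = list("beer", character(0), character(0)))
  stub <- function(texts) c(0.9, 0.1, 0.1)[seq_along(texts)]
  expect_message(
    expect_warning(discover_hashtags(tw, stub), "no testable"),
    "2 tweet"
  )
})

test_that("the curated hashtag fixture carries 24 hashtags in 4 categories", {
  tags <- alcohol_hashtags()
  expect_equal(nrow(tags), 24)
  expect_equal(as.vector(table(tags$category)[c("beer", "wine", "liquor", "ambiguous")]),
               c(14, 5, 3, 2))
  expect_true("ncbeer" %in% tags$hashtag)
  expect_false(any(grepl("^#", tags$hashtag)))
})
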