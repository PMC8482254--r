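test_that("seed expansion returns in/out neighbors above the post threshold", {
  g <- community_graph(
    communities = c(seedy = 5000, big_in = 2000, big_out = 3000, small = 10,
                    stranger = 9000),
    edges = data.frame(src = c("big_in", "seedy", "small"),
                       dst = c("seedy", "big_out", "seedy"))
  )
  expect_identical(expand_seed_communities(g, "seedy", min_posts = 1000),
                   c("big_in", "big_out", "seedy"))
  # the seed is retained even below the threshold; isolated seed stands alone
  iso <- community_graph(c(lonely = 3),
                         data.frame(src = character(0), dst = character(0)))
  expect_identical(expand_seed_communities(iso, "lonely"), "lonely")
  expect_error(expand_seed_communities(g, "nope"), "not in graph")
})

test_that("the curated community fixture expands to all 18 communities", {
  g <- example_community_graph()
  expanded <- expand_seed_communities(g, "drunk", min_posts = 1000)
  expect_length(expanded, 18)
  expect_setequal(expanded, alcohol_subreddits())
})

test_that("expansion matches a brute-force neighbor scan on random graphs", {
  set.seed(404)
  for (rep in 1:20) {
    ids <- sprintf("n%02d", 1:50)
    counts <- stats::setNames(sample(0:30, 50, replace = TRUE), ids)
    edges <- data.frame(src = sample(ids, 120, replace = TRUE),
                        dst = sample(ids, 120, replace = TRUE))
    g <- community_graph(counts, edges)
    seed_id <- sample(ids, 1)
    got <- expand_seed_communities(g, seed_id, min_posts = 10)
    # exhaustive scan over every edge
    nb <- character(0)
    for (i in seq_len(nrow(edges))) {
      if (edges$src[i] == seed_id) nb <- c(nb, edges$dst[i])
      if (edges$dst[i] == seed_id) nb <- c(nb, edges$src[i])
    }
    want <- sort(unique(c(seed_id, nb[counts[nb] >= 10])))
    expect_identical(got, want)
  }
})

test_that("labeled corpora are balanced, deterministic and order-invariant", {
  posts <- data.frame(
    post_id = sprintf("p%04d", 1:2050),
    community = c(rep(sprintf("pos%d", 1:5), each = 10), rep("bg", 2000)),
    title = paste("title", 1:2050),
    stringsAsFactors = FALSE
  )
  corp <- build_labeled_corpus(posts, sprintf("pos%d", 1:5), seed = 3)
  expect_equal(sum(corp$label == "positive"), 50)
  expect_equal(sum(corp$label == "negative"), 50)
  expect_false(any(duplicated(corp$post_id)))

  corp2 <- build_labeled_corpus(posts, sprintf("pos%d", 1:5), seed = 3)
  expect_identical(corp, corp2)
  # permuting input rows does not change the sampled corpus
  corp3 <- build_labeled_corpus(posts[sample(nrow(posts)), ],
                                sprintf("pos%d", 1:5), seed = 3)
  expect_identical(corp, corp3)
  # a different seed draws a different negative sample
  corp4 <- build_labeled_corpus(posts, sprintf("pos%d", 1:5), seed = 4)
  expect_false(identical(sort(corp$post_id), sort(corp4$post_id)))
})

test_that("an insufficient negative pool raises an imbalance error", {
  posts <- data.frame(
    post_id = sprintf("p%02d", 1:15),
    community = c(rep("pos", 10), rep("bg", 5)),
    title = paste("t", 1:15), stringsAsFactors = FALSE
  )
  expect_error(build_labeled_corpus(posts, "pos"), "negative pool too small")
})

test_that("split allocation uses floor with the remainder going to test", {
  ex <- function(n) data.frame(post_id = sprintf("p%07d", seq_len(n)),
                               text = "x", stringsAsFactors = FALSE)
  sizes <- function(s) vapply(s[c("train", "validation", "test")], nrow, 0L)

  # the canonical corpus size: 651,271 examples at 0.8/0.1/0.1
  s <- split_corpus(ex(651271), seed = 1)
  expect_identical(unname(sizes(s)), c(521016L, 65127L, 65128L))

  expect_identical(unname(sizes(split_corpus(ex(10), seed = 1))),
                   c(8L, 1L, 1L))
  # floor(5.6) = 5, floor(0.7) = 0, remainder 2
  expect_identical(unname(sizes(split_corpus(ex(7), seed = 1))),
                   c(5L, 0L, 2L))
})

test_that("splits conserve and partition the input for random sizes", {
  set.seed(77)
  for (n in c(0, 1, 2, 3, sample(4:500, 12))) {
    ex <- data.frame(post_id = sprintf("p%05d", seq_len(n)),
                     text = rep("x", n), stringsAsFactors = FALSE)
    s <- split_corpus(ex, seed = 5)
    all_ids <- c(s$train$post_id, s$validation$post_id, s$test$post_id)
    expect_length(all_ids, n)
    expect_setequal(all_ids, ex$post_id)
    expect_false(any(duplicated(all_ids)))
  }
})

test_that("split contents are invariant to input row order under a fixed seed", {
  ex <- data.frame(post_id = sprintf("p%03d", 1:37), text = letters[1:37 %% 26 + 1],
                   stringsAsFactors = FALSE)
  s1 <- split_corpus(ex, seed = 9)
  s2 <- split_corpus(ex[rev(seq_len(37)), ], seed = 9)
  expect_identical(s1$train$post_id, s2$train$post_id)
  expect_identical(s1$test$post_id, s2$test$post_id)
})

test_that("invalid fractions are rejected", {
  ex <- data.frame(post_id = "p1", text = "x", stringsAsFactors = FALSE)
  expect_error(split_corpus(ex, fractions = c(0.8, 0.1)), "3 non-negative")
  expect_error(split_corpus(ex, fractions = c(0.9, -0.1, 0.2)), "non-negative")
  expect_error(split_corpus(ex, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})
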