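# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles deliberately share no code with the package paths they
# check.

# One-sided enrichment p via the two-proportion z statistic and the normal
# tail (the squared z equals the Pearson chi-square on a 2x2 table).
oracle_chisq_one_sided <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d
  p1 <- a / n1; p2 <- c / n2
  pbar <- (a + c) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  list(statistic = z^2, p_one_sided = stats::pnorm(z, lower.tail = FALSE))
}

# Literal step-up definition of Benjamini-Hochberg selection.
oracle_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ok <- which(p[ord] <= seq_len(m) * q / m)
  sel <- rep(FALSE, m)
  if (length(ok) > 0) sel[ord[seq_len(max(ok))]] <- TRUE
  sel
}

# Rank-and-correlate Spearman with the t-approximation, written from the
# definition (average ranks, Pearson on ranks, t on n - 2 df).
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  tt <- r * sqrt((length(x) - 2) / (1 - r^2))
  list(rho = r, p = 2 * stats::pt(-abs(tt), length(x) - 2))
}

# A small world configuration that keeps unit tests fast while preserving the
# default rates.
small_world_config <- function(seed = 1L, ...) {
  args <- list(
    n_communities = 8, n_alcohol_communities = 3, posts_per_community = 60,
    vocab_background_size = 120, vocab_theme_size = 25,
    n_tweets = 1500, n_areas = 16, seed = seed
  )
  args <- utils::modifyList(args, list(...))
  do.call(world_config, args)
}

# Hand-built tweet table with explicit hashtag sets and coordinates.
make_tweets <- function(texts, hashtags = NULL, lat = NULL, lon = NULL,
                        year = 2015L) {
  n <- length(texts)
  out <- data.frame(
    tweet_id = sprintf("tw%03d", seq_len(n)),
    text = texts,
    lat = if (is.null(lat)) rep(NA_real_, n) else lat,
    lon = if (is.null(lon)) rep(NA_real_, n) else lon,
    year = rep(as.integer(year), length.out = n),
    stringsAsFactors = FALSE
  )
  if (!is.null(hashtags)) out$hashtags <- hashtags
  out
}

# Single unit-square test area with configurable populations and outcomes.
make_square_area <- function(area_id = "a001", x0 = 0, y0 = 0,
                             population = c(`2017` = 9000, `2018` = 11000),
                             confounders = NULL, outcomes = c(score = 1)) {
  if (is.null(confounders)) {
    confounders <- stats::setNames(rep(0, 7), confounder_names())
  }
  list(
    area_id = area_id, level = "county",
    rings = list(cbind(lon = c(x0, x0 + 1, x0 + 1, x0, x0),
                       lat = c(y0, y0, y0 + 1, y0 + 1, y0))),
    population_by_year = population,
    confounders = confounders,
    outcomes = outcomes
  )
}

make_areas <- function(features) {
  structure(list(level = "county", features = features), class = "geo_areas")
}
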