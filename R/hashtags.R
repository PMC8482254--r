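# Hashtag enrichment testing: per-hashtag 2x2 contingency tables of hashtag
# presence against classifier call, a one-sided ("greater") Pearson chi-square
# test for enrichment among positive calls, and Benjamini-Hochberg selection
# at a fixed false discovery rate after a minimum-occurrence filter.

#' Extract hashtags from text
#'
#' A hashtag is the maximal run of word characters following a `#`. Results
#' are case-folded and `#`-stripped; a tweet contributes each hashtag at most
#' once (set semantics).
#'
#' @param texts Character vector.
#' @return A list of character vectors (sorted unique hashtags per text).
#' @export
#' @examples
#' extract_hashtags("Try #CraftBeer and #craftbeer! #beer#wine")[[1]]
#' # "beer" "craftbeer" "wine"
extract_hashtags <- function(texts) {
  matches <- regmatches(texts, gregexpr("#\\w+", texts, perl = TRUE))
  lapply(matches, function(m) sort(unique(tolower(sub("^#", "", m)))))
}

#' Tally one hashtag against classifier calls
#'
#' Builds the 2x2 table crossing per-tweet hashtag presence with the
#' positive/negative call: `a` = present & positive, `b` = present & negative,
#' `c` = absent & positive, `d` = absent & negative. Every tweet must be
#' covered by exactly one prediction.
#'
#' @param tweets data.frame with `tweet_id` and a `hashtags` list-column (or
#'   `text`, from which hashtags are extracted).
#' @param predictions data.frame from [predict_theme()] with `item_id` and
#'   `call`.
#' @param hashtag Hashtag string (lowercase, no `#`).
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
tally_hashtag <- function(tweets, predictions, hashtag) {
  sets <- tweet_hashtag_sets(tweets)
  calls <- match_calls(tweets$tweet_id, predictions)
  present <- vapply(sets, function(h) hashtag %in% h, logical(1))
  pos <- calls == "positive"
  c(a = sum(present & pos), b = sum(present & !pos),
    c = sum(!present & pos), d = sum(!present & !pos))
}

tweet_hashtag_sets <- function(tweets) {
  if (!is.null(tweets$hashtags)) {
    lapply(tweets$hashtags, function(h) unique(tolower(as.character(h))))
  } else {
    extract_hashtags(tweets$text)
  }
}

match_calls <- function(tweet_ids, predictions) {
  idx <- match(tweet_ids, predictions$item_id)
  if (anyNA(idx) || anyDuplicated(predictions$item_id) > 0) {
    stop("predictions must cover every tweet id exactly once", call. = FALSE)
  }
  predictions$call[idx]
}

#' One-sided chi-square test of enrichment on a 2x2 table
#'
#' Pearson chi-square without continuity correction (optionally with the Yates
#' correction); the one-sided "greater" p-value is half the two-sided
#' chi-square p when the observed direction is enrichment
#' (`a/(a+b) > c/(c+d)`) and `1 - p_two/2` otherwise — valid because the 2x2
#' chi-square has one degree of freedom. A zero statistic gives p = 0.5.
#'
#' @param a,b,c,d Cell counts (vectorized): rows are hashtag present/absent,
#'   columns are call positive/negative.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List with numeric vectors `statistic` and `p_one_sided`.
#' @export
chi_square_one_sided <- function(a, b, c, d, correct = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0)) {
    stop("degenerate 2x2 table: a zero marginal leaves the test undefined",
         call. = FALSE)
  }
  dev <- abs(a * d - b * c)
  if (correct) dev <- pmax(0, dev - n / 2)
  statistic <- n * dev^2 / (r1 * r2 * c1 * c2)
  p_two <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  enriched <- a / r1 > c / r2
  p_one <- ifelse(enriched, p_two / 2, 1 - p_two / 2)
  list(statistic = statistic, p_one_sided = p_one)
}

#' Benjamini-Hochberg selection
#'
#' Step-up selection at false discovery rate `q`: with p-values sorted
#' ascending, reject hypotheses 1..k where k is the largest index i with
#' p(i) <= i q / m. Tied p-values share a decision through the max rule.
#'
#' @param p Numeric vector of p-values.
#' @param q False discovery rate in (0, 1).
#' @return Logical vector (in input order): selected or not.
#' @export
bh_select <- function(p, q = 0.05) {
  if (q <= 0 || q >= 1) stop("`q` must lie in (0, 1)", call. = FALSE)
  if (length(p) == 0) return(logical(0))
  stats::p.adjust(p, method = "BH") <= q
}

#' Discover enriched hashtags
#'
#' Composes classifier prediction, per-hashtag 2x2 tallies, the one-sided
#' chi-square test and BH selection. Tweets without hashtags are dropped
#' (their count is recorded in the `n_dropped_no_hashtag` attribute).
#' Hashtags occurring in fewer than `min_count` tweets are excluded before
#' testing and do not enter the BH family; hashtags whose table has a zero
#' marginal (e.g. when every tweet is called positive) are degenerate and
#' likewise excluded (`n_degenerate` attribute).
#'
#' @param tweets data.frame with `tweet_id`, `text` and optionally a
#'   `hashtags` list-column.
#' @param model A `theme_classifier` or adapter function.
#' @param q False discovery rate (default 0.05).
#' @param min_count Minimum per-tweet occurrence count (default 5).
#' @param threshold Classifier decision threshold (default 0.5, inclusive).
#' @param correct Yates continuity correction flag (default `FALSE`).
#' @return data.frame sorted by p then hashtag, with columns `hashtag`, `a`,
#'   `b`, `c`, `d`, `occurrences`, `statistic`, `p_one_sided`, `p_adjusted`
#'   and `significant`.
#' @export
discover_hashtags <- function(tweets, model, q = 0.05, min_count = 5,
                              threshold = 0.5, correct = FALSE) {
  sets <- tweet_hashtag_sets(tweets)
  has_tag <- lengths(sets) > 0
  n_dropped <- sum(!has_tag)
  if (n_dropped > 0) {
    message(n_dropped, " tweet(s) without hashtags dropped before testing")
  }
  tweets <- tweets[has_tag, , drop = FALSE]
  sets <- sets[has_tag]

  preds <- predict_theme(model, tweets$text, ids = tweets$tweet_id,
                         threshold = threshold)
  pos <- preds$call == "positive"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)

  tag <- unlist(sets, use.names = FALSE)
  tweet_pos <- rep.int(pos, lengths(sets))
  all_tags <- sort(unique(tag))
  occ <- as.integer(table(factor(tag, levels = all_tags)))
  a <- as.integer(table(factor(tag[tweet_pos], levels = all_tags)))
  b <- occ - a
  cc <- n_pos - a
  d <- n_neg - b

  degenerate <- occ == nrow(tweets) | n_pos == 0 | n_neg == 0
  testable <- !degenerate & occ >= min_count
  n_deg <- sum(degenerate)

  if (!any(testable)) {
    warning("no testable hashtags after occurrence and degeneracy filters")
    out <- data.frame(
      hashtag = character(0), a = integer(0), b = integer(0), c = integer(0),
      d = integer(0), occurrences = integer(0), statistic = numeric(0),
      p_one_sided = numeric(0), p_adjusted = numeric(0),
      significant = logical(0), stringsAsFactors = FALSE
    )
    attr(out, "n_dropped_no_hashtag") <- n_dropped
    attr(out, "n_degenerate") <- n_deg
    return(out)
  }

  ts <- chi_square_one_sided(a[testable], b[testable], cc[testable],
                             d[testable], correct = correct)
  p_adj <- stats::p.adjust(ts$p_one_sided, method = "BH")
  selected <- bh_select(ts$p_one_sided, q)

  out <- data.frame(
    hashtag = all_tags[testable],
    a = a[testable], b = b[testable], c = cc[testable], d = d[testable],
    occurrences = occ[testable],
    statistic = ts$statistic,
    p_one_sided = ts$p_one_sided,
    p_adjusted = p_adj,
    significant = selected,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_one_sided, out$hashtag), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_no_hashtag") <- n_dropped
  attr(out, "n_degenerate") <- n_deg
  out
}

#' Significant hashtags from a discovery result
#'
#' @param results Output of [discover_hashtags()].
#' @return Character vector of selected hashtags.
#' @export
significant_hashtags <- function(results) {
  results$hashtag[results$significant]
}

#' Curated alcohol hashtag list by beverage category
#'
#' The canonical 24-hashtag set (14 beer, 5 wine, 3 liquor, 2 ambiguous) used
#' for beverage-category stratification. Some published summaries of this
#' list cite a different beer count (19); the itemized 14-entry list is
#' authoritative here, and the file metadata records the conflict.
#'
#' @return data.frame with columns `hashtag` and `category`
#'   (`beer`/`wine`/`liquor`/`ambiguous`).
#' @export
alcohol_hashtags <- function() {
  path <- system.file("extdata", "curated_hashtags.json", package = "themetag")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  data.frame(hashtag = j$hashtags$hashtag, category = j$hashtags$category,
             stringsAsFactors = FALSE)
}
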