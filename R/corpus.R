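# Weak-labeled corpus construction from a seed themed community:
# one-hop link expansion, balanced negative sampling, deterministic
# train/validation/test split.

#' Community link graph
#'
#' @param communities Named integer vector: community id -> post count.
#' @param edges data.frame with character columns `src`, `dst`; an edge
#'   src -> dst means src's description page links to dst.
#' @return A list of class `community_graph`.
#' @export
community_graph <- function(communities, edges) {
  stopifnot(is.numeric(communities), !is.null(names(communities)))
  if (any(communities < 0)) stop("post counts must be >= 0", call. = FALSE)
  edges <- data.frame(src = as.character(edges$src),
                      dst = as.character(edges$dst),
                      stringsAsFactors = FALSE)
  unknown <- setdiff(unique(c(edges$src, edges$dst)), names(communities))
  if (length(unknown) > 0) {
    stop("edge endpoints missing from community table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(communities = communities, edges = edges),
            class = "community_graph")
}

#' Expand a seed community through description links
#'
#' Returns the seed together with every community that links to it or that it
#' links to, restricted to communities with at least `min_posts` posts (the
#' seed is always retained). This is the one-hop weak-label expansion used to
#' assemble the positive-class community set.
#'
#' @param graph A [community_graph()].
#' @param seed Seed community id.
#' @param min_posts Minimum post count for expanded communities (default 1000).
#' @return Sorted character vector of community ids.
#' @export
expand_seed_communities <- function(graph, seed, min_posts = 1000) {
  stopifnot(inherits(graph, "community_graph"))
  if (!seed %in% names(graph$communities)) {
    stop("seed community not in graph: ", seed, call. = FALSE)
  }
  inbound <- graph$edges$src[graph$edges$dst == seed]
  outbound <- graph$edges$dst[graph$edges$src == seed]
  neigh <- unique(c(inbound, outbound))
  neigh <- neigh[graph$communities[neigh] >= min_posts]
  sort(unique(c(seed, neigh)))
}

#' Build a balanced weak-labeled corpus
#'
#' All titles from the positive communities are labeled positive (count P);
#' exactly P titles are then sampled uniformly without replacement from all
#' other communities and labeled negative. The output order is a deterministic
#' shuffle under `seed`. Posts are sorted by id before sampling, so permuting
#' the input row order does not change the result.
#'
#' @param posts data.frame with columns `post_id`, `community`, `title`.
#' @param positive_communities Character vector of positive community ids.
#' @param seed Integer seed for negative sampling and shuffling.
#' @return data.frame with columns `post_id`, `text`, `label`
#'   (`"positive"`/`"negative"`) and `origin` (community id).
#' @export
build_labeled_corpus <- function(posts, positive_communities, seed = 1L) {
  posts <- posts[order(posts$post_id), , drop = FALSE]
  posts <- posts[nzchar(trimws(posts$title)), , drop = FALSE]
  is_pos <- posts$community %in% positive_communities
  n_pos <- sum(is_pos)
  if (n_pos == 0) stop("no posts in positive communities", call. = FALSE)
  pool <- which(!is_pos)
  if (length(pool) < n_pos) {
    stop("negative pool too small for a balanced corpus: need ", n_pos,
         " negatives but only ", length(pool), " posts are available",
         call. = FALSE)
  }
  with_stream(seed, "corpus", {
    neg_idx <- sort(sample(pool, n_pos, replace = FALSE))
    out <- rbind(
      data.frame(post_id = posts$post_id[is_pos],
                 text = posts$title[is_pos],
                 label = "positive",
                 origin = posts$community[is_pos],
                 stringsAsFactors = FALSE),
      data.frame(post_id = posts$post_id[neg_idx],
                 text = posts$title[neg_idx],
                 label = "negative",
                 origin = posts$community[neg_idx],
                 stringsAsFactors = FALSE)
    )
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Split a corpus into train/validation/test partitions
#'
#' A deterministic shuffle under `seed` followed by floor allocation:
#' |train| = floor(f1 n), |validation| = floor(f2 n), and the remainder goes
#' to test. Examples are sorted by `post_id` before shuffling so the split
#' contents are invariant to input row order.
#'
#' @param examples data.frame of labeled examples (must carry `post_id`).
#' @param fractions Numeric length-3 vector summing to 1 (default
#'   `c(0.8, 0.1, 0.1)`).
#' @param seed Integer seed.
#' @return List of class `split_corpus` with elements `train`, `validation`,
#'   `test` and `fractions`.
#' @export
split_corpus <- function(examples, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3 || any(fractions < 0)) {
    stop("`fractions` must be 3 non-negative numbers", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must sum to 1", call. = FALSE)
  }
  examples <- examples[order(examples$post_id), , drop = FALSE]
  n <- nrow(examples)
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  with_stream(seed, "split", {
    perm <- sample.int(n)
    shuffled <- examples[perm, , drop = FALSE]
    rownames(shuffled) <- NULL
    structure(
      list(
        train = shuffled[seq_len(n_train), , drop = FALSE],
        validation = shuffled[seq_len(n_val) + n_train, , drop = FALSE],
        test = if (n > n_train + n_val) {
          shuffled[(n_train + n_val + 1):n, , drop = FALSE]
        } else {
          shuffled[0, , drop = FALSE]
        },
        fractions = fractions
      ),
      class = "split_corpus"
    )
  })
}

#' Curated alcohol-related community list
#'
#' The 18 alcohol-related subreddits (a seed community, r/drunk, plus 17
#' communities reachable by one description-page link) used as the canonical
#' positive-label community set.
#'
#' @return Character vector of 18 community names (without the `r/` prefix).
#' @export
alcohol_subreddits <- function() {
  path <- system.file("extdata", "curated_subreddits.txt", package = "themetag")
  readLines(path, warn = FALSE)
}

#' Synthetic link graph reproducing the curated community expansion
#'
#' Builds a `community_graph` over the curated 18-community list plus
#' unrelated filler communities: every curated community other than the seed
#' is linked with `drunk` (directions alternate), all with post counts >= the
#' default 1000 threshold. This is a synthetic stand-in for a scraped
#' description-link graph; expanding the seed `"drunk"` recovers exactly the
#' curated list.
#'
#' @param filler Number of unlinked background communities to add (default 5).
#' @return A `community_graph`.
#' @export
example_community_graph <- function(filler = 5) {
  curated <- alcohol_subreddits()
  others <- setdiff(curated, "drunk")
  ids <- c(curated, sprintf("filler%02d", seq_len(filler)))
  counts <- stats::setNames(rep(2000L, length(ids)), ids)
  out_edge <- seq_along(others) %% 2 == 0
  edges <- data.frame(
    src = ifelse(out_edge, "drunk", others),
    dst = ifelse(out_edge, others, "drunk"),
    stringsAsFactors = FALSE
  )
  community_graph(counts, edges)
}
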