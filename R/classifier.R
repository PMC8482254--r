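# Pluggable binary theme classifier.
#
# The default model is a regularized log-linear (ridge logistic) classifier on
# token counts, fit with glmnet. Downstream stages consume only the
# prediction contract -- a probability in [0, 1] per text and a binary call at
# a >= 0.5 threshold -- so any external model (e.g. a fine-tuned transformer)
# can be plugged in as a plain function from texts to probabilities.

#' Tokenize text
#'
#' Lowercases and splits on characters outside `[a-z0-9#']`; tokens beginning
#' with `#` are kept intact as hashtag tokens. Empty results are allowed.
#'
#' @param texts Character vector.
#' @return A list of character vectors, one per input text.
#' @export
#' @examples
#' tokenize("Showerbeer time!")[[1]]   # "showerbeer" "time"
#' tokenize("#ilovebeer")[[1]]         # "#ilovebeer"
tokenize <- function(texts) {
  parts <- strsplit(tolower(texts), "[^a-z0-9#']+")
  lapply(parts, function(x) x[nzchar(x)])
}

# Sparse document-term count matrix over a fixed vocabulary.
# Out-of-vocabulary tokens are dropped.
doc_term_matrix <- function(token_lists, vocabulary) {
  lens <- lengths(token_lists)
  tokens <- unlist(token_lists, use.names = FALSE)
  doc <- rep.int(seq_along(token_lists), lens)
  col <- match(tokens, vocabulary)
  keep <- !is.na(col)
  Matrix::sparseMatrix(
    i = doc[keep], j = col[keep], x = 1,
    dims = c(length(token_lists), length(vocabulary)),
    dimnames = list(NULL, vocabulary)
  )
}

#' Train the default theme classifier
#'
#' Fits an L2-regularized logistic regression on token counts. The fit is
#' deterministic given (data, config): glmnet's coordinate descent involves no
#' randomness at a fixed lambda.
#'
#' @param examples data.frame with columns `text` and `label`
#'   (`"positive"`/`"negative"`); both labels must be present.
#' @param l2 L2 regularization strength (default 1; glmnet lambda is `l2/n`).
#' @param threshold Decision threshold on the predicted probability; calls are
#'   positive when probability >= threshold (default 0.5, inclusive).
#' @param seed Integer recorded in the model config (the default fit is
#'   deterministic; the seed matters only for adapters that need one).
#' @return An object of class `theme_classifier` with fields `vocabulary`,
#'   `weights` (named per-token coefficients), `intercept` and `config`.
#' @export
train_classifier <- function(examples, l2 = 1, threshold = 0.5, seed = 1L) {
  labels <- examples$label
  if (length(unique(labels)) < 2) {
    stop("training data must contain both positive and negative examples",
         call. = FALSE)
  }
  toks <- tokenize(examples$text)
  vocabulary <- sort(unique(unlist(toks, use.names = FALSE)))
  if (length(vocabulary) == 0) {
    stop("training data contains no tokens", call. = FALSE)
  }
  x <- doc_term_matrix(toks, vocabulary)
  padded <- FALSE
  if (ncol(x) < 2) {            # glmnet needs >= 2 columns
    x <- cbind(x, Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                       x = numeric(0), dims = c(nrow(x), 1)))
    padded <- TRUE
  }
  y <- as.numeric(labels == "positive")
  fit <- glmnet::glmnet(
    x, y, family = "binomial", alpha = 0,
    lambda = l2 / nrow(x), standardize = FALSE,
    thresh = 1e-10, maxit = 1e6
  )
  beta <- as.numeric(fit$beta[, 1])
  if (padded) beta <- beta[-length(beta)]
  structure(
    list(
      vocabulary = vocabulary,
      weights = stats::setNames(beta, vocabulary),
      intercept = as.numeric(fit$a0[1]),
      config = list(l2 = l2, threshold = threshold, seed = as.integer(seed))
    ),
    class = "theme_classifier"
  )
}

#' Predicted theme probabilities
#'
#' For the default model, the probability is the logistic link applied to the
#' intercept plus token-count-weighted coefficients; an empty text yields the
#' intercept-only probability. A plain function `texts -> probabilities` is
#' accepted as an external-classifier adapter; its output is validated to lie
#' in `[0, 1]` at the call site.
#'
#' @param model A `theme_classifier` or a function from a character vector to
#'   a numeric vector of probabilities.
#' @param texts Character vector.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
classifier_probabilities <- function(model, texts) {
  if (is.function(model)) {
    p <- as.numeric(model(texts))
    if (length(p) != length(texts)) {
      stop("external classifier returned ", length(p), " probabilities for ",
           length(texts), " texts", call. = FALSE)
    }
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
      stop("external classifier violated the prediction contract: ",
           "probabilities must lie in [0, 1]", call. = FALSE)
    }
    return(p)
  }
  stopifnot(inherits(model, "theme_classifier"))
  x <- doc_term_matrix(tokenize(texts), model$vocabulary)
  score <- as.numeric(x %*% model$weights) + model$intercept
  stats::plogis(score)
}

#' Prediction records for a batch of texts
#'
#' @param model A `theme_classifier` or adapter function (see
#'   [classifier_probabilities()]).
#' @param texts Character vector.
#' @param ids Item identifiers (default positional).
#' @param threshold Decision threshold; the call is positive when
#'   probability >= threshold. Defaults to the model's configured threshold,
#'   or 0.5 for adapters.
#' @return data.frame with columns `item_id`, `probability`, `call`.
#' @export
predict_theme <- function(model, texts, ids = as.character(seq_along(texts)),
                          threshold = NULL) {
  if (is.null(threshold)) {
    threshold <- if (inherits(model, "theme_classifier")) {
      model$config$threshold
    } else {
      0.5
    }
  }
  p <- classifier_probabilities(model, texts)
  data.frame(
    item_id = ids,
    probability = p,
    call = ifelse(p >= threshold, "positive", "negative"),
    stringsAsFactors = FALSE
  )
}

#' Serialize / load the default classifier
#'
#' The model round-trips through a single JSON file holding the vocabulary,
#' weights, intercept and training config.
#'
#' @param model A `theme_classifier`.
#' @param path Output / input JSON path.
#' @return `write_classifier` returns `path` invisibly; `read_classifier`
#'   returns a `theme_classifier`.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "theme_classifier"))
  jsonlite::write_json(
    list(
      vocabulary = model$vocabulary,
      weights = as.numeric(model$weights),
      intercept = model$intercept,
      config = model$config
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      vocabulary = as.character(m$vocabulary),
      weights = stats::setNames(as.numeric(m$weights), m$vocabulary),
      intercept = as.numeric(m$intercept),
      config = as.list(m$config)
    ),
    class = "theme_classifier"
  )
}

#' @export
print.theme_classifier <- function(x, ...) {
  cat("<theme_classifier> ridge logistic, ", length(x$vocabulary),
      " tokens, threshold ", x$config$threshold, "\n", sep = "")
  invisible(x)
}
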