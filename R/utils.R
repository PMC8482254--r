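# Internal helpers: seed-stream derivation, JSONL input/output, validation.

#' Derive a reproducible sub-stream seed
#'
#' A single global seed fans out to independent per-stage streams by stable
#' string hashing, so that (for example) adding tweets to a world does not
#' perturb its geography. The hash is integer arithmetic only (exact in
#' doubles), identical across platforms.
#'
#' @param seed Integer global seed.
#' @param stream Character stream name (e.g. `"tweets"`, `"geography"`).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @keywords internal
stream_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1, is.finite(seed), length(stream) == 1)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded from (seed, stream),
# restoring the caller's .Random.seed afterwards.
with_stream <- function(seed, stream, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  expr
}

# Write a list of records (each a named list) as one JSON object per line.
write_jsonl <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- vapply(
    records,
    function(r) as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null")),
    character(1)
  )
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Read a JSONL file into a list of records.
read_jsonl <- function(path) {
  if (!file.exists(path)) stop("JSONL file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}

# Validate that a scalar lies in [0, 1]; used for all rate parameters.
check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop("`", name, "` must be a single probability in [0, 1], got: ",
         deparse(substitute(x)), " = ", format(x), call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop("`", name, "` must be an integer count >= ", min, ", got ", format(x),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Deterministic paste of token vectors into documents given group lengths.
paste_docs <- function(tokens, lengths) {
  ids <- rep.int(seq_along(lengths), lengths)
  out <- character(length(lengths))
  nonempty <- lengths > 0
  if (any(nonempty)) {
    parts <- split(tokens, factor(ids, levels = seq_along(lengths)))
    out <- vapply(parts, paste, character(1), collapse = " ")
  }
  unname(out)
}
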