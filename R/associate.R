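# Area-level association analysis: crude Spearman correlation and
# confounder-adjusted ordinary least squares of each outcome on per-capita
# hashtag prevalence, producing one report row per outcome (and optionally
# per hashtag category).

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average-ranked values (ties share the mean rank);
#' two-sided p via the t-approximation on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, no missing values.
#' @return List with `rho` and `p`.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed; drop ",
                                 "incomplete pairs first", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: a constant vector has undefined rank correlation",
         call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Confounder-adjusted linear regression
#'
#' Ordinary least squares of `outcome` on `[prevalence, confounders,
#' intercept]`. Returns the prevalence coefficient, its two-sided t-test
#' p-value, standard error, 95% confidence interval and design diagnostics
#' (condition number and a flag at kappa > 1e8).
#'
#' @param prevalence Numeric vector (per-capita prevalence).
#' @param outcome Numeric outcome vector.
#' @param confounders Numeric matrix or data.frame of confounder columns.
#' @return List with `beta`, `beta_p`, `se`, `ci` (length 2), `n` and
#'   `diagnostics`.
#' @export
adjusted_regression <- function(prevalence, outcome, confounders) {
  confounders <- as.matrix(confounders)
  n <- length(outcome)
  stopifnot(length(prevalence) == n, nrow(confounders) == n)
  p_pred <- 1 + ncol(confounders)
  if (n <= p_pred + 1) {
    stop("too few areas (", n, ") for ", p_pred, " predictors", call. = FALSE)
  }
  design <- cbind(`(Intercept)` = 1, prevalence = prevalence, confounders)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(outcome = outcome, prevalence = prevalence, confounders)
  fit <- stats::lm(outcome ~ ., data = df)
  sm <- summary(fit)$coefficients
  est <- sm["prevalence", "Estimate"]
  se <- sm["prevalence", "Std. Error"]
  dof <- fit$df.residual
  tcrit <- stats::qt(0.975, dof)
  list(
    beta = unname(est),
    beta_p = unname(sm["prevalence", "Pr(>|t|)"]),
    se = unname(se),
    ci = c(est - tcrit * se, est + tcrit * se),
    n = n,
    diagnostics = list(
      kappa = kappa(design, exact = TRUE),
      ill_conditioned = kappa(design, exact = TRUE) > 1e8
    )
  )
}

#' Run the association suite
#'
#' For each hashtag category (a named list of hashtag sets; use a single
#' `all` entry for the unstratified analysis) and each outcome: restrict
#' tweets to the category's hashtags, recompute per-area prevalence, apply
#' the inclusion filters, drop areas missing the outcome, and report the
#' crude Spearman correlation and the confounder-adjusted regression
#' coefficient. Outcomes absent from every area are skipped with a warning.
#'
#' @param tweets Tweet data.frame (hashtag-filtered tweets are derived per
#'   category).
#' @param areas A `geo_areas` object carrying confounders and outcomes.
#' @param hashtag_sets Named list: category -> character vector of hashtags.
#' @param outcomes Character vector of outcome names (default: every outcome
#'   present in `areas`).
#' @param years Year range for population means.
#' @param scale Per-capita normalization constant (default 10,000).
#' @param min_tweets,min_population Inclusion filters (defaults 1 and 1000).
#' @return data.frame with columns `outcome`, `level`, `category`, `n`,
#'   `spearman_rho`, `spearman_p`, `beta`, `beta_p`.
#' @export
run_association_suite <- function(tweets, areas, hashtag_sets,
                                  outcomes = NULL, years = NULL, scale = 1e4,
                                  min_tweets = 1, min_population = 1000) {
  stopifnot(inherits(areas, "geo_areas"), is.list(hashtag_sets),
            !is.null(names(hashtag_sets)))
  at <- area_table(areas, years = years)
  available <- setdiff(colnames(at), c("area_id", "mean_population",
                                       confounder_names()))
  if (is.null(outcomes)) outcomes <- available
  missing_out <- setdiff(outcomes, available)
  if (length(missing_out) > 0) {
    warning("outcome(s) absent from all areas, skipped: ",
            paste(missing_out, collapse = ", "))
    outcomes <- intersect(outcomes, available)
  }
  rows <- list()
  for (cat_name in names(hashtag_sets)) {
    sub <- filter_alcohol_tweets(tweets, hashtag_sets[[cat_name]])
    prev <- compute_prevalence(sub[sub$geotagged, , drop = FALSE], areas,
                               years = years, scale = scale)
    prev <- apply_inclusion_filters(prev, min_tweets = min_tweets,
                                    min_population = min_population)
    merged <- merge(prev, at, by = "area_id")
    for (out_name in outcomes) {
      ok <- !is.na(merged[[out_name]])
      m <- merged[ok, , drop = FALSE]
      row <- data.frame(
        outcome = out_name, level = areas$level, category = cat_name,
        n = nrow(m), spearman_rho = NA_real_, spearman_p = NA_real_,
        beta = NA_real_, beta_p = NA_real_, stringsAsFactors = FALSE
      )
      res <- tryCatch({
        sp <- spearman_assoc(m$per_10k, m[[out_name]])
        reg <- adjusted_regression(m$per_10k, m[[out_name]],
                                   as.matrix(m[, confounder_names()]))
        list(sp = sp, reg = reg)
      }, error = function(e) {
        warning("association for outcome '", out_name, "' (category '",
                cat_name, "') failed: ", conditionMessage(e))
        NULL
      })
      if (!is.null(res)) {
        row$spearman_rho <- res$sp$rho
        row$spearman_p <- res$sp$p
        row$beta <- res$reg$beta
        row$beta_p <- res$reg$beta_p
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
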