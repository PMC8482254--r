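# Geotagged-post prevalence: point-in-polygon area assignment (boundary
# points inclusive, lexicographic tie-break), hashtag filtering, and
# population-normalized prevalence per 10,000 persons with the standard
# inclusion filters (>= 1 tweet, mean population strictly > 1000).

# Is (px, py) on the segment (x1,y1)-(x2,y2)?
on_segment <- function(px, py, x1, y1, x2, y2, eps = 1e-12) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  scale <- max(abs(c(x1, y1, x2, y2, px, py)), 1)
  abs(cross) <= eps * scale &&
    px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
    py >= min(y1, y2) - eps && py <= max(y1, y2) + eps
}

# Ray-casting containment for one ring; boundary points count as inside.
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring) - 1  # closed ring: last vertex repeats the first
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
    if (on_segment(px, py, x1, y1, x2, y2)) return(TRUE)
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px < xint) inside <- !inside
    }
  }
  inside
}

#' Assign points to areas
#'
#' Boundary-inclusive ray-casting point-in-polygon. Areas are scanned in
#' lexicographic `area_id` order, so when several areas claim a point (shared
#' borders) the smallest id wins deterministically.
#'
#' @param lon,lat Numeric vectors of point coordinates.
#' @param areas A `geo_areas` object.
#' @return Character vector of `area_id`s, `NA` for points outside all areas.
#' @export
assign_area <- function(lon, lat, areas) {
  stopifnot(inherits(areas, "geo_areas"), length(lon) == length(lat))
  ord <- order(vapply(areas$features, `[[`, character(1), "area_id"))
  assigned <- rep(NA_character_, length(lon))
  todo <- which(!is.na(lon) & !is.na(lat))
  for (f in areas$features[ord]) {
    if (length(todo) == 0) break
    for (ring in f$rings) {
      xmin <- min(ring[, 1]); xmax <- max(ring[, 1])
      ymin <- min(ring[, 2]); ymax <- max(ring[, 2])
      cand <- todo[lon[todo] >= xmin & lon[todo] <= xmax &
                     lat[todo] >= ymin & lat[todo] <= ymax]
      if (length(cand) == 0) next
      hit <- cand[vapply(cand, function(i) point_in_ring(lon[i], lat[i], ring),
                         logical(1))]
      if (length(hit) > 0) {
        assigned[hit] <- f$area_id
        todo <- setdiff(todo, hit)
      }
    }
  }
  assigned
}

#' Filter tweets to those carrying a significant hashtag
#'
#' Keeps tweets whose hashtag set intersects `significant`; a logical
#' `geotagged` column flags the subset with latitude/longitude present.
#'
#' @param tweets Tweet data.frame (with `hashtags` list-column or `text`).
#' @param significant Character vector of hashtags (lowercase, no `#`).
#' @return The kept subset of `tweets`, with a `geotagged` column added.
#' @export
filter_alcohol_tweets <- function(tweets, significant) {
  sets <- tweet_hashtag_sets(tweets)
  keep <- vapply(sets, function(h) any(h %in% significant), logical(1))
  out <- tweets[keep, , drop = FALSE]
  out$geotagged <- !is.na(out$lat) & !is.na(out$lon)
  rownames(out) <- NULL
  out
}

# Mean population over the configured year range for one feature.
mean_population <- function(feature, years = NULL) {
  pop <- feature$population_by_year
  if (!is.null(years)) {
    have <- intersect(as.character(years), names(pop))
    if (length(have) == 0) {
      stop("area ", feature$area_id, " has no population estimates in the ",
           "requested year range", call. = FALSE)
    }
    pop <- pop[have]
  }
  mean(as.numeric(pop))
}

#' Population-normalized prevalence per area
#'
#' Counts geotagged tweets per assigned area and divides by the mean of the
#' per-year population estimates over `years`, scaled per `scale` persons
#' (default 10,000). One record is emitted per area, including zero-count
#' areas. Tweets that fall outside every area are never silently dropped:
#' their count and coordinates are attached as attributes `n_unassigned` and
#' `unassigned_coords`. Areas with zero mean population have undefined
#' prevalence (`per_10k = NA`, `valid_population = FALSE`).
#'
#' @param tweets Geotagged tweet data.frame (rows without coordinates are
#'   ignored for counting but reported via the `n_not_geotagged` attribute).
#' @param areas A `geo_areas` object.
#' @param years Year range for the population mean (default: all years
#'   present per area).
#' @param scale Normalization constant (default 10,000).
#' @return data.frame with columns `area_id`, `level`, `tweet_count`,
#'   `mean_population`, `per_10k`, `valid_population`.
#' @export
compute_prevalence <- function(tweets, areas, years = NULL, scale = 1e4) {
  stopifnot(inherits(areas, "geo_areas"))
  geo <- !is.na(tweets$lat) & !is.na(tweets$lon)
  gt <- tweets[geo, , drop = FALSE]
  assigned <- assign_area(gt$lon, gt$lat, areas)
  ids <- sort(vapply(areas$features, `[[`, character(1), "area_id"))
  counts <- table(factor(assigned, levels = ids))
  mp <- vapply(areas$features, mean_population, numeric(1), years = years)
  names(mp) <- vapply(areas$features, `[[`, character(1), "area_id")
  mp <- mp[ids]
  valid <- mp > 0
  out <- data.frame(
    area_id = ids,
    level = areas$level,
    tweet_count = as.integer(counts),
    mean_population = as.numeric(mp),
    per_10k = ifelse(valid, as.integer(counts) / mp * scale, NA_real_),
    valid_population = valid,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  un <- is.na(assigned)
  attr(out, "n_unassigned") <- sum(un)
  attr(out, "unassigned_coords") <-
    data.frame(lon = gt$lon[un], lat = gt$lat[un])
  attr(out, "n_not_geotagged") <- sum(!geo)
  out
}

#' Apply area inclusion filters
#'
#' Keeps records with at least `min_tweets` tweets and mean population
#' strictly greater than `min_population` (an area at exactly the population
#' bound is excluded). Records with undefined prevalence are always dropped.
#'
#' @param records Output of [compute_prevalence()].
#' @param min_tweets Minimum tweet count (default 1).
#' @param min_population Strict lower bound on mean population (default 1000).
#' @return The surviving subset of `records`.
#' @export
apply_inclusion_filters <- function(records, min_tweets = 1,
                                    min_population = 1000) {
  keep <- records$valid_population &
    records$tweet_count >= min_tweets &
    records$mean_population > min_population
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flat per-area table of populations, confounders and outcomes
#'
#' @param areas A `geo_areas` object.
#' @param years Year range for the population mean.
#' @return data.frame keyed by `area_id` with `mean_population`, the seven
#'   confounder columns and one column per outcome.
#' @export
area_table <- function(areas, years = NULL) {
  stopifnot(inherits(areas, "geo_areas"))
  ids <- vapply(areas$features, `[[`, character(1), "area_id")
  conf <- do.call(rbind, lapply(areas$features, function(f) {
    as.numeric(f$confounders[confounder_names()])
  }))
  colnames(conf) <- confounder_names()
  outcome_names <- sort(unique(unlist(lapply(areas$features, function(f) {
    names(f$outcomes)
  }))))
  outs <- do.call(rbind, lapply(areas$features, function(f) {
    vapply(outcome_names, function(nm) {
      if (nm %in% names(f$outcomes)) as.numeric(f$outcomes[[nm]]) else NA_real_
    }, numeric(1))
  }))
  out <- data.frame(
    area_id = ids,
    mean_population = vapply(areas$features, mean_population, numeric(1),
                             years = years),
    conf,
    stringsAsFactors = FALSE
  )
  if (length(outcome_names) > 0) {
    outs <- matrix(outs, nrow = length(ids),
                   dimnames = list(NULL, outcome_names))
    out <- cbind(out, as.data.frame(outs))
  }
  ord <- order(out$area_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
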