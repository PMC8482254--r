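# Readers and writers for the on-disk world schema:
#   posts.jsonl   {community, title, post_id}
#   graph.tsv     src <TAB> dst (plus communities.tsv with post counts)
#   tweets.jsonl  {tweet_id, text, hashtags, lat, lon, year} (lat/lon optional)
#   areas.geojson FeatureCollection of Polygon features
#   truth.json    {planted_hashtags, true_beta, area_latent_rate}

#' Write a generated world to a directory
#'
#' Emits `posts.jsonl`, `graph.tsv`, `communities.tsv` (per-community post
#' counts), `tweets.jsonl`, `areas.geojson` and `truth.json`. The files
#' round-trip losslessly through [read_world()].
#'
#' @param world A `theme_world` from [generate_world()].
#' @param dir Output directory, created if needed.
#' @return The directory path, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "theme_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) {
    stop("directory not writable: ", dir, call. = FALSE)
  }
  write_posts(world$posts, file.path(dir, "posts.jsonl"))
  write_graph(world$graph, file.path(dir, "graph.tsv"),
              file.path(dir, "communities.tsv"))
  write_tweets(world$tweets, file.path(dir, "tweets.jsonl"))
  write_areas_geojson(world$areas, file.path(dir, "areas.geojson"))
  jsonlite::write_json(
    list(
      planted_hashtags = world$truth$planted_hashtags,
      true_beta = world$truth$true_beta,
      area_latent_rate = as.list(world$truth$area_latent_rate)
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

write_posts <- function(posts, path) {
  recs <- lapply(seq_len(nrow(posts)), function(i) {
    list(community = posts$community[i], title = posts$title[i],
         post_id = posts$post_id[i])
  })
  write_jsonl(recs, path)
}

#' Read a community-post corpus from JSONL
#'
#' @param path Path to a `posts.jsonl` file with objects
#'   `{community, title, post_id}`.
#' @return A data.frame with columns `post_id`, `community`, `title`.
#' @export
read_posts <- function(path) {
  recs <- read_jsonl(path)
  data.frame(
    post_id = vapply(recs, `[[`, character(1), "post_id"),
    community = vapply(recs, `[[`, character(1), "community"),
    title = vapply(recs, `[[`, character(1), "title"),
    stringsAsFactors = FALSE
  )
}

write_graph <- function(graph, edge_path, community_path) {
  utils::write.table(graph$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(community = names(graph$communities),
               post_count = as.integer(graph$communities)),
    community_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
}

#' Read a community link graph
#'
#' @param edge_path Tab-separated edge list `src<TAB>dst` (no header).
#' @param community_path Optional tab-separated table with header
#'   `community  post_count`. When absent, post counts default to 0 for every
#'   community mentioned in the edge list.
#' @return A `community_graph`.
#' @export
read_graph <- function(edge_path, community_path = NULL) {
  edges <- if (file.size(edge_path) > 0) {
    utils::read.table(edge_path, sep = "\t", header = FALSE,
                      col.names = c("src", "dst"),
                      colClasses = "character")
  } else {
    data.frame(src = character(0), dst = character(0),
               stringsAsFactors = FALSE)
  }
  if (!is.null(community_path)) {
    tab <- utils::read.table(community_path, sep = "\t", header = TRUE,
                             colClasses = c("character", "integer"))
    communities <- stats::setNames(tab$post_count, tab$community)
  } else {
    ids <- sort(unique(c(edges$src, edges$dst)))
    communities <- stats::setNames(rep(0L, length(ids)), ids)
  }
  community_graph(communities, edges)
}

write_tweets <- function(tweets, path) {
  recs <- lapply(seq_len(nrow(tweets)), function(i) {
    r <- list(tweet_id = tweets$tweet_id[i], text = tweets$text[i],
              hashtags = as.list(tweets$hashtags[[i]]))
    if (!is.na(tweets$lat[i])) {
      r$lat <- tweets$lat[i]
      r$lon <- tweets$lon[i]
    }
    r$year <- tweets$year[i]
    r
  })
  write_jsonl(recs, path)
}

#' Read a tweet corpus from JSONL
#'
#' @param path Path to `tweets.jsonl` with objects
#'   `{tweet_id, text, hashtags, lat, lon, year}`; `lat`/`lon` are absent for
#'   tweets without a geotag.
#' @return A data.frame with columns `tweet_id`, `text`, `lat`, `lon`, `year`
#'   and a list-column `hashtags` (lowercase, no `#`).
#' @export
read_tweets <- function(path) {
  recs <- read_jsonl(path)
  get_num <- function(r, k) if (is.null(r[[k]])) NA_real_ else as.numeric(r[[k]])
  out <- data.frame(
    tweet_id = vapply(recs, `[[`, character(1), "tweet_id"),
    text = vapply(recs, `[[`, character(1), "text"),
    lat = vapply(recs, get_num, numeric(1), "lat"),
    lon = vapply(recs, get_num, numeric(1), "lon"),
    year = vapply(recs, function(r) as.integer(r$year), integer(1)),
    stringsAsFactors = FALSE
  )
  out$hashtags <- lapply(recs, function(r) as.character(unlist(r$hashtags)))
  out
}

write_areas_geojson <- function(areas, path) {
  stopifnot(inherits(areas, "geo_areas"))
  features <- lapply(areas$features, function(f) {
    coords <- lapply(f$rings, function(ring) {
      lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
    })
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = coords),
      properties = list(
        area_id = f$area_id,
        level = f$level,
        population = as.list(f$population_by_year),
        confounders = as.list(f$confounders),
        outcomes = as.list(f$outcomes)
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read geographic areas from a GeoJSON FeatureCollection
#'
#' Each feature must be a Polygon (or MultiPolygon) whose properties carry
#' `area_id`, `level`, a `population` object keyed by year, a `confounders`
#' object with the seven fields of [confounder_names()], and an `outcomes`
#' object. Rings are validated at load time: they must be closed (first vertex
#' equals last) and have at least four vertices.
#'
#' @param path Path to a GeoJSON file.
#' @return A `geo_areas` object.
#' @export
read_areas_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  features <- lapply(gj$features, function(f) {
    geom <- f$geometry
    rings <- switch(
      geom$type,
      Polygon = lapply(geom$coordinates, parse_ring),
      MultiPolygon = unlist(lapply(geom$coordinates, function(poly) {
        lapply(poly, parse_ring)
      }), recursive = FALSE),
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    )
    p <- f$properties
    conf <- unlist(p$confounders)
    missing <- setdiff(confounder_names(), names(conf))
    if (length(missing) > 0) {
      stop("area ", p$area_id, " missing confounders: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    list(
      area_id = as.character(p$area_id),
      level = as.character(p$level),
      rings = rings,
      population_by_year = unlist(p$population),
      confounders = conf[confounder_names()],
      outcomes = unlist(p$outcomes)
    )
  })
  level <- unique(vapply(features, `[[`, character(1), "level"))
  if (length(level) > 1) {
    stop("areas mix levels: ", paste(level, collapse = ", "), call. = FALSE)
  }
  structure(list(level = level, features = features), class = "geo_areas")
}

parse_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(pt) as.numeric(unlist(pt)[1:2])))
  colnames(m) <- c("lon", "lat")
  if (nrow(m) < 4 || any(m[1, ] != m[nrow(m), ])) {
    stop("polygon ring must be closed with at least 4 vertices", call. = FALSE)
  }
  m
}

#' Read world truth
#'
#' @param path Path to `truth.json`.
#' @return List with `planted_hashtags`, `true_beta`, `area_latent_rate`.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    planted_hashtags = as.character(tr$planted_hashtags),
    true_beta = as.numeric(tr$true_beta),
    area_latent_rate = unlist(tr$area_latent_rate)
  )
}

#' Read a whole world directory
#'
#' Inverse of [write_world()].
#'
#' @param dir Directory containing the world files.
#' @return A list with `posts`, `graph`, `tweets`, `areas`, `truth`.
#' @export
read_world <- function(dir) {
  list(
    posts = read_posts(file.path(dir, "posts.jsonl")),
    graph = read_graph(file.path(dir, "graph.tsv"),
                       file.path(dir, "communities.tsv")),
    tweets = read_tweets(file.path(dir, "tweets.jsonl")),
    areas = read_areas_geojson(file.path(dir, "areas.geojson")),
    truth = read_truth(file.path(dir, "truth.json"))
  )
}
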