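#' Two-backend geocoding consensus
#'
#' A free-form location string is accepted only when two independent
#' geocoder backends agree: both must return coordinates and the results
#' must lie within one degree of each other on each axis (closed bound,
#' so a difference of exactly 1 degree is still accepted). The accepted
#' coordinate is the midpoint of the two results. The rule is symmetric
#' in its arguments.
#'
#' @param a,b data.frames (or lists) with numeric `lat` and `lon`, `NA`
#'   where the backend found nothing; recycled element-wise.
#' @param tolerance per-axis agreement bound in degrees (default 1).
#' @return data.frame with columns `lat`, `lon` (NA when rejected) and
#'   logical `accepted`.
#' @export
geocodeConsensus <- function(a, b, tolerance = 1) {
  a <- as.data.frame(a); b <- as.data.frame(b)
  n <- max(nrow(a), nrow(b))
  ok <- is.finite(a$lat) & is.finite(a$lon) &
        is.finite(b$lat) & is.finite(b$lon) &
        abs(a$lat - b$lat) <= tolerance & abs(a$lon - b$lon) <= tolerance
  data.frame(lat = ifelse(ok, (a$lat + b$lat) / 2, NA_real_),
             lon = ifelse(ok, (a$lon + b$lon) / 2, NA_real_),
             accepted = ok)
}

#' Gazetteer-backed geocoder backend
#'
#' Builds a geocoder function (the backend contract: character vector of
#' location strings in, `lat`/`lon` data.frame out) from a gazetteer
#' table. Lookup is case-insensitive on the trimmed string; unknown
#' strings yield `NA` ("not found"). Tests and synthetic corpora use
#' fixture gazetteers; no live service is ever called.
#'
#' @param gazetteer data.frame with columns `name`, `backend`, `lat`,
#'   `lon`.
#' @param backend which backend's rows to use.
#' @return `function(locations) -> data.frame(lat, lon)`.
#' @export
gazetteerGeocoder <- function(gazetteer, backend) {
  g <- gazetteer[gazetteer$backend == backend, , drop = FALSE]
  key <- tolower(trimws(g$name))
  function(locations) {
    i <- match(tolower(trimws(as.character(locations))), key)
    data.frame(lat = g$lat[i], lon = g$lon[i])
  }
}

#' Assign coordinates to regions
#'
#' Point-in-box containment against a region table (ISO-3166-2-style
#' codes with latitude/longitude bounds). Boxes are closed; when a point
#' falls in several boxes (boxes may overlap) the lexicographically
#' smallest region code wins, making boundary assignment deterministic.
#' Points outside every box are unassigned (`NA`).
#'
#' @param lat,lon numeric vectors of coordinates.
#' @param regions data.frame with columns `code`, `latMin`, `latMax`,
#'   `lonMin`, `lonMax`.
#' @return character vector of region codes, `NA` where unassigned.
#' @export
assignRegion <- function(lat, lon, regions) {
  regions <- regions[order(regions$code), , drop = FALSE]
  out <- rep(NA_character_, length(lat))
  for (i in seq_along(lat)) {
    if (!is.finite(lat[i]) || !is.finite(lon[i])) next
    hit <- which(lat[i] >= regions$latMin & lat[i] <= regions$latMax &
                 lon[i] >= regions$lonMin & lon[i] <= regions$lonMax)
    if (length(hit)) out[i] <- regions$code[hit[1L]]
  }
  out
}

#' Bundled North-American region table
#'
#' Approximate bounding boxes for the 51 US regions (50 states plus DC)
#' and the 13 Canadian provinces and territories. The boxes are coarse
#' envelopes intended as default plumbing for region assignment; for
#' precise work supply your own polygon-derived table.
#'
#' @return data.frame with columns `code`, `latMin`, `latMax`, `lonMin`,
#'   `lonMax`.
#' @export
northAmericaRegions <- function() {
  utils::read.csv(system.file("extdata", "regions_na.csv",
                              package = "poliscope"),
                  stringsAsFactors = FALSE)
}

#' Regional representation check against census counts
#'
#' Correlates per-region user counts with external census population
#' counts over the regions present in both tables, reporting Pearson's r
#' with a Fisher-z 95% confidence interval and two-sided p (see
#' [pearsonCI()]). High correlation indicates each region is represented
#' in proportion to its population.
#'
#' @param userCounts named numeric, region -> user count.
#' @param census named numeric, region -> census population.
#' @return list with `r`, `ci`, `p`, `n` (regions used).
#' @export
representationCorrelation <- function(userCounts, census) {
  common <- intersect(names(userCounts), names(census))
  if (length(common) < 3L)
    stop("insufficient regions: need >= 3 overlapping regions, have ",
         length(common))
  pearsonCI(as.numeric(userCounts[common]), as.numeric(census[common]))
}
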