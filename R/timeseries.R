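#' Calendar grids for conditioning the index
#'
#' `weeklyGrid()` returns the start dates (Sundays) of every Sunday-start
#' week fully contained in the window; `dailyGrid()` returns every day of
#' the window inclusive. The reference analysis window October 11 2020 to
#' January 3 2021 (Oct 11 is a Sunday) yields exactly 12 weekly bins, and
#' the full collection window October 9 2020 to January 4 2021 yields 88
#' daily bins.
#'
#' @param start,end window bounds (coerced with `as.Date`).
#' @return a `Date` vector of bin starts.
#' @export
weeklyGrid <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(start <= end)
  # first Sunday on or after `start`; weekdays: 0 = Sunday
  wd <- as.integer(format(start, "%w"))
  first <- start + ((7L - wd) %% 7L)
  starts <- seq(first, end, by = "7 days")
  starts[starts + 6L <= end]
}

#' @rdname weeklyGrid
#' @export
dailyGrid <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(start <= end)
  seq(start, end, by = "day")
}

# bin each date to its grid period start (NA outside the grid)
binPeriod <- function(dates, grid, granularity) {
  dates <- as.Date(dates)
  if (granularity == "daily") {
    out <- dates
    out[!(dates %in% grid)] <- NA
    return(out)
  }
  idx <- findInterval(as.numeric(dates), as.numeric(grid))
  out <- grid[pmax(idx, 1L)]
  out[idx < 1L | dates - out > 6L] <- NA
  out
}

#' Polarization series conditioned on period, region and topic
#'
#' For every (period, region, topic) cell: the topic-relevant tweets of
#' the cell's users are mean-pooled into per-user embeddings, the users
#' are partitioned by party family, and the polarization index is
#' computed — exactly for cells up to `exactMax` users, by the
#' subsampling approximation above that. Cells without enough support
#' (fewer than two party families present, or fewer than `minPerParty`
#' users in a present family) are flagged `defined = FALSE` rather than
#' zero-filled.
#'
#' @param tweets data.frame with columns `tweet_id`, `user_id`,
#'   `timestamp` (Date or POSIXct), and a `topics` list-column (see
#'   [assignTopics()]).
#' @param tweetEmbeddings numeric matrix, one row per tweet, rownames =
#'   `tweet_id`.
#' @param userFamilies named character, user id -> party family.
#' @param userRegions named character, user id -> region code; `NULL`
#'   puts every user in one region `"ALL"` (country-level series).
#' @param window length-2 window (start, end).
#' @param granularity `"weekly"` (Sunday-start weeks) or `"daily"`.
#' @param topics topic names to condition on; default all topics present.
#' @param exactMax cell size up to which the exact index is used
#'   (default 2000); larger cells use [poliApprox()].
#' @param approxCfg an [approxConfig()] for large cells; when its seed is
#'   set, each cell derives a distinct deterministic seed from it.
#' @param minPerParty minimum users per present family (default 2).
#' @return data.frame with one row per cell: `period`, `region`, `topic`,
#'   `poli`, `defined`, `method`, `nUsers`, `volume` (tweets in the
#'   cell), and one `n_<family>` column per family. Attributes
#'   `granularity` and `window` are set.
#' @export
computeSeries <- function(tweets, tweetEmbeddings, userFamilies,
                          userRegions = NULL, window,
                          granularity = c("weekly", "daily"),
                          topics = NULL, exactMax = 2000L,
                          approxCfg = approxConfig(), minPerParty = 2L) {
  granularity <- match.arg(granularity)
  stopifnot(is.matrix(tweetEmbeddings), !is.null(rownames(tweetEmbeddings)),
            all(c("tweet_id", "user_id", "timestamp", "topics") %in%
                  names(tweets)))
  grid <- if (granularity == "weekly") weeklyGrid(window[1], window[2])
          else dailyGrid(window[1], window[2])
  if (is.null(topics))
    topics <- sort(unique(unlist(tweets$topics, use.names = FALSE)))
  families <- sort(unique(unname(userFamilies)))

  tw <- tweets
  tw$period <- binPeriod(tw$timestamp, grid, granularity)
  tw$family <- unname(userFamilies[as.character(tw$user_id)])
  tw$region <- if (is.null(userRegions)) "ALL"
               else unname(userRegions[as.character(tw$user_id)])
  keep <- !is.na(tw$period) & !is.na(tw$family) & !is.na(tw$region)
  tw <- tw[keep, , drop = FALSE]
  regions <- sort(unique(tw$region))

  rows <- list(); k <- 0L
  for (tp in topics) {
    hasTopic <- vapply(tw$topics, function(s) tp %in% s, logical(1))
    twt <- tw[hasTopic, , drop = FALSE]
    for (rg in regions) {
      twr <- twt[twt$region == rg, , drop = FALSE]
      for (pd in seq_along(grid)) {
        cell <- twr[twr$period == grid[pd], , drop = FALSE]
        k <- k + 1L
        rows[[k]] <- summarizeCell(cell, tweetEmbeddings, grid[pd], rg, tp,
                                   families, exactMax, approxCfg,
                                   minPerParty, cellIndex = k)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "granularity") <- granularity
  attr(out, "window") <- as.Date(c(window[1], window[2]))
  out
}

summarizeCell <- function(cell, tweetEmbeddings, period, region, topic,
                          families, exactMax, approxCfg, minPerParty,
                          cellIndex) {
  base <- data.frame(period = period, region = region, topic = topic,
                     poli = NA_real_, defined = FALSE, method = "none",
                     nUsers = 0L, volume = nrow(cell),
                     stringsAsFactors = FALSE)
  for (f in families) base[[paste0("n_", f)]] <- 0L
  if (!nrow(cell)) return(base)
  pooled <- poolUserEmbeddings(
    tweetEmbeddings[as.character(cell$tweet_id), , drop = FALSE],
    cell$user_id)
  fam <- unname(tapply(cell$family, as.character(cell$user_id),
                       function(x) x[1])[rownames(pooled$embeddings)])
  counts <- table(fam)
  for (f in names(counts)) base[[paste0("n_", f)]] <- as.integer(counts[[f]])
  base$nUsers <- nrow(pooled$embeddings)
  if (length(counts) < 2L || any(counts < minPerParty)) return(base)
  pop <- EmbeddedPopulation(pooled$embeddings, fam)
  n <- nrow(pooled$embeddings)
  if (n <= exactMax) {
    r <- poliExact(pop)
    base$poli <- poliValue(r); base$defined <- r@defined
    base$method <- "exact"
  } else {
    cfg <- approxCfg
    if (!is.null(cfg$seed)) cfg$seed <- (cfg$seed + cellIndex) %% .Machine$integer.max
    r <- poliApprox(pop, cfg)
    base$poli <- poliValue(r); base$defined <- is.finite(base$poli)
    base$method <- "approx"
  }
  base
}

#' Rank regions by average weekly polarization
#'
#' Averages each region's defined weekly index values and ranks regions
#' so that rank 1 is the highest average. For `topic = "overall"` each
#' region's score is the unweighted mean of its per-topic means over
#' `topics` (default: all topics in the series except `conspiracy`,
#' whose role in the source analyses is volume-based rather than an
#' index topic). Ties break by region code; regions with no defined
#' cells are excluded from the ranking and listed in the `"excluded"`
#' attribute.
#'
#' @param series a weekly series from [computeSeries()].
#' @param topic one topic name, or `"overall"`.
#' @param topics topics entering the overall mean.
#' @return data.frame (`region`, `meanPoli`, `rank`), highest first.
#' @export
rankRegions <- function(series, topic = "overall", topics = NULL) {
  df <- as.data.frame(series)
  if (topic == "overall") {
    if (is.null(topics))
      topics <- setdiff(sort(unique(df$topic)), "conspiracy")
    perTopic <- lapply(topics, function(tp) regionMeans(df, tp))
    allRegions <- sort(unique(unlist(lapply(perTopic, names))))
    score <- vapply(allRegions, function(rg)
      mean(vapply(perTopic, function(mns) mns[rg][[1]], numeric(1)),
           na.rm = TRUE), numeric(1))
  } else {
    score <- regionMeans(df, topic)
  }
  excluded <- names(score)[is.nan(score) | is.na(score)]
  score <- score[!(names(score) %in% excluded)]
  ord <- order(-score, names(score))
  out <- data.frame(region = names(score)[ord],
                    meanPoli = unname(score[ord]),
                    rank = seq_along(score))
  attr(out, "excluded") <- excluded
  out
}

regionMeans <- function(df, tp) {
  d <- df[df$topic == tp, , drop = FALSE]
  regions <- sort(unique(d$region))
  vapply(stats::setNames(regions, regions), function(rg) {
    v <- d$poli[d$region == rg & d$defined]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
}

#' Event-triggered average of a daily series
#'
#' Aligns fixed-width windows of a daily series at a set of event dates
#' and reports, per day-offset from the event, the mean and standard
#' deviation across events. Events whose window does not fit inside the
#' series span are dropped (with a message); if none remain the call
#' errors. Adding a constant to the series shifts the profile by exactly
#' that constant.
#'
#' @param series data.frame with `period` (Date) and a value column, or a
#'   named numeric vector keyed by date.
#' @param events `Date` vector of event dates.
#' @param halfWindow window half-width in days.
#' @param valueColumn value column name (default `"poli"`).
#' @return data.frame (`offset`, `mean`, `sd`, `nEvents`).
#' @export
eventTriggeredAverage <- function(series, events, halfWindow,
                                  valueColumn = "poli") {
  if (is.data.frame(series)) {
    dates <- as.Date(series$period)
    vals <- series[[valueColumn]]
  } else {
    dates <- as.Date(names(series)); vals <- as.numeric(series)
  }
  events <- as.Date(events)
  span <- range(dates)
  usable <- events - halfWindow >= span[1] & events + halfWindow <= span[2]
  if (any(!usable))
    message(sum(!usable), " event(s) dropped: window exceeds series span")
  events <- events[usable]
  if (!length(events)) stop("no usable events")
  offsets <- seq.int(-halfWindow, halfWindow)
  mat <- vapply(events, function(ev)
    vals[match(ev + offsets, dates)], numeric(length(offsets)))
  mat <- matrix(mat, nrow = length(offsets))
  sdRow <- apply(mat, 1L, function(r) {
    r <- r[is.finite(r)]
    if (length(r) > 1L) stats::sd(r) else 0
  })
  data.frame(offset = offsets,
             mean = rowMeans(mat, na.rm = TRUE),
             sd = sdRow,
             nEvents = apply(mat, 1L, function(r) sum(is.finite(r))))
}

#' Aggregate per-topic series into a country-level series
#'
#' Combines per-topic index values period by period, either as the
#' unweighted mean over topics with a defined value, or weighted by each
#' topic's share of tweet volume in the period. Periods where every topic
#' is undefined stay undefined. The unweighted mean is always bounded by
#' the per-topic minimum and maximum of the period.
#'
#' @param series a series from [computeSeries()] (one region).
#' @param mode `"mean"` or `"volume_weighted"`.
#' @return data.frame (`period`, `poli`, `defined`, `nTopics`).
#' @export
aggregateTopics <- function(series, mode = c("mean", "volume_weighted")) {
  mode <- match.arg(mode)
  df <- as.data.frame(series)
  periods <- sort(unique(df$period))
  out <- lapply(periods, function(pd) {
    d <- df[df$period == pd & df$defined, , drop = FALSE]
    if (!nrow(d) || (mode == "volume_weighted" && sum(d$volume) == 0))
      return(data.frame(period = pd, poli = NA_real_, defined = FALSE,
                        nTopics = 0L))
    v <- if (mode == "mean") mean(d$poli)
         else sum(d$poli * d$volume) / sum(d$volume)
    data.frame(period = pd, poli = v, defined = TRUE, nTopics = nrow(d))
  })
  do.call(rbind, out)
}

#' Share of a topic's tweets per key and period
#'
#' Computes, per key (region, party family, ...) and period, the
#' percentage of the key's tweets tagged with `topic` out of all its
#' tweets in the period, optionally averaged over periods. Zero-volume
#' periods are undefined and excluded from averages.
#'
#' @param tweets data.frame with `user_id`, `timestamp`, `topics`
#'   list-column.
#' @param topic topic name.
#' @param keys named character, user id -> key; tweets of unkeyed users
#'   are dropped.
#' @param window length-2 window.
#' @param granularity `"weekly"` or `"daily"`.
#' @param average if `TRUE` (default) return the per-key mean over
#'   defined periods, else the full key x period table.
#' @return data.frame (`key`, `share`) or (`key`, `period`, `share`).
#' @export
topicShare <- function(tweets, topic, keys, window,
                       granularity = c("weekly", "daily"), average = TRUE) {
  granularity <- match.arg(granularity)
  grid <- if (granularity == "weekly") weeklyGrid(window[1], window[2])
          else dailyGrid(window[1], window[2])
  tw <- tweets
  tw$period <- binPeriod(tw$timestamp, grid, granularity)
  tw$key <- unname(keys[as.character(tw$user_id)])
  tw <- tw[!is.na(tw$period) & !is.na(tw$key), , drop = FALSE]
  tw$hit <- vapply(tw$topics, function(s) topic %in% s, logical(1))
  cells <- expand.grid(key = sort(unique(tw$key)), period = grid,
                       stringsAsFactors = FALSE)
  cells$share <- mapply(function(k, pd) {
    d <- tw[tw$key == k & tw$period == pd, , drop = FALSE]
    if (!nrow(d)) NA_real_ else 100 * sum(d$hit) / nrow(d)
  }, cells$key, cells$period)
  if (!average) return(cells)
  agg <- tapply(cells$share, cells$key, function(v) mean(v[!is.na(v)]))
  data.frame(key = names(agg), share = as.numeric(agg))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' The correlation report used throughout the package: Pearson's r, a
#' 95% confidence interval from the Fisher z-transform with standard
#' error `1/sqrt(n - 3)`, and a two-sided p-value from the t
#' distribution (delegated to [stats::cor.test()], which implements
#' exactly this).
#'
#' @param x,y numeric vectors, length >= 3, finite, non-constant.
#' @return list with `r`, `ci` (length 2), `p`, `n`.
#' @export
pearsonCI <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("degenerate input: non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p = ct$p.value, n = length(x))
}
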