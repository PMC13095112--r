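#' Synthetic study configuration
#'
#' Parameters of the synthetic-data generator. Embeddings are drawn from
#' one isotropic Gaussian cluster per party family (optionally
#' heavier-tailed), with family centroids `separation` apart; tweets are
#' the user's vector plus noise. The defaults describe the reference
#' study conditions: two party families, embedding dimension 768, a
#' within-family spread of 1, and a centroid separation of 8 — a
#' strongly but incompletely separated regime in which the index lies
#' below 1 and subsample estimates of it are tightly concentrated, as
#' observed for real partisan discourse (total separation would be a
#' separation two orders of magnitude above the spread). Tests typically
#' reduce `d` to 8 for speed.
#'
#' @param nUsersPerFamily users per family (per region, for corpora).
#' @param families family labels (two or more).
#' @param d embedding dimension.
#' @param separation distance between family centroids (>= 0).
#' @param sigma within-family standard deviation (> 0).
#' @param tweetNoise sd of tweet-level noise around the user vector.
#' @param tweetsPerUserMean mean of the (shifted-geometric, >= 1)
#'   per-user tweet count.
#' @param window length-2 study window (dates).
#' @param regions data.frame with columns `region` and `separation`
#'   (per-region planted separation); `NULL` = one region at
#'   `separation`.
#' @param topicRates named per-topic tagging probabilities.
#' @param keywordRate probability that a user's profile carries a family
#'   keyword.
#' @param heavyTailed draw cluster noise from a scaled t(3) instead of a
#'   Gaussian.
#' @param seed integer seed; the generator is fully reproducible.
#' @return list with class `"synthConfig"`.
#' @export
synthConfig <- function(nUsersPerFamily = 200L,
                        families = c("Democrat", "Republican"),
                        d = 768L, separation = 8, sigma = 1,
                        tweetNoise = 0.5, tweetsPerUserMean = 5,
                        window = c("2020-10-09", "2021-01-04"),
                        regions = NULL,
                        topicRates = c(lockdown = 0.25, mask = 0.25,
                                       vaccine = 0.25, conspiracy = 0.1),
                        keywordRate = 0.5, heavyTailed = FALSE,
                        seed = NULL) {
  stopifnot(nUsersPerFamily >= 2, length(families) >= 2, d >= 1,
            separation >= 0, sigma > 0, tweetNoise >= 0,
            tweetsPerUserMean >= 1, keywordRate >= 0, keywordRate <= 1)
  window <- as.Date(window)
  stopifnot(length(window) == 2, window[1] <= window[2])
  if (is.null(regions))
    regions <- data.frame(region = "R1", separation = separation)
  structure(list(nUsersPerFamily = as.integer(nUsersPerFamily),
                 families = as.character(families), d = as.integer(d),
                 separation = separation, sigma = sigma,
                 tweetNoise = tweetNoise,
                 tweetsPerUserMean = tweetsPerUserMean, window = window,
                 regions = regions, topicRates = topicRates,
                 keywordRate = keywordRate, heavyTailed = heavyTailed,
                 seed = seed),
            class = "synthConfig")
}

familyCentroids <- function(k, d, separation) {
  ctr <- matrix(0, k, d)
  if (k == 2L) ctr[2, 1] <- separation
  else for (i in seq_len(k)) ctr[i, i] <- separation / sqrt(2)
  ctr
}

clusterNoise <- function(n, d, sigma, heavyTailed) {
  if (heavyTailed) matrix(stats::rt(n * d, df = 3) / sqrt(3) * sigma,
                          ncol = d)
  else matrix(stats::rnorm(n * d, 0, sigma), ncol = d)
}

#' Generate a party-clustered embedding population
#'
#' Draws `nUsersPerFamily` user vectors per family from isotropic
#' clusters around centroids `separation` apart and returns the
#' [EmbeddedPopulation-class] together with the planted ground truth.
#'
#' @param cfg a [synthConfig()].
#' @param computeExact also compute the exact index on the generated
#'   population (only honored up to 20000 users).
#' @return list with `population`, and `truth` (list: `labels`,
#'   `centroids`, `separation`, `sigma`, and `exactPoli` when requested).
#' @export
generatePopulation <- function(cfg, computeExact = FALSE) {
  stopifnot(inherits(cfg, "synthConfig"))
  withSeed(cfg$seed, {
    k <- length(cfg$families)
    ctr <- familyCentroids(k, cfg$d, cfg$separation)
    n <- cfg$nUsersPerFamily
    x <- do.call(rbind, lapply(seq_len(k), function(i)
      clusterNoise(n, cfg$d, cfg$sigma, cfg$heavyTailed) +
        matrix(ctr[i, ], n, cfg$d, byrow = TRUE)))
    lab <- rep(cfg$families, each = n)
    ids <- sprintf("u%05d", seq_len(nrow(x)))
    rownames(x) <- ids
    pop <- EmbeddedPopulation(x, lab, ids)
    truth <- list(labels = stats::setNames(lab, ids), centroids = ctr,
                  separation = cfg$separation, sigma = cfg$sigma)
    if (computeExact && nrow(x) <= 20000L)
      truth$exactPoli <- poliValue(poliExact(pop, maxUsers = 20000L))
    list(population = pop, truth = truth)
  })
}

#' Generate a synthetic tweet corpus with planted ground truth
#'
#' Emits everything the downstream modules consume: users (with profile
#' text carrying a family keyword at `keywordRate`, a location string
#' resolvable by the bundled two-backend fixture gazetteer, and a planted
#' family and region), tweets (timestamps uniform over the window,
#' hashtags drawn per `topicRates`, placeholder text), per-tweet
#' embeddings (user vector plus noise; the user vectors cluster by family
#' with each region's own planted separation), the fixture gazetteer and
#' a synthetic non-overlapping region table. Fully reproducible from the
#' seed; with `dir` set, the fixture files are also written (see
#' [writeCorpus()]).
#'
#' @param cfg a [synthConfig()].
#' @param dir optional output directory for fixture files.
#' @param partyLex party lexicon supplying profile keywords; families in
#'   `cfg` must be parties of this lexicon. Default [usPartyLexicon()].
#' @return list with `tweets`, `users`, `embeddings` (tweets x d matrix),
#'   `gazetteer`, `regions`, `truth`.
#' @export
generateCorpus <- function(cfg, dir = NULL, partyLex = usPartyLexicon()) {
  stopifnot(inherits(cfg, "synthConfig"),
            all(cfg$families %in% names(partyLex$keywords)))
  corpus <- withSeed(cfg$seed, buildCorpus(cfg, partyLex))
  if (!is.null(dir)) writeCorpus(corpus, dir)
  corpus
}

buildCorpus <- function(cfg, partyLex) {
  regions <- cfg$regions
  k <- length(cfg$families)
  days <- dailyGrid(cfg$window[1], cfg$window[2])
  topicLex <- defaultTopicLexicon()

  # synthetic non-overlapping region boxes in 3-degree latitude bands
  regTab <- data.frame(code = regions$region,
                       latMin = 20 + 3 * (seq_len(nrow(regions)) - 1),
                       latMax = 20 + 3 * (seq_len(nrow(regions)) - 1) + 2,
                       lonMin = -100, lonMax = -96)
  ctrLat <- (regTab$latMin + regTab$latMax) / 2
  gaz <- rbind(
    data.frame(name = paste0(tolower(regions$region), " city"),
               backend = "osm", lat = ctrLat, lon = -98),
    data.frame(name = paste0(tolower(regions$region), " city"),
               backend = "arcgis", lat = ctrLat + 0.3, lon = -98.4))

  users <- list(); vectors <- list(); uid <- 0L
  for (r in seq_len(nrow(regions))) {
    ctr <- familyCentroids(k, cfg$d, regions$separation[r])
    for (i in seq_len(k)) {
      n <- cfg$nUsersPerFamily
      v <- clusterNoise(n, cfg$d, cfg$sigma, cfg$heavyTailed) +
        matrix(ctr[i, ], n, cfg$d, byrow = TRUE)
      ids <- sprintf("u%05d", uid + seq_len(n)); uid <- uid + n
      fam <- cfg$families[i]
      hasKw <- stats::runif(n) < cfg$keywordRate
      kws <- sample(partyLex$keywords[[fam]], n, replace = TRUE)
      profile <- ifelse(hasKw, paste0("Posting daily. ", kws, "."),
                        "Posting daily about this and that.")
      rownames(v) <- ids
      users[[length(users) + 1L]] <- data.frame(
        user_id = ids, profile_text = profile,
        location_text = paste0(regions$region[r], " city"),
        display_name = paste0("First", ids, " Last", ids),
        family = fam, region = regions$region[r],
        stringsAsFactors = FALSE)
      vectors[[length(vectors) + 1L]] <- v
    }
  }
  users <- do.call(rbind, users)
  userVec <- do.call(rbind, vectors)

  p <- 1 / cfg$tweetsPerUserMean
  nTweets <- stats::rgeom(nrow(users), p) + 1L
  tweetUser <- rep(users$user_id, nTweets)
  total <- length(tweetUser)
  tweetIds <- sprintf("t%07d", seq_len(total))
  timestamps <- sample(days, total, replace = TRUE)
  topics <- names(cfg$topicRates)
  hashtags <- lapply(seq_len(total), function(i) {
    tags <- character(0)
    for (tp in topics)
      if (stats::runif(1) < cfg$topicRates[[tp]])
        tags <- c(tags, sample(topicLex$topics[[tp]], 1))
    tags
  })
  text <- vapply(hashtags, function(h)
    paste(c("a post about current affairs",
            if (length(h)) paste0("#", h)), collapse = " "), "")
  emb <- userVec[tweetUser, , drop = FALSE] +
    matrix(stats::rnorm(total * cfg$d, 0, cfg$tweetNoise), ncol = cfg$d)
  rownames(emb) <- tweetIds
  tweets <- data.frame(tweet_id = tweetIds, user_id = tweetUser,
                       timestamp = timestamps, text = text,
                       stringsAsFactors = FALSE)
  tweets$hashtags <- hashtags

  list(tweets = tweets, users = users, embeddings = emb,
       gazetteer = gaz, regions = regTab,
       truth = list(families = stats::setNames(users$family, users$user_id),
                    regions = stats::setNames(users$region, users$user_id),
                    separations = stats::setNames(regions$separation,
                                                  regions$region),
                    config = unclass(cfg)))
}

#' Write a synthetic corpus to fixture files
#'
#' Writes `tweets.jsonl`, `users.csv`, `embeddings.tsv`, `gazetteer.csv`,
#' `regions.csv` and `truth.json` under `dir`. Output is byte-identical
#' for identical corpora.
#'
#' @param corpus a corpus from [generateCorpus()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeTweetsJSONL(corpus$tweets, file.path(dir, "tweets.jsonl"))
  utils::write.csv(corpus$users, file.path(dir, "users.csv"),
                   row.names = FALSE)
  writeEmbeddingsTSV(corpus$embeddings, file.path(dir, "embeddings.tsv"))
  utils::write.csv(corpus$gazetteer, file.path(dir, "gazetteer.csv"),
                   row.names = FALSE)
  utils::write.csv(corpus$regions, file.path(dir, "regions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(corpus$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
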