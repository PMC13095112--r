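test_that("calendar grids match the reference analysis windows", {
  wk <- weeklyGrid("2020-10-11", "2021-01-03")
  expect_length(wk, 12)
  expect_equal(wk[1], as.Date("2020-10-11"))        # a Sunday
  expect_true(all(format(wk, "%w") == "0"))
  expect_length(dailyGrid("2020-10-09", "2021-01-04"), 88)

  # window opening mid-week: first bin is the next Sunday
  wk2 <- weeklyGrid("2020-10-07", "2020-11-03")
  expect_equal(wk2[1], as.Date("2020-10-11"))
  expect_length(wk2, 3)                             # only complete weeks
})

test_that("pearson correlation report matches known values", {
  x <- 1:10
  expect_equal(pearsonCI(x, 2 * x + 1)$r, 1)
  got <- pearsonCI(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(got$r, 0.8)
  expect_equal(got$n, 4)
  # CI from the Fisher z-transform with SE 1/sqrt(n-3)
  z <- atanh(0.8) + c(-1, 1) * qnorm(0.975)
  expect_equal(got$ci, tanh(z), tolerance = 1e-9)
  expect_error(pearsonCI(rep(1, 5), 1:5), "degenerate")
  expect_error(pearsonCI(c(1, 2), c(3, 4)), "n >= 3")
})

test_that("independent inputs give near-zero correlation", {
  set.seed(6)
  x <- rnorm(2000); y <- rnorm(2000)
  got <- pearsonCI(x, y)
  expect_lt(abs(got$r), 0.06)
  expect_true(got$ci[1] < 0 && got$ci[2] > 0)
})

makeSeriesDF <- function(regions, weeks, poli, topic = "vaccine") {
  df <- expand.grid(region = regions, period = weeks,
                    stringsAsFactors = FALSE)
  df$topic <- topic
  df$poli <- poli
  df$defined <- !is.na(poli)
  df$volume <- 10L
  df
}

test_that("region ranking orders by mean weekly index, ties by code", {
  weeks <- weeklyGrid("2020-10-11", "2021-01-03")[1:3]
  df <- makeSeriesDF(c("A", "B"), weeks, c(0.9, 0.1, 0.9, 0.1, 0.9, 0.1))
  rk <- rankRegions(df, topic = "vaccine")
  expect_equal(rk$region[rk$rank == 1], "A")

  tied <- makeSeriesDF(c("Z", "Q"), weeks, rep(0.5, 6))
  rk2 <- rankRegions(tied, topic = "vaccine")
  expect_equal(rk2$region, c("Q", "Z"))             # code order on ties

  holes <- makeSeriesDF(c("A", "B"), weeks,
                        c(0.9, NA, 0.9, NA, 0.9, NA))
  rk3 <- rankRegions(holes, topic = "vaccine")
  expect_equal(rk3$region, "A")
  expect_equal(attr(rk3, "excluded"), "B")
})

test_that("overall ranking averages the per-topic means", {
  weeks <- weeklyGrid("2020-10-11", "2021-01-03")[1:2]
  df <- rbind(makeSeriesDF("A", weeks, c(0.2, 0.2), "lockdown"),
              makeSeriesDF("A", weeks, c(0.6, 0.6), "mask"),
              makeSeriesDF("B", weeks, c(0.5, 0.5), "lockdown"),
              makeSeriesDF("B", weeks, c(0.5, 0.5), "mask"),
              makeSeriesDF("A", weeks, c(0.99, 0.99), "conspiracy"))
  rk <- rankRegions(df, topic = "overall")
  # conspiracy excluded by default: A = mean(0.2, 0.6) = 0.4 < B = 0.5
  expect_equal(rk$region[rk$rank == 1], "B")
  expect_equal(rk$meanPoli[rk$region == "A"], 0.4)
})

test_that("event-triggered averaging reproduces hand-computed profiles", {
  days <- dailyGrid("2020-11-01", "2020-11-30")
  const <- data.frame(period = days, poli = 0.42)
  ev <- as.Date(c("2020-11-10", "2020-11-20"))
  prof <- eventTriggeredAverage(const, ev, halfWindow = 3)
  expect_equal(prof$mean, rep(0.42, 7))
  expect_equal(prof$sd, rep(0, 7))

  ramp <- data.frame(period = days, poli = seq_along(days) / 100)
  one <- eventTriggeredAverage(ramp, ev[1], halfWindow = 2)
  expect_equal(one$mean, c(0.08, 0.09, 0.10, 0.11, 0.12))
  expect_equal(one$sd, rep(0, 5))

  two <- eventTriggeredAverage(ramp, ev, halfWindow = 1)
  expect_equal(two$mean, c((0.09 + 0.19) / 2, (0.10 + 0.20) / 2,
                           (0.11 + 0.21) / 2))
  expect_equal(two$sd, rep(sd(c(0.09, 0.19)), 3))
})

test_that("event averaging shifts with the series and drops bad events", {
  days <- dailyGrid("2020-11-01", "2020-11-30")
  set.seed(3)
  s <- data.frame(period = days, poli = runif(length(days)))
  ev <- as.Date(c("2020-11-10", "2020-11-20"))
  p1 <- eventTriggeredAverage(s, ev, halfWindow = 4)
  s2 <- s; s2$poli <- s2$poli + 0.25
  p2 <- eventTriggeredAverage(s2, ev, halfWindow = 4)
  expect_equal(p2$mean, p1$mean + 0.25)
  expect_equal(p2$sd, p1$sd)

  expect_message(
    p3 <- eventTriggeredAverage(s, as.Date(c("2020-11-02", "2020-11-15")),
                                halfWindow = 5),
    "dropped")
  expect_equal(p3$nEvents, rep(1L, 11))
  expect_error(
    suppressMessages(eventTriggeredAverage(s, as.Date("2020-11-01"),
                                           halfWindow = 5)),
    "no usable events")
})

test_that("topic aggregation averages and volume-weights per period", {
  pd <- as.Date("2020-10-11")
  df <- data.frame(period = pd, region = "ALL",
                   topic = c("lockdown", "mask", "vaccine"),
                   poli = c(0.2, 0.4, 0.6), defined = TRUE,
                   volume = c(1L, 1L, 2L))
  expect_equal(aggregateTopics(df, "mean")$poli, 0.4)
  expect_equal(aggregateTopics(df, "volume_weighted")$poli, 0.45)

  eq <- df; eq$volume <- 5L
  expect_equal(aggregateTopics(eq, "mean")$poli,
               aggregateTopics(eq, "volume_weighted")$poli)

  deg <- df; deg$volume <- c(100L, 0L, 0L)
  expect_equal(aggregateTopics(deg, "volume_weighted")$poli, 0.2)

  undef <- df; undef$defined <- FALSE
  expect_false(aggregateTopics(undef, "mean")$defined)

  # unweighted mean stays inside the per-topic range
  set.seed(10)
  rnd <- df; rnd$poli <- runif(3)
  agg <- aggregateTopics(rnd, "mean")$poli
  expect_gte(agg, min(rnd$poli)); expect_lte(agg, max(rnd$poli))
})

test_that("topic shares are percentages with undefined zero-volume cells", {
  days <- dailyGrid("2020-10-11", "2020-10-12")
  tweets <- data.frame(
    tweet_id = paste0("t", 1:12),
    user_id = "u1",
    timestamp = rep(days[1], 12))
  tweets$topics <- c(rep(list("conspiracy"), 3), rep(list(character(0)), 9))
  keys <- c(u1 = "US")
  out <- topicShare(tweets, "conspiracy", keys,
                    window = c("2020-10-11", "2020-10-12"),
                    granularity = "daily", average = FALSE)
  expect_equal(out$share[out$period == days[1]], 25)
  expect_true(is.na(out$share[out$period == days[2]]))  # zero volume
  avg <- topicShare(tweets, "conspiracy", keys,
                    window = c("2020-10-11", "2020-10-12"),
                    granularity = "daily")
  expect_equal(avg$share, 25)                           # NA period excluded

  all3 <- tweets; all3$topics <- rep(list("conspiracy"), 12)
  expect_equal(topicShare(all3, "conspiracy", keys,
                          window = c("2020-10-11", "2020-10-12"),
                          granularity = "daily")$share, 100)
  none <- tweets; none$topics <- rep(list(character(0)), 12)
  expect_equal(topicShare(none, "conspiracy", keys,
                          window = c("2020-10-11", "2020-10-12"),
                          granularity = "daily")$share, 0)
})

test_that("a conditioned series recovers a time-homogeneous planted index", {
  # 84-day window = 12 complete Sunday-start weeks, so every tweet lands
  # in a weekly bin and cell volumes add up to the corpus total
  cfg <- synthConfig(nUsersPerFamily = 60, d = 8, separation = 6,
                     tweetsPerUserMean = 12,
                     window = c("2020-10-11", "2021-01-02"),
                     topicRates = c(vaccine = 0.5), keywordRate = 1,
                     seed = 77)
  corpus <- generateCorpus(cfg)
  tweets <- assignTopics(corpus$tweets, defaultTopicLexicon())
  fams <- corpus$truth$families
  ser <- computeSeries(tweets, corpus$embeddings, fams,
                       window = cfg$window, granularity = "weekly",
                       topics = "vaccine")
  expect_equal(nrow(ser), 12)                      # 12 weekly bins, one region
  expect_true(all(ser$defined))
  expect_true(all(ser$poli >= 0 & ser$poli <= 1))
  # constant planted separation: weeks differ only by sampling noise
  expect_lt(sd(ser$poli), 0.05)
  expect_true(all(ser$method == "exact"))
  expect_equal(sum(ser$volume),
               sum(vapply(tweets$topics, function(s) "vaccine" %in% s,
                          logical(1))))
})

test_that("cells without two supported families are flagged, not zeroed", {
  days <- as.Date("2020-10-11") + 0:1
  emb <- matrix(rnorm(12), 6, 2,
                dimnames = list(paste0("t", 1:6), NULL))
  tweets <- data.frame(tweet_id = paste0("t", 1:6),
                       user_id = c("a", "b", "c", "d", "a", "b"),
                       timestamp = c(rep(days[1], 4), rep(days[2], 2)))
  tweets$topics <- rep(list("mask"), 6)
  fams <- c(a = "L", b = "L", c = "R", d = "R")
  ser <- computeSeries(tweets, emb, fams, window = days,
                       granularity = "daily", topics = "mask")
  expect_equal(nrow(ser), 2)
  expect_true(ser$defined[1])                      # 2 + 2 users
  expect_false(ser$defined[2])                     # one family only
  expect_true(is.na(ser$poli[2]))
  expect_equal(ser$n_L, c(2L, 2L))
  expect_equal(ser$n_R, c(2L, 0L))
})
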