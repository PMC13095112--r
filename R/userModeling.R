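#' Mean-pooled user embedding
#'
#' A user's representation is the arithmetic component-wise mean of the
#' embeddings of their (topic-relevant) tweets. Permutation-invariant in
#' tweet order and contained in the convex hull of the inputs.
#'
#' @param tweetVectors numeric matrix, one row per tweet embedding (a
#'   single vector is accepted).
#' @return numeric vector of length `ncol(tweetVectors)`.
#' @export
aggregateUserEmbedding <- function(tweetVectors) {
  if (is.null(dim(tweetVectors))) tweetVectors <- matrix(tweetVectors, nrow = 1)
  if (nrow(tweetVectors) == 0) stop("no tweets: cannot pool an empty set")
  colMeans(tweetVectors)
}

#' Pool tweet embeddings into per-user embeddings
#'
#' Groups rows of a tweet-embedding matrix by user and mean-pools each
#' group.
#'
#' @param tweetEmbeddings numeric matrix, rows = tweets.
#' @param tweetUsers character/factor of the same length as
#'   `nrow(tweetEmbeddings)` giving each tweet's user.
#' @return list with `embeddings` (users x d matrix, rownames = user ids)
#'   and `nTweets` (named integer).
#' @export
poolUserEmbeddings <- function(tweetEmbeddings, tweetUsers) {
  stopifnot(nrow(tweetEmbeddings) == length(tweetUsers))
  g <- as.character(tweetUsers)
  sums <- rowsum(tweetEmbeddings, g)
  n <- as.vector(table(g)[rownames(sums)])
  list(embeddings = sums / n,
       nTweets = stats::setNames(as.integer(n), rownames(sums)))
}

#' Keyword-based profile party classification
#'
#' A user is *politically explicit* when their profile description
#' contains at least one party keyword. Matching is on word boundaries
#' after Unicode NFKC normalization and lowercasing, with multi-word
#' phrases matched as contiguous token runs (so `"gop"` does not fire
#' inside `"gopher"`). Profiles matching keywords of two or more parties
#' are labeled `"ambiguous"` and excluded from seed sets; profiles
#' matching none are `"none"`. Keywords are matched literally, including
#' in negated contexts ("never trump" still fires) — a known bias of the
#' rule stage.
#'
#' @param profileText character vector of profile descriptions.
#' @param lexicon a [partyLexicon()].
#' @return character vector: a party name, `"none"`, or `"ambiguous"`.
#' @export
classifyProfile <- function(profileText, lexicon) {
  stopifnot(inherits(lexicon, "partyLexicon"))
  canon <- canonicalTokens(profileText)
  hits <- vapply(lexicon$keywords, function(kws) {
    h <- rep(FALSE, length(canon))
    for (k in kws) h <- h | containsPhrase(canon, k)
    h
  }, logical(length(canon)))
  if (length(canon) == 1L) hits <- matrix(hits, nrow = 1,
                                          dimnames = list(NULL, names(lexicon$keywords)))
  nHit <- rowSums(hits)
  out <- rep("none", length(canon))
  out[nHit == 1L] <- colnames(hits)[apply(hits[nHit == 1L, , drop = FALSE],
                                          1L, which)]
  out[nHit >= 2L] <- "ambiguous"
  out
}

#' Filter users by activity level
#'
#' Keeps users whose count of (topic-relevant) tweets reaches the
#' threshold. Thresholds of 10 tweets (United States) and 5 (Canada) were
#' found to balance label quality against user coverage in the source
#' study; the boundary is inclusive.
#'
#' @param tweetCounts named numeric vector, user id -> relevant-tweet
#'   count.
#' @param threshold minimum count (>= 1).
#' @return character vector of retained user ids.
#' @export
activityFilter <- function(tweetCounts, threshold) {
  stopifnot(threshold >= 1)
  names(tweetCounts)[tweetCounts >= threshold]
}

#' Merge parties into partisan families
#'
#' Maps party labels to family labels via the lexicon's family map. Users
#' whose party is outside the map (minor parties, regional parties) are
#' dropped.
#'
#' @param labels named character, user id -> party.
#' @param familyMap named character party -> family, or a [partyLexicon()].
#' @return named character, user id -> family (mapped users only).
#' @export
mergePartyFamilies <- function(labels, familyMap) {
  if (inherits(familyMap, "partyLexicon")) familyMap <- familyMap$familyMap
  keep <- as.character(labels) %in% names(familyMap)
  stats::setNames(unname(familyMap[as.character(labels[keep])]),
                  names(labels)[keep])
}

#' Reference activity classifier (fit/predict contract)
#'
#' The label-propagation stage accepts any classifier exposing
#' `fit(x, y) -> model` and `predict(model, x) -> labels`. This reference
#' implementation is a deterministic seeded multinomial-logistic (linear)
#' model on the mean-pooled user embeddings; it stands behind the
#' contract, not for any particular architecture.
#'
#' @param seed integer seed fixed at fit time.
#' @param maxit maximum optimizer iterations.
#' @param decay ridge penalty on the weights; a light penalty keeps the
#'   boundary between the class clusters when the seed set is small and
#'   linearly separable (unpenalized logistic fits diverge there).
#' @return a list with `fit` and `predict` functions.
#' @export
linearActivityClassifier <- function(seed = 1L, maxit = 300L, decay = 0.01) {
  list(
    fit = function(x, y) {
      df <- data.frame(.y = factor(y), x)
      withSeed(seed, nnet::multinom(.y ~ ., data = df, trace = FALSE,
                                    maxit = maxit, decay = decay))
    },
    predict = function(model, x) {
      as.character(stats::predict(model, newdata = data.frame(x),
                                  type = "class"))
    })
}

#' Propagate seed party-family labels to unlabeled active users
#'
#' Fits the classifier on the embeddings of keyword-labeled (seed) users
#' and predicts families for the remaining users; seed labels always win
#' on conflict. Every family must contribute at least 10 seed users.
#'
#' @param seedLabels named character, user id -> family, for the seed set.
#' @param embeddings users x d matrix with user ids as rownames (seeds
#'   and unlabeled users).
#' @param classifier a fit/predict contract as returned by
#'   [linearActivityClassifier()].
#' @param minSeeds minimum seeds per family (default 10).
#' @return named character covering all users in `embeddings`.
#' @export
propagateLabels <- function(seedLabels, embeddings,
                            classifier = linearActivityClassifier(),
                            minSeeds = 10L) {
  stopifnot(!is.null(rownames(embeddings)))
  seedLabels <- stats::setNames(as.character(seedLabels), names(seedLabels))
  seedLabels <- seedLabels[names(seedLabels) %in% rownames(embeddings)]
  tab <- table(seedLabels)
  if (length(tab) < 2L || any(tab < minSeeds))
    stop("insufficient seeds: every family needs >= ", minSeeds,
         " seed users (have: ",
         paste(names(tab), tab, sep = "=", collapse = ", "), ")")
  model <- classifier$fit(embeddings[names(seedLabels), , drop = FALSE],
                          seedLabels)
  rest <- setdiff(rownames(embeddings), names(seedLabels))
  out <- seedLabels
  if (length(rest)) {
    pred <- classifier$predict(model, embeddings[rest, , drop = FALSE])
    out <- c(out, stats::setNames(as.character(pred), rest))
  }
  out[rownames(embeddings)]
}

stripEmojis <- function(x) {
  stringi::stri_replace_all_regex(as.character(x),
                                  "[\\p{So}\\p{Sk}\\p{Cs}\\p{Co}]+", "")
}

#' Match users to voter registration records
#'
#' Links users to registration records by county plus exact name match:
#' display names are stripped of emojis and parsed as first / middle /
#' last tokens, and a user matches a record when the county agrees and
#' either (first, last) or (first, middle, last) equals the record's name.
#' Keys are md5 hashes of `"name|county"` after lowercasing. Users whose
#' name matches more than one record in their county are dropped as
#' non-unique, as are users matched to parties outside `majorParties`.
#'
#' @param users data.frame with columns `user_id`, `display_name`,
#'   `county`.
#' @param records data.frame with columns `name`, `county`, `party`.
#' @param majorParties parties retained after matching.
#' @return named character, user id -> registered party (matched users
#'   only).
#' @export
matchVoterRecords <- function(users, records,
                              majorParties = c("Democrat", "Republican")) {
  stopifnot(all(c("user_id", "display_name", "county") %in% names(users)),
            all(c("name", "county", "party") %in% names(records)))
  keyOf <- function(name, county)
    cli::hash_md5(tolower(paste0(trimws(name), "|", trimws(county))))
  recKey <- keyOf(canonicalTokens(records$name), records$county)

  out <- character(); ids <- character()
  for (i in seq_len(nrow(users))) {
    nm <- canonicalTokens(stripEmojis(users$display_name[i]))
    toks <- strsplit(nm, " ", fixed = TRUE)[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) < 2L) next
    cands <- paste(toks[1], toks[length(toks)])
    if (length(toks) > 2L)
      cands <- c(cands, paste(toks[1],
                              paste(toks[-c(1, length(toks))], collapse = " "),
                              toks[length(toks)]))
    keys <- keyOf(cands, users$county[i])
    hit <- which(recKey %in% keys)
    if (length(hit) != 1L) next               # unmatched or non-unique
    p <- records$party[hit]
    if (!(p %in% majorParties)) next
    ids <- c(ids, users$user_id[i]); out <- c(out, p)
  }
  stats::setNames(out, ids)
}
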