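#' Harvest frequent hashtags from a corpus
#'
#' Counts hashtag occurrences over all tweets and keeps tags reaching the
#' frequency threshold (tags seen fewer than `minCount` times are
#' discarded; the boundary is inclusive). Results are ordered by
#' descending count with lexicographic tie-break so lexicon exports are
#' reproducible.
#'
#' @param tweets data.frame with a `hashtags` list-column of lowercase
#'   tags (a plain list of character vectors also works).
#' @param minCount frequency threshold (default 100).
#' @return named integer vector, tag -> count, ordered.
#' @export
extractHashtags <- function(tweets, minCount = 100L) {
  tags <- if (is.data.frame(tweets)) tweets$hashtags else tweets
  tags <- unlist(tags, use.names = FALSE)
  if (!length(tags)) return(stats::setNames(integer(0), character(0)))
  tab <- table(tolower(tags))
  tab <- tab[tab >= minCount]
  counts <- as.integer(tab)
  ord <- order(-counts, names(tab))
  stats::setNames(counts[ord], names(tab)[ord])
}

#' Rule-based multi-label topic assignment
#'
#' Returns, per tweet, every topic with at least one matching hashtag or
#' text keyword; an empty set means the tweet is irrelevant to all
#' topics. Hashtags match by exact (lowercased) tag membership; keywords
#' match in the tweet text on word boundaries. Matching is set-valued and
#' idempotent — repeating a tag adds nothing. Conspiracy-topic matching
#' is stance-agnostic: tweets promoting and tweets debunking a theory are
#' equally relevant.
#'
#' @param tweets data.frame with `hashtags` list-column and optionally
#'   `text`.
#' @param lexicon a [topicLexicon()].
#' @return list of character vectors, one per tweet.
#' @export
classifyTopicKeywords <- function(tweets, lexicon) {
  stopifnot(inherits(lexicon, "topicLexicon"))
  n <- nrow(tweets)
  hashtags <- tweets$hashtags %||% vector("list", n)
  canonText <- if (!is.null(tweets$text)) canonicalTokens(tweets$text)
               else rep("", n)
  relevant <- matrix(FALSE, n, length(lexicon$topics),
                     dimnames = list(NULL, names(lexicon$topics)))
  for (tp in names(lexicon$topics)) {
    terms <- lexicon$topics[[tp]]
    tagHit <- vapply(hashtags, function(h) any(tolower(h) %in% terms),
                     logical(1))
    txtHit <- rep(FALSE, n)
    for (k in terms) txtHit <- txtHit | containsPhrase(canonText, k)
    relevant[, tp] <- tagHit | txtHit
  }
  lapply(seq_len(n), function(i) colnames(relevant)[relevant[i, ]])
}

#' @rdname classifyTopicKeywords
#' @return `assignTopics()` returns `tweets` with a `topics` list-column
#'   added.
#' @export
assignTopics <- function(tweets, lexicon) {
  tweets$topics <- classifyTopicKeywords(tweets, lexicon)
  tweets
}
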