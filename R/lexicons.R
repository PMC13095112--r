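#' Party keyword lexicons
#'
#' A party lexicon maps each party to a set of lowercase keyword phrases
#' that mark a user's profile as politically explicit, plus a family map
#' grouping parties into partisan-leaning families (used where individual
#' parties are too confusable to model separately). Parties absent from
#' the family map are dropped when merging (e.g. minor parties).
#'
#' `usPartyLexicon()` and `canadaPartyLexicon()` return the built-in
#' lexicons for the two major US parties and the five main Canadian
#' federal parties; the Canadian family map groups Liberal, New Democratic
#' and Green into the liberal-left family (`LPF`) and Conservative and
#' People's Party into the conservative-right family (`RPF`).
#'
#' @param keywords named list, party -> character vector of keyword
#'   phrases (lowercase).
#' @param familyMap named character, party -> family.
#' @return a list with class `"partyLexicon"` and elements `keywords`,
#'   `familyMap`.
#' @examples
#' lex <- usPartyLexicon()
#' classifyProfile("Progressive mom. Vote!", lex)  # "Democrat"
#' @export
partyLexicon <- function(keywords, familyMap) {
  stopifnot(is.list(keywords), length(keywords) > 0,
            all(nzchar(names(keywords))))
  if (any(!vapply(keywords, length, 1L)))
    stop("every party needs at least one keyword")
  keywords <- lapply(keywords, function(k) tolower(as.character(k)))
  familyMap <- vapply(familyMap, as.character, "")
  structure(list(keywords = keywords, familyMap = familyMap),
            class = "partyLexicon")
}

#' @rdname partyLexicon
#' @export
usPartyLexicon <- function() {
  partyLexicon(
    keywords = list(
      Democrat   = c("liberal", "progressive", "democrat", "biden"),
      Republican = c("conservative", "gop", "republican", "trump")),
    familyMap = c(Democrat = "Democrat", Republican = "Republican"))
}

#' @rdname partyLexicon
#' @export
canadaPartyLexicon <- function() {
  partyLexicon(
    keywords = list(
      CPC = c("erin o'toole", "andrew scheer", "conservative",
              "conservative party", "cpc", "cpc2021", "cpc2019",
              "conservative party of canada"),
      GPC = c("annamie paul", "green party", "gpc", "gpc2019", "gpc2021",
              "green party of canada"),
      LPC = c("justin trudeau", "liberal", "liberal party", "lpc",
              "lpc2021", "lpc2019", "liberal party of canada"),
      NDP = c("jagmeet singh", "new democrat", "new democrats",
              "new democratic party", "ndp", "ndp2021", "ndp2019"),
      PPC = c("maxime bernier", "people's party", "ppc", "ppc2019",
              "ppc2021", "people's party of canada")),
    familyMap = c(LPC = "LPF", NDP = "LPF", GPC = "LPF",
                  CPC = "RPF", PPC = "RPF"))
}

#' Topic lexicons
#'
#' Maps topic names to hashtag/keyword sets used for rule-based topic
#' assignment. Topic sets need not be disjoint: a tweet can belong to
#' several topics. `minCount` is the corpus-frequency threshold applied
#' when candidate hashtags are harvested with [extractHashtags()].
#'
#' `defaultTopicLexicon()` covers the four pandemic discussion topics
#' (lockdown, mask, vaccine, conspiracy) with a compact built-in tag set;
#' conspiracy tags are stance-agnostic (promotion and debunking both make
#' a tweet relevant).
#'
#' @param topics named list, topic -> character vector of lowercase
#'   hashtags/keywords.
#' @param minCount candidate-hashtag frequency threshold (default 100).
#' @return a list with class `"topicLexicon"`.
#' @export
topicLexicon <- function(topics, minCount = 100L) {
  stopifnot(is.list(topics), length(topics) > 0, all(nzchar(names(topics))),
            minCount >= 1)
  topics <- lapply(topics, function(k) tolower(as.character(k)))
  structure(list(topics = topics, minCount = as.integer(minCount)),
            class = "topicLexicon")
}

#' @rdname topicLexicon
#' @export
defaultTopicLexicon <- function(minCount = 100L) {
  topicLexicon(list(
    lockdown   = c("lockdown", "stayhome", "stayathome", "shutdown"),
    mask       = c("maskup", "wearamask", "masks", "maskmandate"),
    vaccine    = c("vaccine", "vaccinated", "covidvaccine", "vaccines"),
    conspiracy = c("plandemic", "scamdemic", "hoax", "greatreset")),
    minCount = minCount)
}
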