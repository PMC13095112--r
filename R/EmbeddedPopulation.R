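#' Construct an EmbeddedPopulation
#'
#' Builds the package's central object from a users-by-dimensions embedding
#' matrix and a party label per user. Rows of `embeddings` are users (in
#' the order of `party`); internally the matrix is stored transposed, in
#' the dimensions-by-users orientation conventional for
#' SummarizedExperiment assays.
#'
#' @param embeddings numeric matrix, one row per user, one column per
#'   embedding dimension; all values finite.
#' @param party character or factor, one party (or party-family) label per
#'   user; at least two distinct labels must be present.
#' @param userIds optional character vector of unique user identifiers;
#'   defaults to rownames of `embeddings` or `u1, u2, ...`.
#' @return an [EmbeddedPopulation-class].
#' @examples
#' x <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
#' pop <- EmbeddedPopulation(x, c("A", "A", "B", "B"))
#' nPerParty(pop)
#' @export
EmbeddedPopulation <- function(embeddings, party, userIds = NULL) {
  embeddings <- as.matrix(embeddings)
  storage.mode(embeddings) <- "double"
  party <- as.factor(party)
  if (nrow(embeddings) != length(party))
    stop("one party label per user is required (nrow(embeddings) != length(party))")
  if (is.null(userIds)) {
    userIds <- rownames(embeddings)
    if (is.null(userIds)) userIds <- paste0("u", seq_len(nrow(embeddings)))
  }
  userIds <- as.character(userIds)
  a <- t(embeddings)
  dimnames(a) <- list(colnames(embeddings), userIds)
  se <- SummarizedExperiment(
    assays = list(embeddings = a),
    colData = DataFrame(party = droplevels(party), row.names = userIds))
  methods::new("EmbeddedPopulation", se)
}

#' @rdname EmbeddedPopulation
#' @return `embeddingMatrix()` returns the users-by-dimensions matrix;
#'   `partyLabels()` the per-user factor; `userIds()` the identifiers;
#'   `nPerParty()` a named table of users per party.
#' @export
setMethod("embeddingMatrix", "EmbeddedPopulation", function(x)
  t(assay(x, "embeddings")))

#' @rdname EmbeddedPopulation
#' @export
setMethod("partyLabels", "EmbeddedPopulation", function(x)
  colData(x)$party)

#' @rdname EmbeddedPopulation
#' @export
setMethod("userIds", "EmbeddedPopulation", function(x) colnames(x))

#' @rdname EmbeddedPopulation
#' @export
setMethod("nPerParty", "EmbeddedPopulation", function(x) {
  tab <- table(partyLabels(x))
  stats::setNames(as.integer(tab), names(tab))
})

setMethod("show", "EmbeddedPopulation", function(object) {
  np <- nPerParty(object)
  cat("EmbeddedPopulation:", ncol(object), "users,",
      nrow(object), "dimensions\n")
  cat("  parties:", paste0(names(np), " (", np, ")", collapse = ", "), "\n")
})
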