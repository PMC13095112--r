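#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame
NULL

#' EmbeddedPopulation: party-partitioned user embeddings
#'
#' The central data object of the package: one embedding vector per user
#' together with a party (or party-family) label. Internally a
#' [SummarizedExperiment::SummarizedExperiment] whose single assay,
#' `"embeddings"`, is a `d x n` numeric matrix (embedding dimensions in
#' rows, users in columns) and whose `colData` carries the `party` factor.
#' The polarization index is computed on objects of this class.
#'
#' Validity requires all embedding values finite, a party label for every
#' user, at least two distinct parties observed, and at least one user per
#' observed party.
#'
#' @seealso [EmbeddedPopulation()] for construction from a users-by-dims
#'   matrix, [poliExact()], [poliApprox()].
#' @export
setClass("EmbeddedPopulation", contains = "SummarizedExperiment")

setValidity("EmbeddedPopulation", function(object) {
  msg <- character()
  if (!("embeddings" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'embeddings' is required")
  else {
    e <- assay(object, "embeddings")
    if (!is.numeric(e)) msg <- c(msg, "'embeddings' assay must be numeric")
    else if (!all(is.finite(e))) msg <- c(msg, "embeddings contain non-finite values")
    if (nrow(e) < 1L) msg <- c(msg, "embedding dimension must be >= 1")
  }
  if (!("party" %in% colnames(colData(object))))
    msg <- c(msg, "colData column 'party' is required")
  else {
    p <- colData(object)$party
    if (anyNA(p)) msg <- c(msg, "every user needs a party label")
    if (length(unique(as.character(p[!is.na(p)]))) < 2L)
      msg <- c(msg, "at least two distinct parties are required")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "user ids (colnames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' DistanceSummary: the pairwise-distance sums behind the index
#'
#' Holds the ingredients of the polarization index for one population:
#' `m`, the number of unordered within-party pairs; `sW`, the sum of
#' within-party pairwise distances; and `sMin` / `sMax`, the sums of the
#' `m` smallest / largest pairwise distances over all users irrespective
#' of label. Invariantly `sMin <= sW <= sMax`.
#'
#' @slot m numeric(1), count of within-party unordered pairs.
#' @slot sW numeric(1), within-party distance sum.
#' @slot sMin numeric(1), sum of the m smallest pairwise distances.
#' @slot sMax numeric(1), sum of the m largest pairwise distances.
#' @export
setClass("DistanceSummary",
  representation(m = "numeric", sW = "numeric", sMin = "numeric",
                 sMax = "numeric"))

setValidity("DistanceSummary", function(object) {
  msg <- character()
  if (object@m < 0) msg <- c(msg, "m must be >= 0")
  if (any(c(object@sW, object@sMin, object@sMax) < -1e-12))
    msg <- c(msg, "distance sums must be non-negative")
  if (object@sW < object@sMin - 1e-9 || object@sW > object@sMax + 1e-9)
    msg <- c(msg, "sMin <= sW <= sMax violated")
  if (length(msg)) msg else TRUE
})

#' PolarizationIndex: the index value with its support
#'
#' Result of [poliExact()]. `poli` lies in \[0, 1\] when defined; when the
#' population geometry is degenerate (all pairwise distances equal, so
#' `sMax == sMin`) the index is undefined and `poli` is `NA` with
#' `defined == FALSE`.
#'
#' @slot poli numeric(1), the index, or `NA_real_` when undefined.
#' @slot defined logical(1).
#' @slot nUsers integer(1).
#' @slot nPerParty named integer, users per party.
#' @slot summary the underlying [DistanceSummary-class].
#' @export
setClass("PolarizationIndex",
  representation(poli = "numeric", defined = "logical", nUsers = "integer",
                 nPerParty = "integer", summary = "DistanceSummary"))

#' ApproxResult: subsampling estimate of the index
#'
#' Result of [poliApprox()]: the mean index over the final round's
#' repeated subsamples, with the dispersion and the full per-round trace.
#'
#' @slot estimate numeric(1), mean index over the final round.
#' @slot std numeric(1), standard deviation over the final round.
#' @slot cv numeric(1), coefficient of variation at termination.
#' @slot finalFraction numeric(1), sampling fraction of the final round.
#' @slot converged logical(1), `FALSE` if the fraction cap was reached
#'   with the CV still above the threshold.
#' @slot rounds data.frame trace: columns `round`, `fraction`, `rep`,
#'   `poli`.
#' @slot config list of the configuration used.
#' @export
setClass("ApproxResult",
  representation(estimate = "numeric", std = "numeric", cv = "numeric",
                 finalFraction = "numeric", converged = "logical",
                 rounds = "data.frame", config = "list"))
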