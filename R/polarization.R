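#' Exact polarization index of a party-partitioned embedding population
#'
#' The index rescales the sum of within-party pairwise distances by its
#' attainable extremes over the population. With `sW` the sum of Euclidean
#' distances over unordered user pairs sharing a party, `m` the number of
#' such pairs, and `sMin` / `sMax` the sums of the `m` smallest / largest
#' pairwise distances over all users regardless of label,
#'
#' \deqn{poli = (S_{max} - S_w) / (S_{max} - S_{min})}
#'
#' which is 1 minus the C-index of the party partition. It ranges from 0
#' (each party's users are maximally dispersed among the others) to 1
#' (parties form the tightest possible clusters). When every pairwise
#' distance is equal (`sMax == sMin`, e.g. all users coincident) no
#' information about separation exists and the index is undefined: the
#' result carries `NA` with `defined = FALSE`.
#'
#' The exact path materializes all `n(n-1)/2` pairwise distances; the sums
#' of the `m` smallest and largest are obtained by partial selection. A
#' guard refuses populations larger than `maxUsers` and points to
#' [poliApprox()].
#'
#' @param pop an [EmbeddedPopulation-class]. At least one party must have
#'   two or more users (`m >= 1`), otherwise a "degenerate partition"
#'   error is raised.
#' @param maxUsers guard on the exact path (default 50000); above this the
#'   full distance matrix is considered impractical.
#' @param ... unused.
#' @return `poliExact()` returns a [PolarizationIndex-class];
#'   `distanceSummary()` a [DistanceSummary-class]; `withinPartySum()` a
#'   single non-negative number; `poliValue()` extracts the numeric index
#'   (`NA` when undefined).
#' @examples
#' pop <- EmbeddedPopulation(rbind(c(0, 0), c(0, 2), c(0, 1), c(0, 5)),
#'                           c("A", "A", "B", "B"))
#' poliValue(poliExact(pop))  # 3/7
#' @rdname poliExact
#' @export
setMethod("poliExact", "EmbeddedPopulation", function(pop, maxUsers = 50000L, ...) {
  n <- ncol(pop)
  if (n > maxUsers)
    stop("population has ", n, " users; the exact path is limited to ",
         maxUsers, " - use poliApprox()")
  ds <- distanceSummary(pop)
  np <- nPerParty(pop)
  denom <- ds@sMax - ds@sMin
  if (denom <= 0) {
    # all m-extreme sums equal: no geometric information (e.g. coincident
    # points); undefined by design, excluded from downstream averages
    return(methods::new("PolarizationIndex", poli = NA_real_,
                        defined = FALSE, nUsers = as.integer(n),
                        nPerParty = np, summary = ds))
  }
  v <- (ds@sMax - ds@sW) / denom
  v <- min(max(v, 0), 1)  # clamp tiny float excursions at the extremes
  methods::new("PolarizationIndex", poli = v, defined = TRUE,
               nUsers = as.integer(n), nPerParty = np, summary = ds)
})

#' @rdname poliExact
#' @export
setMethod("distanceSummary", "EmbeddedPopulation", function(pop, ...) {
  x <- embeddingMatrix(pop)
  lab <- partyLabels(pop)
  counts <- table(lab)
  # numeric, not integer: |p|(|p|-1)/2 overflows 32-bit ints for large parties
  m <- sum(as.numeric(counts) * (as.numeric(counts) - 1) / 2)
  if (m < 1)
    stop("degenerate partition: no party has two or more users (m = 0)")
  sW <- 0
  for (p in names(counts)) {
    if (counts[[p]] >= 2)
      sW <- sW + sum(stats::dist(x[lab == p, , drop = FALSE]))
  }
  dv <- as.vector(stats::dist(x))
  L <- length(dv)
  if (m < L) {
    dv <- sort(dv, partial = unique(c(m, L - m + 1L)))
    sMin <- sum(dv[seq_len(m)])
    sMax <- sum(dv[seq.int(L - m + 1L, L)])
  } else {
    sMin <- sMax <- sum(dv)
  }
  methods::new("DistanceSummary", m = as.numeric(m), sW = sW,
               sMin = sMin, sMax = sMax)
})

#' @rdname poliExact
#' @export
setMethod("withinPartySum", "EmbeddedPopulation", function(pop, ...) {
  x <- embeddingMatrix(pop)
  lab <- partyLabels(pop)
  s <- 0
  for (p in levels(lab)) {
    xp <- x[lab == p, , drop = FALSE]
    if (nrow(xp) >= 2) s <- s + sum(stats::dist(xp))
  }
  s
})

#' @rdname poliExact
#' @export
setMethod("poliValue", "PolarizationIndex", function(x) x@poli)

#' @rdname poliExact
#' @export
setMethod("poliValue", "ApproxResult", function(x) x@estimate)

setMethod("show", "PolarizationIndex", function(object) {
  cat("PolarizationIndex:",
      if (object@defined) format(object@poli, digits = 6) else "undefined",
      "\n")
  np <- object@nPerParty
  cat("  n =", object@nUsers, "users;",
      paste0(names(np), " = ", np, collapse = ", "), "\n")
  s <- object@summary
  cat(sprintf("  m = %d; sW = %.6g; sMin = %.6g; sMax = %.6g\n",
              as.integer(s@m), s@sW, s@sMin, s@sMax))
})
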