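# Independent brute-force reference for the polarization index: explicit
# double loops over user pairs and a full sort, sharing no code with the
# package's exact path.
bruteForcePoli <- function(x, lab, details = FALSE) {
  n <- nrow(x)
  lab <- as.character(lab)
  dAll <- numeric(0)
  dWithin <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      dij <- sqrt(sum((x[i, ] - x[j, ])^2))
      dAll <- c(dAll, dij)
      if (lab[i] == lab[j]) dWithin <- c(dWithin, dij)
    }
  }
  m <- length(dWithin)
  stopifnot(m >= 1)
  srt <- sort(dAll)
  sMin <- sum(srt[seq_len(m)])
  sMax <- sum(rev(srt)[seq_len(m)])
  sW <- sum(dWithin)
  poli <- if (sMax > sMin) (sMax - sW) / (sMax - sMin) else NA_real_
  if (details) list(poli = poli, m = m, sW = sW, sMin = sMin, sMax = sMax)
  else poli
}
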