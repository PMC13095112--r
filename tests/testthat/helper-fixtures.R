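# Small constructors shared across test files.

makePop <- function(x, lab) EmbeddedPopulation(as.matrix(x), lab)

# a random multi-party population for fuzz/property tests
randomPopulation <- function(n, nParties = 2, d = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lab <- sample(LETTERS[seq_len(nParties)], n, replace = TRUE)
  # make sure every party occurs and at least one has two members
  lab[seq_len(nParties)] <- LETTERS[seq_len(nParties)]
  lab[nParties + 1] <- LETTERS[1]
  makePop(matrix(rnorm(n * d), ncol = d), lab)
}

# two Gaussian family clusters at a given separation
gaussianPop <- function(nPer, d = 8, delta = 4, sigma = 1, seed = 1) {
  cfg <- synthConfig(nUsersPerFamily = nPer, families = c("L", "R"),
                     d = d, separation = delta, sigma = sigma, seed = seed)
  generatePopulation(cfg)$population
}

# the two 4-point reference configurations at the index extremes
separatedPop <- function() makePop(rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1)),
                                   c("A", "A", "B", "B"))
interleavedPop <- function() makePop(rbind(c(0, 0), c(10, 1), c(10, 0), c(0, 1)),
                                     c("A", "A", "B", "B"))
# the 4-point population with poli = 3/7
midPop <- function() makePop(rbind(c(0, 0), c(0, 2), c(0, 1), c(0, 5)),
                             c("A", "A", "B", "B"))
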