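# Evaluate expr under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards. NULL seed = use (and
# advance) the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Canonical token form used for every keyword/profile comparison:
# Unicode NFKC, lowercase, punctuation collapsed to spaces. Multi-word
# phrases become contiguous token sequences, and short keywords cannot
# fire inside longer words ("gop" vs "gopher").
canonicalTokens <- function(x) {
  x <- stringi::stri_trans_nfkc(as.character(x))
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(x, "[^\\p{L}\\p{N}]+", " ")
  stringi::stri_trim_both(x)
}

# TRUE where the canonicalized haystack contains the canonicalized phrase
# as a contiguous token run.
containsPhrase <- function(canonHaystack, phrase) {
  p <- canonicalTokens(phrase)
  if (!nzchar(p)) return(rep(FALSE, length(canonHaystack)))
  stringi::stri_detect_fixed(paste0(" ", canonHaystack, " "),
                             paste0(" ", p, " "))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
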