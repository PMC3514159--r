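`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible seed for a labelled RNG stream
#'
#' Each stochastic operation in the package consumes its own RNG stream,
#' derived from the user-visible seed and a fixed call label.  Adding one
#' generator call to a script therefore never shifts the draws of another.
#'
#' @param rng_seed Integer seed supplied by the caller.
#' @param label Character label naming the stream.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(rng_seed, label) {
  stopifnot(is.numeric(rng_seed), length(rng_seed) == 1L, is.character(label))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(rng_seed)) %% 2147483647 + h) %% 2147483647)
}

# Evaluate `code` under the stream seed, restoring .Random.seed afterwards.
with_stream <- function(rng_seed, label, code) {
  withr::with_seed(derive_seed(rng_seed, label), code)
}

# Format a numeric cell so that re-reading reproduces the stored double
# exactly; whole numbers keep a trailing ".0" so a corrected p of 1 is
# written "1.0", never blank or bare.
fmt_number <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- sprintf("%.17g", v)
    if (!grepl("[.eE]", s)) s <- paste0(s, ".0")
    s
  }, character(1))
}
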