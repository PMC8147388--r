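#' Derive a named RNG sub-stream seed from a global seed
#'
#' One global seed drives independent, named pseudo-random streams
#' (probe effects, batch effects, noise, ...) so that refactoring one
#' stage of the simulator never perturbs the draws of another.
#'
#' @param seed integer global seed.
#' @param stream character stream name.
#' @return An integer seed, strictly below 2^31.
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # small deterministic hash of the stream name
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) %% 1000003L) * 2011L + (h %% 65521L) * 31L) %% 2147483629L
}

with_stream <- function(seed, stream, code) {
  withr::with_seed(stream_seed(seed, stream), code)
}

#' @noRd
assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

BIOTYPES <- c("lncRNA", "mRNA", "negative_control")
MATERIALS <- c("CuO", "MWCNT", "TiO2p", "TiO2r", "control")
SURFACES <- c("Core", "COOH", "NH2", "PEG", "none")
DISPERSANTS <- c("PBS", "PBS_BSA")
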