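#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package operations never disturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Stage logging
#'
#' Lightweight message logger used by every pipeline stage to report input
#' counts, filter survivors and seeds. Silenced with
#' `options(archdelta.verbose = FALSE)`.
#'
#' @param ... Passed to [sprintf()].
#' @keywords internal
ad_log <- function(...) {
  if (isTRUE(getOption("archdelta.verbose", FALSE))) {
    message("[archdelta] ", sprintf(...))
  }
  invisible(NULL)
}

# Derive a reproducible sub-seed from a master seed and a stage label.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
sub_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647L)
}
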