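# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
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

#' The closed vocabulary of sample groups
#'
#' Sample groups cross the tumour/normal axis with the multiple (MPLC) vs.
#' solitary (SPLC) primary lung cancer axis.
#'
#' @return Character vector of the four admissible group labels.
#' @export
tme_groups <- function() {
  c("MPLC_Tumour", "MPLC_Normal", "SPLC_Tumour", "SPLC_Normal")
}

# Derive a deterministic per-stage sub-seed from a user seed; kept below
# 2^31 - 1 so it is always a valid R integer seed.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483629)
}
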