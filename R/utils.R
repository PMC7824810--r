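`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a root seed and a stage label
#'
#' All randomness in the pipeline flows from one root seed; each stage draws
#' from its own named substream so that stages can be re-run independently.
#'
#' @param seed integer root seed.
#' @param label character stage label.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 69069 + h * 1013904223) %% 2147483647)
}

stop_msg <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
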