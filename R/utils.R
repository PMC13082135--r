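#' Inverse logit
#'
#' @param x numeric vector of log-odds.
#' @return probabilities in (0, 1).
#' @export
expit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

# clamp probabilities away from 0/1
clip_prob <- function(p, clip) pmin(pmax(p, clip), 1 - clip)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)

is_prob <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
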