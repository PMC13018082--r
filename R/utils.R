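# internal numeric helpers

#' @importFrom rlang %||% abort warn
#' @importFrom stats dnorm pnorm qnorm optim runif rpois rexp rbinom integrate setNames
#' @importFrom utils head tail
NULL

# log(sum(exp(x))) without overflow; -Inf for empty / all -Inf input
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# combine two partial logsumexp accumulators
lse_pair <- function(a, b) logsumexp(c(a, b))

stop_coseg <- function(msg, class = "coseg_error", ...) {
  rlang::abort(msg, class = c(class, "coseg_error"), ...)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_coseg(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
}

GENES <- c("BRCA1", "BRCA2", "PALB2")
CANCERS <- c("BC", "CBC", "OC", "PANC")
MODES <- c("all_relevant", "first_diagnosis", "first_diagnosis_plus_cbc",
           "legacy_cbc")
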