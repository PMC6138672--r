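#' Round half away from zero
#'
#' Table-style rounding: 0.05 rounds up to 0.1, unlike [round()] which rounds
#' to even. Used when comparing computed feature values against published
#' tables that were typeset with conventional half-up rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` places.
#' @export
#' @examples
#' round_half_up(3.45, 1)  # 3.5, where round(3.45, 1) gives 3.4
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: stop with a class so tests can target specific failure modes
.tc_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "trapclient_error")))
}

# derive a stage seed from a global seed; stays inside 32-bit integer range
.stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 131L + h) %% .Machine$integer.max)
}
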