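#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows distinct n count rename relocate
#' @importFrom stats quantile aov pchisq qgamma rbinom rlnorm runif setNames
#' @importFrom utils head
NULL

# Internal: message-level logging to stderr, silenced via option.
pv_log <- function(...) {
  if (isTRUE(getOption("statindili.quiet", FALSE))) return(invisible(NULL))
  message(sprintf(...))
}

# Half-up rounding (R's round() is banker's rounding; reported percentages
# use conventional half-up at `digits` decimals).
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- rlang::`%||%`
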