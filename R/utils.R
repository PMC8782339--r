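#' @importFrom rlang %||% abort warn inform .data
#' @importFrom stats dnorm pnorm qnorm sd median rlnorm rnorm rpois rexp runif
#' @importFrom utils head tail
NULL

# round half away from zero at `digits` decimals (R's round() is half-even;
# printed percentages here follow the half-up convention)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# log(sum(exp(x))) without overflow
lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# derive independent 32-bit sub-seeds from a master seed by a fixed counter
# scheme, so replications are reproducible and distinct
derive_seed <- function(master, counter) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(counter)) %% 2147483647) + 1L
}

`%||%` <- rlang::`%||%`
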