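## Small shared helpers.

#' Round half away from zero
#'
#' Percentages are reported to one decimal with halves rounded up
#' (`round_half_up(96.875, 1)` is 96.9), matching the conventional reporting
#' style rather than IEEE banker's rounding.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Derive a per-stage seed from a master seed
#'
#' Keeps every source of randomness tied to one master seed while decoupling
#' stages; results stay below 2^31.
#'
#' @param master integer master seed.
#' @param stage stage label.
#' @keywords internal
derive_seed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(master) * 2654435 + h) %% 2147483647)
}
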