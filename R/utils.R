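#' Truncate (not round) to a fixed number of decimals
#'
#' Printed duplication statistics (Ka/Ks ratios to 4 decimals, divergence
#' times to 2) are truncated toward zero, so 0.1664/2.5295 reports 0.0657
#' rather than 0.0658.
#'
#' @param x numeric vector.
#' @param digits number of decimal places kept.
#' @return numeric vector truncated toward zero.
#' @export
#' @examples
#' trunc_dec(0.1664 / 2.5295, 4)
trunc_dec <- function(x, digits = 4) {
  stopifnot(is.numeric(x), digits >= 0)
  trunc(x * 10^digits) / 10^digits
}

#' Round half away from zero to a fixed number of decimals
#'
#' Commercial ("half-up") rounding used for reported aggregates, where R's
#' `round()` would round half to even.
#'
#' @inheritParams trunc_dec
#' @return numeric vector.
#' @export
#' @examples
#' round_half_up(6.592, 2) # 6.59
#' round_half_up(529.5, 0) # 530
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), digits >= 0)
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# shared validation helper: stop with a labelled message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DNA4 <- c("A", "C", "G", "T")
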