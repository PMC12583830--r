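#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino acids in alphabetical one-letter order. This
#' ordering fixes the column order of every fitness matrix handled by the
#' package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA_BASES <- c("A", "C", "G", "T")

# Signal a classed error so callers can distinguish failure modes.
fs_stop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("fitscan_error_", class),
                                     "fitscan_error", "error", "condition")))
}

# Run `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
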