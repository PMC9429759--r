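# Internal helpers shared across modules.

# Unit conventions (package-wide, never inferred from data):
#   diameters in micrometres, droplet volumes in picolitres,
#   cell densities in CFU per millilitre.
# 1 mL = 1e9 pL, 1 pL = 1000 um^3.
.PL_PER_ML <- 1e9
.UM3_PER_PL <- 1000

.BASES <- c("A", "C", "G", "T")

#' Derive a child RNG seed from a root seed and an operation label
#'
#' All stochastic operations in the simulator draw their randomness from a
#' child stream derived from `(seed, label)` by a fixed documented scheme:
#' the label's UTF-8 bytes are folded into a 31-bit integer by repeated
#' `(31 * h + byte) mod (2^31 - 1)` and added to the seed modulo
#' `2^31 - 1`. Operations therefore stay reproducible even when the order
#' in which they are called changes.
#'
#' @param seed integer root seed.
#' @param label character scalar naming the operation or stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  m <- 2^31 - 1
  h <- 0
  for (b in as.integer(utf8ToInt(label))) h <- (31 * h + b) %% m
  as.integer((abs(seed) + h) %% m)
}

# stop() with a consistent error class so callers can distinguish
# domain/configuration errors from programming errors.
.err <- function(class, msg, ...) {
  stop(structure(class = c(class, "dropstrain_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    .err("dropstrain_domain_error", "%s must be a positive number", name)
  invisible(x)
}

.check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    .err("dropstrain_domain_error", "%s must be a non-negative number", name)
  invisible(x)
}
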