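# Classed conditions so callers (and the command-line wrapper) can tell
# malformed input apart from semantically invalid input.

ftu_error <- function(msg, class) {
  stop(structure(
    class = c(class, "ftu_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ftu_validation_error <- function(msg) ftu_error(msg, "ftu_validation_error")
ftu_parse_error      <- function(msg) ftu_error(msg, "ftu_parse_error")
ftu_lookup_error     <- function(msg) ftu_error(msg, "ftu_lookup_error")
ftu_structural_error <- function(msg) ftu_error(msg, "ftu_structural_error")
ftu_io_error         <- function(msg) ftu_error(msg, "ftu_io_error")

#' Round half away from zero
#'
#' Presentation rounding used when reporting motif similarity scores:
#' exact halves round up (`0.635` at 2 digits gives `0.64`), unlike
#' [base::round()]'s round-half-to-even. Internal computations always keep
#' full precision; this is applied only when printing or exporting.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.635, 2) # 0.64
#' @export
round_half_up <- function(x, digits = 2) {
  # small epsilon guards against representation error just below a half
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x) sprintf("%.6g", x)
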