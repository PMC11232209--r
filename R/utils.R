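#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_wider pivot_longer
#' @importFrom purrr map map_dbl map_chr map_lgl imap pmap list_rbind
NULL

# typed conditions: every validation failure carries a class so callers can
# distinguish schema errors from parse errors from parameter errors
stop_rehab <- function(message, class, ...) {
  abort(message, class = c(class, "rehabpose_error"), ...)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE) {
  if (!is_scalar_number(x)) {
    stop_rehab(sprintf("`%s` must be a single finite number", name), "rehabpose_parameter_error")
  }
  bad <- if (strict_lo) x <= lo else x < lo
  if (bad || x > hi) {
    stop_rehab(sprintf("`%s` = %s is outside its allowed range", name, format(x)),
               "rehabpose_parameter_error")
  }
  invisible(x)
}
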