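#' Label an amount with its currency
#'
#' Monetary amounts move through the pipeline as plain doubles carrying a
#' `currency` attribute. The label exists so that conversion to US$ can be
#' applied exactly once: converting an amount that is already in US$ is an
#' error, and aggregating across currencies is blocked by the arithmetic
#' helpers used internally.
#'
#' @param x numeric amount(s).
#' @param currency currency label, e.g. `"ETB"` or `"USD"`.
#' @return `x` with a `currency` attribute.
#' @export
as_money <- function(x, currency) {
  stopifnot(is.numeric(x), is.character(currency), length(currency) == 1)
  attr(x, "currency") <- currency
  x
}

#' @rdname as_money
#' @export
currency <- function(x) {
  cur <- attr(x, "currency", exact = TRUE)
  if (is.null(cur)) NA_character_ else cur
}

#' Convert local-currency amounts to US$
#'
#' @param amount numeric amount(s); if labelled (see [as_money()]) the label
#'   must not already be `"USD"`.
#' @param rate exchange rate in local currency units per 1 US$ (> 0).
#' @return the amount in US$, labelled `"USD"`.
#' @examples
#' to_usd(28440, 28.44) # 1000
#' @export
to_usd <- function(amount, rate) {
  if (!is.numeric(rate) || length(rate) != 1 || is.na(rate) || rate <= 0) {
    abort("`rate` must be a single positive number (local currency per US$).")
  }
  cur <- currency(amount)
  if (!is.na(cur) && identical(cur, "USD")) {
    abort("Amount is already in US$; refusing to convert twice.")
  }
  as_money(unclass(amount) / rate, "USD")
}

# Commercial rounding: ties away from zero, as used in the printed tables
# (base round() uses banker's rounding, which would turn 38.45 into 38.4).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
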