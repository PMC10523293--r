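#' @importFrom data.table data.table as.data.table rbindlist setorder setnames setcolorder fifelse := .N .SD fread fwrite
#' @importFrom stats rbinom rpois rnbinom runif rmultinom dhyper pchisq setNames
#' @importFrom utils adist head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Report-layer rounding. Base R's \code{round()} rounds half to even
#' (banker's rounding); published clinical tables conventionally round half
#' up, so 58.45 prints as 58.5 rather than 58.4.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage at report precision
#'
#' @param num numerator.
#' @param den denominator.
#' @param digits decimal places (default 1, the granularity used throughout
#'   the report tables).
#' @return numeric percentage, rounded half-up.
#' @export
pct <- function(num, den, digits = 1) {
  if (den == 0) return(NA_real_)
  round_half_up(100 * num / den, digits)
}

## Tokenize with character offsets (0-based, half-open spans).
## Tokens are runs of letters/digits/apostrophes; everything else separates.
tokenize_offsets <- function(text) {
  loc <- stringi::stri_locate_all_regex(text, "[A-Za-z0-9']+")[[1]]
  if (is.na(loc[1, 1])) {
    return(data.table(token = character(), start = integer(), end = integer()))
  }
  data.table(
    token = stringi::stri_sub(text, loc[, 1], loc[, 2]),
    start = as.integer(loc[, 1] - 1L),
    end   = as.integer(loc[, 2])
  )
}

## Split a phrase into lowercase tokens (same rule as tokenize_offsets).
phrase_tokens <- function(phrase) {
  stringi::stri_extract_all_regex(tolower(phrase), "[a-z0-9']+")[[1]]
}

## Locate a multi-token phrase inside a token table; returns integer vector of
## start token indices (possibly empty). Case-insensitive.
find_token_seq <- function(tokens_lower, phrase_toks) {
  k <- length(phrase_toks)
  n <- length(tokens_lower)
  if (k == 0L || n < k) return(integer())
  if (k == 1L) return(which(tokens_lower == phrase_toks))
  cand <- which(tokens_lower == phrase_toks[1])
  cand <- cand[cand + k - 1L <= n]
  if (!length(cand)) return(integer())
  keep <- vapply(cand, function(i) {
    all(tokens_lower[i:(i + k - 1L)] == phrase_toks)
  }, logical(1))
  cand[keep]
}

stop_config <- function(...) {
  stop(structure(class = c("hinstab_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
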