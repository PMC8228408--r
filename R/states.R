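#' Alphanumeric character-state symbols
#'
#' Ordered multistate characters are written with the 36-symbol alphabet
#' `0`-`9`, `A`-`Z`, the scheme used by NEXUS files of phylogenetic software:
#' `'0'` codes value 0 (a substructure absent from a molecule), `'9'` codes 9,
#' `'A'` codes 10 and `'Z'` codes 35.
#'
#' @format A character vector of length 36; `state_symbols[k + 1]` is the
#'   symbol for state value `k`.
#' @export
state_symbols <- c(as.character(0:9), LETTERS)

#' Encode substructure lengths as alphanumeric state symbols
#'
#' Maps non-negative integer lengths onto the 36-symbol state alphabet.
#' Lengths above 35 exceed the alphabet and are clipped to `'Z'` with a
#' warning.
#'
#' @param length integer vector of lengths (>= 0). Length 0 means the
#'   substructure is absent.
#' @return character vector of single symbols from `0-9A-Z`.
#' @seealso [decode_state()]
#' @examples
#' encode_state(c(0, 9, 10, 35))
#' @export
encode_state <- function(length) {
  if (length(length) == 0L) return(character(0))
  if (any(is.na(length))) stop("state lengths must not be NA")
  if (any(length < 0)) stop("state lengths must be >= 0, got ",
                            paste(length[length < 0], collapse = ", "))
  if (any(length != floor(length))) stop("state lengths must be integers")
  if (any(length > 35)) {
    warning(sum(length > 35), " length(s) > 35 clipped to state 'Z'")
    length <- pmin(length, 35)
  }
  state_symbols[length + 1L]
}

#' Decode alphanumeric state symbols to integer values
#'
#' @param symbol character vector of single symbols from `0-9A-Z`
#'   (lower case accepted).
#' @return integer vector of state values in 0..35.
#' @seealso [encode_state()]
#' @export
decode_state <- function(symbol) {
  if (length(symbol) == 0L) return(integer(0))
  idx <- match(toupper(symbol), state_symbols)
  if (any(is.na(idx)))
    stop("invalid state symbol(s): ",
         paste(unique(symbol[is.na(idx)]), collapse = ", "))
  idx - 1L
}
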