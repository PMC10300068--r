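# Luhn mod-16 check digits for hex payloads, as used by the nih
# ("named information for humans") identifier dialect to catch
# transcription errors in hand-copied hashes.
#
# Convention used here: map each hex character to its value 0..15;
# walking right-to-left, double every second value starting with the
# rightmost; any doubled value v >= 16 is replaced by (v div 16) +
# (v mod 16); the check digit is (16 - (sum mod 16)) mod 16, rendered as
# one hex character.

luhn16_sum <- function(vals) {
  n <- length(vals)
  # positions counted from the right; rightmost (i == 1) is doubled
  doubled <- rev(vals)
  idx <- seq_along(doubled) %% 2 == 1
  doubled[idx] <- doubled[idx] * 2L
  over <- doubled >= 16L
  doubled[over] <- doubled[over] %/% 16L + doubled[over] %% 16L
  sum(doubled)
}

hex_values <- function(payload) {
  if (!is.character(payload) || length(payload) != 1L || !nzchar(payload) ||
      !is_hex(payload)) {
    sc_abort("check digits are defined for nonempty hex payloads only",
             "signcite_malformed_payload")
  }
  strtoi(strsplit(tolower(payload), "")[[1]], 16L)
}

#' Luhn mod-16 check digit of a hex payload
#'
#' Computes the single hex character that makes a transcribed payload
#' self-checking: any single-character substitution in the payload
#' changes the check digit.
#'
#' @param hex_payload Nonempty hex string.
#' @return One lowercase hex character.
#' @examples
#' compute_check_digit("f")   # "1"
#' @export
compute_check_digit <- function(hex_payload) {
  s <- luhn16_sum(hex_values(hex_payload))
  hex_chars[((16L - (s %% 16L)) %% 16L) + 1L]
}

#' Verify a payload against its check digit
#'
#' @param hex_payload Nonempty hex string.
#' @param digit Claimed check digit (one hex character).
#' @return `TRUE` iff the digit matches [compute_check_digit()] of the
#'   payload.
#' @export
verify_check_digit <- function(hex_payload, digit) {
  stopifnot(is.character(digit), length(digit) == 1L)
  identical(compute_check_digit(hex_payload), tolower(digit))
}
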