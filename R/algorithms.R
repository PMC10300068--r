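# Registry of cryptographic hash algorithms usable in content signatures.
#
# A content signature names both a digest and the algorithm that produced
# it, so the toolkit keeps an explicit registry mapping short lowercase
# tokens ("sha256") to digest length and a digest function. sha1 and md5
# are registered for interoperability with repositories that expose those
# hashes, but are flagged weak and computing with them warns.

the_algorithms <- new.env(parent = emptyenv())

#' Register a hash algorithm
#'
#' Adds an algorithm to the registry used by [compute_signature()] and the
#' signature parser. The built-in registrations are `sha256` (the default
#' and recommended algorithm), `sha1`, and `md5`; the latter two are
#' considered cryptographically weak and carry a warning when used.
#'
#' @param token Short lowercase algorithm name, e.g. `"sha256"`.
#' @param digest_bits Digest length in bits; must be a positive multiple
#'   of 8.
#' @param digest_fn Function mapping a raw vector (or readable binary
#'   connection) to a raw digest of exactly `digest_bits / 8` bytes.
#' @param weak Logical; if `TRUE`, computing signatures with this
#'   algorithm emits a weak-algorithm warning.
#' @return The registered algorithm definition, invisibly.
#' @export
register_algorithm <- function(token, digest_bits, digest_fn, weak = FALSE) {
  stopifnot(is.character(token), length(token) == 1L, nzchar(token),
            token == tolower(token),
            is.numeric(digest_bits), digest_bits > 0, digest_bits %% 8 == 0,
            is.function(digest_fn))
  alg <- list(token = token, digest_bits = as.integer(digest_bits),
              digest_fn = digest_fn, weak = isTRUE(weak))
  assign(token, alg, envir = the_algorithms)
  invisible(alg)
}

#' Look up a registered hash algorithm
#'
#' @param token Algorithm token (case-insensitive).
#' @return A list with fields `token`, `digest_bits`, `digest_fn`, `weak`.
#' @export
hash_algorithm <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  token <- tolower(token)
  if (!exists(token, envir = the_algorithms, inherits = FALSE)) {
    sc_abort(sprintf("unsupported hash algorithm: '%s'", token),
             "signcite_unsupported_algorithm")
  }
  get(token, envir = the_algorithms, inherits = FALSE)
}

#' List registered algorithm tokens
#' @return Character vector of tokens.
#' @export
list_algorithms <- function() {
  sort(ls(envir = the_algorithms))
}

hex_length <- function(alg) alg$digest_bits %/% 4L

# Built-ins stream connections through openssl's hashers, so arbitrarily
# large files are digested in bounded memory.
.register_builtins <- function() {
  register_algorithm("sha256", 256L, function(x) unclass(openssl::sha256(x)))
  register_algorithm("sha1", 160L, function(x) unclass(openssl::sha1(x)),
                     weak = TRUE)
  register_algorithm("md5", 128L, function(x) unclass(openssl::md5(x)),
                     weak = TRUE)
}

.onLoad <- function(libname, pkgname) {
  .register_builtins()
}
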