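# Content signatures: compute, encode, parse, translate, truncate, verify.
#
# The canonical text form of a signature is a content-hash URI,
# hash://<algorithm>/<hex digest>, with lowercase hexadecimal (each
# character encoding 4 bits). The same digest bytes can be carried by the
# named-information (ni) scheme and by its human-oriented nih variant,
# optionally protected by a Luhn mod-16 check digit; translation between
# schemes preserves the digest exactly and never re-hashes.

hex_chars <- c("0","1","2","3","4","5","6","7","8","9","a","b","c","d","e","f")

raw_to_hex <- function(x) paste(as.character(x), collapse = "")

hex_to_raw <- function(hex) {
  hex <- tolower(hex)
  n <- nchar(hex)
  stopifnot(n %% 2 == 0)
  pairs <- substring(hex, seq(1, n, 2), seq(2, n, 2))
  as.raw(strtoi(pairs, 16L))
}

is_hex <- function(x) grepl("^[0-9a-fA-F]+$", x)

#' Construct a content signature
#'
#' A content signature pairs the raw digest of some exact bytes with the
#' token of the algorithm that produced it. Usually obtained from
#' [compute_signature()] or [parse_signature()] rather than built directly.
#'
#' @param algorithm Registered algorithm token.
#' @param digest Raw vector of exactly `digest_bits / 8` bytes, or the
#'   equivalent full-length hex string.
#' @return An object of class `content_signature`.
#' @export
content_signature <- function(algorithm, digest) {
  alg <- hash_algorithm(algorithm)
  if (is.character(digest)) {
    if (!is_hex(digest) || nchar(digest) != hex_length(alg)) {
      sc_abort("digest hex must be full-length hexadecimal",
               "signcite_malformed_payload")
    }
    digest <- hex_to_raw(digest)
  }
  stopifnot(is.raw(digest))
  if (length(digest) * 8L != alg$digest_bits) {
    sc_abort(sprintf("digest length %d bytes does not match %s (%d bits)",
                     length(digest), alg$token, alg$digest_bits),
             "signcite_malformed_payload")
  }
  structure(list(algorithm = alg$token, digest = digest),
            class = "content_signature")
}

#' Construct a signature prefix
#'
#' A truncated signature: the leading `n` hex characters of a full digest.
#' Prefixes trade collision resistance for readability; see
#' [truncate_signature()].
#'
#' @param algorithm Registered algorithm token.
#' @param prefix_hex Hex string, 1 to the algorithm's full hex length
#'   characters.
#' @return An object of class `signature_prefix`.
#' @export
signature_prefix <- function(algorithm, prefix_hex) {
  alg <- hash_algorithm(algorithm)
  stopifnot(is.character(prefix_hex), length(prefix_hex) == 1L)
  prefix_hex <- tolower(prefix_hex)
  if (!is_hex(prefix_hex)) {
    sc_abort("prefix must be hexadecimal", "signcite_malformed_payload")
  }
  if (nchar(prefix_hex) < 1L || nchar(prefix_hex) > hex_length(alg)) {
    sc_abort("prefix length out of range for algorithm",
             "signcite_invalid_length")
  }
  structure(list(algorithm = alg$token, prefix_hex = prefix_hex),
            class = "signature_prefix")
}

#' @export
is_full_signature <- function(x) inherits(x, "content_signature")

#' @export
is_signature_prefix <- function(x) inherits(x, "signature_prefix")

sig_hex <- function(x) {
  if (is_full_signature(x)) raw_to_hex(x$digest)
  else if (is_signature_prefix(x)) x$prefix_hex
  else if (inherits(x, "parsed_signature")) sig_hex(x$payload)
  else sc_abort("not a signature object", "signcite_not_a_signature")
}

sig_payload <- function(x) {
  if (inherits(x, "parsed_signature")) x$payload else x
}

#' @export
format.content_signature <- function(x, ...) {
  sprintf("hash://%s/%s", x$algorithm, raw_to_hex(x$digest))
}

#' @export
format.signature_prefix <- function(x, ...) {
  sprintf("hash://%s/%s", x$algorithm, x$prefix_hex)
}

#' @export
print.content_signature <- function(x, ...) {
  cat("<content signature> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.signature_prefix <- function(x, ...) {
  cat("<signature prefix> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.content_signature <- function(x, ...) format(x)

#' @export
as.character.signature_prefix <- function(x, ...) format(x)

#' @export
`==.content_signature` <- function(e1, e2) {
  identical(e1$algorithm, e2$algorithm) && identical(e1$digest, e2$digest)
}

as_bytes <- function(content) {
  if (is.raw(content)) return(content)
  if (is.character(content) && length(content) == 1L) {
    return(charToRaw(content))
  }
  sc_abort("content must be a raw vector, single string, or connection",
           "signcite_validation_error")
}

#' Compute the content signature of a byte stream
#'
#' Hashes the exact bytes of `content` and returns a full content
#' signature. Hashing is deterministic and location-agnostic: equal bytes
#' always give equal signatures regardless of where or when they are
#' hashed, and chunked (connection) input gives the same digest as a
#' whole-buffer raw vector.
#'
#' @param content A raw vector, a single character string (hashed as the
#'   bytes of its text — use [hash_file()] or a connection for files), or
#'   a readable binary connection (streamed in bounded memory).
#' @param algorithm Registered algorithm token; default `"sha256"`.
#' @return A [content_signature()].
#' @examples
#' compute_signature("abc")
#' @export
compute_signature <- function(content, algorithm = "sha256") {
  alg <- hash_algorithm(algorithm)
  if (alg$weak) {
    sc_warn(sprintf("'%s' is a weak hash algorithm; prefer sha256",
                    alg$token),
            "signcite_weak_algorithm")
  }
  x <- if (inherits(content, "connection")) content else as_bytes(content)
  digest <- alg$digest_fn(x)
  content_signature(alg$token, digest)
}

#' Compute the content signature of a file
#'
#' Streams the file through the hash function, so files of any size are
#' handled in bounded memory.
#'
#' @inheritParams compute_signature
#' @param path Path to an existing file.
#' @return A [content_signature()].
#' @export
hash_file <- function(path, algorithm = "sha256") {
  if (!file.exists(path)) {
    sc_abort(sprintf("file not found: %s", path), "signcite_storage_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  compute_signature(con, algorithm)
}

# --- parsing ---------------------------------------------------------------

percent_decode <- function(x) {
  if (grepl("%", x, fixed = TRUE)) utils::URLdecode(x) else x
}

#' Parse a content signature from text
#'
#' Recognizes three interchangeable identifier dialects carrying the same
#' digest bytes:
#' \itemize{
#'   \item content-hash URIs, `hash://<alg>/<payload>`;
#'   \item named-information URIs, `ni:///<alg>;<payload>`;
#'   \item human-oriented nih strings, `nih:<alg>;<hex>[;<check digit>]`.
#' }
#' Scheme tokens match case-insensitively and hex payloads are
#' canonicalized to lowercase. Payloads may be hex or (for hash and ni)
#' unpadded or padded base64url; percent-encoded characters are decoded
#' before interpretation. A hex payload shorter than the algorithm's full
#' digest parses as a [signature_prefix()]. An nih check digit, when
#' present, is verified with Luhn mod-16.
#'
#' @param text A single identifier string.
#' @return An object of class `parsed_signature`: a list with `payload`
#'   (a [content_signature()] or [signature_prefix()]), `scheme` (one of
#'   `"hash-uri"`, `"ni"`, `"nih"`), `encoding` (`"hex"` or
#'   `"base64url"`), and `source_text`.
#' @export
parse_signature <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  if (grepl("^hash://", s, ignore.case = TRUE)) {
    rest <- sub("^hash://", "", s, ignore.case = TRUE)
    m <- regmatches(rest, regexec("^([A-Za-z0-9-]+)/(.+)$", rest))[[1]]
    if (length(m) == 0L) {
      sc_abort("malformed hash URI", "signcite_malformed_payload")
    }
    out <- parse_payload(tolower(m[2]), m[3], scheme = "hash-uri")
  } else if (grepl("^ni:///", s, ignore.case = TRUE)) {
    rest <- sub("^ni:///", "", s, ignore.case = TRUE)
    m <- regmatches(rest, regexec("^([A-Za-z0-9-]+);(.+)$", rest))[[1]]
    if (length(m) == 0L) {
      sc_abort("malformed ni URI", "signcite_malformed_payload")
    }
    out <- parse_payload(tolower(m[2]), m[3], scheme = "ni")
  } else if (grepl("^nih:", s, ignore.case = TRUE)) {
    rest <- sub("^nih:", "", s, ignore.case = TRUE)
    m <- regmatches(rest,
                    regexec("^([A-Za-z0-9-]+);([^;]+)(;([0-9a-fA-F]))?$",
                            rest))[[1]]
    if (length(m) == 0L) {
      sc_abort("malformed nih identifier", "signcite_malformed_payload")
    }
    payload <- percent_decode(m[3])
    if (!is_hex(payload)) {
      sc_abort("nih payload must be hexadecimal",
               "signcite_malformed_payload")
    }
    if (nzchar(m[5])) {
      if (!verify_check_digit(tolower(payload), tolower(m[5]))) {
        sc_abort("nih check digit does not match payload",
                 "signcite_malformed_payload")
      }
    }
    out <- parse_payload(tolower(m[2]), payload, scheme = "nih")
  } else {
    sc_abort(sprintf("not a recognized content signature: '%s'", s),
             "signcite_not_a_signature")
  }
  out$source_text <- text
  out
}

parse_payload <- function(token, payload, scheme) {
  alg <- hash_algorithm(token)   # unsupported-algorithm error if unknown
  payload <- percent_decode(payload)
  full_hex <- hex_length(alg)
  if (is_hex(payload)) {
    n <- nchar(payload)
    if (n > full_hex) {
      sc_abort("payload longer than the algorithm's digest",
               "signcite_malformed_payload")
    }
    payload <- tolower(payload)
    p <- if (n == full_hex) content_signature(alg$token, payload)
         else signature_prefix(alg$token, payload)
    structure(list(payload = p, scheme = scheme, encoding = "hex",
                   source_text = NA_character_),
              class = "parsed_signature")
  } else if (grepl("^[A-Za-z0-9_-]+=*$", payload)) {
    if (scheme == "nih") {
      sc_abort("nih payload must be hexadecimal",
               "signcite_malformed_payload")
    }
    bytes <- tryCatch(jsonlite::base64url_dec(sub("=+$", "", payload)),
                      error = function(e) NULL)
    if (is.null(bytes) || length(bytes) * 8L != alg$digest_bits) {
      sc_abort("base64url payload does not decode to a full digest",
               "signcite_malformed_payload")
    }
    structure(list(payload = content_signature(alg$token, bytes),
                   scheme = scheme, encoding = "base64url",
                   source_text = NA_character_),
              class = "parsed_signature")
  } else {
    sc_abort("payload contains characters illegal in hex and base64url",
             "signcite_malformed_payload")
  }
}

#' @export
format.parsed_signature <- function(x, ...) {
  format_signature(x$payload, scheme = x$scheme, encoding = x$encoding)
}

#' @export
print.parsed_signature <- function(x, ...) {
  cat("<parsed signature> ", format(x),
      sprintf("  [%s, %s]", x$scheme, x$encoding), "\n", sep = "")
  invisible(x)
}

# --- formatting ------------------------------------------------------------

b64url_alphabet <- c(LETTERS, letters, 0:9, "-", "_")

# base64url of a 4-bit-granular hex prefix: regroup the bits into 6-bit
# units. Only defined when the bit count is a multiple of 6.
bits_to_base64url <- function(hex) {
  vals <- strtoi(strsplit(hex, "")[[1]], 16L)
  bits <- as.vector(t(sapply(vals, function(v) as.integer(intToBits(v))[4:1])))
  stopifnot(length(bits) %% 6 == 0)
  units <- matrix(bits, nrow = 6)
  idx <- as.integer(2^(5:0) %*% units)
  paste(b64url_alphabet[idx + 1L], collapse = "")
}

percent_encode_reserved <- function(x) {
  x <- gsub("+", "%2B", x, fixed = TRUE)
  x <- gsub("/", "%2F", x, fixed = TRUE)
  gsub("=", "%3D", x, fixed = TRUE)
}

#' Render a signature in a chosen identifier dialect
#'
#' Formats a full signature or prefix as a content-hash URI, an ni URI,
#' or an nih string. Hex output is lowercase; base64url output is
#' unpadded. nih output always appends a Luhn mod-16 check digit.
#'
#' @param payload A [content_signature()], [signature_prefix()], or the
#'   result of [parse_signature()].
#' @param scheme One of `"hash-uri"`, `"ni"`, `"nih"`.
#' @param encoding `"hex"` or `"base64url"` (nih is hex-only).
#' @param percent_encode If `TRUE`, percent-encodes the URI-reserved
#'   characters `+`, `/`, and `=` in the payload (a no-op for hex and
#'   unpadded base64url).
#' @return A single identifier string.
#' @export
format_signature <- function(payload, scheme = c("hash-uri", "ni", "nih"),
                             encoding = c("hex", "base64url"),
                             percent_encode = FALSE) {
  scheme <- match.arg(scheme)
  encoding <- match.arg(encoding)
  payload <- sig_payload(payload)
  alg <- payload$algorithm
  if (encoding == "hex") {
    body <- sig_hex(payload)
  } else {
    if (scheme == "nih") {
      sc_abort("nih identifiers are hex-only",
               "signcite_unsupported_combination")
    }
    if (is_full_signature(payload)) {
      body <- sub("=+$", "", jsonlite::base64url_enc(payload$digest))
    } else {
      nbits <- nchar(payload$prefix_hex) * 4L
      if (nbits %% 6 != 0) {
        sc_abort(sprintf(
          "prefix of %d bits cannot be base64url-encoded (not a multiple of 6)",
          nbits), "signcite_unsupported_combination")
      }
      body <- bits_to_base64url(payload$prefix_hex)
    }
  }
  if (percent_encode) body <- percent_encode_reserved(body)
  switch(scheme,
         "hash-uri" = sprintf("hash://%s/%s", alg, body),
         "ni" = sprintf("ni:///%s;%s", alg, body),
         "nih" = sprintf("nih:%s;%s;%s", alg, body,
                         compute_check_digit(body)))
}

#' Translate a signature between identifier dialects
#'
#' Re-expresses a signature string in another scheme/encoding while
#' preserving the digest bytes exactly. Translation never re-hashes and
#' never crosses algorithms: an md5-based identifier cannot become a
#' sha256-based one.
#'
#' @param text Identifier string in any supported dialect.
#' @param scheme,encoding Target dialect (see [format_signature()]).
#' @param algorithm Optional assertion of the expected algorithm token;
#'   an impossible-translation error is raised if it differs from the
#'   parsed algorithm.
#' @param percent_encode Passed to [format_signature()].
#' @return The translated identifier string.
#' @export
translate_signature <- function(text, scheme = c("hash-uri", "ni", "nih"),
                                encoding = c("hex", "base64url"),
                                algorithm = NULL, percent_encode = FALSE) {
  p <- parse_signature(text)
  if (!is.null(algorithm) &&
      tolower(algorithm) != sig_payload(p)$algorithm) {
    sc_abort(sprintf(
      "cannot translate a %s signature into a %s one: hashes from different algorithms are not interchangeable",
      sig_payload(p)$algorithm, tolower(algorithm)),
      "signcite_impossible_translation")
  }
  format_signature(p$payload, scheme = scheme, encoding = encoding,
                   percent_encode = percent_encode)
}

#' Truncate a signature to a readable prefix
#'
#' Keeps the first `n_chars` hex characters of the digest. Truncation
#' shrinks the keyspace from 16^64 to 16^n (see [keyspace_size()]), so
#' short prefixes trade collision resistance for readability; prefixes
#' shorter than 16 characters trigger a warning.
#'
#' @param sig A full [content_signature()] (or parsed signature).
#' @param n_chars Number of hex characters to keep, 1 to the full length.
#' @return A [signature_prefix()].
#' @export
truncate_signature <- function(sig, n_chars) {
  sig <- sig_payload(sig)
  if (!is_full_signature(sig)) {
    sc_abort("can only truncate a full content signature",
             "signcite_not_a_signature")
  }
  full <- hex_length(hash_algorithm(sig$algorithm))
  if (!is.numeric(n_chars) || length(n_chars) != 1L ||
      n_chars < 1 || n_chars > full || n_chars != round(n_chars)) {
    sc_abort(sprintf("n_chars must be an integer in 1..%d", full),
             "signcite_invalid_length")
  }
  if (n_chars < 16) {
    sc_warn(sprintf(
      "a %d-character prefix has a keyspace of only 16^%d; collisions become plausible",
      n_chars, n_chars), "signcite_short_prefix")
  }
  signature_prefix(sig$algorithm, substr(sig_hex(sig), 1L, n_chars))
}

#' Test whether a (possibly truncated) signature matches a full one
#'
#' @param candidate A [content_signature()] or [signature_prefix()] (or a
#'   parsed signature); a full-length candidate makes this an equality
#'   test.
#' @param full A full [content_signature()].
#' @return `TRUE` iff the algorithms agree and the candidate's hex is a
#'   prefix of the full signature's hex.
#' @export
sig_matches <- function(candidate, full) {
  candidate <- sig_payload(candidate)
  full <- sig_payload(full)
  if (!is_full_signature(full)) {
    sc_abort("'full' must be a full content signature",
             "signcite_not_a_signature")
  }
  identical(candidate$algorithm, full$algorithm) &&
    startsWith(sig_hex(full), sig_hex(candidate))
}

#' Exact keyspace of an n-character hex digest
#'
#' Each hex character encodes 4 bits, so an n-character digest can take
#' 16^n values. Returned as an arbitrary-precision integer: 16 characters
#' already give 2^64 (about 1.8e19) possibilities, and the full 64
#' characters of SHA-256 give 2^256.
#'
#' @param n_chars Number of hex characters (>= 1).
#' @return An [openssl::bignum] holding exactly 16^n.
#' @export
keyspace_size <- function(n_chars) {
  if (!is.numeric(n_chars) || length(n_chars) != 1L || n_chars < 1 ||
      n_chars != round(n_chars)) {
    sc_abort("n_chars must be a positive integer", "signcite_invalid_length")
  }
  openssl::bignum(16L)^openssl::bignum(as.integer(n_chars))
}

#' Verify bytes against a cited signature
#'
#' Recomputes the content signature of `content` with the cited
#' algorithm and compares. A mismatch is a result (evidence of content
#' drift), not an error.
#'
#' @param content Raw vector, string, or connection (see
#'   [compute_signature()]).
#' @param cited A full [content_signature()] or a [signature_prefix()]
#'   (or a parsed signature).
#' @return An object of class `verification_outcome` with `status`
#'   (`"match"`, `"prefix_match"`, or `"mismatch"`) and `observed`, the
#'   full signature actually computed from the bytes.
#' @export
verify_content <- function(content, cited) {
  cited <- sig_payload(cited)
  observed <- suppressWarnings(compute_signature(content, cited$algorithm))
  hit <- sig_matches(cited, observed)
  status <- if (!hit) "mismatch"
            else if (is_full_signature(cited)) "match"
            else "prefix_match"
  structure(list(status = status, observed = observed, cited = cited),
            class = "verification_outcome")
}

#' @export
print.verification_outcome <- function(x, ...) {
  cat(sprintf("<verification> %s\n  observed %s\n", x$status,
              format(x$observed)))
  invisible(x)
}
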