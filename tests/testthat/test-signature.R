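# Content signature computation, parsing, translation, truncation.

test_that("sha256 of 'abc' reproduces the FIPS 180 test vector", {
  sig <- compute_signature("abc")
  expect_equal(
    format(sig),
    "hash://sha256/ba7816bf8f01cfea414140de5dae2223b00361a396177a9cb410ff61f20015ad")
  expect_equal(format(compute_signature(charToRaw("abc"))), format(sig))
})

test_that("hashing is deterministic, stream-invariant, and matches an independent implementation", {
  blobs <- seeded_blobs(100, seed = 11)
  hexes <- character(length(blobs))
  for (i in seq_along(blobs)) {
    b <- blobs[[i]]
    s1 <- compute_signature(b)
    s2 <- compute_signature(b)
    expect_true(s1 == s2)
    expect_equal(format(hash_streamed(b)), format(s1))
    # independent oracle: the digest package's SHA-256
    expect_equal(
      signcite:::sig_hex(s1),
      digest::digest(b, algo = "sha256", serialize = FALSE))
    hexes[i] <- signcite:::sig_hex(s1)
  }
  # distinctness across the corpus
  expect_equal(anyDuplicated(hexes), 0L)
})

test_that("file hashing streams the same digest as in-memory hashing", {
  b <- seeded_blobs(1, seed = 3, min_size = 5000, max_size = 5000)[[1]]
  f <- withr::local_tempfile()
  writeBin(b, f)
  expect_true(hash_file(f) == compute_signature(b))
})

test_that("unknown algorithms and weak algorithms are surfaced", {
  expect_error(compute_signature("abc", "sha3-512"),
               class = "signcite_unsupported_algorithm")
  expect_warning(compute_signature("abc", "md5"),
                 class = "signcite_weak_algorithm")
  expect_warning(s <- compute_signature("abc", "sha1"),
                 class = "signcite_weak_algorithm")
  expect_equal(nchar(signcite:::sig_hex(s)), 40L)  # 160 bits
})

test_that("the printed identifier dialects parse to the same digest bytes", {
  p_hash <- parse_signature(REF$readable64)
  p_ni <- parse_signature(REF$readable_ni)
  expect_s3_class(p_hash$payload, "content_signature")
  expect_equal(p_hash$scheme, "hash-uri")
  expect_equal(p_ni$scheme, "ni")
  expect_identical(p_hash$payload$digest, p_ni$payload$digest)
  expect_length(p_hash$payload$digest, 32L)
})

test_that("scheme tokens match case-insensitively and hex canonicalizes to lowercase", {
  # the paper prints 'Hash://sha256/...' at sentence start
  p <- parse_signature(sub("^hash", "Hash", REF$readable64))
  expect_equal(format(p$payload), REF$readable64)
  p2 <- parse_signature(toupper_payload <- sub(
    "29d30b", "29D30B", REF$readable64))
  expect_equal(format(p2$payload), REF$readable64)
})

test_that("short hex payloads parse as prefixes; malformed payloads error", {
  p <- parse_signature(REF$readable16)
  expect_s3_class(p$payload, "signature_prefix")
  expect_equal(p$payload$prefix_hex, "29d30b566f924355")
  expect_error(parse_signature("hash://sha256/xyz"),
               class = "signcite_malformed_payload")
  expect_error(parse_signature(paste0(REF$readable64, "00")),
               class = "signcite_malformed_payload")
  expect_error(parse_signature("https://example.org/a"),
               class = "signcite_not_a_signature")
  expect_error(parse_signature("hash://sha256/!!!"),
               class = "signcite_malformed_payload")
})

test_that("format(parse(s)) is the identity on canonical printed signatures", {
  for (s in unlist(REF)) {
    expect_equal(format(parse_signature(s)), s)
  }
})

test_that("parse/format round-trips hold for random digests in every dialect", {
  blobs <- seeded_blobs(20, seed = 5)
  for (b in blobs) {
    sig <- compute_signature(b)
    for (scheme in c("hash-uri", "ni")) {
      for (enc in c("hex", "base64url")) {
        txt <- format_signature(sig, scheme, enc)
        back <- parse_signature(txt)
        expect_true(back$payload == sig)
        expect_equal(back$scheme, scheme)
        expect_equal(back$encoding, enc)
        expect_equal(format(back), txt)
      }
    }
    nih <- format_signature(sig, "nih", "hex")
    expect_true(parse_signature(nih)$payload == sig)
  }
})

test_that("base64url output is unpadded and percent-encoding covers reserved characters", {
  sig <- compute_signature("abc")
  b64 <- format_signature(sig, "hash-uri", "base64url")
  expect_false(grepl("=", b64, fixed = TRUE))
  expect_equal(nchar(sub("^hash://sha256/", "", b64)), 43L)  # 256 bits, no pad
  # padded input is accepted on parse
  padded <- paste0(b64, "=")
  expect_true(parse_signature(padded)$payload == sig)
  expect_equal(signcite:::percent_encode_reserved("a+b/c="), "a%2Bb%2Fc%3D")
  # percent-encoded payloads are decoded before interpretation
  pct <- sub("-", "%2D", format_signature(sig, "ni", "base64url"))
  if (grepl("%2D", pct, fixed = TRUE)) {
    expect_true(parse_signature(pct)$payload == sig)
  }
})

test_that("translation preserves digest bytes and is an involution", {
  ni <- translate_signature(REF$readable64, "ni", "hex")
  expect_equal(ni, REF$readable_ni)
  expect_equal(translate_signature(ni, "hash-uri", "hex"), REF$readable64)
  # to its own scheme/encoding: canonical form of the input
  expect_equal(translate_signature(REF$readable64, "hash-uri", "hex"),
               REF$readable64)
  # hex -> base64url -> hex round trip
  b64 <- translate_signature(REF$readable64, "hash-uri", "base64url")
  expect_equal(translate_signature(b64, "hash-uri", "hex"), REF$readable64)
  # translation never crosses algorithms
  expect_error(
    translate_signature(REF$readable64, "ni", "hex", algorithm = "md5"),
    class = "signcite_impossible_translation")
})

test_that("truncation reproduces the printed 32- and 16-character forms", {
  sig <- parse_signature(REF$readable64)
  expect_equal(format(truncate_signature(sig, 32)), REF$readable32)
  expect_warning(p16 <- truncate_signature(sig, 15),
                 class = "signcite_short_prefix")
  expect_silent(p16 <- truncate_signature(sig, 16))
  expect_equal(format(p16), REF$readable16)
  # full-length truncation equals the full hex and matches as full
  p64 <- truncate_signature(sig, 64)
  expect_equal(signcite:::sig_hex(p64), signcite:::sig_hex(sig$payload))
  expect_true(sig_matches(p64, sig$payload))
  expect_error(truncate_signature(sig, 0), class = "signcite_invalid_length")
  expect_error(truncate_signature(sig, 65), class = "signcite_invalid_length")
})

test_that("prefix matching is monotone over all truncation lengths", {
  sig <- compute_signature(seeded_blobs(1, seed = 9)[[1]])
  for (n in 1:64) {
    expect_true(sig_matches(suppressWarnings(truncate_signature(sig, n)),
                            sig))
  }
  expect_true(sig_matches(sig, sig))
  other <- compute_signature("something else")
  expect_false(sig_matches(suppressWarnings(truncate_signature(other, 16)),
                           sig))
})

test_that("keyspace sizes are exact powers of 16", {
  expect_equal(as.character(keyspace_size(16)), "18446744073709551616")
  expect_equal(as.character(keyspace_size(16)), oracle_pow16(16))
  expect_equal(as.character(keyspace_size(32)), oracle_pow16(32))
  # 2^128 printed in full
  expect_equal(as.character(keyspace_size(32)),
               "340282366920938463463374607431768211456")
  expect_equal(as.character(keyspace_size(1)), "16")
  for (n in c(2, 5, 21, 47, 64)) {
    expect_equal(as.character(keyspace_size(n)), oracle_pow16(n))
  }
  expect_error(keyspace_size(0), class = "signcite_invalid_length")
})

test_that("verify_content distinguishes match, prefix_match, and mismatch", {
  b <- seeded_blobs(1, seed = 21)[[1]]
  sig <- compute_signature(b)
  expect_equal(verify_content(b, sig)$status, "match")
  # flip a single bit
  tampered <- b
  tampered[1] <- xor(tampered[1], as.raw(1))
  out <- verify_content(tampered, sig)
  expect_equal(out$status, "mismatch")
  expect_false(out$observed == sig)
  # a prefix of the content's own hash gives prefix_match
  pre <- suppressWarnings(truncate_signature(sig, 16))
  expect_equal(verify_content(b, pre)$status, "prefix_match")
  expect_equal(verify_content(tampered, pre)$status, "mismatch")
  # the outcome always carries the observed full signature
  expect_true(verify_content(tampered, pre)$observed ==
                compute_signature(tampered))
})

test_that("custom algorithms can be registered and used end to end", {
  register_algorithm("toylen", 8L,
                     function(x) as.raw(length(x) %% 256L))
  s <- compute_signature(as.raw(1:18), "toylen")
  expect_equal(format(s), "hash://toylen/12")
  expect_true(parse_signature("hash://toylen/12")$payload == s)
})
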