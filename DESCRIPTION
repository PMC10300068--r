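Package: signcite
Title: Signed Data Citations with Verifiable Content Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for creating and verifying signed data citations:
    customary citations extended with cryptographic content signatures
    (content-hash URIs such as hash://sha256/...). Supports computing,
    parsing, translating, and truncating content signatures; packaging
    reference lists into recursively citable collection descriptions;
    a content-addressed store and location registry for detecting link
    rot and content drift; building and verifying Merkle-style citation
    graphs with PROV provenance emitted as N-Quads; and deterministic
    synthetic corpora and web timelines for testing drift and rot
    detection.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    openssl,
    jsonlite,
    uuid,
    utils,
    stats
Suggests:
    digest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
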