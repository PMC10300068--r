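# Content-addressed repository: bytes live at a path derived from their
# own signature, so the store can always prove it is returning exactly
# the cited content. Layout <root>/<alg>/<hex[1:2]>/<hex[3:4]>/<hex>,
# a two-level fan-out that keeps directory sizes bounded.

#' Open (or create) a content store
#'
#' @param root Directory for the store; created if absent.
#' @return An object of class `content_store`.
#' @export
content_store <- function(root) {
  if (!dir.exists(root)) {
    ok <- dir.create(root, recursive = TRUE, showWarnings = FALSE)
    if (!ok) sc_abort(sprintf("cannot create store root: %s", root),
                      "signcite_storage_error")
  }
  structure(list(root = normalizePath(root)), class = "content_store")
}

#' @export
print.content_store <- function(x, ...) {
  cat("<content store> ", x$root, "\n", sep = "")
  invisible(x)
}

store_path <- function(store, sig) {
  hex <- sig_hex(sig)
  file.path(store$root, sig$algorithm,
            substr(hex, 1, 2), substr(hex, 3, 4), hex)
}

#' Put bytes into the store
#'
#' Stores the content under its own signature. Idempotent: re-putting
#' identical bytes is a no-op. If the derived path already holds
#' different bytes, the store is corrupt and a corruption error is
#' raised rather than silently overwriting.
#'
#' @param store A [content_store()].
#' @param content Raw vector or single string (see [compute_signature()]).
#' @param algorithm Algorithm token for addressing; default `"sha256"`.
#' @return The content's full [content_signature()], invisibly.
#' @export
store_put <- function(store, content, algorithm = "sha256") {
  stopifnot(inherits(store, "content_store"))
  bytes <- as_bytes(content)
  sig <- suppressWarnings(compute_signature(bytes, algorithm))
  path <- store_path(store, sig)
  if (file.exists(path)) {
    existing <- readBin(path, "raw", n = file.size(path))
    if (!identical(existing, bytes)) {
      sc_abort(sprintf(
        "store corruption: %s exists with bytes that do not hash to it",
        format(sig)), "signcite_corruption_error")
    }
    return(invisible(sig))
  }
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({writeBin(bytes, path); TRUE},
                 error = function(e) FALSE)
  if (!ok) sc_abort(sprintf("failed to write %s", path),
                    "signcite_storage_error")
  invisible(sig)
}

store_candidates <- function(store, algorithm, prefix_hex) {
  algdir <- file.path(store$root, algorithm)
  if (!dir.exists(algdir)) return(character())
  files <- list.files(algdir, recursive = TRUE, full.names = FALSE)
  hexes <- basename(files)
  hexes[startsWith(hexes, prefix_hex)]
}

#' Get verified bytes from the store
#'
#' Content is re-hashed before being returned: the store never hands
#' back bytes whose recomputed signature differs from the request, so
#' on-disk tampering surfaces as a corruption error rather than wrong
#' data. A prefix query succeeds only when it is unambiguous.
#'
#' @param store A [content_store()].
#' @param sig A full [content_signature()], a [signature_prefix()], a
#'   parsed signature, or an identifier string.
#' @return An object of class `resolved_content` with fields `content`
#'   (raw), `source` (the store path), and `verification` (a
#'   `verification_outcome` whose status is always `"match"`).
#' @export
store_get <- function(store, sig) {
  stopifnot(inherits(store, "content_store"))
  if (is.character(sig)) sig <- parse_signature(sig)
  sig <- sig_payload(sig)
  if (is_signature_prefix(sig)) {
    hits <- store_candidates(store, sig$algorithm, sig$prefix_hex)
    if (length(hits) == 0L) {
      sc_abort(sprintf("no stored content matches %s", format(sig)),
               "signcite_not_found")
    }
    if (length(hits) > 1L) {
      sc_abort(sprintf("prefix %s is ambiguous; candidates: %s",
                       format(sig),
                       paste(sprintf("hash://%s/%s", sig$algorithm, hits),
                             collapse = ", ")),
               "signcite_ambiguous_prefix",
               candidates = sprintf("hash://%s/%s", sig$algorithm, hits))
    }
    sig <- content_signature(sig$algorithm, hits)
  }
  path <- store_path(store, sig)
  if (!file.exists(path)) {
    sc_abort(sprintf("not in store: %s", format(sig)), "signcite_not_found")
  }
  bytes <- readBin(path, "raw", n = file.size(path))
  outcome <- verify_content(bytes, sig)
  if (outcome$status != "match") {
    sc_abort(sprintf(
      "store corruption: bytes at %s hash to %s, not the requested %s",
      path, format(outcome$observed), format(sig)),
      "signcite_corruption_error", observed = outcome$observed)
  }
  structure(list(content = bytes, source = path, verification = outcome),
            class = "resolved_content")
}

#' @export
print.resolved_content <- function(x, ...) {
  cat(sprintf("<resolved content> %d bytes from %s\n  %s\n",
              length(x$content), x$source, format(x$verification$observed)))
  invisible(x)
}

# Unverified read, for building resolvers that must be able to *observe*
# drifted bytes (verification then happens in the caller, e.g.
# verify_graph()). Returns NULL when absent.
store_read_raw <- function(store, sig) {
  path <- store_path(store, sig_payload(sig))
  if (!file.exists(path)) return(NULL)
  readBin(path, "raw", n = file.size(path))
}

#' Resolver over a content store
#'
#' Builds the resolver function used by the graph operations: it maps a
#' full signature to raw bytes from the store, or `NULL` when absent.
#' Bytes are returned unverified so that callers (e.g. [verify_graph()])
#' can classify drifted content instead of erroring.
#'
#' @param store A [content_store()].
#' @return `function(sig) -> raw or NULL`.
#' @export
store_resolver <- function(store) {
  stopifnot(inherits(store, "content_store"))
  function(sig) store_read_raw(store, sig)
}
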