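# Signed citations and collection descriptions.
#
# A signed citation is a customary citation (creators, date, title,
# optional access locations) extended with a content signature of the
# cited bytes. Because signatures are location-agnostic, access events
# are optional convenience metadata, not part of the identity.
#
# A collection description is a plain-text reference list whose entries
# are themselves signed citations; hashing its canonical ASCII bytes
# yields one signature that recursively cites every entry.

#' Construct a signed citation
#'
#' @param creators Character vector of creator names.
#' @param date Publication year or date string.
#' @param title Title text.
#' @param signature A full [content_signature()] (or a parseable
#'   identifier string) of the cited bytes.
#' @param access_events Optional data frame with columns `location` and
#'   `accessed` (ISO 8601 date strings), one row per retrieval; may be
#'   empty or `NULL` because signatures identify content independently
#'   of location.
#' @return An object of class `signed_citation`.
#' @export
signed_citation <- function(creators, date, title, signature,
                            access_events = NULL) {
  if (is.character(signature)) {
    signature <- sig_payload(parse_signature(signature))
  }
  signature <- sig_payload(signature)
  if (!is_full_signature(signature)) {
    sc_abort("a signed citation requires one full content signature",
             "signcite_validation_error")
  }
  if (is.null(access_events)) {
    access_events <- data.frame(location = character(),
                                accessed = character())
  }
  stopifnot(is.data.frame(access_events),
            all(c("location", "accessed") %in% names(access_events)))
  structure(list(creators = as.character(creators),
                 date = as.character(date),
                 title = as.character(title),
                 signature = signature,
                 access_events = access_events),
            class = "signed_citation")
}

#' Render a signed citation as text
#'
#' Layout: `<Creators>. <Date>. <Title> <hash://...>` followed, for each
#' access event, by ` Accessed at <location> on <date>.` With no access
#' events the text ends after the signature.
#'
#' @param citation A [signed_citation()].
#' @return A single string.
#' @export
render_signed_citation <- function(citation) {
  stopifnot(inherits(citation, "signed_citation"))
  head <- sprintf("%s. %s. %s %s",
                  paste(citation$creators, collapse = ", "),
                  citation$date, citation$title,
                  format(citation$signature))
  ev <- citation$access_events
  if (nrow(ev) == 0L) return(head)
  clauses <- sprintf(" Accessed at %s on %s.", ev$location, ev$accessed)
  paste0(head, paste(clauses, collapse = ""))
}

#' @export
print.signed_citation <- function(x, ...) {
  cat(render_signed_citation(x), "\n")
  invisible(x)
}

#' Extract every content signature from free text
#'
#' Scans arbitrary prose for hash://, ni:///, and nih: tokens and parses
#' each one, preserving order of appearance and duplicates. Surrounding
#' punctuation is stripped. Malformed candidates (e.g. illegal payload
#' characters) are skipped, not fatal; they are reported in the
#' `diagnostics` attribute of the result.
#'
#' @param text A character string (vectors are collapsed with newlines).
#' @return A list of `parsed_signature` objects, in order of appearance,
#'   with attribute `diagnostics`: a character vector describing any
#'   skipped candidates.
#' @export
extract_signatures <- function(text) {
  text <- paste(text, collapse = "\n")
  pat <- "(hash://[A-Za-z0-9-]+/[A-Za-z0-9_%=+-]+|ni:///[A-Za-z0-9-]+;[A-Za-z0-9_%=+-]+|nih:[A-Za-z0-9-]+(;[A-Za-z0-9_%-]+)+)"
  hits <- regmatches(text, gregexpr(pat, text, ignore.case = TRUE))[[1]]
  out <- list()
  diagnostics <- character()
  for (h in hits) {
    # strip sentence punctuation that the charset can pick up at the end
    h <- sub("[.,;:]+$", "", h)
    p <- tryCatch(parse_signature(h), error = function(e) e)
    if (inherits(p, "error")) {
      diagnostics <- c(diagnostics,
                       sprintf("skipped '%s': %s", h, conditionMessage(p)))
    } else {
      out[[length(out) + 1L]] <- p
    }
  }
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Package citation texts into a collection description
#'
#' Joins the entries into one canonical ASCII document and signs its
#' exact bytes, making the whole collection citable by a single
#' signature. Canonical form: entries separated by one blank line, LF
#' line endings, a single trailing newline. Entry order matters — the
#' hash of \{a,b\} differs from the hash of \{b,a\} — so an optional
#' lexicographic `sort` is available for collections with set semantics.
#'
#' @param entries Character vector of citation texts (ASCII;
#'   `allow_utf8 = TRUE` relaxes this to UTF-8).
#' @param sort If `TRUE`, entries are lexicographically ordered (in the C
#'   locale) before joining, giving a canonical set representation.
#' @param allow_utf8 Permit non-ASCII entries, hashed as UTF-8 bytes.
#' @return An object of class `collection_description` with fields
#'   `entries`, `canonical_bytes` (raw), and `signature` (sha256 of the
#'   canonical bytes).
#' @export
package_collection <- function(entries, sort = FALSE, allow_utf8 = FALSE) {
  entries <- as.character(entries)
  if (!allow_utf8) {
    bad <- which(vapply(entries,
                        function(e) any(charToRaw(enc2utf8(e)) > 0x7f),
                        logical(1)))
    if (length(bad) > 0L) {
      sc_abort(sprintf(
        "entry %d is not ASCII-encodable (set allow_utf8 = TRUE to hash UTF-8 bytes)",
        bad[1]), "signcite_encoding_error")
    }
  }
  if (sort) {
    old <- Sys.getlocale("LC_COLLATE")
    on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
    Sys.setlocale("LC_COLLATE", "C")
    entries <- base::sort(entries)
  }
  text <- if (length(entries) == 0L) "" else
    paste0(paste(entries, collapse = "\n\n"), "\n")
  canonical <- charToRaw(enc2utf8(text))
  structure(list(entries = entries,
                 canonical_bytes = canonical,
                 signature = compute_signature(canonical, "sha256")),
            class = "collection_description")
}

#' @export
print.collection_description <- function(x, ...) {
  cat(sprintf("<collection description> %d entries\n  %s\n",
              length(x$entries), format(x$signature)))
  invisible(x)
}
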