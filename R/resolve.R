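# Verified resolution: turn a content signature back into bytes by
# trying a sequence of sources — local store first, then registries
# paired with a fetcher. Every candidate is verified against the
# requested signature before being returned; drifted or failing
# candidates are logged and skipped.
#
# The fetcher is injectable (function(url) -> raw or NULL) so tests and
# simulations run against an in-memory web; a real HTTP fetcher can be
# plugged in by the caller. Network access never happens unless a
# fetcher is supplied.

#' Describe a registry + fetcher resolution source
#'
#' @param registry A [signature_registry()] listing known locations.
#' @param fetcher `function(url) -> raw or NULL`; `NULL` bytes mean the
#'   location failed.
#' @return A source usable in [resolve_signature()].
#' @export
registry_source <- function(registry, fetcher) {
  stopifnot(inherits(registry, "signature_registry"), is.function(fetcher))
  structure(list(registry = registry, fetcher = fetcher),
            class = "registry_source")
}

#' Resolve a signature to verified bytes
#'
#' Tries each source in order. A [content_store()] source is queried
#' directly; a [registry_source()] is asked for every location ever
#' observed serving the signature (most recent observation first) and
#' each location is fetched and verified. The first candidate whose
#' recomputed signature matches is returned; everything else goes into
#' the attempt log.
#'
#' @param sig A full [content_signature()] (or identifier string).
#' @param sources List of [content_store()] and/or [registry_source()]
#'   objects, tried in order.
#' @return A `resolved_content` object (`content`, `source`,
#'   `verification`) with attribute `attempts`. If no source yields
#'   verified bytes, an unresolvable error carrying the attempt log in
#'   its `attempts` field is raised.
#' @export
resolve_signature <- function(sig, sources) {
  if (is.character(sig)) sig <- parse_signature(sig)
  sig <- sig_payload(sig)
  if (length(sources) == 0L) {
    sc_abort("at least one source is required", "signcite_validation_error")
  }
  if (inherits(sources, c("content_store", "registry_source"))) {
    sources <- list(sources)
  }
  attempts <- character()
  for (src in sources) {
    if (inherits(src, "content_store")) {
      res <- tryCatch(store_get(src, sig), signcite_error = function(e) e)
      if (inherits(res, "resolved_content")) {
        attr(res, "attempts") <- attempts
        return(res)
      }
      attempts <- c(attempts,
                    sprintf("store %s: %s", src$root, conditionMessage(res)))
    } else if (inherits(src, "registry_source")) {
      recs <- query_registry(src$registry, signature = sig)
      if (nrow(recs) > 0L) {
        # most recent observation of the content first
        recs <- recs[order(recs$observed_at, decreasing = TRUE), ,
                     drop = FALSE]
      }
      for (loc in unique(recs$location)) {
        bytes <- src$fetcher(loc)
        if (is.null(bytes)) {
          attempts <- c(attempts, sprintf("%s: fetch failed (link rot?)",
                                          loc))
          next
        }
        outcome <- verify_content(bytes, sig)
        if (outcome$status == "match") {
          res <- structure(list(content = bytes, source = loc,
                                verification = outcome),
                           class = "resolved_content")
          attr(res, "attempts") <- attempts
          return(res)
        }
        attempts <- c(attempts,
                      sprintf("%s: content drift, observed %s", loc,
                              format(outcome$observed)))
      }
      if (nrow(recs) == 0L) {
        attempts <- c(attempts, "registry: no known location for signature")
      }
    } else {
      sc_abort("sources must be content stores or registry sources",
               "signcite_validation_error")
    }
  }
  sc_abort(sprintf("unresolvable: %s (%d attempts failed)", format(sig),
                   length(attempts)),
           "signcite_unresolvable", attempts = attempts)
}

#' Resolve a URL through its registered signature
#'
#' Uses the URL as an alias for content: the URL's most recent
#' *successful* registry record supplies the signature, which is then
#' resolved through [resolve_signature()] — the live URL itself is not
#' re-queried first. This returns the originally observed bytes even
#' after the remote location drifts, and older signatures for the same
#' URL remain queryable as earlier versions.
#'
#' @param url Location URI previously observed in the registry.
#' @param registry A [signature_registry()] holding observations of the
#'   URL.
#' @param sources Sources for [resolve_signature()] (e.g. a local
#'   [content_store()]).
#' @return A `resolved_content` object, with attribute `alias_signature`.
#' @export
resolve_location <- function(url, registry, sources) {
  hist <- query_registry(registry, location = url)
  hist <- hist[hist$outcome != FAILED_MARKER, , drop = FALSE]
  if (nrow(hist) == 0L) {
    sc_abort(sprintf(
      "no successful observation of %s on record; cannot use it as a content alias",
      url), "signcite_no_alias")
  }
  hist <- hist[order(hist$observed_at, seq_len(nrow(hist))), , drop = FALSE]
  sig <- parse_signature(hist$outcome[nrow(hist)])
  res <- resolve_signature(sig, sources)
  attr(res, "alias_signature") <- sig_payload(sig)
  res
}
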