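# Location registries: append-only tables of lightweight observation
# records — a timestamp, a URL, and the content signature served there
# (or a failure marker). Registries are what make signed citations
# repairable: when a cited location rots or drifts, alternative
# locations of the same signature can be looked up.
#
# Serialization is TSV with header (observed_at, location, outcome);
# outcome is a hash:// URI or the marker "FAILED"; timestamps are UTC
# ISO 8601 with seconds.

FAILED_MARKER <- "FAILED"

new_registry_df <- function() {
  data.frame(observed_at = character(), location = character(),
             outcome = character(), stringsAsFactors = FALSE)
}

#' Create or load a location registry
#'
#' @param path Optional TSV file backing the registry. If it exists it is
#'   loaded; new observations are appended to it. With `path = NULL` the
#'   registry is in-memory only.
#' @return An object of class `signature_registry` (records are held in
#'   an environment so appends mutate the registry in place, preserving
#'   append-only file semantics).
#' @export
signature_registry <- function(path = NULL) {
  env <- new.env(parent = emptyenv())
  env$records <- new_registry_df()
  env$path <- path
  if (!is.null(path) && file.exists(path)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("observed_at", "location", "outcome")
    if (!all(need %in% names(df))) {
      sc_abort(sprintf("registry file %s lacks columns %s", path,
                       paste(need, collapse = ", ")),
               "signcite_validation_error")
    }
    env$records <- df[, need]
  }
  structure(list(env = env), class = "signature_registry")
}

#' @export
print.signature_registry <- function(x, ...) {
  cat(sprintf("<signature registry> %d records%s\n",
              nrow(x$env$records),
              if (is.null(x$env$path)) " (in-memory)"
              else paste0(" @ ", x$env$path)))
  invisible(x)
}

valid_timestamp <- function(x) {
  grepl("^\\d{4}-\\d{2}-\\d{2}([T ]\\d{2}:\\d{2}:\\d{2}(Z|[+-]\\d{2}:?\\d{2})?)?$",
        x)
}

valid_uri <- function(x) grepl("^[A-Za-z][A-Za-z0-9+.-]*:\\S+$", x)

#' Append one observation to a registry
#'
#' Records that at `observed_at` the given location served content with
#' the given signature (or failed to respond). Records are append-only
#' and never rewritten; re-observations of the same location accumulate
#' chronologically.
#'
#' @param registry A [signature_registry()].
#' @param location URI observed.
#' @param outcome A full [content_signature()] (or identifier string),
#'   or `NA`/`"FAILED"` for an unreachable location.
#' @param observed_at ISO 8601 UTC timestamp string; defaults to now.
#' @return The appended record as a one-row data frame, invisibly.
#' @export
register_observation <- function(registry, location, outcome,
                                 observed_at = format(Sys.time(),
                                   "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) {
  stopifnot(inherits(registry, "signature_registry"))
  if (!is.character(location) || length(location) != 1L ||
      !valid_uri(location)) {
    sc_abort(sprintf("not a valid URI: '%s'", location),
             "signcite_validation_error")
  }
  if (!is.character(observed_at) || length(observed_at) != 1L ||
      !valid_timestamp(observed_at)) {
    sc_abort(sprintf("not an ISO 8601 timestamp: '%s'", observed_at),
             "signcite_validation_error")
  }
  outcome_chr <- if (length(outcome) == 1L &&
                     (is.na(outcome) || identical(outcome, FAILED_MARKER))) {
    FAILED_MARKER
  } else {
    if (is.character(outcome)) outcome <- parse_signature(outcome)
    outcome <- sig_payload(outcome)
    if (!is_full_signature(outcome)) {
      sc_abort("an observation outcome must be a full signature or FAILED",
               "signcite_validation_error")
    }
    format(outcome)
  }
  rec <- data.frame(observed_at = observed_at, location = location,
                    outcome = outcome_chr, stringsAsFactors = FALSE)
  env <- registry$env
  env$records <- rbind(env$records, rec)
  if (!is.null(env$path)) {
    write_header <- !file.exists(env$path) || file.size(env$path) == 0
    con <- file(env$path, "a")
    on.exit(close(con))
    if (write_header) {
      writeLines("observed_at\tlocation\toutcome", con)
    }
    writeLines(paste(rec$observed_at, rec$location, rec$outcome,
                     sep = "\t"), con)
  }
  invisible(rec)
}

#' Query a registry
#'
#' @param registry A [signature_registry()].
#' @param signature Optional: restrict to records whose outcome is this
#'   signature (all locations ever observed serving that content).
#' @param location Optional: restrict to this location's history, in
#'   chronological (file) order.
#' @param latest_per_location If `TRUE`, keep only each location's most
#'   recent record (after the other filters).
#' @return A data frame of records; empty results are valid.
#' @export
query_registry <- function(registry, signature = NULL, location = NULL,
                           latest_per_location = FALSE) {
  stopifnot(inherits(registry, "signature_registry"))
  df <- registry$env$records
  if (!is.null(signature)) {
    if (is.character(signature)) signature <- parse_signature(signature)
    target <- format(sig_payload(signature))
    df <- df[df$outcome == target, , drop = FALSE]
  }
  if (!is.null(location)) {
    df <- df[df$location == location, , drop = FALSE]
  }
  if (latest_per_location && nrow(df) > 0L) {
    # stable: order by timestamp within location, ties broken by file order
    df <- df[order(df$location, df$observed_at,
                   seq_len(nrow(df))), , drop = FALSE]
    df <- df[!duplicated(df$location, fromLast = TRUE), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Classify a pair of consecutive observations of one location
#'
#' Truth table over (previous, current):
#' \itemize{
#'   \item no previous record, any current: `"initial"` — a baseline, not
#'     a change (link rot and drift are defined relative to earlier
#'     successful observations);
#'   \item success then success with the same signature: `"unchanged"`;
#'   \item success then success with a different signature:
#'     `"content_drift"`;
#'   \item success then failure: `"link_rot"`;
#'   \item failure then failure: `"unchanged"` (still down, nothing new
#'     lost);
#'   \item failure then success: `"initial"` (content observed for the
#'     first time at this location).
#' }
#'
#' @param previous A registry record (one-row data frame or list with
#'   `location` and `outcome`), or `NULL` for a first observation.
#' @param current The newer record for the same location.
#' @return One of `"initial"`, `"unchanged"`, `"content_drift"`,
#'   `"link_rot"`.
#' @export
classify_observation <- function(previous, current) {
  cur <- as.list(current)
  if (is.null(previous)) {
    return("initial")
  }
  prev <- as.list(previous)
  if (!identical(as.character(prev$location), as.character(cur$location))) {
    sc_abort("cannot compare observations of different locations",
             "signcite_invalid_comparison")
  }
  p_ok <- !identical(as.character(prev$outcome), FAILED_MARKER)
  c_ok <- !identical(as.character(cur$outcome), FAILED_MARKER)
  if (p_ok && c_ok) {
    if (identical(as.character(prev$outcome), as.character(cur$outcome)))
      "unchanged" else "content_drift"
  } else if (p_ok && !c_ok) {
    "link_rot"
  } else if (!p_ok && !c_ok) {
    "unchanged"
  } else {
    "initial"
  }
}

#' Classify every location's full observation history
#'
#' Walks each location's chronological records pairwise with
#' [classify_observation()] and reports the most severe status seen:
#' `content_drift` and `link_rot` dominate `unchanged`/`initial` (a
#' location that ever drifted is a drifted location). When both occur,
#' the later event wins.
#'
#' @param registry A [signature_registry()].
#' @return Data frame with columns `location` and `status`.
#' @export
classify_registry <- function(registry) {
  df <- registry$env$records
  locs <- unique(df$location)
  status <- vapply(locs, function(loc) {
    h <- df[df$location == loc, , drop = FALSE]
    h <- h[order(h$observed_at, seq_len(nrow(h))), , drop = FALSE]
    last_change <- "initial"
    seen_change <- FALSE
    for (i in seq_len(nrow(h))) {
      prev <- if (i == 1L) NULL else h[i - 1L, ]
      st <- classify_observation(prev, h[i, ])
      if (st %in% c("content_drift", "link_rot")) {
        last_change <- st
        seen_change <- TRUE
      } else if (!seen_change && st == "unchanged") {
        last_change <- "unchanged"
      }
    }
    last_change
  }, character(1))
  data.frame(location = locs, status = unname(status),
             stringsAsFactors = FALSE)
}
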