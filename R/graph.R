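# Recursive citation graphs.
#
# Because a collection description embeds the content signatures of the
# items it cites, and is itself cited by its own signature, a single
# root signature pins down an entire Merkle-style DAG of content: no
# byte anywhere in the graph can change without invalidating every
# signature on the path up to the root. Building a graph means
# resolving the root, verifying it, extracting the signatures embedded
# in its (verified) bytes, and recursing.
#
# Acquisition provenance — how and from where each piece of content was
# obtained — is recorded as PROV N-Quads using three predicates:
# prov#used (the location), prov#generated (the content signature), and
# prov#startedAtTime. The graph label of each quad is the acquisition
# activity's URN, making every acquisition self-describing.

PROV_USED <- "http://www.w3.org/ns/prov#used"
PROV_GENERATED <- "http://www.w3.org/ns/prov#generated"
PROV_STARTED <- "http://www.w3.org/ns/prov#startedAtTime"
XSD_DATETIME <- "http://www.w3.org/2001/XMLSchema#dateTime"

#' Describe a content acquisition event
#'
#' @param used_location URI the content was retrieved from.
#' @param generated Full [content_signature()] (or identifier string) of
#'   the retrieved bytes.
#' @param started_at ISO 8601 UTC timestamp; defaults to now.
#' @param activity_id URN identifying the acquisition activity; defaults
#'   to a fresh `urn:uuid:`.
#' @return An object of class `acquisition_event`.
#' @export
acquisition_event <- function(used_location, generated,
                              started_at = format(Sys.time(),
                                "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                              activity_id = paste0("urn:uuid:",
                                                   uuid::UUIDgenerate())) {
  if (!valid_uri(used_location)) {
    sc_abort(sprintf("not a valid URI: '%s'", used_location),
             "signcite_validation_error")
  }
  if (!valid_uri(activity_id)) {
    sc_abort(sprintf("not a valid URI: '%s'", activity_id),
             "signcite_validation_error")
  }
  if (!valid_timestamp(started_at)) {
    sc_abort(sprintf("not an ISO 8601 timestamp: '%s'", started_at),
             "signcite_validation_error")
  }
  if (is.character(generated)) generated <- parse_signature(generated)
  generated <- sig_payload(generated)
  if (!is_full_signature(generated)) {
    sc_abort("an acquisition generates a full content signature",
             "signcite_validation_error")
  }
  structure(list(activity_id = activity_id, used_location = used_location,
                 generated = generated, started_at = started_at),
            class = "acquisition_event")
}

#' Record an acquisition as PROV N-Quads
#'
#' Emits exactly three quads per event — what location the activity
#' used, what content signature it generated, and when it started —
#' in that fixed order, labelled with the activity URN.
#'
#' @param event An [acquisition_event()].
#' @return Character vector of three N-Quads lines.
#' @export
record_acquisition <- function(event) {
  stopifnot(inherits(event, "acquisition_event"))
  a <- event$activity_id
  c(nq_line(a, PROV_USED, nq_iri(event$used_location), a),
    nq_line(a, PROV_GENERATED, nq_iri(format(event$generated)), a),
    nq_line(a, PROV_STARTED,
            nq_literal(event$started_at, XSD_DATETIME), a))
}

# Decode stored bytes to text for signature scanning. Random binary
# blobs (leaves) contain NULs / invalid sequences; drop NULs and declare
# latin1 so every byte is a valid character — embedded signatures are
# pure ASCII and survive unchanged.
bytes_to_scan_text <- function(bytes) {
  txt <- rawToChar(bytes[bytes != as.raw(0L)])
  Encoding(txt) <- "latin1"
  txt
}

# Extract cited signatures from verified content. RDF content: IRIs in
# subject and object position with the hash scheme, plus a textual scan
# of literals (graphs embed hash URIs both ways). Text content: plain
# scan. Returns list(signatures = list of full content_signatures in
# order of appearance, medium = "text"|"rdf").
extract_citations <- function(bytes) {
  txt <- bytes_to_scan_text(bytes)
  if (looks_like_nquads(txt)) {
    df <- parse_nquads(txt)
    cands <- character()
    for (i in seq_len(nrow(df))) {
      if (grepl("^hash://", df$subject[i], ignore.case = TRUE)) {
        cands <- c(cands, df$subject[i])
      }
      if (df$object_is_iri[i] &&
          grepl("^hash://", df$object[i], ignore.case = TRUE)) {
        cands <- c(cands, df$object[i])
      } else if (!df$object_is_iri[i]) {
        lits <- extract_signatures(df$object[i])
        cands <- c(cands, vapply(lits, function(p) format(sig_payload(p)),
                                 character(1)))
      }
    }
    sigs <- list()
    for (s in cands) {
      p <- tryCatch(parse_signature(s), error = function(e) NULL)
      if (!is.null(p) && is_full_signature(sig_payload(p))) {
        sigs[[length(sigs) + 1L]] <- sig_payload(p)
      }
    }
    list(signatures = sigs, medium = "rdf")
  } else {
    hits <- extract_signatures(txt)
    sigs <- Filter(function(p) is_full_signature(sig_payload(p)), hits)
    list(signatures = lapply(sigs, sig_payload), medium = "text")
  }
}

# Shared depth-first traversal. Returns per-node status in traversal
# order; edges only ever originate from verified nodes (unverified
# content cannot be trusted to cite anything).
traverse_graph <- function(root, resolver) {
  if (is.character(root)) root <- parse_signature(root)
  root <- sig_payload(root)
  if (!is_full_signature(root)) {
    sc_abort("graph root must be a full content signature",
             "signcite_not_a_signature")
  }
  nodes <- character()      # canonical hash URIs, traversal order
  status <- character()     # verified | drifted | unreachable
  edges <- data.frame(container = character(), referenced = character(),
                      medium = character(), stringsAsFactors = FALSE)
  visited <- new.env(parent = emptyenv())

  visit <- function(sig) {
    uri <- format(sig)
    if (exists(uri, envir = visited, inherits = FALSE)) return(invisible())
    assign(uri, TRUE, envir = visited)
    bytes <- resolver(sig)
    if (is.null(bytes)) {
      nodes <<- c(nodes, uri); status <<- c(status, "unreachable")
      return(invisible())
    }
    outcome <- verify_content(bytes, sig)
    if (outcome$status != "match") {
      nodes <<- c(nodes, uri); status <<- c(status, "drifted")
      return(invisible())
    }
    nodes <<- c(nodes, uri); status <<- c(status, "verified")
    ext <- extract_citations(bytes)
    for (child in ext$signatures) {
      child_uri <- format(child)
      if (child_uri == uri) next  # content cannot cite its own hash
      edges <<- rbind(edges,
                      data.frame(container = uri, referenced = child_uri,
                                 medium = ext$medium,
                                 stringsAsFactors = FALSE))
      visit(child)
    }
    invisible()
  }
  visit(root)
  list(root = format(root),
       nodes = data.frame(signature = nodes, status = status,
                          stringsAsFactors = FALSE),
       edges = edges)
}

#' Build a citation graph from a root signature
#'
#' Resolves the root, verifies its bytes, extracts every embedded
#' content signature (plain-text scan for text content; subject/object
#' IRIs plus literal scan for N-Quads content), and recurses depth-first
#' with a visited set. Children that cannot be resolved, or whose bytes
#' no longer match their cited signature, are recorded in `unresolved`
#' and traversal continues.
#'
#' @param root Full [content_signature()] or identifier string.
#' @param resolver `function(sig) -> raw or NULL`, e.g.
#'   [store_resolver()].
#' @return An object of class `citation_graph`: `root`, `nodes`
#'   (character vector of verified hash URIs in traversal order),
#'   `edges` (data frame `container`, `referenced`, `medium`), and
#'   `unresolved` (data frame `signature`, `reason`).
#' @export
build_graph <- function(root, resolver) {
  tr <- traverse_graph(root, resolver)
  ok <- tr$nodes$status == "verified"
  unresolved <- data.frame(
    signature = tr$nodes$signature[!ok],
    reason = ifelse(tr$nodes$status[!ok] == "unreachable",
                    "not-found", "drift"),
    stringsAsFactors = FALSE)
  structure(list(root = tr$root,
                 nodes = tr$nodes$signature[ok],
                 edges = tr$edges,
                 unresolved = unresolved),
            class = "citation_graph")
}

#' @export
print.citation_graph <- function(x, ...) {
  cat(sprintf("<citation graph> %d nodes, %d edges, %d unresolved\n  root %s\n",
              length(x$nodes), nrow(x$edges), nrow(x$unresolved), x$root))
  invisible(x)
}

#' Verify every node reachable from a root signature
#'
#' Re-resolves and re-hashes all content reachable from the root.
#' Statuses: `verified` (bytes match the citing signature), `drifted`
#' (a source produced bytes, but they hash differently), `unreachable`
#' (no source produced bytes). Deterministic for a fixed resolver state.
#'
#' @inheritParams build_graph
#' @return An object of class `verification_report`: `root`, `nodes`
#'   (data frame `signature`, `status`), and `counts` (named vector over
#'   the three statuses, summing to the number of distinct signatures
#'   seen).
#' @export
verify_graph <- function(root, resolver) {
  tr <- traverse_graph(root, resolver)
  counts <- c(verified = sum(tr$nodes$status == "verified"),
              drifted = sum(tr$nodes$status == "drifted"),
              unreachable = sum(tr$nodes$status == "unreachable"))
  structure(list(root = tr$root, nodes = tr$nodes, counts = counts),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("<verification report> root %s\n  %s\n", x$root,
              paste(names(x$counts), x$counts, sep = ": ",
                    collapse = ", ")))
  invisible(x)
}

#' Render a graph's leaves as a signed reference list
#'
#' Produces one citation entry per leaf (nodes with no outgoing edges)
#' in traversal order, using the signed-citation template. Leaves
#' without metadata get placeholder creator/title fields; the signature
#' is always real. The result can be fed straight back into
#' [package_collection()] to mint a new citable collection.
#'
#' @param graph A [build_graph()] result.
#' @param metadata Optional lookup: a `function(signature_uri)` returning
#'   a list with any of `creators`, `date`, `title`, `access_events`, or
#'   a named list keyed by signature URI.
#' @return Character vector of citation texts, one per leaf.
#' @export
render_reference_list <- function(graph, metadata = NULL) {
  stopifnot(inherits(graph, "citation_graph"))
  leaves <- setdiff(graph$nodes, unique(graph$edges$container))
  lookup <- if (is.function(metadata)) metadata
            else function(uri) metadata[[uri]]
  vapply(leaves, function(uri) {
    md <- if (is.null(metadata)) NULL else lookup(uri)
    cit <- signed_citation(
      creators = md$creators %||% "Unknown creator",
      date = md$date %||% "n.d",
      title = md$title %||% "Untitled content",
      signature = parse_signature(uri),
      access_events = md$access_events)
    render_signed_citation(cit)
  }, character(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count distinct resources matching a pattern in an N-Quads document
#'
#' Scans subject and object IRIs of every parseable quad and counts the
#' distinct IRIs matching the pattern (a regular expression).
#' Unparseable lines are skipped and reported via the `skipped`
#' attribute.
#'
#' @param quads N-Quads text (string or lines).
#' @param pattern Regular expression matched against IRIs.
#' @return Integer count of distinct matching IRIs, with attributes
#'   `resources` (the IRIs) and `skipped` (diagnostics).
#' @export
tally_resources <- function(quads, pattern) {
  df <- parse_nquads(quads)
  iris <- c(df$subject, df$object[df$object_is_iri])
  hits <- unique(iris[grepl(pattern, iris)])
  structure(length(hits), resources = hits,
            skipped = attr(df, "skipped"))
}

# Relation vocabulary for claims about distinct digital assets.
RELATION_IRIS <- c(
  "same-as" = "http://www.w3.org/2002/07/owl#sameAs",
  "different-from" = "http://www.w3.org/2002/07/owl#differentFrom",
  "derived-from" = "http://www.w3.org/ns/prov#wasDerivedFrom")

#' Assert a relation claim between two content signatures
#'
#' Claims record opinions — e.g. that two byte-wise different images
#' depict the same thing — without ever altering content identity; they
#' are additive annotations, separable from the structural citation
#' graph. A `different-from` claim between equal signatures is a
#' contradiction (identical bytes cannot be different content) and is
#' rejected.
#'
#' @param subject,object Full [content_signature()]s (or identifier
#'   strings).
#' @param relation `"same-as"`, `"different-from"`, `"derived-from"`, or
#'   a custom IRI.
#' @param asserter Optional name of who makes the claim.
#' @param asserted_at Optional ISO 8601 timestamp.
#' @param claim_id URN for the claim; defaults to a fresh `urn:uuid:`.
#' @return Character vector of N-Quads lines (the relation quad first,
#'   then attribution/time annotations if supplied).
#' @export
assert_relation <- function(subject, relation, object, asserter = NULL,
                            asserted_at = NULL,
                            claim_id = paste0("urn:uuid:",
                                              uuid::UUIDgenerate())) {
  as_full <- function(x) {
    if (is.character(x)) x <- parse_signature(x)
    x <- sig_payload(x)
    if (!is_full_signature(x)) {
      sc_abort("relation claims require full signatures",
               "signcite_validation_error")
    }
    x
  }
  subject <- as_full(subject)
  object <- as_full(object)
  rel_iri <- if (relation %in% names(RELATION_IRIS)) {
    RELATION_IRIS[[relation]]
  } else if (valid_uri(relation)) {
    relation
  } else {
    sc_abort(sprintf("unknown relation: '%s'", relation),
             "signcite_validation_error")
  }
  if (identical(relation, "different-from") && subject == object) {
    sc_abort(
      "contradiction: a signature cannot be different-from itself (identical bytes are identical content)",
      "signcite_contradiction")
  }
  lines <- nq_line(format(subject), rel_iri, nq_iri(format(object)),
                   claim_id)
  if (!is.null(asserter)) {
    lines <- c(lines,
               nq_line(claim_id,
                       "http://www.w3.org/ns/prov#wasAttributedTo",
                       nq_literal(asserter), claim_id))
  }
  if (!is.null(asserted_at)) {
    lines <- c(lines,
               nq_line(claim_id, PROV_STARTED,
                       nq_literal(asserted_at, XSD_DATETIME), claim_id))
  }
  lines
}
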