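# Minimal N-Quads emission and line-level parsing for the provenance
# dialect used here: IRIs and URNs only (no blank nodes, for byte-stable
# output), plus typed literals. Full RDF machinery is deliberately out
# of scope; the graph operations only need to read IRIs and literals
# back out of quad lines.

nq_iri <- function(x) sprintf("<%s>", x)

nq_literal <- function(value, datatype = NULL) {
  esc <- gsub("\\", "\\\\", value, fixed = TRUE)
  esc <- gsub('"', '\\"', esc, fixed = TRUE)
  esc <- gsub("\n", "\\n", esc, fixed = TRUE)
  if (is.null(datatype)) sprintf('"%s"', esc)
  else sprintf('"%s"^^<%s>', esc, datatype)
}

nq_line <- function(subject, predicate, object, graph) {
  sprintf("%s %s %s %s .", nq_iri(subject), nq_iri(predicate), object,
          nq_iri(graph))
}

NQ_PATTERN <- paste0(
  '^\\s*<([^>]+)>',                                   # subject IRI
  '\\s+<([^>]+)>',                                    # predicate IRI
  '\\s+(<[^>]+>|"(?:[^"\\\\]|\\\\.)*"',               # object IRI or literal
  '(?:\\^\\^<[^>]+>|@[A-Za-z0-9-]+)?)',               # datatype / lang
  '(?:\\s+<([^>]+)>)?',                               # optional graph IRI
  '\\s*\\.\\s*$')

#' Parse N-Quads lines
#'
#' Line-level parser for the IRI/literal subset of N-Quads emitted by
#' this package (blank nodes are not supported). Unparseable non-empty
#' lines are skipped with a diagnostic, not fatal.
#'
#' @param text N-Quads document as a single string or vector of lines.
#' @return Data frame with columns `subject`, `predicate`, `object`
#'   (IRIs bare, literals with their lexical value), `object_is_iri`,
#'   and `graph` (`NA` for triples); attribute `skipped` holds
#'   diagnostics for rejected lines.
#' @export
parse_nquads <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*#", lines)]
  skipped <- character()
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec(NQ_PATTERN, lines[i]))[[1]]
    if (length(m) == 0L) {
      skipped <- c(skipped, sprintf("line %d: not a valid quad: %s", i,
                                    substr(lines[i], 1, 80)))
      next
    }
    obj <- m[4]
    is_iri <- startsWith(obj, "<")
    if (is_iri) {
      obj_val <- substr(obj, 2, nchar(obj) - 1L)
    } else {
      lex <- sub('^"((?:[^"\\\\]|\\\\.)*)".*$', "\\1", obj)
      lex <- gsub("\\n", "\n", lex, fixed = TRUE)
      lex <- gsub('\\"', '"', lex, fixed = TRUE)
      obj_val <- gsub("\\\\", "\\", lex, fixed = TRUE)
    }
    rows[[i]] <- data.frame(subject = m[2], predicate = m[3],
                            object = obj_val, object_is_iri = is_iri,
                            graph = if (nzchar(m[5])) m[5] else NA_character_,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(subject = character(), predicate = character(),
                      object = character(), object_is_iri = logical(),
                      graph = character(), stringsAsFactors = FALSE)
  }
  attr(out, "skipped") <- skipped
  out
}

# Heuristic used by the graph builder: content is treated as RDF when
# every non-empty line parses as a quad (and there is at least one).
looks_like_nquads <- function(text) {
  df <- parse_nquads(text)
  nrow(df) > 0L && length(attr(df, "skipped")) == 0L
}
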