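# Deterministic synthetic data: nested content corpora mirroring the
# structure of signed reference lists and RDF collection descriptions,
# and a simulated web timeline with known injected rates of content
# drift and link rot for parameter-recovery testing.
#
# One integer seed drives all randomness; the ambient RNG state is
# saved and restored so generation never perturbs a caller's stream.

with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

random_blob <- function(min_size, max_size) {
  size <- if (min_size == max_size) min_size
          else sample(min_size:max_size, 1L)
  as.raw(sample(0:255, size, replace = TRUE))
}

#' Generate a nested synthetic corpus in a content store
#'
#' Builds a complete `fanout`-ary tree of `depth` levels: the last level
#' holds seeded random binary blobs (leaves); every level above holds
#' collection descriptions embedding the signatures of its children —
#' alternating between plain-text signed reference lists (the level just
#' above the leaves) and N-Quads membership documents, so both citation
#' media are exercised. Everything is stored content-addressed;
#' identical specs yield byte-identical corpora and the same root
#' signature.
#'
#' @param store A [content_store()] to populate.
#' @param depth Total number of tree levels (>= 1; `depth = 1` is a
#'   single blob). `depth = 2, fanout = 2` gives the minimal
#'   one-collection / two-leaves shape of a two-entry reference list.
#' @param fanout Children per collection (>= 1).
#' @param blob_size Two-element range of leaf sizes in bytes.
#' @param seed Integer seed; fully determines the corpus.
#' @return A list: `root` (the root [content_signature()]),
#'   `root_citation` (a [signed_citation()] for the root), `items`
#'   (data frame `level`, `kind`, `signature` for all stored items, root
#'   first), and `leaves` (character vector of leaf hash URIs).
#' @export
generate_corpus <- function(store, depth, fanout,
                            blob_size = c(64, 4096), seed = 1) {
  stopifnot(inherits(store, "content_store"),
            depth >= 1, fanout >= 1, length(blob_size) == 2,
            blob_size[1] >= 1, blob_size[1] <= blob_size[2])
  with_seed(seed, function() {
    sigs_by_level <- vector("list", depth)
    kinds_by_level <- character(depth)

    n_leaves <- fanout^(depth - 1L)
    kinds_by_level[depth] <- "blob"
    sigs_by_level[[depth]] <- vapply(seq_len(n_leaves), function(i) {
      format(store_put(store, random_blob(blob_size[1], blob_size[2])))
    }, character(1))

    for (l in rev(seq_len(depth - 1L))) {
      # level just above the leaves is plain text; alternate upward
      kind <- if ((depth - 1L - l) %% 2L == 0L) "text" else "rdf"
      kinds_by_level[l] <- kind
      n <- fanout^(l - 1L)
      child_uris <- sigs_by_level[[l + 1L]]
      sigs_by_level[[l]] <- vapply(seq_len(n), function(i) {
        kids <- child_uris[((i - 1L) * fanout + 1L):(i * fanout)]
        bytes <- if (kind == "text") {
          entries <- vapply(seq_along(kids), function(k) {
            render_signed_citation(signed_citation(
              creators = "Synthetic Data Generator",
              date = "2021",
              title = sprintf("Synthetic item %d at level %d", k, l + 1L),
              signature = parse_signature(kids[k])))
          }, character(1))
          package_collection(entries)$canonical_bytes
        } else {
          ctx <- sprintf("urn:corpus:collection:%d-%d", l, i)
          lines <- vapply(kids, function(k) {
            nq_line(ctx, "http://www.w3.org/ns/prov#hadMember",
                    nq_iri(k), ctx)
          }, character(1), USE.NAMES = FALSE)
          charToRaw(paste0(paste(lines, collapse = "\n"), "\n"))
        }
        format(store_put(store, bytes))
      }, character(1))
    }

    items <- do.call(rbind, lapply(seq_len(depth), function(l) {
      data.frame(level = l, kind = kinds_by_level[l],
                 signature = sigs_by_level[[l]],
                 stringsAsFactors = FALSE)
    }))
    root <- sig_payload(parse_signature(sigs_by_level[[1L]][1L]))
    list(root = root,
         root_citation = signed_citation(
           creators = "Synthetic Data Generator", date = "2021",
           title = sprintf("Synthetic corpus (depth %d, fanout %d, seed %d)",
                           depth, fanout, seed),
           signature = root),
         items = items,
         leaves = sigs_by_level[[depth]])
  })
}

#' Simulate a web of locations with injected drift and rot
#'
#' Creates `n_locations` URLs each serving a distinct seeded random
#' blob. Each location is independently labelled `drift` (with
#' probability `p_drift`), `rot` (`p_rot`), or `stable`, with a change
#' epoch drawn uniformly from the non-initial epochs. At epoch 0 every
#' location serves its true content; from its change epoch onward a
#' drift location serves its blob with one seeded random byte flipped
#' (a minimal copy-error perturbation) and a rot location fails. One
#' observation per location per epoch is appended to a registry, so
#' [classify_registry()] can be checked against the known truth.
#'
#' @param n_locations Number of simulated URLs.
#' @param p_drift,p_rot Per-location probabilities of drift and rot;
#'   must sum to at most 1 (a location cannot both drift and rot).
#' @param epochs Number of observation epochs (>= 2).
#' @param seed Integer seed; fully determines the simulation.
#' @param blob_size Size of each location's content in bytes.
#' @param registry_path Optional path for the TSV-backed registry.
#' @return A list: `registry` (a [signature_registry()] with all
#'   observations), `truth` (data frame `location`, `label`,
#'   `change_epoch`; `NA` epoch for stable locations), and `web`
#'   (`function(url, epoch) -> raw or NULL`, the simulated fetch).
#' @export
simulate_timeline <- function(n_locations, p_drift, p_rot, epochs = 4,
                              seed = 1, blob_size = 64,
                              registry_path = NULL) {
  stopifnot(n_locations >= 1, p_drift >= 0, p_rot >= 0,
            p_drift + p_rot <= 1, epochs >= 2)
  with_seed(seed, function() {
    locations <- sprintf("https://sim.example/item-%05d",
                         seq_len(n_locations))
    blobs <- lapply(seq_len(n_locations), function(i)
      random_blob(blob_size, blob_size))

    u <- stats::runif(n_locations)
    label <- ifelse(u < p_drift, "drift",
                    ifelse(u < p_drift + p_rot, "rot", "stable"))
    change_epoch <- ifelse(label == "stable", NA_integer_,
                           sample(seq_len(epochs - 1L), n_locations,
                                  replace = TRUE))

    drifted <- lapply(seq_len(n_locations), function(i) {
      if (label[i] != "drift") return(NULL)
      b <- blobs[[i]]
      pos <- sample(length(b), 1L)
      b[pos] <- xor(b[pos], as.raw(sample(1:255, 1L)))
      b
    })

    serve <- function(i, epoch) {
      if (label[i] == "stable" || epoch < change_epoch[i]) return(blobs[[i]])
      if (label[i] == "drift") return(drifted[[i]])
      NULL  # rot
    }

    # build the observation table in bulk (append-only order: by epoch,
    # then location)
    obs_at <- character(0); obs_loc <- character(0); obs_out <- character(0)
    for (epoch in 0:(epochs - 1L)) {
      stamp <- sprintf("2021-%02d-01T00:00:00Z", epoch + 1L)
      outcomes <- vapply(seq_len(n_locations), function(i) {
        b <- serve(i, epoch)
        if (is.null(b)) FAILED_MARKER
        else format(compute_signature(b, "sha256"))
      }, character(1))
      obs_at <- c(obs_at, rep(stamp, n_locations))
      obs_loc <- c(obs_loc, locations)
      obs_out <- c(obs_out, outcomes)
    }
    records <- data.frame(observed_at = obs_at, location = obs_loc,
                          outcome = obs_out, stringsAsFactors = FALSE)

    registry <- signature_registry(registry_path)
    registry$env$records <- records
    if (!is.null(registry_path)) {
      utils::write.table(records, registry_path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }

    web <- function(url, epoch) {
      i <- match(url, locations)
      if (is.na(i)) return(NULL)
      serve(i, epoch)
    }

    list(registry = registry,
         truth = data.frame(location = locations, label = label,
                            change_epoch = change_epoch,
                            stringsAsFactors = FALSE),
         web = web)
  })
}
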