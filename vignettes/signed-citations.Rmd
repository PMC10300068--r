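---
title: "Signed citations: verifiable content identifiers, citation graphs, and drift monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed citations: verifiable content identifiers, citation graphs, and drift monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signcite)
```

## The model

A *content signature* is a pair (algorithm token, digest bytes), where
the digest is a cryptographic hash of the exact bytes of some digital
content. Its canonical text form is a content-hash URI,
`hash://<algorithm>/<hex digest>`, lowercase hexadecimal, each character
carrying 4 bits (so SHA-256 gives 64 characters). Two assumptions carry
the entire method:

1. **Determinism.** Equal bytes hash equally, everywhere, forever. The
   association between a signature and content is therefore verifiable
   by anyone holding the content, with no infrastructure.
2. **Collision resistance.** For SHA-256, the probability that two
   different byte streams share a digest is negligible, so different
   digests prove different content, and (for practical purposes) equal
   digests prove equal content.

Nothing else is assumed: no registry has to stay online, no resolver
has to keep redirects fresh, no authority mints identifiers. A *signed
citation* adds such a signature to a customary citation (creators,
date, title, and — as convenience only — where and when the content was
retrieved). Location is metadata, not identity.

Two verifiable identities compose into graphs: a *collection
description* is a document that embeds the signatures of other content
and is itself cited by one signature. Because each link is a hash of
exact bytes, the resulting structure is a Merkle-style DAG — no byte
anywhere below the root can change without invalidating every
signature on the path up to it. `verify_graph()` turns that property
into an operational check: re-resolve and re-hash everything reachable
from the root, and report each node as `verified`, `drifted`, or
`unreachable`.

Against this identity layer, *content drift* and *link rot* become
measurable events on locations. A registry row is just
`(observed_at, location, outcome)` with outcome either a signature or a
failure marker; comparing consecutive rows for one location gives a
four-way classification (`initial`, `unchanged`, `content_drift`,
`link_rot`).

## Parameters and conventions that matter

**Hash algorithms.** `sha256` (256 bits) is the default and the only
recommended algorithm. `sha1` (160 bits) and `md5` (128 bits) are
registered because real repositories expose such hashes, but computing
with them warns: both are cryptographically broken for collision
resistance, which is the property the whole method leans on.
`register_algorithm()` is an extension point; translation between
identifier dialects never crosses algorithms, because an md5 digest
simply is not a sha256 digest.

**Identifier dialects.** Hex is canonical (lowercase; the parser
accepts mixed case and case-insensitive scheme tokens, since prose
capitalizes sentence-initial `Hash://…`). The `ni:///<alg>;<payload>`
form accepts hex *and* base64url payloads: published usage keeps hex
inside ni identifiers even though the scheme is usually shown with
base64url, so the parser takes both and the formatter emits whichever
is requested. Base64url output is unpadded; padded input is accepted;
`+`, `/`, `=` can be percent-encoded on request for embedding in URIs.
One genuine ambiguity exists: a payload made entirely of hex characters
that is shorter than the full digest could in principle be base64url.
The parser prefers the hex reading (it parses as a prefix); a full-hex
base64url digest is astronomically improbable, and prefixes are a
documented, printed usage.

**Truncation.** Whole hex characters only (4-bit granularity, matching
printed 64/32/16-character usage). `keyspace_size(n) = 16^n` is exact
arbitrary-precision arithmetic — 16 characters give 2^64 ≈ 1.8 × 10^19
possibilities, 32 give 2^128 — and prefixes shorter than 16 characters
trigger a warning rather than an error: the keyspace is then small
enough that collisions stop being unthinkable, but the cutoff is a
readability/risk compromise, not a cliff.

**Check digits.** The Luhn mod-16 convention is pinned down precisely
so independent implementations agree: map hex characters to 0–15;
right-to-left, double every second value starting with the rightmost;
fold doubled values v ≥ 16 to (v div 16) + (v mod 16); check digit =
(16 − sum mod 16) mod 16. Because folding is a permutation of 0–15,
every single-character substitution shifts the checksum — 100%
single-substitution detection is a theorem here, and the test suite
confirms it by brute force over all positions and all substitutions.

**Collection canonicalization.** "Hash an ASCII encoding of the text"
underdetermines the bytes, so `package_collection()` fixes them:
entries joined by exactly one blank line, LF line endings, one trailing
newline, ASCII enforced (UTF-8 by explicit flag). Entry order is
significant — the hash of {a,b} differs from the hash of {b,a} — with
an opt-in lexicographic `sort` (C locale) for collections with set
semantics, off by default. The empty collection hashes the empty byte
string, a well-defined degenerate case. A consequence worth stating:
the previously published hash of the familiar two-image reference list
cannot be reproduced without knowing its exact whitespace, so that
specific value is recorded as an observation, never asserted.

**Store and registry.** The store layout is
`<root>/<alg>/<hex[1:2]>/<hex[3:4]>/<hex>` — standard two-level fan-out
bounding directory sizes. The store's invariant is absolute: bytes are
re-hashed on every read, and a mismatch is a corruption error, never a
return value. Prefix lookups must be unique; ambiguity is an error
listing the candidates, not a choice. Registries serialize as TSV with
header `(observed_at, location, outcome)`, UTC ISO 8601 timestamps,
`FAILED` as the failure marker; records are append-only. Ties on
timestamp are broken by file order (later row wins), so replaying a
registry is deterministic.

**Resolution.** `resolve_signature()` tries sources in order (local
store first), verifies every fetched candidate, and returns the first
match with its provenance; all failed or drifted candidates are kept in
an attempt log. When a registry knows several locations for one
signature they are tried most-recently-observed first — recency is the
best available predictor that a copy is still there; this ranking is a
package choice, documented rather than prescribed. URL aliasing
(`resolve_location()`) maps a URL to its most recent *successful*
observation and resolves that signature; the live URL is deliberately
not re-fetched first, which is exactly what makes aliases stable under
remote drift, and older signatures for the same URL remain queryable as
earlier versions. The fetcher is injectable
(`function(url) -> raw or NULL`) with no default network
implementation: tests and simulations run against an in-memory web, and
callers opt into real HTTP explicitly.

**Classification truth table.** Only four of the (previous, current)
combinations are substantive; the remainder are completed as follows
and documented in `classify_observation()`: a first observation is
`initial` whether it succeeds or fails (rot and drift are defined
relative to an earlier *successful* observation); failure followed by
failure is `unchanged` (still down, nothing newly lost); failure
followed by success is `initial` (a fresh baseline — without an earlier
success there is nothing to compare content against).
`classify_registry()` summarizes a location's history by its change
events, with drift and rot dominating quiet statuses.

## Provenance and relation claims

Acquisition provenance is emitted as N-Quads in a minimal PROV dialect:
three quads per acquisition (`prov#used` the location,
`prov#generated` the signature, `prov#startedAtTime` as an
`xsd:dateTime` literal), with the activity URN in the graph position so
each acquisition is self-describing. Blank nodes are never emitted —
IRIs and URNs only — because byte-stable output is worth more here than
RDF generality. The bundled reader handles exactly this subset
(IRI/literal terms, line-level, junk lines skipped with diagnostics);
conformance of the emitted quads is checked in the tests against an
independent N-Quads parser.

Relation claims (`assert_relation()`) record *opinions* — same-as,
different-from, derived-from, or any custom IRI — between two
signatures without touching content identity. The single enforced
consistency rule: `different-from` between equal signatures is a
contradiction, because identical bytes cannot be different content.
Everything else is left to the asserter, by design; byte-identity is
objective, sameness-of-meaning is not.

## What the synthetic data emulates

`generate_corpus()` builds a complete fanout-ary tree: random binary
blobs at the leaves (default 64–4096 bytes — big enough that all hashes
are distinct in practice, small enough for fast suites), collection
descriptions above, alternating plain-text signed reference lists (the
level above the leaves, mirroring a human-readable reference list) and
N-Quads membership documents (mirroring machine-readable RDF
collections). `depth` counts tree levels in total, so depth 3 / fanout
3 gives 1 + 3 + 9 = 13 items and depth 2 / fanout 2 is the minimal
one-collection, two-leaves shape of a two-entry reference list. One
integer seed determines every byte; the ambient RNG state is saved and
restored.

`simulate_timeline()` emulates the *methodology* of longitudinal URL
monitoring: n locations, each independently labelled drift (probability
`p_drift`), rot (`p_rot`), or stable, with a change epoch uniform over
the non-initial epochs; drifted locations serve their blob with one
seeded random byte flipped (the minimal copy-error perturbation —
exactly the kind of change a human cannot see and a hash cannot miss),
rotten locations return nothing. One observation per location per epoch
is appended to a registry. The acceptance configuration is n = 2000,
p_drift = 0.30, p_rot = 0.20, 4 epochs — rates inside the ranges
reported for real biodiversity-dataset URL cohorts, at a size where the
binomial standard error on a recovered rate is about 1 percentage
point, so a ±3-point recovery check is a ≈3σ test.

What the simulation deliberately does not model: real image payloads,
partial or truncated responses, latency and retries, correlated
failures (a dying host takes all its URLs at once), locations that
both drift and later rot, or recovery after rot. Passing the recovery
test therefore shows that the classification logic and registry
plumbing are correct under clean conditions — not that these rates
are what any particular real cohort would show, nor that real drift is
always a one-byte change (it is usually much larger, which only makes
detection easier).

## Numerical and interface choices

* Streaming: built-in algorithms hash connections in bounded memory,
  so file size never matters; chunked and whole-buffer input provably
  agree (tested across a seeded corpus).
* Degenerate inputs: empty content is hashable (its SHA-256 is a
  well-known constant), the empty collection is packageable, an empty
  registry query is an empty result, not an error.
* Graph traversal is depth-first in order of appearance with a visited
  set, so traversal terminates even on adversarial inputs and node and
  edge order is reproducible; self-citation edges are dropped (content
  cannot embed its own full hash).
* Unverified bytes never cross an API boundary: `store_get()` and
  `resolve_signature()` re-hash before returning, and graph building
  extracts citations only from verified nodes. The one deliberate
  exception is `store_resolver()`, which returns raw bytes *to the
  verifier itself* so that `verify_graph()` can classify drifted
  content instead of erroring on first contact.
* Exit codes in the CLI: 0 success, 1 mismatch or drift found, 2 not
  found or unresolvable, 3 usage error — so shell pipelines can
  distinguish "verified false" from "could not check".

## Problem sizes in the test suite

The suites are sized for seconds, not minutes: 100-blob hashing
corpora; a 13-node graph with exhaustive single-leaf tampering (9
rebuild-and-verify cycles); 2000 locations × 4 epochs for rate
recovery; 1000 payloads with all single-character substitutions
(≈ 500k checks) for the check digit. These sizes already give exact or
≈3σ discrimination for every property tested; larger runs change
nothing but the wait.

## Known limitations

* Only `hash://`, `ni:///`, and `nih:` dialects are spoken. Foreign
  content-based schemes (UNF, Trusty URI, SWH-ID, magnet) are
  recognized as out of scope rather than mistranslated.
* The N-Quads reader is a subset parser for the package's own dialect;
  documents using blank nodes or multi-line literals should go through
  a full RDF stack.
* No garbage collection, access control, or replication policy in the
  store; it is a verifiable repository primitive, not an archive
  product.
* Registry recency ranking is a heuristic; nothing guarantees the most
  recent location is the best one.
* Verification proves byte identity only. Semantic equivalence of
  different bytes (resized images, re-serialized datasets) is exactly
  what relation claims exist to record, and exactly what the hash
  cannot decide.
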