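# signcite

Verifiable, location-agnostic data citation for R.

Ordinary data citations point at *locations* — URLs, or persistent
identifiers that redirect to URLs — and locations are brittle: the bytes
behind them change (**content drift**) or disappear (**link rot**), and
nothing in the citation lets a reader notice. `signcite` implements
**signed citations**: customary citations extended with a cryptographic
**content signature** of the exact cited bytes, written as a
content-hash URI

```
hash://<algorithm>/<hash value>        e.g.  hash://sha256/ba7816bf…0015ad
```

Because SHA-256 is deterministic and collision-resistant, anyone holding
the content can recompute the hash and verify — independently of where,
when, or from whom the bytes were retrieved. The audience is anyone who
publishes, curates, or archives digital research data (the motivating
use cases come from biodiversity informatics: specimen images, evolving
aggregator datasets, media-record knowledge graphs).

The toolkit covers:

* **Signature arithmetic** — compute (`compute_signature()`,
  `hash_file()`), parse, and verify signatures; translate losslessly
  between the `hash://`, `ni:///`, and human-oriented `nih:` dialects
  (hex or unpadded base64url, digest bytes always preserved, never
  re-hashed); truncate to readable prefixes, with `keyspace_size(n)` =
  16^n quantifying the collision-resistance cost; Luhn mod-16 check
  digits for transcription-error detection.
* **Signed citations and collections** — render and parse citation text
  (`render_signed_citation()`, `extract_signatures()`), and package a
  reference list into a canonical ASCII collection description signed by
  one signature (`package_collection()`). Collections can cite
  collections, so a single signature recursively pins an arbitrary
  corpus (a Merkle DAG: any changed byte anywhere invalidates the path
  to the root).
* **Store, registry, resolution** — a content-addressed store that never
  returns unverified bytes (`store_put()`/`store_get()`); append-only
  TSV registries of `(timestamp, URL, signature)` observations;
  drift/rot classification of location histories
  (`classify_observation()`, `classify_registry()`); verified resolution
  through stores and registries with an injectable fetcher
  (`resolve_signature()`), and URLs usable as aliases for signatures
  (`resolve_location()`).
* **Citation graphs with provenance** — build and verify recursive
  citation graphs from a root signature (`build_graph()`,
  `verify_graph()`), render their leaves back into a signable reference
  list, emit acquisition provenance as PROV N-Quads
  (`record_acquisition()`), and make relation claims between signatures
  (`assert_relation()`).
* **Synthetic test worlds** — deterministic nested corpora
  (`generate_corpus()`) and a simulated web timeline with injected drift
  and rot rates (`simulate_timeline()`) for end-to-end validation.

A command-line interface (`exec/signcite`, or `run_cli()` in-process)
exposes the same operations: `hash`, `verify`, `translate`, `truncate`,
`checkdigit`, `cite`, `pack`, `put`, `get`, `register`, `locations`,
`resolve`, `monitor`, `graph`, `fixtures`.

## Worked example

```r
library(signcite)

sig <- compute_signature("abc")
sig
#> <content signature> hash://sha256/ba7816bf8f01cfea414140de5dae2223b00361a396177a9cb410ff61f20015ad

format(truncate_signature(sig, 32))        # readable 32-char prefix, keyspace 16^32
#> [1] "hash://sha256/ba7816bf8f01cfea414140de5dae2223"
translate_signature(format(sig), "ni", "hex")
#> [1] "ni:///sha256;ba7816bf8f01cfea414140de5dae2223b00361a396177a9cb410ff61f20015ad"
format_signature(sig, "nih", "hex")        # with Luhn mod-16 check digit
#> [1] "nih:sha256;ba7816bf8f01cfea414140de5dae2223b00361a396177a9cb410ff61f20015ad;3"
keyspace_size(16)                          # 2^64 possible 16-char prefixes
#> [b] 18446744073709551616
```

The SHA-256 digest of the ASCII bytes `"abc"` is the classic test-vector
value, so the first line can be checked against any other SHA-256
implementation. A recursive corpus is cited, verified, and
tamper-checked through one root signature:

```r
store <- content_store(file.path(tempdir(), "demo-store"))
corpus <- generate_corpus(store, depth = 3, fanout = 3, seed = 2024)
verify_graph(corpus$root, store_resolver(store))
#> <verification report> root hash://sha256/adba2f352e1289c90b7dbf2c613234e3470365ae19518219471f5e313caa57e0
#>   verified: 13, drifted: 0, unreachable: 0
```

All 13 nodes (1 root + 3 mid-level collections + 9 leaf blobs) verify.
Flipping a single bit in any one stored leaf changes its recomputed
hash, and the report pinpoints exactly that leaf:

```r
#> <verification report> root hash://sha256/adba2f352e1289c90b7dbf2c613234e3470365ae19518219471f5e313caa57e0
#>   verified: 12, drifted: 1, unreachable: 0
```

Drift and rot monitoring recovers injected rates from a simulated web of
2000 locations observed over 4 epochs (30% drifting, 20% rotting):

```r
sim <- simulate_timeline(n_locations = 2000, p_drift = 0.30, p_rot = 0.20,
                         epochs = 4, seed = 1)
cls <- classify_registry(sim$registry)
mean(cls$status == "content_drift"); mean(cls$status == "link_rot")
#> drift: 30.1%  rot: 19.8%
```

The recovered fractions differ from 30%/20% only by binomial sampling
noise (standard error ≈ 1 percentage point at n = 2000).

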