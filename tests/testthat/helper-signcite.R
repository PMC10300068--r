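# Shared fixtures, built in code.

# The printed identifier strings the package must reproduce exactly.
REF <- list(
  bee_head = "hash://sha256/edde5b2b45961e356f27b81a3aa51584de4761ad9fa678c4b9fa3230808ea356",
  bee_lateral = "hash://sha256/8d49bd24f6ba300b4de44fd218b53294f4cc0106cd9631018ef819b38345c75d",
  bees_graph = "hash://sha256/85138e506a29fb73099fb050372d8a379794ab57fe4bfdf141743db0de2b985c",
  readable64 = "hash://sha256/29d30b566f924355a383b13cd48c3aa239d42cba0a55f4ccfc2930289b88b43c",
  readable32 = "hash://sha256/29d30b566f924355a383b13cd48c3aa2",
  readable16 = "hash://sha256/29d30b566f924355",
  readable_ni = "ni:///sha256;29d30b566f924355a383b13cd48c3aa239d42cba0a55f4ccfc2930289b88b43c",
  wing_a = "hash://sha256/79d795bff23567be10d36934facc8befca300e426d0abbd7c273269fe8ec427b",
  wing_b = "hash://sha256/86b657f8828b235371322894c65ec62909f62f874c1b1528e49edddb5fc2271a")

HEAD_CITATION <- paste0(
  "Museum of Comparative Zoology, Harvard University. 2021. ",
  "Head Frontal View of MCZ:ENT:17219 Nomadopsis puellae (Cockerell, 1933) ",
  REF$bee_head,
  " Accessed at http://mczbase.mcz.harvard.edu/specimen_images/entomology/large/MCZ-ENT00017219_Spinoliella_puellae_hef.jpg on 2021-12-07.")

LATERAL_CITATION <- paste0(
  "Museum of Comparative Zoology, Harvard University. 2021. ",
  "Habitus Lateral View of MCZ:ENT:17219 Nomadopsis puellae (Cockerell, 1933) ",
  REF$bee_lateral,
  " Accessed at http://mczbase.mcz.harvard.edu/specimen_images/entomology/large/MCZ-ENT00017219_Spinoliella_puellae_hal.jpg on 2021-12-07.")

seeded_blobs <- function(n, seed = 1, min_size = 16, max_size = 256) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    as.raw(sample(0:255, sample(min_size:max_size, 1), replace = TRUE))
  })
}

# Independent arbitrary-precision 16^n: schoolbook multiplication on
# decimal digit vectors, sharing no code with the implementation.
oracle_pow16 <- function(n) {
  digits <- c(1L)  # little-endian decimal digits
  for (i in seq_len(n)) {
    prod <- digits * 16L
    carry <- 0L
    for (j in seq_along(prod)) {
      v <- prod[j] + carry
      prod[j] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      prod <- c(prod, carry %% 10L)
      carry <- carry %/% 10L
    }
    digits <- prod
  }
  paste(rev(digits), collapse = "")
}

# Hash a raw vector through a streamed connection, to confirm streamed
# and whole-buffer hashing agree.
hash_streamed <- function(bytes) {
  con <- rawConnection(bytes)
  on.exit(close(con))
  compute_signature(con)
}

make_corpus <- function(depth = 3, fanout = 3, seed = 42) {
  store <- content_store(withr::local_tempdir(.local_envir = parent.frame()))
  corpus <- generate_corpus(store, depth = depth, fanout = fanout,
                            seed = seed)
  list(store = store, corpus = corpus)
}
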