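# Shared fixtures, built in code. Heavier cohort objects are created lazily
# and cached for the session so several test files can share one simulation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small five-genome group layout used by the pattern tests
toy_groups <- function() {
  group_assignment(c(EUR_1 = "EUR", EUR_2 = "EUR", ASIA_N_1 = "ASIA_N",
                     ASIA_S_1 = "ASIA_S", TIBET_1 = "TIBET"))
}

# hand-built catalog from a records data.frame and presence matrix
toy_catalog <- function(records, presence) {
  structure(list(records = records, presence = presence),
            class = "sv_catalog")
}

# reads with explicit sequences/qualities (quality as integer vectors)
make_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- lapply(nchar(seqs), function(w) rep(40L, w))
  qs <- vapply(quals, function(q) rawToChar(as.raw(q + 33L)), "")
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(qs))
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# the mid-sized cohort shared by the genotyper tests and acceptance suite
genotyper_study <- function() {
  cached("genotyper_study", function() {
    cfg <- sim_config(seed = 5, genome_length = 60000, depth = 20,
                      error_rate = 0)
    st <- simulate_study(cfg, n_sv = 16, size_range = c(120, 800),
                         te_fraction = 0.5, reads = TRUE)
    pan <- st$panel[st$panel$pattern != "none" & st$panel$length > 100, ]
    lr <- lapply(seq_len(nrow(pan)), function(i) {
      rec <- list(ref_start = pan$ref_position[i],
                  ref_end = pan$ref_position[i] +
                    ifelse(pan$type[i] == "deletion", pan$length[i], 0),
                  type = pan$type[i],
                  alt_seq = ifelse(pan$type[i] == "insertion",
                                   pan$sequence[i], ""))
      local_reference_from_record(st$reference, rec, flank = 200)
    })
    names(lr) <- pan$name
    st$panel_selected <- pan
    st$local_refs <- lr
    st
  })
}
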