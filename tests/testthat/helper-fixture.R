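# Shared simulated fixture, memoised so multiple test files reuse one run.
.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_pinniped_fixture(seed = seed)
  }
  .fixture_cache[[key]]
}

fixture_groups <- function() {
  list(phocids = c("spotted_seal", "harbor_seal", "caspian_seal",
                   "n_elephant_seal"),
       otariids = c("australian_sea_lion", "s_american_sea_lion"),
       outgroup = c("domestic_dog", "red_fox"))
}

# Translate one taxon's reference-frame codons (complete, gap-free ones).
ref_frame_codons <- function(alignment, taxon) {
  fm <- build_frame_map(alignment)
  row <- alignment$seqs[taxon, ]
  cods <- split(which(!fm$inserted), fm$codon_index[!fm$inserted])
  vapply(cods[vapply(cods, length, integer(1)) == 3L],
         function(cc) paste(row[cc], collapse = ""), character(1))
}
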