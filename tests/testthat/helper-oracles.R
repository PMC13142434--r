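# Shared fixtures and independent oracles.

extdata <- function(name) system.file("extdata", name, package = "varcat")

tp53_catvar <- function() {
  read_categorical_variants(extdata("tp53_cnloss.json"))$catvars[[1]]
}

tp53_context <- function() {
  evaluation_context(feature_table = load_feature_table(extdata("tp53_features.bed")))
}

# mutated-string oracle: apply an allele to its reference by plain string
# surgery — independent of the normalization path it is used to check
apply_allele <- function(refseq, al) {
  s <- al$location$start
  e <- al$location$end
  paste0(substr(refseq, 1, s), al$state,
         substr(refseq, e + 1, nchar(refseq)))
}

# brute-force enumeration of every spelling of a length-L deletion that
# yields the same mutated string as deleting [s0, s0+L)
equivalent_deletion_spellings <- function(refseq, s0, L) {
  target <- apply_allele(refseq, allele(seq_location("r", s0, s0 + L), ""))
  hits <- list()
  for (s in 0:(nchar(refseq) - L)) {
    al <- allele(seq_location("r", s, s + L), "")
    if (identical(apply_allele(refseq, al), target)) {
      hits[[length(hits) + 1L]] <- al
    }
  }
  hits
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small universe used across engine/entailment tests
small_universe <- function(seed = 11) {
  generate_universe(universe_config(n_references = 2, ref_length = 1200,
                                    n_genes = 4, n_snvs = 30, n_indels = 16,
                                    n_cnvs = 20, n_adjacencies = 6,
                                    n_repeat_tracts = 8), seed = seed)
}
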