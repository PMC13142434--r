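test_that("equivalent indel spellings collapse to one canonical form", {
  ref <- "GGCAGAGAGATT"
  a <- allele(seq_location("r", 3, 5), "")
  b <- allele(seq_location("r", 5, 7), "")
  # oracle first: both spellings must denote the same molecule
  expect_identical(apply_allele(ref, a), apply_allele(ref, b))
  na <- normalize_allele(a, ref)
  nb <- normalize_allele(b, ref)
  expect_identical(na$digest_id, nb$digest_id)
  expect_identical(canonical_serialize(na$allele), canonical_serialize(nb$allele))
  # the normalized form still denotes the same molecule
  expect_identical(apply_allele(ref, na$allele), apply_allele(ref, a))
})

test_that("every oracle-equivalent deletion spelling normalizes identically", {
  withr::with_seed(71, {
    for (rep in 1:30) {
      unit <- random_dna_string(sample(1:3, 1))
      copies <- sample(3:6, 1)
      prefix <- random_dna_string(sample(5:20, 1))
      ref <- paste0(prefix, strrep(unit, copies),
                    random_dna_string(sample(5:20, 1)))
      L <- nchar(unit)
      s0 <- nchar(prefix) + sample(0:(L * (copies - 1)), 1)
      spellings <- equivalent_deletion_spellings(ref, s0, L)
      expect_gte(length(spellings), 2L)
      digests <- vapply(spellings, function(al)
        normalize_allele(al, ref)$digest_id, character(1))
      expect_length(unique(digests), 1L)
    }
  })
})

test_that("substitutions pass through trimmed only and identities are flagged", {
  ref <- "GGCAGAGAGATT"
  snv <- normalize_allele(allele(seq_location("r", 3, 4), "G"), ref)
  expect_equal(snv$allele$location$start, 3L)
  expect_equal(snv$allele$location$end, 4L)
  expect_identical(snv$allele$state, "G")
  expect_false(snv$is_identity)

  idn <- normalize_allele(allele(seq_location("r", 2, 4), "CA"), ref)
  expect_true(idn$is_identity)

  # padded spelling of the same substitution trims to the same core
  padded <- normalize_allele(allele(seq_location("r", 2, 5), "CGG"), ref)
  expect_identical(padded$digest_id, snv$digest_id)
})

test_that("normalization is idempotent over random edits", {
  withr::with_seed(72, {
    ref <- random_dna_string(300)
    for (i in 1:100) {
      s <- sample(0:290, 1)
      e <- s + sample(0:8, 1)
      st <- if (stats::runif(1) < 0.3) "" else random_dna_string(sample(1:6, 1))
      n1 <- normalize_allele(allele(seq_location("r", s, e), st), ref)
      n2 <- normalize_allele(n1$allele, ref)
      expect_identical(n2$digest_id, n1$digest_id)
      expect_identical(canonical_serialize(n2$allele), canonical_serialize(n1$allele))
    }
  })
})

test_that("protein alleles are trimmed but never repeat-shuffled", {
  prot <- as_reference_registry(list(p = "MKAAAAKL"))
  d1 <- normalize_allele(allele(seq_location("p", 2, 3), ""), prot[["p"]])
  d2 <- normalize_allele(allele(seq_location("p", 4, 5), ""), prot[["p"]])
  # same molecule, but residue-level justification is deliberately not applied
  expect_false(identical(d1$digest_id, d2$digest_id))
  expect_equal(d1$allele$location$start, 2L)
})

test_that("out-of-bounds and foreign symbols raise classed errors", {
  expect_error(normalize_allele(allele(seq_location("r", 5, 20), "A"), "ACGTACGT"),
               class = "cv_error_out_of_bounds")
  expect_error(normalize_allele(allele(seq_location("r", 1, 2), "J"), "ACGTACGT"),
               class = "cv_error_alphabet_mismatch")
  regs <- as_reference_registry(list(r = "ACGT"))
  expect_error(normalize_allele(allele(seq_location("nope", 0, 1), "A"), regs),
               class = "cv_error_missing_reference")
})

test_that("digests are deterministic, field-order free, and collision-free in practice", {
  al <- allele(seq_location("chr1", 100, 101), "T")
  expect_identical(normalize_allele(al, strrep("A", 200))$digest_id,
                   normalize_allele(al, strrep("A", 200))$digest_id)
  # same content, different construction order of the serialized fields
  x <- list(b = 1L, a = "z")
  y <- list(a = "z", b = 1L)
  expect_identical(compute_digest(x), compute_digest(y))

  withr::with_seed(73, {
    keys <- unique(replicate(10000, paste0(
      sample(c("chrA", "chrB"), 1), ":", sample.int(5e6, 1), ":",
      paste(sample(c("A", "C", "G", "T"), sample(1:4, 1), replace = TRUE),
            collapse = ""))))
    digests <- vapply(keys, function(k) compute_digest(list(k = k)), character(1))
    expect_equal(anyDuplicated(digests), 0L)
    expect_true(all(grepl("^OBJ\\.[A-Za-z0-9_-]{24}$", digests)))
  })
})

test_that("canonical serialization is a fixed point through parse and re-serialize", {
  cv <- tp53_catvar()
  b1 <- canonical_serialize(cv)
  parsed <- jsonlite::fromJSON(rawToChar(b1), simplifyVector = FALSE)
  b2 <- canonical_serialize(parsed)
  expect_identical(b1, b2)
  expect_error(canonical_serialize(list(x = sys.function())),
               class = "cv_error_unserializable")
})
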