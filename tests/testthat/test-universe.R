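test_that("universe generation is deterministic in (config, seed) and varies with seed", {
  cfg <- universe_config(n_snvs = 15, n_indels = 8, n_cnvs = 8, n_adjacencies = 4,
                         n_repeat_tracts = 6, n_genes = 3)
  u1 <- generate_universe(cfg, seed = 5)
  u2 <- generate_universe(cfg, seed = 5)
  expect_identical(canonical_serialize(lapply(u1$variants, as_payload)),
                   canonical_serialize(lapply(u2$variants, as_payload)))
  expect_identical(u1$references[["ref1"]]$seq, u2$references[["ref1"]]$seq)

  digests <- vapply(1:10, function(s) compute_digest(
    lapply(generate_universe(cfg, seed = s)$variants, as_payload)), character(1))
  expect_equal(anyDuplicated(digests), 0L)
})

test_that("degenerate configurations are rejected", {
  expect_error(universe_config(n_genes = 0), class = "cv_error_bad_config")
  expect_error(universe_config(ref_length = 100), class = "cv_error_bad_config")
  expect_error(universe_config(n_indels = 1000, n_repeat_tracts = 2),
               class = "cv_error_bad_config")
})

test_that("every generated variant validates against its reference", {
  u <- small_universe(seed = 41)
  for (v in u$variants) {
    expect_true(report_ok(validate_molecular_variant(v, u$references)),
                label = v$id)
  }
  # planted indels all expose at least two equivalent spellings
  expect_gt(length(u$indel_spellings), 0L)
  for (id in names(u$indel_spellings)) {
    expect_gte(length(u$indel_spellings[[id]]), 2L)
  }
})

test_that("extensions behave as set semantics demand on constructed categories", {
  u <- small_universe(seed = 42)
  ctx <- build_context(u)
  target <- Filter(function(v) v$kind == "ALLELE", u$variants)[[3]]
  singleton <- categorical_variant("one", "", list(defining_allele(target$payload)))
  expect_identical(extension(singleton, u, ctx), target$id)

  contradictory <- categorical_variant("none", "", list(
    copy_count(0, 1), copy_count(3, 4)))
  expect_identical(extension(contradictory, u, ctx), character(0))
})

test_that("appending a constraint never enlarges an extension", {
  u <- small_universe(seed = 43)
  ctx <- build_context(u)
  for (s in 1:20) {
    cv <- generate_random_category(u, seed = 900 + s)
    extra <- generate_random_category(u, seed = 950 + s)$constraints[[1]]
    wider <- extension(cv, u, ctx)
    narrower <- extension(categorical_variant(
      cv$id, cv$label, c(cv$constraints, list(extra))), u, ctx)
    expect_true(all(narrower %in% wider))
  }
})

test_that("random categories are reproducible, valid, and honour requested profiles", {
  u <- small_universe(seed = 44)
  expect_identical(canonical_serialize(generate_random_category(u, seed = 7)),
                   canonical_serialize(generate_random_category(u, seed = 7)))
  for (s in 1:40) {
    cv <- generate_random_category(u, seed = s)
    expect_true(report_ok(validate_categorical_variant(cv, u$references)))
  }
  for (p in c("CanonicalAllele", "ProteinSequenceConsequence", "CategoricalCNV",
              "FunctionVariant", "GeneFusion")) {
    cv <- generate_random_category(u, seed = 77, profile = p)
    expect_true(report_ok(validate_profile(cv, p, references = u$references)),
                label = p)
  }
  expect_error(generate_random_category(u, seed = 1, profile = "Nope"),
               class = "cv_error_unknown_profile")
})

test_that("oracle entailment is reflexive and detects planted subset structure", {
  u <- small_universe(seed = 45)
  ctx <- build_context(u)
  cv <- generate_random_category(u, seed = 3)
  expect_true(oracle_entails(cv, cv, u, ctx)$holds)

  gene <- u$features[u$features$class == "gene", ][1, ]
  narrow <- categorical_variant("n", "", list(feature_context(gene$id),
                                              copy_count(0, 1)))
  wide <- categorical_variant("w", "", list(feature_context(gene$id),
                                            copy_count(0, 3)))
  o <- oracle_entails(narrow, wide, u, ctx)
  expect_true(o$holds)
  expect_null(o$witness)
})

test_that("the planted exon-deletion scenario recovers its ground truth exactly", {
  u <- generate_exon_deletion_universe(seed = 9)
  ctx <- build_context(u)
  ext <- extension(u$planted$category, u, ctx)
  expect_identical(sort(ext), sort(u$planted$inside_ids))
  expect_length(ext, u$planted$n_inside)
})

test_that("universes survive the trip through their public file formats", {
  u <- small_universe(seed = 46)
  dir <- withr::local_tempdir()
  write_universe(u, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "references.fasta", "features.tsv", "variants.vcf", "annotations.tsv",
    "indel_spellings.vcf")))))
  back <- read_universe(dir)
  expect_equal(nrow(back$skipped), 0L)
  expect_length(back$variants, length(u$variants))
  expect_equal(as.data.frame(back$features), as.data.frame(u$features))
  # allele digests agree between the in-memory world and the file trip
  mem <- Filter(function(v) v$kind == "ALLELE", u$variants)
  got <- Filter(function(v) v$kind == "ALLELE", back$variants)
  mem_d <- stats::setNames(vapply(mem, `[[`, character(1), "digest_id"),
                           vapply(mem, `[[`, character(1), "id"))
  for (v in got) expect_identical(v$digest_id, unname(mem_d[[v$id]]), label = v$id)
})
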