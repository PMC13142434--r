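test_that("every shipped fixture classifies to exactly the profile its filename declares", {
  cases <- c(tp53_cnloss = "CategoricalCNV",
             canonical_allele = "CanonicalAllele",
             protein_sequence_consequence = "ProteinSequenceConsequence",
             function_variant = "FunctionVariant",
             gene_fusion = "GeneFusion")
  for (f in names(cases)) {
    cv <- read_categorical_variants(extdata(paste0(f, ".json")))$catvars[[1]]
    expect_identical(classify_profile(cv), unname(cases[[f]]), label = f)
    expect_true(report_ok(validate_profile(cv, cases[[f]])), label = f)
  }
})

test_that("profile shape rules reject extra, missing, and over-counted constraints", {
  al <- defining_allele(allele(seq_location("chr1", 10, 11), "T"))
  ok <- categorical_variant("p1", "", list(al))
  expect_true(report_ok(validate_profile(ok, "CanonicalAllele")))

  extra <- categorical_variant("p2", "", list(al, copy_count(1, 2)))
  rep2 <- validate_profile(extra, "CanonicalAllele")
  expect_true("UNEXPECTED_CONSTRAINT" %in% rep2$code)

  cnv_no_dose <- categorical_variant("p3", "", list(feature_context("TP53")))
  expect_true("MISSING_CONSTRAINT" %in%
                validate_profile(cnv_no_dose, "CategoricalCNV")$code)

  cnv_two_dose <- categorical_variant("p4", "", list(
    feature_context("TP53"), copy_count(0, 1), copy_change("LOSS")))
  expect_true("BAD_CARDINALITY" %in%
                validate_profile(cnv_two_dose, "CategoricalCNV")$code)

  expect_error(validate_profile(ok, "NoSuchProfile"),
               class = "cv_error_unknown_profile")
})

test_that("alphabet extra rules separate the two allele profiles", {
  refs <- as_reference_registry(list(dna1 = "ACGTACGTACGT", prot1 = "MKLVW"))
  on_dna <- categorical_variant("d", "", list(
    defining_allele(allele(seq_location("dna1", 2, 3), "A"))))
  on_prot <- categorical_variant("p", "", list(
    defining_allele(allele(seq_location("prot1", 2, 3), "A"))))
  expect_identical(classify_profile(on_dna, references = refs), "CanonicalAllele")
  expect_identical(classify_profile(on_prot, references = refs),
                   "ProteinSequenceConsequence")
  expect_true("WRONG_ALPHABET" %in%
                validate_profile(on_prot, "CanonicalAllele", references = refs)$code)
})

test_that("profile validity is invariant under constraint permutation and can be empty", {
  ks <- list(feature_context("TP53"),
             defining_location(seq_location("r", 0, 100)), copy_change("LOSS"))
  for (perm in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    cv <- categorical_variant("x", "", ks[perm])
    expect_identical(classify_profile(cv), "CategoricalCNV")
  }
  lone_function <- categorical_variant("y", "", list(
    function_constraint("loss_of_function")))
  expect_identical(classify_profile(lone_function), character(0))
})

test_that("gene fusions accept either feature-sided adjacency shape", {
  one <- categorical_variant("f1", "", list(adjacency_constraint("BCR", "ABL1")))
  expect_true(report_ok(validate_profile(one, "GeneFusion")))
  by_loc <- categorical_variant("f2", "", list(
    adjacency_constraint(seq_location("r", 0, 10), "ABL1")))
  expect_true("SIDES_NOT_FEATURES" %in% validate_profile(by_loc, "GeneFusion")$code)
  two <- categorical_variant("f3", "", list(
    feature_context("BCR"), feature_context("ABL1"),
    adjacency_constraint(seq_location("r", 0, 10), "ABL1")))
  expect_true(report_ok(validate_profile(two, "GeneFusion")))
})

test_that("a registry loaded from JSON drives validation like the built-in one", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('[
    {"name": "DoseOnGene", "maturity": "Draft",
     "shapes": [{"FEATURE_CONTEXT": [1, 1], "COPY_COUNT|COPY_CHANGE": [1, null]}]}
  ]', path)
  reg <- read_profile_registry(path)
  expect_named(reg, "DoseOnGene")
  cv <- categorical_variant("z", "", list(feature_context("TP53"),
                                          copy_change("LOSS"), copy_count(0, 1)))
  expect_true(report_ok(validate_profile(cv, "DoseOnGene", registry = reg)))
  expect_identical(classify_profile(cv, registry = reg), "DoseOnGene")
  expect_false(report_ok(validate_profile(
    categorical_variant("z2", "", list(copy_count(0, 1))), "DoseOnGene",
    registry = reg)))
})

test_that("maturity labels mark the in-progress profiles as experimental", {
  expect_setequal(experimental_profiles(), c("FunctionVariant", "GeneFusion"))
  expect_setequal(experimental_kinds(), c("FUNCTION", "ADJACENCY"))
})
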