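test_that("the packaged TP53 copy-loss category is structurally valid", {
  cv <- tp53_catvar()
  expect_length(cv$constraints, 3L)
  report <- validate_categorical_variant(cv)
  expect_true(report_ok(report))
  expect_equal(sum(report$level == "error"), 0L)
})

test_that("invariant violations are reported as data with stable codes", {
  empty <- categorical_variant("c0", "no constraints", list())
  expect_false(report_ok(validate_categorical_variant(empty)))
  expect_true("EMPTY_CONSTRAINTS" %in% validate_categorical_variant(empty)$code)

  bad_range <- categorical_variant("c1", "inverted range", list(copy_count(3, 1)))
  expect_true("BAD_RANGE" %in% validate_categorical_variant(bad_range)$code)

  bad_loc <- categorical_variant("c2", "inverted interval", list(
    defining_location(seq_location("r", 10, 5))))
  expect_true("BAD_INTERVAL" %in% validate_categorical_variant(bad_loc)$code)

  refs <- as_reference_registry(list(r = "ACGTACGT"))
  oob <- categorical_variant("c3", "out of bounds", list(
    defining_location(seq_location("r", 2, 50))))
  expect_true("OUT_OF_BOUNDS" %in% validate_categorical_variant(oob, refs)$code)

  alpha <- categorical_variant("c4", "protein state on DNA", list(
    defining_allele(allele(seq_location("r", 1, 2), "W"))))
  expect_true("ALPHABET_MISMATCH" %in% validate_categorical_variant(alpha, refs)$code)
})

test_that("validation is invariant under constraint permutation", {
  ks <- list(copy_count(3, 1), feature_context("TP53"),
             defining_location(seq_location("r", 9, 4)), copy_change("LOSS"))
  a <- validate_categorical_variant(categorical_variant("p", "", ks))
  b <- validate_categorical_variant(categorical_variant("p", "", rev(ks)))
  expect_setequal(a$code, b$code)
  expect_equal(nrow(a), nrow(b))
})

test_that("repeated kinds notice and unknown declared profile warning are non-fatal", {
  cv <- categorical_variant("c5", "two locations", list(
    defining_location(seq_location("r", 0, 10)),
    defining_location(seq_location("r", 5, 20))),
    declared_profile = "NoSuchProfile")
  report <- validate_categorical_variant(cv)
  expect_true(report_ok(report))
  expect_true("REPEATED_KIND" %in% report$code[report$level == "info"])
  expect_true("UNKNOWN_PROFILE" %in% report$code[report$level == "warning"])
})

test_that("molecular variant kind tags must match the payload", {
  al <- allele(seq_location("r", 3, 4), "A")
  ok <- molecular_variant("v1", al)
  expect_identical(ok$kind, "ALLELE")
  expect_true(report_ok(validate_molecular_variant(ok)))
  mismatched <- molecular_variant("v2", al, kind = "COPY_NUMBER")
  expect_true("KIND_MISMATCH" %in% validate_molecular_variant(mismatched)$code)
})

test_that("copy-number variants require a count or a change code", {
  loc <- seq_location("r", 0, 100)
  expect_error(copy_number(loc), class = "cv_error_missing_copy_state")
  expect_silent(copy_number(loc, count = 0))
  expect_silent(copy_number(loc, change_code = "COMPLETE_LOSS"))
  expect_error(copy_number(loc, change_code = "SOMewhat"), class = "cv_error_unknown_code")
})
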