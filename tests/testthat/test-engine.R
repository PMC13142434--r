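test_that("a chr17 copy-loss overlapping TP53 is a member of the TP53 CNLoss category", {
  cv <- tp53_catvar()
  ctx <- tp53_context()
  cnv <- molecular_variant("del17p", copy_number(
    seq_location("GRCh38:chr17", 6000000, 8000000), count = 1,
    change_code = "LOSS"))
  report <- match_variant(cv, cnv, ctx)
  expect_true(report$overall)
  expect_true(all(vapply(report$verdicts, function(v) v$status, character(1)) ==
                    "SATISFIED"))

  # an SNV inside TP53 satisfies the location but not the dosage constraint
  snv <- molecular_variant("snv_tp53", allele(
    seq_location("GRCh38:chr17", 7675000, 7675001), "T"))
  report2 <- match_variant(cv, snv, ctx)
  expect_false(report2$overall)
  statuses <- vapply(report2$verdicts, function(v) v$status, character(1))
  expect_identical(statuses[3], "INAPPLICABLE")  # CopyChange lacks its attribute
  expect_identical(statuses[2], "SATISFIED")
})

test_that("copy-count and copy-change semantics honour boundaries and the hierarchy", {
  ctx <- evaluation_context()
  loc <- seq_location("r", 100, 200)
  two <- molecular_variant("cn2", copy_number(loc, count = 2))
  three <- molecular_variant("cn3", copy_number(loc, count = 3))
  expect_identical(evaluate_constraint(copy_count(2, 2), two, ctx)$status, "SATISFIED")
  expect_identical(evaluate_constraint(copy_count(2, 2), three, ctx)$status, "UNSATISFIED")

  complete <- molecular_variant("cn0", copy_number(loc, change_code = "COMPLETE_LOSS"))
  expect_identical(evaluate_constraint(copy_change("LOSS"), complete, ctx)$status,
                   "SATISFIED")
  expect_identical(evaluate_constraint(copy_change("COMPLETE_LOSS"),
    molecular_variant("cnl", copy_number(loc, change_code = "LOSS")), ctx)$status,
    "UNSATISFIED")
  gain <- molecular_variant("cng", copy_number(loc, change_code = "HIGH_LEVEL_GAIN"))
  expect_identical(evaluate_constraint(copy_change("LOSS"), gain, ctx)$status,
                   "UNSATISFIED")
  # a bare count never satisfies a change-code constraint
  expect_identical(evaluate_constraint(copy_change("LOSS"), two, ctx)$status,
                   "INAPPLICABLE")
})

test_that("applicability depends on attribute presence, never attribute values", {
  ctx <- evaluation_context(
    feature_table = feature_table_from_df(data.frame(
      id = "G1", symbol = "GENE1", sequence_id = "r", start = 10, end = 90)),
    function_hierarchy = default_function_hierarchy())
  snv <- molecular_variant("s", allele(seq_location("r", 50, 51), "A"))
  expect_identical(evaluate_constraint(copy_change("LOSS"), snv, ctx)$status,
                   "INAPPLICABLE")
  expect_identical(evaluate_constraint(copy_count(0, 9), snv, ctx)$status,
                   "INAPPLICABLE")
  expect_identical(evaluate_constraint(function_constraint("loss_of_function"),
                                       snv, ctx)$status, "INAPPLICABLE")
  annotated <- molecular_variant("s2", allele(seq_location("r", 50, 51), "A"),
    annotation = variant_annotation("GENE1", "missense_variant"))
  expect_identical(evaluate_constraint(function_constraint("loss_of_function"),
                                       annotated, ctx)$status, "UNSATISFIED")
  expect_identical(evaluate_constraint(function_constraint("protein_altering"),
                                       annotated, ctx)$status, "SATISFIED")
  # feature context: via overlap, via symbol, and inapplicable without either
  expect_identical(evaluate_constraint(feature_context("G1"), snv, ctx)$status,
                   "SATISFIED")
  off <- molecular_variant("s3", allele(seq_location("other", 5, 6), "A"),
                           annotation = variant_annotation("gene1"))
  expect_identical(evaluate_constraint(feature_context("G1"), off, ctx)$status,
                   "SATISFIED")  # case-insensitive symbol match
  adj <- molecular_variant("a1", adjacency(seq_location("r", 20, 21),
                                           seq_location("r", 70, 71)))
  expect_identical(evaluate_constraint(feature_context("G1"), adj, ctx)$status,
                   "INAPPLICABLE")
  expect_error(evaluate_constraint(feature_context("NOPE"), snv, ctx),
               class = "cv_error_unknown_feature")
})

test_that("defining-allele matching goes through normalization and equivalence tables", {
  ref <- "GGCAGAGAGATT"
  regs <- as_reference_registry(list(r = ref))
  ctx <- evaluation_context(references = regs)
  k <- defining_allele(allele(seq_location("r", 3, 5), ""))
  shifted <- molecular_variant("v", allele(seq_location("r", 5, 7), ""))
  expect_identical(evaluate_constraint(k, shifted, ctx)$status, "SATISFIED")
  other <- molecular_variant("w", allele(seq_location("r", 1, 2), "T"))
  expect_identical(evaluate_constraint(k, other, ctx)$status, "UNSATISFIED")
  cnv <- molecular_variant("c", copy_number(seq_location("r", 0, 10), count = 1))
  expect_identical(evaluate_constraint(k, cnv, ctx)$status, "INAPPLICABLE")

  # a foreign digest mapped onto the defining allele's digest also satisfies
  want <- normalize_allele(k$allele, ref)$digest_id
  have <- normalize_allele(other$payload, ref)$digest_id
  ctx_eq <- evaluation_context(references = regs,
                               allele_equivalences = stats::setNames(want, have))
  expect_identical(evaluate_constraint(k, other, ctx_eq)$status, "SATISFIED")
})

test_that("adjacency constraints resolve sides and honour the ordered flag", {
  ft <- feature_table_from_df(data.frame(
    id = c("GA", "GB"), symbol = c("GA", "GB"), sequence_id = c("r1", "r2"),
    start = c(100, 400), end = c(200, 600)))
  ctx <- evaluation_context(feature_table = ft)
  fwd <- molecular_variant("f", adjacency(seq_location("r1", 150, 151),
                                          seq_location("r2", 500, 501)))
  rev <- molecular_variant("g", adjacency(seq_location("r2", 500, 501),
                                          seq_location("r1", 150, 151)))
  ordered <- adjacency_constraint("GA", "GB", ordered = TRUE)
  unordered <- adjacency_constraint("GA", "GB", ordered = FALSE)
  expect_identical(evaluate_constraint(ordered, fwd, ctx)$status, "SATISFIED")
  expect_identical(evaluate_constraint(ordered, rev, ctx)$status, "UNSATISFIED")
  expect_identical(evaluate_constraint(unordered, rev, ctx)$status, "SATISFIED")
  snv <- molecular_variant("s", allele(seq_location("r1", 150, 151), "A"))
  expect_identical(evaluate_constraint(ordered, snv, ctx)$status, "INAPPLICABLE")
  by_loc <- adjacency_constraint(seq_location("r1", 140, 160), "GB")
  expect_identical(evaluate_constraint(by_loc, fwd, ctx)$status, "SATISFIED")
})

test_that("batch matching equals elementwise matching and respects ordering", {
  u <- small_universe()
  ctx <- build_context(u)
  cats <- lapply(1:3, function(s) generate_random_category(u, seed = 100 + s))
  vars <- u$variants[1:10]
  batch <- match_batch(cats, vars, ctx)
  expect_equal(dim(batch$overall), c(3L, 10L))
  for (i in 1:3) for (j in 1:10) {
    expect_identical(batch$overall[i, j],
                     match_variant(cats[[i]], vars[[j]], ctx)$overall)
  }
  perm <- c(4, 1, 9, 2)
  batch2 <- match_batch(cats, vars[perm], ctx)
  expect_identical(batch2$overall, batch$overall[, perm])

  single <- match_batch(cats[1], vars[1], ctx)
  expect_equal(dim(single$overall), c(1L, 1L))
  expect_identical(single$reports[[1, 1]]$overall,
                   match_variant(cats[[1]], vars[[1]], ctx)$overall)

  # the batch path must reproduce the brute-force extension exactly
  full <- match_batch(cats, u$variants, ctx)
  for (i in 1:3) {
    ids <- vapply(u$variants, `[[`, character(1), "id")
    expect_identical(ids[full$overall[i, ]], extension(cats[[i]], u, ctx))
  }
})
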