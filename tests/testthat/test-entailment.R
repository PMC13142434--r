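ctx0 <- evaluation_context(feature_table = feature_table_from_df(data.frame(
  id = "G1", symbol = "GENE1", sequence_id = "r", start = 50, end = 500)))

test_that("constraint subsumption follows the closed rule set", {
  expect_identical(subsumes(copy_change("COMPLETE_LOSS"), copy_change("LOSS"),
                            ctx0)$status, "ENTAILS")
  expect_identical(subsumes(copy_change("LOSS"), copy_change("COMPLETE_LOSS"),
                            ctx0)$status, "UNKNOWN")
  expect_identical(subsumes(copy_change("LOSS"), copy_change("GAIN"),
                            ctx0)$status, "UNKNOWN")

  expect_identical(subsumes(copy_count(0, 1), copy_count(0, 2), ctx0)$status,
                   "ENTAILS")
  # disjoint ranges are not decided at rule level
  expect_identical(subsumes(copy_count(0, 1), copy_count(2, 4), ctx0)$status,
                   "UNKNOWN")

  inner <- defining_location(seq_location("r", 100, 200), "CONTAINED")
  outer <- defining_location(seq_location("r", 50, 500), "CONTAINED")
  expect_identical(subsumes(inner, outer, ctx0)$status, "ENTAILS")
  expect_identical(subsumes(outer, inner, ctx0)$status, "UNKNOWN")
  expect_identical(subsumes(inner, feature_context("G1"), ctx0)$status, "ENTAILS")
  expect_identical(subsumes(feature_context("G1"), feature_context("G1"),
                            ctx0)$status, "ENTAILS")
  # cross-kind pairs outside the rules stay unknown
  expect_identical(subsumes(function_constraint("loss_of_function"),
                            copy_change("LOSS"), ctx0)$status, "UNKNOWN")
})

test_that("a defining allele is subsumed by regions covering its justified interval", {
  ref <- "GGCAGAGAGATT"
  ctx <- evaluation_context(references = as_reference_registry(list(r = ref)))
  da <- defining_allele(allele(seq_location("r", 3, 5), ""))  # justifies to [3,10)
  expect_identical(subsumes(da, defining_location(seq_location("r", 0, 12),
                                                  "CONTAINED"), ctx)$status,
                   "ENTAILS")
  expect_identical(subsumes(da, defining_location(seq_location("r", 0, 6),
                                                  "CONTAINED"), ctx)$status,
                   "UNKNOWN")
})

test_that("categories entail componentwise and every category entails itself", {
  a <- categorical_variant("a", "", list(
    defining_location(seq_location("r", 100, 150), "CONTAINED"), copy_count(0, 1)))
  b <- categorical_variant("b", "", list(
    defining_location(seq_location("r", 50, 500), "CONTAINED"), copy_count(0, 2)))
  v <- entails(a, b, ctx0)
  expect_identical(v$status, "ENTAILS")
  expect_identical(entails(b, a, ctx0)$status, "UNKNOWN")
  expect_identical(entails(a, a, ctx0)$status, "ENTAILS")

  u <- small_universe()
  ctx <- build_context(u)
  for (s in 1:20) {
    cv <- generate_random_category(u, seed = 400 + s)
    expect_identical(entails(cv, cv, ctx)$status, "ENTAILS")
  }
})

test_that("probing a finite universe turns refuted unknowns into counterexamples", {
  u <- small_universe()
  ctx <- build_context(u)
  gene <- u$features[u$features$class == "gene", ][1, ]
  wide <- categorical_variant("w", "any dosage on gene", list(
    feature_context(gene$id)))
  narrow <- categorical_variant("n", "deep loss on gene", list(
    feature_context(gene$id), copy_change("LOSS")))
  # narrow -> wide holds syntactically; wide -> narrow needs a witness
  expect_identical(entails(narrow, wide, ctx)$status, "ENTAILS")
  v <- entails(wide, narrow, ctx, probe_universe = u)
  if (v$status == "NOT_ENTAILED") {
    expect_true(v$witness %in% extension(wide, u, ctx))
    expect_false(v$witness %in% extension(narrow, u, ctx))
  } else {
    expect_identical(v$status, "UNKNOWN")
  }
})

test_that("entailment verdicts are sound against the brute-force oracle", {
  u <- small_universe(seed = 21)
  ctx <- build_context(u)
  cats <- lapply(1:20, function(s) generate_random_category(u, seed = 500 + s))
  exts <- lapply(cats, extension, universe = u, ctx = ctx)
  verdicts <- matrix("", 20, 20)
  for (i in 1:20) for (j in 1:20) {
    verdicts[i, j] <- entails(cats[[i]], cats[[j]], ctx)$status
    if (verdicts[i, j] == "ENTAILS") {
      expect_true(all(exts[[i]] %in% exts[[j]]),
                  info = sprintf("pair (%d,%d)", i, j))
    }
  }
  # ENTAILS-fragment transitivity: never refuted on sampled triples
  ent <- which(verdicts == "ENTAILS", arr.ind = TRUE)
  for (r in seq_len(nrow(ent))) {
    i <- ent[r, 1]; j <- ent[r, 2]
    ks <- which(verdicts[j, ] == "ENTAILS")
    for (k in ks) {
      expect_false(identical(entails(cats[[i]], cats[[k]], ctx)$status,
                             "NOT_ENTAILED"))
    }
  }
})
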