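# Profiles: named structural templates over constraint kinds. Profiles are
# data (a registry), not code — adopters can register local templates; the
# shipped registry holds the five standard category types with their
# maturity labels.

profile_def <- function(name, maturity, shapes, allele_alphabet = NULL,
                        adjacency_sides = NULL) {
  structure(list(name = name, maturity = maturity, shapes = shapes,
                 allele_alphabet = allele_alphabet,
                 adjacency_sides = adjacency_sides),
            class = "cv_profile")
}

shape <- function(...) {
  # named arguments kind = c(min, max); the shape also fixes the allowed kinds
  groups <- list(...)
  lapply(groups, function(g) c(min = g[[1]], max = g[[2]]))
}

#' The shipped profile registry
#'
#' Five named structural templates for common categorical-variant shapes:
#'
#' | profile | maturity | shape |
#' |---|---|---|
#' | `CanonicalAllele` | Trial use | one defining allele on a DNA reference |
#' | `ProteinSequenceConsequence` | Trial use | one defining allele on a protein reference |
#' | `CategoricalCNV` | Draft | at least one of defining location / feature context, exactly one of copy count / copy change |
#' | `FunctionVariant` | In progress | one feature context plus one function constraint |
#' | `GeneFusion` | In progress | one adjacency with both sides feature-specified, or two feature contexts plus one adjacency |
#'
#' "In progress" profiles are experimental: command-line use requires
#' `--experimental`.
#'
#' @return A named list of profile definitions.
#' @export
profile_registry <- function() {
  list(
    CanonicalAllele = profile_def(
      "CanonicalAllele", "Trial use",
      shapes = list(shape(DEFINING_ALLELE = c(1, 1))),
      allele_alphabet = "DNA"),
    ProteinSequenceConsequence = profile_def(
      "ProteinSequenceConsequence", "Trial use",
      shapes = list(shape(DEFINING_ALLELE = c(1, 1))),
      allele_alphabet = "PROTEIN"),
    CategoricalCNV = profile_def(
      "CategoricalCNV", "Draft",
      shapes = list(shape(`DEFINING_LOCATION|FEATURE_CONTEXT` = c(1, Inf),
                          `COPY_COUNT|COPY_CHANGE` = c(1, 1)))),
    FunctionVariant = profile_def(
      "FunctionVariant", "In progress",
      shapes = list(shape(FEATURE_CONTEXT = c(1, 1), FUNCTION = c(1, 1)))),
    GeneFusion = profile_def(
      "GeneFusion", "In progress",
      shapes = list(shape(ADJACENCY = c(1, 1)),
                    shape(FEATURE_CONTEXT = c(2, 2), ADJACENCY = c(1, 1))),
      adjacency_sides = "features")
  )
}

profile_names <- function(registry = profile_registry()) {
  vapply(registry, `[[`, character(1), "name")
}

#' Experimental profile names
#' @param registry A profile registry.
#' @return Names of profiles with "In progress" maturity.
#' @export
experimental_profiles <- function(registry = profile_registry()) {
  names(registry)[vapply(registry, function(p) p$maturity == "In progress", logical(1))]
}

#' Load a profile registry from JSON
#'
#' Local implementations can replace or extend the shipped registry with a
#' JSON array of profile objects: `name`, `maturity`, `shapes` (an array
#' of objects mapping a kind pattern like `"DEFINING_LOCATION|FEATURE_CONTEXT"`
#' to `[min, max]`, `null` max meaning unbounded), and optional
#' `alleleAlphabet` / `adjacencySides` extra rules.
#'
#' @param path Path to the JSON file.
#' @return A named list of profile definitions.
#' @export
read_profile_registry <- function(path) {
  docs <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = "\n"),
                             simplifyVector = FALSE)
  out <- lapply(docs, function(d) {
    shapes <- lapply(d$shapes, function(sh) {
      lapply(sh, function(g) {
        mx <- if (is.null(g[[2]])) Inf else as.numeric(g[[2]])
        c(min = as.numeric(g[[1]]), max = mx)
      })
    })
    profile_def(d$name, if (is.null(d$maturity)) "Draft" else d$maturity,
                shapes = shapes,
                allele_alphabet = d$alleleAlphabet,
                adjacency_sides = d$adjacencySides)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

shape_violations <- function(kinds, sh, catvar, profile) {
  report <- new_report()
  allowed <- unlist(strsplit(names(sh), "|", fixed = TRUE))
  extra <- setdiff(kinds, allowed)
  for (k in unique(extra)) {
    report <- add_violation(report, "UNEXPECTED_CONSTRAINT",
      sprintf("profile %s does not allow %s constraints", profile, k))
  }
  for (pat in names(sh)) {
    members <- unlist(strsplit(pat, "|", fixed = TRUE))
    nfound <- sum(kinds %in% members)
    if (nfound < sh[[pat]][["min"]]) {
      report <- add_violation(report, "MISSING_CONSTRAINT",
        sprintf("profile %s requires at least %d of {%s}, found %d",
                profile, sh[[pat]][["min"]], paste(members, collapse = ", "), nfound))
    } else if (nfound > sh[[pat]][["max"]]) {
      report <- add_violation(report, "BAD_CARDINALITY",
        sprintf("profile %s allows at most %d of {%s}, found %d",
                profile, sh[[pat]][["max"]], paste(members, collapse = ", "), nfound))
    }
  }
  report
}

#' Validate a category against a named profile
#'
#' Checks that the category's constraint multiset matches the profile's
#' structural template, plus the profile's extra rules: defining-allele
#' alphabet for the allele profiles (resolved through `references` when
#' the sequence is known, otherwise inferred from the state string) and
#' feature-specified adjacency sides for single-adjacency gene fusions.
#' Profile validity does not depend on constraint order.
#'
#' @param catvar A [categorical_variant()].
#' @param profile Profile name.
#' @param registry A profile registry (default [profile_registry()]).
#' @param references Optional reference registry for alphabet resolution.
#' @return A `cv_report`; see [report_ok()].
#' @export
validate_profile <- function(catvar, profile, registry = profile_registry(),
                             references = NULL) {
  def <- registry[[profile]]
  if (is.null(def))
    stop(cv_error("UNKNOWN_PROFILE", paste0("profile not registered: ", profile)))
  kinds <- vapply(catvar$constraints, function(k)
    if (inherits(k, "cv_constraint")) k$kind else "?", character(1))
  # a category fits a profile when any one of its shapes accepts it
  reports <- lapply(def$shapes, shape_violations, kinds = kinds,
                    catvar = catvar, profile = profile)
  ok <- vapply(reports, report_ok, logical(1))
  report <- if (any(ok)) new_report() else reports[[which.min(vapply(reports, nrow, 0L))]]

  if (report_ok(report) && !is.null(def$allele_alphabet)) {
    for (k in catvar$constraints) {
      if (inherits(k, "cv_constraint") && k$kind == "DEFINING_ALLELE") {
        alpha <- allele_reference_alphabet(k$allele, references)
        if (!is.na(alpha) && alpha != def$allele_alphabet) {
          report <- add_violation(report, "WRONG_ALPHABET",
            sprintf("profile %s requires a %s reference, allele sits on %s",
                    profile, def$allele_alphabet, alpha))
        }
      }
    }
  }
  if (report_ok(report) && identical(def$adjacency_sides, "features") &&
      sum(kinds == "FEATURE_CONTEXT") == 0L) {
    for (k in catvar$constraints) {
      if (inherits(k, "cv_constraint") && k$kind == "ADJACENCY" &&
          !(is.character(k$side_a) && is.character(k$side_b))) {
        report <- add_violation(report, "SIDES_NOT_FEATURES",
          sprintf("profile %s requires both adjacency sides to name features", profile))
      }
    }
  }
  report
}

allele_reference_alphabet <- function(al, references) {
  if (!is.null(references)) {
    a <- reference_alphabet(as_reference_registry(references), al$location$sequence_id)
    if (!is.na(a)) return(a)
  }
  if (!nzchar(al$state)) return(NA_character_)
  infer_alphabet(al$state)
}

#' Classify a category against all registered profiles
#'
#' @inheritParams validate_profile
#' @return Character vector of profile names whose validation passes, in
#'   registry order; empty when none match.
#' @export
classify_profile <- function(catvar, registry = profile_registry(),
                             references = NULL) {
  hits <- vapply(names(registry), function(p)
    report_ok(validate_profile(catvar, p, registry, references)), logical(1))
  names(registry)[hits]
}
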