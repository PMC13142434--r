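# Structural validation. Violations are data (a report), not exceptions:
# a malformed document must never abort a batch.

new_report <- function() {
  structure(data.frame(code = character(), level = character(),
                       where = character(), message = character(),
                       stringsAsFactors = FALSE),
            class = c("cv_report", "data.frame"))
}

add_violation <- function(report, code, message, level = "error", where = "") {
  row <- data.frame(code = code, level = level, where = where,
                    message = message, stringsAsFactors = FALSE)
  structure(rbind(report, row), class = c("cv_report", "data.frame"))
}

#' Is a validation report clean?
#'
#' @param report A report from [validate_categorical_variant()] or
#'   [validate_profile()].
#' @return `TRUE` when the report contains no `error`-level violations
#'   (warnings and informational notices do not invalidate).
#' @export
report_ok <- function(report) {
  !any(report$level == "error")
}

#' @export
print.cv_report <- function(x, ...) {
  if (nrow(x) == 0L) cat("valid: no violations\n")
  else print.data.frame(x, row.names = FALSE)
  invisible(x)
}

check_location <- function(report, loc, where, references = NULL) {
  if (!inherits(loc, "cv_location")) {
    return(add_violation(report, "BAD_LOCATION", "not a sequence location", where = where))
  }
  if (is.na(loc$start) || is.na(loc$end) || loc$start < 0L || loc$start > loc$end) {
    report <- add_violation(report, "BAD_INTERVAL",
      sprintf("need 0 <= start <= end, got [%s,%s)", loc$start, loc$end), where = where)
  }
  if (!is.null(references) && loc$sequence_id %in% names(references)) {
    len <- reference_length(references, loc$sequence_id)
    if (!is.na(len) && loc$end > len) {
      report <- add_violation(report, "OUT_OF_BOUNDS",
        sprintf("interval [%d,%d) exceeds reference %s length %d",
                loc$start, loc$end, loc$sequence_id, len), where = where)
    }
  }
  report
}

check_constraint <- function(report, k, i, references = NULL) {
  where <- sprintf("constraints[%d]", i)
  if (!inherits(k, "cv_constraint") || is.null(k$kind)) {
    return(add_violation(report, "BAD_CONSTRAINT", "not a constraint object", where = where))
  }
  if (!k$kind %in% constraint_kinds()) {
    return(add_violation(report, "UNKNOWN_KIND",
                         paste0("unknown constraint kind: ", k$kind), where = where))
  }
  switch(k$kind,
    DEFINING_ALLELE = {
      if (!inherits(k$allele, "cv_allele")) {
        report <- add_violation(report, "BAD_ALLELE", "missing or malformed allele", where = where)
      } else {
        report <- check_location(report, k$allele$location, where, references)
        alpha <- state_alphabet_ok(k$allele, references)
        if (!alpha) {
          report <- add_violation(report, "ALPHABET_MISMATCH",
            "allele state contains symbols outside the reference alphabet", where = where)
        }
      }
    },
    DEFINING_LOCATION = {
      report <- check_location(report, k$location, where, references)
      if (!k$match_mode %in% c("EXACT", "CONTAINED", "OVERLAPS")) {
        report <- add_violation(report, "BAD_MATCH_MODE",
          paste0("unknown match mode: ", k$match_mode), where = where)
      }
    },
    COPY_COUNT = {
      if (is.na(k$min) || is.na(k$max) || k$min > k$max) {
        report <- add_violation(report, "BAD_RANGE",
          sprintf("copy-count range [%s,%s] is empty or malformed", k$min, k$max),
          where = where)
      } else if (k$min < 0L) {
        report <- add_violation(report, "NEGATIVE_COPIES",
          "copy counts cannot be negative", where = where)
      }
    },
    COPY_CHANGE = {
      if (!k$code %in% copy_change_codes()) {
        report <- add_violation(report, "UNKNOWN_CODE",
          paste0("unknown copy-change code: ", k$code), where = where)
      }
    },
    FEATURE_CONTEXT = {
      if (!is.character(k$feature) || !nzchar(k$feature)) {
        report <- add_violation(report, "BAD_FEATURE", "empty feature reference", where = where)
      }
    },
    FUNCTION = {
      if (!is.character(k$term) || !nzchar(k$term)) {
        report <- add_violation(report, "BAD_TERM", "empty function term", where = where)
      }
    },
    ADJACENCY = {
      for (side in list(k$side_a, k$side_b)) {
        if (inherits(side, "cv_location")) {
          report <- check_location(report, side, where, references)
        } else if (!is.character(side) || !nzchar(side)) {
          report <- add_violation(report, "BAD_SIDE",
            "adjacency side must be a feature id or a location", where = where)
        }
      }
    })
  report
}

# alphabet check only when the reference (hence alphabet) is known
state_alphabet_ok <- function(al, references) {
  if (is.null(references) || !al$location$sequence_id %in% names(references)) return(TRUE)
  alpha <- reference_alphabet(references, al$location$sequence_id)
  state_matches_alphabet(al$state, alpha)
}

state_matches_alphabet <- function(state, alphabet) {
  if (!nzchar(state)) return(TRUE)
  chars <- strsplit(state, "")[[1]]
  allowed <- if (identical(alphabet, "DNA")) strsplit("ACGTUN", "")[[1]]
             else strsplit("ACDEFGHIKLMNPQRSTVWYXBZU*", "")[[1]]
  all(chars %in% allowed)
}

#' Validate a categorical variant
#'
#' Checks every structural invariant of a categorical variant: a non-empty
#' constraint list, well-formed kind-specific parameters (interval order,
#' copy ranges, known vocabulary codes), in-bounds locations and alphabet
#' consistency when a reference registry is supplied. Violations are
#' returned as rows, never raised; repeated constraint kinds yield an
#' informational notice and an unknown declared profile a warning.
#'
#' @param catvar A [categorical_variant()].
#' @param references Optional reference registry
#'   ([as_reference_registry()]) enabling bounds/alphabet checks.
#' @return A `cv_report` data frame with columns `code`, `level`, `where`,
#'   `message`; see [report_ok()].
#' @export
#' @examples
#' cv <- categorical_variant("ex", "bad range", list(copy_count(3, 1)))
#' validate_categorical_variant(cv)
validate_categorical_variant <- function(catvar, references = NULL) {
  report <- new_report()
  if (!inherits(catvar, "cv_catvar")) {
    return(add_violation(report, "NOT_CATEGORICAL_VARIANT",
                         "not a categorical variant object"))
  }
  if (length(catvar$constraints) == 0L) {
    report <- add_violation(report, "EMPTY_CONSTRAINTS",
      "a categorical variant needs at least one constraint")
  }
  for (i in seq_along(catvar$constraints)) {
    report <- check_constraint(report, catvar$constraints[[i]], i, references)
  }
  kinds <- vapply(catvar$constraints, function(k)
    if (inherits(k, "cv_constraint") && !is.null(k$kind)) k$kind else NA_character_,
    character(1))
  dup <- unique(kinds[!is.na(kinds) & duplicated(kinds)])
  for (d in dup) {
    report <- add_violation(report, "REPEATED_KIND",
      sprintf("constraint kind %s appears more than once (conjunction applies)", d),
      level = "info")
  }
  if (!is.null(catvar$declared_profile) &&
      !catvar$declared_profile %in% profile_names()) {
    report <- add_violation(report, "UNKNOWN_PROFILE",
      paste0("declared profile not in registry: ", catvar$declared_profile),
      level = "warning")
  }
  report
}

#' Validate a molecular variant
#'
#' Checks the payload/kind tag agreement and payload well-formedness of an
#' assayed variant.
#'
#' @inheritParams validate_categorical_variant
#' @param variant A [molecular_variant()].
#' @return A `cv_report`.
#' @export
validate_molecular_variant <- function(variant, references = NULL) {
  report <- new_report()
  if (!inherits(variant, "cv_variant")) {
    return(add_violation(report, "NOT_MOLECULAR_VARIANT", "not a molecular variant"))
  }
  expected <- tryCatch(payload_kind(variant$payload), error = function(e) NA_character_)
  if (is.na(expected)) {
    report <- add_violation(report, "BAD_PAYLOAD", "unrecognized payload object")
  } else if (!identical(variant$kind, expected)) {
    report <- add_violation(report, "KIND_MISMATCH",
      sprintf("kind tag %s does not match payload kind %s", variant$kind, expected))
  }
  if (identical(expected, "ALLELE")) {
    report <- check_location(report, variant$payload$location, "payload", references)
  } else if (identical(expected, "COPY_NUMBER")) {
    report <- check_location(report, variant$payload$location, "payload", references)
    if (!is.null(variant$payload$count) && variant$payload$count < 0L) {
      report <- add_violation(report, "NEGATIVE_COPIES", "negative copy count", where = "payload")
    }
  } else if (identical(expected, "ADJACENCY")) {
    report <- check_location(report, variant$payload$breakend_a, "payload.breakendA", references)
    report <- check_location(report, variant$payload$breakend_b, "payload.breakendB", references)
  }
  report
}
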