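# Entailment (subsumption) between categorical variants. The rule set is
# deliberately sound but incomplete: ENTAILS is only produced when a rule
# chain guarantees extension containment in every universe; everything the
# rules cannot decide stays UNKNOWN, optionally refined to NOT_ENTAILED by
# probing a finite universe for a counterexample.

tri_verdict <- function(status, witness = NULL, justification = NULL) {
  structure(list(status = status, witness = witness,
                 justification = justification),
            class = "cv_tri_verdict")
}

#' @export
print.cv_tri_verdict <- function(x, ...) {
  cat(sprintf("<Entailment> %s\n", x$status))
  if (!is.null(x$witness)) cat("  counterexample:", x$witness, "\n")
  if (!is.null(x$justification) && nrow(x$justification) > 0L) {
    print.data.frame(x$justification, row.names = FALSE)
  }
  invisible(x)
}

#' Does one constraint subsume another?
#'
#' Returns `ENTAILS` when every variant satisfying `a` must satisfy `b`,
#' by a closed rule set: structurally identical constraints; defining
#' allele vs defining allele (digest equality); defining allele vs
#' defining location (the normalized allele's interval related to `b`'s
#' interval under `b`'s match mode — every equivalent spelling of the
#' allele lies inside its fully-justified interval, so containment
#' transfers); contained-location nesting; contained location inside a
#' feature's interval; same feature; copy-count range inclusion; and
#' copy-change specialization. All other pairs return `UNKNOWN` — never
#' `NOT_ENTAILED`, since a failed rule does not witness a counterexample.
#'
#' @param a,b `cv_constraint` objects.
#' @param ctx An [evaluation_context()].
#' @return A `cv_tri_verdict` with `status` `"ENTAILS"` or `"UNKNOWN"` and
#'   a one-row justification.
#' @export
subsumes <- function(a, b, ctx) {
  rule <- subsumption_rule(a, b, ctx)
  if (is.null(rule)) {
    tri_verdict("UNKNOWN",
                justification = data.frame(rule = "none", detail = "no applicable rule",
                                           stringsAsFactors = FALSE))
  } else {
    tri_verdict("ENTAILS",
                justification = data.frame(rule = rule$rule, detail = rule$detail,
                                           stringsAsFactors = FALSE))
  }
}

# NULL when no rule fires; otherwise list(rule, detail)
subsumption_rule <- function(a, b, ctx) {
  if (cv_equal(a, b)) {
    return(list(rule = "identity", detail = "structurally identical constraints"))
  }
  if (a$kind == "DEFINING_ALLELE" && b$kind == "DEFINING_ALLELE") {
    da <- context_allele_digest(ctx, a$allele)
    db <- context_allele_digest(ctx, b$allele)
    if (identical(da, db)) {
      return(list(rule = "allele_digest", detail = paste0("same canonical digest ", da)))
    }
    return(NULL)
  }
  if (a$kind == "DEFINING_ALLELE" && b$kind == "DEFINING_LOCATION") {
    # an equivalence table may admit alleles at other locations; stay UNKNOWN
    if (!is.null(ctx$allele_equivalences)) {
      da <- context_allele_digest(ctx, a$allele)
      incoming <- setdiff(names(ctx$allele_equivalences)[
        unname(ctx$allele_equivalences) == da], da)
      if (length(incoming) > 0L) return(NULL)
    }
    loc <- normalized_allele_location(ctx, a$allele)
    cl <- b$location
    if (loc$sequence_id != cl$sequence_id) return(NULL)
    ok <- switch(b$match_mode,
      EXACT = loc$start == cl$start && loc$end == cl$end,
      CONTAINED = interval_contained(loc$start, loc$end, cl$start, cl$end),
      OVERLAPS = all_spellings_overlap(loc, cl))
    if (ok) {
      return(list(rule = "allele_in_location",
                  detail = sprintf("allele [%d,%d) %s [%d,%d)", loc$start, loc$end,
                                   tolower(b$match_mode), cl$start, cl$end)))
    }
    return(NULL)
  }
  if (a$kind == "DEFINING_LOCATION" && b$kind == "DEFINING_LOCATION") {
    if (a$match_mode == "CONTAINED" && b$match_mode == "CONTAINED" &&
        a$location$sequence_id == b$location$sequence_id &&
        interval_contained(a$location$start, a$location$end,
                           b$location$start, b$location$end)) {
      return(list(rule = "location_nesting",
                  detail = sprintf("[%d,%d) within [%d,%d)",
                                   a$location$start, a$location$end,
                                   b$location$start, b$location$end)))
    }
    return(NULL)
  }
  if (a$kind == "DEFINING_LOCATION" && b$kind == "FEATURE_CONTEXT") {
    if (a$match_mode != "CONTAINED") return(NULL)
    feat <- resolve_feature(ctx, b$feature)
    if (a$location$sequence_id == feat$sequence_id &&
        interval_contained(a$location$start, a$location$end, feat$start, feat$end)) {
      return(list(rule = "location_in_feature",
                  detail = sprintf("[%d,%d) within %s [%d,%d)",
                                   a$location$start, a$location$end,
                                   feat$id, feat$start, feat$end)))
    }
    return(NULL)
  }
  if (a$kind == "FEATURE_CONTEXT" && b$kind == "FEATURE_CONTEXT") {
    fa <- resolve_feature(ctx, a$feature)
    fb <- resolve_feature(ctx, b$feature)
    if (identical(fa$id, fb$id)) {
      return(list(rule = "same_feature", detail = paste0("both resolve to ", fa$id)))
    }
    return(NULL)
  }
  if (a$kind == "COPY_COUNT" && b$kind == "COPY_COUNT") {
    if (a$min >= b$min && a$max <= b$max) {
      return(list(rule = "count_range",
                  detail = sprintf("[%d,%d] within [%d,%d]", a$min, a$max, b$min, b$max)))
    }
    return(NULL)
  }
  if (a$kind == "COPY_CHANGE" && b$kind == "COPY_CHANGE") {
    if (b$code %in% hierarchy_ancestors(a$code, ctx$copy_change_hierarchy)) {
      return(list(rule = "change_specialization",
                  detail = sprintf("%s specializes %s", a$code, b$code)))
    }
    return(NULL)
  }
  NULL
}

normalized_allele_location <- function(ctx, al) {
  entry <- if (!is.null(ctx$references)) ctx$references[[al$location$sequence_id]]
  if (!is.null(entry)) normalize_allele(al, entry)$allele$location else al$location
}

# OVERLAPS must hold for every spelling of the allele, not just the
# fully-justified one; spellings tile the justified interval, so require
# the constraint interval to cover a band every spelling touches. We only
# certify the conservative case: the justified interval contained in the
# constraint interval (then every spelling overlaps trivially).
all_spellings_overlap <- function(loc, cl) {
  interval_contained(loc$start, loc$end, cl$start, cl$end)
}

#' Does one category entail another?
#'
#' `a` entails `b` when every member of `a` is a member of `b` in every
#' universe. The verdict is `ENTAILS` when every constraint of `b` is
#' subsumed ([subsumes()]) by some constraint of `a` (componentwise
#' coverage, sound by construction); otherwise, when `probe_universe` is
#' supplied and some variant there satisfies `a` but not `b`, the verdict
#' is `NOT_ENTAILED` with that witness; otherwise `UNKNOWN`. A category
#' always entails itself.
#'
#' @param a,b [categorical_variant()] objects.
#' @param ctx An [evaluation_context()].
#' @param probe_universe Optional [generate_universe()] result used only
#'   to search for counterexamples.
#' @return A `cv_tri_verdict`; `justification` maps each constraint of `b`
#'   to the subsuming constraint of `a` and the rule used.
#' @export
entails <- function(a, b, ctx, probe_universe = NULL) {
  rows <- list()
  covered <- TRUE
  for (j in seq_along(b$constraints)) {
    found <- NULL
    for (i in seq_along(a$constraints)) {
      rule <- subsumption_rule(a$constraints[[i]], b$constraints[[j]], ctx)
      if (!is.null(rule)) {
        found <- data.frame(b_constraint = j, a_constraint = i,
                            rule = rule$rule, detail = rule$detail,
                            stringsAsFactors = FALSE)
        break
      }
    }
    if (is.null(found)) {
      covered <- FALSE
      found <- data.frame(b_constraint = j, a_constraint = NA_integer_,
                          rule = "uncovered", detail = "no subsuming constraint",
                          stringsAsFactors = FALSE)
    }
    rows[[j]] <- found
  }
  justification <- do.call(rbind, rows)
  if (covered) return(tri_verdict("ENTAILS", justification = justification))
  if (!is.null(probe_universe)) {
    probe <- oracle_entails(a, b, probe_universe, ctx)
    if (!probe$holds) {
      return(tri_verdict("NOT_ENTAILED", witness = probe$witness,
                         justification = justification))
    }
  }
  tri_verdict("UNKNOWN", justification = justification)
}
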