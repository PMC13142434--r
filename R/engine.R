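# The constraint engine: per-constraint verdicts, conjunctive category
# membership, and batch matching. Verdicts distinguish UNSATISFIED (the
# attribute was tested and failed) from INAPPLICABLE (the variant lacks
# the attribute the constraint tests); applicability depends only on
# attribute presence, never on attribute values.

verdict <- function(status, code, message) {
  structure(list(status = status, code = code, message = message),
            class = "cv_verdict")
}

#' Evaluate one constraint against one variant
#'
#' Kind-specific semantics:
#' * `DEFINING_ALLELE` — satisfied when the variant allele's normalized
#'   digest equals the defining allele's, directly or through the
#'   context's equivalence table; inapplicable for non-allele variants.
#' * `DEFINING_LOCATION` — relates the variant's payload location to the
#'   constraint interval under the constraint's match mode (`EXACT`,
#'   `CONTAINED`, `OVERLAPS`); inapplicable only when the variant has no
#'   single location (adjacencies).
#' * `COPY_COUNT` — count within `[min, max]`; inapplicable unless a
#'   copy-number variant with a count.
#' * `COPY_CHANGE` — change code equal to, or specializing, the constraint
#'   code; inapplicable without a change code (a bare count is never
#'   auto-converted: no baseline ploidy is assumed).
#' * `FEATURE_CONTEXT` — location overlaps the feature interval, or the
#'   annotation carries the feature's symbol; inapplicable when the
#'   variant has neither a location nor gene-symbol annotation.
#' * `FUNCTION` — an annotated term equals the constraint term or descends
#'   from it in the context hierarchy; inapplicable without function
#'   annotation.
#' * `ADJACENCY` — both breakends satisfy the two side specifications
#'   (swappable when the constraint is unordered); inapplicable for
#'   non-adjacency variants.
#'
#' @param constraint A `cv_constraint`.
#' @param variant A [molecular_variant()].
#' @param ctx An [evaluation_context()].
#' @return A `cv_verdict` with fields `status` (`"SATISFIED"`,
#'   `"UNSATISFIED"` or `"INAPPLICABLE"`), `code`, `message`.
#' @export
evaluate_constraint <- function(constraint, variant, ctx) {
  switch(constraint$kind,
    DEFINING_ALLELE = eval_defining_allele(constraint, variant, ctx),
    DEFINING_LOCATION = eval_defining_location(constraint, variant),
    COPY_COUNT = eval_copy_count(constraint, variant),
    COPY_CHANGE = eval_copy_change(constraint, variant, ctx),
    FEATURE_CONTEXT = eval_feature_context(constraint, variant, ctx),
    FUNCTION = eval_function(constraint, variant, ctx),
    ADJACENCY = eval_adjacency(constraint, variant, ctx),
    stop(cv_error("UNKNOWN_KIND", paste0("unknown constraint kind: ", constraint$kind))))
}

eval_defining_allele <- function(k, v, ctx) {
  if (v$kind != "ALLELE")
    return(verdict("INAPPLICABLE", "NOT_ALLELE", "variant is not a sequence allele"))
  want <- context_allele_digest(ctx, k$allele)
  have <- context_allele_digest(ctx, v$payload, cached = v$digest_id)
  if (identical(want, have))
    verdict("SATISFIED", "DIGEST_MATCH", paste0("allele digest ", have))
  else
    verdict("UNSATISFIED", "DIGEST_MISMATCH",
            sprintf("variant %s != defining %s", have, want))
}

eval_defining_location <- function(k, v) {
  loc <- variant_location(v)
  if (is.null(loc))
    return(verdict("INAPPLICABLE", "NO_LOCATION", "variant has no single location"))
  cl <- k$location
  if (loc$sequence_id != cl$sequence_id)
    return(verdict("UNSATISFIED", "OTHER_SEQUENCE",
                   sprintf("variant on %s, constraint on %s",
                           loc$sequence_id, cl$sequence_id)))
  hit <- switch(k$match_mode,
    EXACT = loc$start == cl$start && loc$end == cl$end,
    CONTAINED = interval_contained(loc$start, loc$end, cl$start, cl$end),
    OVERLAPS = interval_overlaps(loc$start, loc$end, cl$start, cl$end))
  if (hit)
    verdict("SATISFIED", "LOCATION_MATCH",
            sprintf("[%d,%d) %s [%d,%d)", loc$start, loc$end,
                    tolower(k$match_mode), cl$start, cl$end))
  else
    verdict("UNSATISFIED", "LOCATION_MISS",
            sprintf("[%d,%d) fails %s of [%d,%d)", loc$start, loc$end,
                    tolower(k$match_mode), cl$start, cl$end))
}

eval_copy_count <- function(k, v) {
  if (v$kind != "COPY_NUMBER" || is.null(v$payload$count))
    return(verdict("INAPPLICABLE", "NO_COUNT", "variant carries no absolute copy count"))
  n <- v$payload$count
  if (n >= k$min && n <= k$max)
    verdict("SATISFIED", "COUNT_IN_RANGE", sprintf("%d in [%d,%d]", n, k$min, k$max))
  else
    verdict("UNSATISFIED", "COUNT_OUT_OF_RANGE",
            sprintf("%d outside [%d,%d]", n, k$min, k$max))
}

eval_copy_change <- function(k, v, ctx) {
  if (v$kind != "COPY_NUMBER" || is.null(v$payload$change_code))
    return(verdict("INAPPLICABLE", "NO_CHANGE_CODE", "variant carries no change code"))
  code <- v$payload$change_code
  anc <- hierarchy_ancestors(code, ctx$copy_change_hierarchy)
  if (k$code %in% anc)
    verdict("SATISFIED", "CHANGE_MATCH", sprintf("%s satisfies %s", code, k$code))
  else
    verdict("UNSATISFIED", "CHANGE_MISMATCH",
            sprintf("%s is not %s nor a specialization of it", code, k$code))
}

eval_feature_context <- function(k, v, ctx) {
  feat <- resolve_feature(ctx, k$feature)
  loc <- variant_location(v)
  symbols <- if (!is.null(v$annotation)) v$annotation$gene_symbols else character()
  if (is.null(loc) && length(symbols) == 0L)
    return(verdict("INAPPLICABLE", "NO_CONTEXT",
                   "variant has neither a location nor gene annotation"))
  if (!is.null(loc) && loc$sequence_id == feat$sequence_id &&
      interval_overlaps(loc$start, loc$end, feat$start, feat$end))
    return(verdict("SATISFIED", "FEATURE_OVERLAP",
                   sprintf("overlaps %s [%d,%d)", feat$id, feat$start, feat$end)))
  if (tolower(feat$symbol) %in% tolower(symbols))
    return(verdict("SATISFIED", "SYMBOL_MATCH",
                   paste0("annotated with symbol ", feat$symbol)))
  verdict("UNSATISFIED", "OUTSIDE_FEATURE",
          paste0("no overlap with, or annotation of, feature ", feat$id))
}

eval_function <- function(k, v, ctx) {
  terms <- if (!is.null(v$annotation)) v$annotation$function_terms else character()
  if (length(terms) == 0L)
    return(verdict("INAPPLICABLE", "NO_FUNCTION_ANNOTATION",
                   "variant carries no functional-consequence annotation"))
  for (t in terms) {
    cand <- if (k$use_hierarchy) hierarchy_ancestors(t, ctx$function_hierarchy) else t
    if (k$term %in% cand)
      return(verdict("SATISFIED", "TERM_MATCH",
                     sprintf("term %s satisfies %s", t, k$term)))
  }
  verdict("UNSATISFIED", "TERM_MISMATCH",
          sprintf("no annotated term satisfies %s", k$term))
}

eval_adjacency <- function(k, v, ctx) {
  if (v$kind != "ADJACENCY")
    return(verdict("INAPPLICABLE", "NOT_ADJACENCY", "variant is not an adjacency"))
  side_ok <- function(breakend, side) {
    if (is.character(side)) {
      feat <- resolve_feature(ctx, side)
      breakend$sequence_id == feat$sequence_id &&
        interval_contained(breakend$start, breakend$end, feat$start, feat$end)
    } else {
      breakend$sequence_id == side$sequence_id &&
        interval_contained(breakend$start, breakend$end, side$start, side$end)
    }
  }
  a <- v$payload$breakend_a
  b <- v$payload$breakend_b
  hit <- (side_ok(a, k$side_a) && side_ok(b, k$side_b)) ||
    (!k$ordered && side_ok(b, k$side_a) && side_ok(a, k$side_b))
  if (hit)
    verdict("SATISFIED", "SIDES_MATCH", "both breakends satisfy their sides")
  else
    verdict("UNSATISFIED", "SIDES_MISMATCH",
            "breakends do not satisfy the side specifications")
}

#' Match a variant against a categorical definition
#'
#' Evaluates every constraint of the category against the variant and
#' combines verdicts conjunctively: the variant is a member exactly when
#' every constraint is `SATISFIED` (closed-world membership: an
#' `INAPPLICABLE` verdict also blocks membership — the extension contains
#' only variants demonstrably satisfying every constraint).
#'
#' @param catvar A [categorical_variant()].
#' @param variant A [molecular_variant()].
#' @param ctx An [evaluation_context()].
#' @return A `cv_match_report`: `categorical_variant_id`, `variant_id`,
#'   `verdicts` (one per constraint, in order) and `overall` (logical).
#' @export
#' @examples
#' ft <- feature_table_from_df(data.frame(
#'   id = "TP53", symbol = "TP53", sequence_id = "17",
#'   start = 7668402, end = 7687538, strand = "-", class = "gene"))
#' ctx <- evaluation_context(feature_table = ft)
#' cnv <- molecular_variant("del17p", copy_number(
#'   seq_location("17", 7100000, 7800000), change_code = "LOSS"))
#' cat_tp53 <- categorical_variant("cv1", "TP53 CNLoss", list(
#'   feature_context("TP53"), copy_change("LOSS")))
#' match_variant(cat_tp53, cnv, ctx)$overall
match_variant <- function(catvar, variant, ctx) {
  verdicts <- lapply(catvar$constraints, evaluate_constraint,
                     variant = variant, ctx = ctx)
  overall <- all(vapply(verdicts, function(v) v$status == "SATISFIED", logical(1)))
  structure(list(categorical_variant_id = catvar$id, variant_id = variant$id,
                 verdicts = verdicts, overall = overall),
            class = "cv_match_report")
}

#' @export
print.cv_match_report <- function(x, ...) {
  cat(sprintf("<Match> %s vs %s: %s\n", x$categorical_variant_id, x$variant_id,
              if (x$overall) "MEMBER" else "non-member"))
  for (i in seq_along(x$verdicts)) {
    v <- x$verdicts[[i]]
    cat(sprintf("  [%d] %-12s %s: %s\n", i, v$status, v$code, v$message))
  }
  invisible(x)
}

#' Match many categories against many variants
#'
#' @param catvars List of categorical variants (rows).
#' @param variants List of molecular variants (columns).
#' @param ctx An [evaluation_context()].
#' @return A list with `reports` (a `length(catvars) x length(variants)`
#'   matrix of match reports, dimnames the respective ids) and `overall`
#'   (the corresponding logical membership matrix). Element `(i, j)`
#'   equals `match_variant(catvars[[i]], variants[[j]], ctx)`; permuting
#'   inputs permutes rows/columns identically.
#' @export
match_batch <- function(catvars, variants, ctx) {
  nr <- length(catvars); nc <- length(variants)
  reports <- vector("list", nr * nc)
  dim(reports) <- c(nr, nc)
  overall <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rep_ij <- match_variant(catvars[[i]], variants[[j]], ctx)
      reports[[i, j]] <- rep_ij
      overall[i, j] <- rep_ij$overall
    }
  }
  ids_r <- vapply(catvars, `[[`, character(1), "id")
  ids_c <- vapply(variants, `[[`, character(1), "id")
  dimnames(reports) <- dimnames(overall) <- list(ids_r, ids_c)
  list(reports = reports, overall = overall)
}
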