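# Evaluation context: everything constraint evaluation needs beyond the
# variant and the category — feature intervals, reference residues for
# normalization, term hierarchies, allele equivalences.

#' Evaluation context for matching and entailment
#'
#' @param feature_table A feature table ([load_feature_table()] or built in
#'   code) resolving feature ids/symbols to intervals; may be `NULL` when
#'   no feature-context or adjacency constraints are in play.
#' @param references Optional reference registry
#'   ([as_reference_registry()]); with it, defining-allele evaluation
#'   normalizes both sides before comparing digests.
#' @param function_hierarchy Optional named character vector mapping a
#'   consequence term to its parent term (acyclic); lower-cased.
#' @param allele_equivalences Optional named character vector mapping an
#'   allele digest to its canonical equivalent (user-supplied, e.g. from
#'   transcript projection done elsewhere). Must be idempotent: a value may
#'   not be remapped further.
#' @param copy_change_hierarchy Parent map over [copy_change_codes()];
#'   the built-in specialization edges by default.
#' @return A `cv_context` object.
#' @export
evaluation_context <- function(feature_table = NULL, references = NULL,
                               function_hierarchy = NULL,
                               allele_equivalences = NULL,
                               copy_change_hierarchy = cc_parents) {
  if (!is.null(references)) references <- as_reference_registry(references)
  if (!is.null(function_hierarchy)) {
    function_hierarchy <- stats::setNames(tolower(function_hierarchy),
                                          tolower(names(function_hierarchy)))
    check_acyclic(function_hierarchy, "function hierarchy")
  }
  check_acyclic(copy_change_hierarchy, "copy-change hierarchy")
  if (!is.null(allele_equivalences)) {
    # idempotence: a digest that appears as a value must not map onward
    onward <- intersect(unname(allele_equivalences), names(allele_equivalences))
    bad <- onward[allele_equivalences[onward] != onward]
    if (length(bad) > 0L)
      stop(cv_error("BAD_EQUIVALENCES",
        paste0("equivalence map is not idempotent at: ", paste(bad, collapse = ", "))))
  }
  structure(list(feature_table = feature_table, references = references,
                 function_hierarchy = function_hierarchy,
                 allele_equivalences = allele_equivalences,
                 copy_change_hierarchy = copy_change_hierarchy),
            class = "cv_context")
}

check_acyclic <- function(parents, what) {
  for (k in names(parents)) {
    seen <- character()
    cur <- k
    while (cur %in% names(parents)) {
      if (cur %in% seen) stop(cv_error("CYCLIC_HIERARCHY",
                                       paste0(what, " contains a cycle at ", cur)))
      seen <- c(seen, cur)
      cur <- unname(parents[[cur]])
    }
  }
  invisible(TRUE)
}

# resolve a feature id or symbol to its table row; classed error when absent
resolve_feature <- function(ctx, feature) {
  ft <- ctx$feature_table
  if (!is.null(ft)) {
    hit <- which(ft$id == feature)
    if (length(hit) == 0L) hit <- which(tolower(ft$symbol) == tolower(feature))
    if (length(hit) >= 1L) return(ft[hit[1L], , drop = FALSE])
  }
  stop(cv_error("UNKNOWN_FEATURE",
                paste0("feature not in feature table: ", feature)))
}

# canonical digest of a variant/constraint allele under the context:
# normalize against the registry when the sequence is known, then apply the
# equivalence table once.
context_allele_digest <- function(ctx, al, cached = NULL) {
  d <- cached
  if (is.null(d)) {
    entry <- if (!is.null(ctx$references)) ctx$references[[al$location$sequence_id]]
    d <- if (!is.null(entry)) normalize_allele(al, entry)$digest_id
         else allele_digest(al)
  }
  if (!is.null(ctx$allele_equivalences) && d %in% names(ctx$allele_equivalences)) {
    d <- unname(ctx$allele_equivalences[[d]])
  }
  d
}

# interval relations on 0-based half-open intervals; zero-width intervals
# (insertion points, breakends) use closed point containment so that a
# point inside a region counts as overlapping it
interval_contained <- function(s1, e1, s2, e2) {
  s1 >= s2 && e1 <= e2
}

interval_overlaps <- function(s1, e1, s2, e2) {
  if (s1 == e1) return(s2 <= s1 && s1 <= e2)
  if (s2 == e2) return(s1 <= s2 && s2 <= e1)
  s1 < e2 && s2 < e1
}
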