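# Domain types: sequence references and locations, molecular variants
# (alleles, copy-number variants, adjacencies), constraints, and
# categorical variants. All objects are plain lists with S3 classes;
# coordinates are inter-residue, 0-based, half-open throughout.

#' Sequence reference descriptor
#'
#' Describes a reference sequence (a contig, transcript or protein) that
#' locations anchor to. The residues themselves live in a reference
#' registry (see [as_reference_registry()]).
#'
#' @param id Opaque, unique reference identifier (e.g. an
#'   assembly-qualified contig label).
#' @param length Sequence length in residues (non-negative integer).
#' @param alphabet `"DNA"` or `"PROTEIN"`.
#' @return A `cv_reference` object.
#' @export
seq_reference <- function(id, length, alphabet = c("DNA", "PROTEIN")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L, nchar(id) > 0L,
            is.numeric(length), length >= 0)
  structure(list(id = id, length = as.integer(length), alphabet = alphabet),
            class = c("cv_reference", "cv_object"))
}

#' Sequence location
#'
#' An interval on a reference sequence in inter-residue coordinates:
#' 0-based, half-open `[start, end)`. A zero-width location (`start == end`)
#' denotes a point between residues (an insertion site or breakend).
#'
#' @param sequence_id Identifier of the reference the interval lies on.
#' @param start,end Inter-residue coordinates, `0 <= start <= end`.
#' @return A `cv_location` object.
#' @export
seq_location <- function(sequence_id, start, end) {
  stopifnot(is.character(sequence_id), length(sequence_id) == 1L,
            is.numeric(start), is.numeric(end))
  structure(list(sequence_id = sequence_id,
                 start = as.integer(start), end = as.integer(end)),
            class = c("cv_location", "cv_object"))
}

#' Sequence allele
#'
#' A literal replacement of the residues at a location by `state`. An empty
#' `state` with a nonempty location is a deletion; a nonempty `state` at a
#' zero-width location is an insertion; equal-length nonempty pairs are
#' substitutions.
#'
#' @param location A [seq_location()].
#' @param state Replacement residue string (possibly empty).
#' @return A `cv_allele` object.
#' @export
allele <- function(location, state) {
  stopifnot(inherits(location, "cv_location"),
            is.character(state), length(state) == 1L, !is.na(state))
  structure(list(location = location, state = toupper(state)),
            class = c("cv_allele", "cv_object"))
}

#' Copy-change vocabulary
#'
#' Relative copy-dosage codes with their specialization edges:
#' `COMPLETE_LOSS` and `LOW_LEVEL_LOSS` specialize `LOSS`;
#' `LOW_LEVEL_GAIN` and `HIGH_LEVEL_GAIN` specialize `GAIN`. The loss and
#' gain branches are disjoint.
#'
#' @return Character vector of the six codes.
#' @export
copy_change_codes <- function() {
  c("COMPLETE_LOSS", "LOSS", "LOW_LEVEL_LOSS",
    "GAIN", "LOW_LEVEL_GAIN", "HIGH_LEVEL_GAIN")
}

# parent edge map of the specialization hierarchy
cc_parents <- c(COMPLETE_LOSS = "LOSS", LOW_LEVEL_LOSS = "LOSS",
                LOW_LEVEL_GAIN = "GAIN", HIGH_LEVEL_GAIN = "GAIN")

# code plus all its ancestors under a parent map (default: copy-change)
hierarchy_ancestors <- function(code, parents = cc_parents) {
  out <- code
  while (!is.na(code) && code %in% names(parents)) {
    code <- unname(parents[[code]])
    if (code %in% out) stop("cyclic hierarchy at ", code)
    out <- c(out, code)
  }
  out
}

#' Copy-number variant
#'
#' A copy-number observation over a genomic segment: an absolute copy
#' `count`, a relative `change_code` (see [copy_change_codes()]), or both.
#'
#' @param location Segment as a [seq_location()].
#' @param count Optional absolute copy number (non-negative integer).
#' @param change_code Optional code from [copy_change_codes()].
#' @return A `cv_copy_number` object.
#' @export
copy_number <- function(location, count = NULL, change_code = NULL) {
  stopifnot(inherits(location, "cv_location"))
  if (is.null(count) && is.null(change_code))
    stop(cv_error("MISSING_COPY_STATE",
                  "a copy-number variant needs a count or a change code"))
  if (!is.null(count)) {
    stopifnot(is.numeric(count), count >= 0)
    count <- as.integer(count)
  }
  if (!is.null(change_code)) {
    if (!change_code %in% copy_change_codes())
      stop(cv_error("UNKNOWN_CODE", paste0("unknown copy-change code: ", change_code)))
  }
  structure(list(location = location, count = count, change_code = change_code),
            class = c("cv_copy_number", "cv_object"))
}

#' Adjacency (breakend junction)
#'
#' The joining of two sequence breakends, the molecular substrate of
#' rearrangements and gene fusions. `orientation` is descriptive metadata
#' from the source record; side-swapping during matching is governed by the
#' adjacency *constraint's* `ordered` flag.
#'
#' @param breakend_a,breakend_b Zero-width or small [seq_location()]s.
#' @param orientation `"AB"`, `"BA"` or `"UNORDERED"`.
#' @return A `cv_adjacency` object.
#' @export
adjacency <- function(breakend_a, breakend_b,
                      orientation = c("AB", "BA", "UNORDERED")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(breakend_a, "cv_location"), inherits(breakend_b, "cv_location"))
  structure(list(breakend_a = breakend_a, breakend_b = breakend_b,
                 orientation = orientation),
            class = c("cv_adjacency", "cv_object"))
}

#' Variant annotation
#'
#' Optional per-variant annotation used by feature-context and functional
#' constraints: overlapping/affected gene symbols and functional-consequence
#' terms. Terms are case-normalized to lower case, symbols kept as given
#' (matching is case-insensitive).
#'
#' @param gene_symbols Character vector (may be empty).
#' @param function_terms Character vector of consequence terms (may be empty).
#' @return A `cv_annotation` object.
#' @export
variant_annotation <- function(gene_symbols = character(),
                               function_terms = character()) {
  structure(list(gene_symbols = unique(as.character(gene_symbols)),
                 function_terms = unique(tolower(as.character(function_terms)))),
            class = c("cv_annotation", "cv_object"))
}

#' Molecular (assayed) variant
#'
#' A concrete variant observed in a sample: an allele, a copy-number
#' variant, or an adjacency, plus optional annotation. The `kind` tag is
#' normally inferred from the payload; passing it explicitly allows the
#' validator to detect tag/payload mismatches in foreign documents.
#'
#' @param id Opaque variant identifier.
#' @param payload A [allele()], [copy_number()] or [adjacency()].
#' @param annotation Optional [variant_annotation()].
#' @param kind Optional explicit tag, one of `"ALLELE"`, `"COPY_NUMBER"`,
#'   `"ADJACENCY"`.
#' @param digest_id Optional precomputed allele digest (set by
#'   normalization/ingestion; used as a cache during matching).
#' @return A `cv_variant` object.
#' @export
molecular_variant <- function(id, payload, annotation = NULL, kind = NULL,
                              digest_id = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  inferred <- payload_kind(payload)
  if (is.null(kind)) kind <- inferred
  if (!is.null(annotation)) stopifnot(inherits(annotation, "cv_annotation"))
  structure(list(id = id, kind = kind, payload = payload,
                 annotation = annotation, digest_id = digest_id),
            class = c("cv_variant", "cv_object"))
}

payload_kind <- function(payload) {
  if (inherits(payload, "cv_allele")) return("ALLELE")
  if (inherits(payload, "cv_copy_number")) return("COPY_NUMBER")
  if (inherits(payload, "cv_adjacency")) return("ADJACENCY")
  stop(cv_error("BAD_PAYLOAD", "payload must be an allele, copy number or adjacency"))
}

# single location of a variant payload, or NULL (adjacencies have two
# breakends, not one location)
variant_location <- function(variant) {
  switch(variant$kind,
         ALLELE = variant$payload$location,
         COPY_NUMBER = variant$payload$location,
         NULL)
}

constraint_kinds <- function() {
  c("DEFINING_ALLELE", "DEFINING_LOCATION", "COPY_COUNT", "COPY_CHANGE",
    "FEATURE_CONTEXT", "FUNCTION", "ADJACENCY")
}

#' Constraint kinds still maturing
#'
#' Functional-consequence and adjacency constraints (and the profiles built
#' on them) are in-progress classes; the command-line tools refuse them
#' unless `--experimental` is given.
#' @return Character vector of kind names.
#' @export
experimental_kinds <- function() c("FUNCTION", "ADJACENCY")

new_constraint <- function(kind, params) {
  structure(c(list(kind = kind), params),
            class = c("cv_constraint", "cv_object"))
}

#' Defining-allele constraint
#'
#' Satisfied by allele variants whose normalized digest equals the defining
#' allele's digest (directly or through the context's allele-equivalence
#' table).
#'
#' @param allele The defining [allele()].
#' @param equivalence_set Optional identifier of an equivalence set (purely
#'   descriptive; resolution uses the evaluation context's table).
#' @return A `cv_constraint`.
#' @export
defining_allele <- function(allele, equivalence_set = NULL) {
  stopifnot(inherits(allele, "cv_allele"))
  new_constraint("DEFINING_ALLELE",
                 list(allele = allele, equivalence_set = equivalence_set))
}

#' Defining-location constraint
#'
#' Relates the variant's location to a fixed interval. `match_mode`
#' `"CONTAINED"` (default; e.g. "deletions within exon 19") requires the
#' variant interval to lie inside the constraint interval, `"EXACT"`
#' requires identity, `"OVERLAPS"` a nonempty intersection.
#'
#' @param location Constraint interval as a [seq_location()].
#' @param match_mode `"CONTAINED"`, `"EXACT"` or `"OVERLAPS"`.
#' @return A `cv_constraint`.
#' @export
defining_location <- function(location,
                              match_mode = c("CONTAINED", "EXACT", "OVERLAPS")) {
  stopifnot(inherits(location, "cv_location"))
  match_mode <- match.arg(match_mode)
  new_constraint("DEFINING_LOCATION",
                 list(location = location, match_mode = match_mode))
}

#' Copy-count constraint
#'
#' Satisfied by copy-number variants whose absolute count lies in the
#' inclusive range `[min, max]`.
#'
#' @param min,max Inclusive copy-count bounds (`max` defaults to `min`).
#' @return A `cv_constraint`.
#' @export
copy_count <- function(min, max = min) {
  new_constraint("COPY_COUNT",
                 list(min = as.integer(min), max = as.integer(max)))
}

#' Copy-change constraint
#'
#' Satisfied by copy-number variants whose change code equals, or
#' specializes, `code` in the copy-change hierarchy (e.g. `COMPLETE_LOSS`
#' satisfies a `LOSS` constraint).
#'
#' @param code A code from [copy_change_codes()].
#' @return A `cv_constraint`.
#' @export
copy_change <- function(code) {
  new_constraint("COPY_CHANGE", list(code = code))
}

#' Feature-context constraint
#'
#' Satisfied when the variant's location overlaps the named feature's
#' interval, or its annotation carries the feature's gene symbol
#' (case-insensitive exact match).
#'
#' @param feature Feature id or symbol, resolved through the evaluation
#'   context's feature table.
#' @return A `cv_constraint`.
#' @export
feature_context <- function(feature) {
  stopifnot(is.character(feature), length(feature) == 1L)
  new_constraint("FEATURE_CONTEXT", list(feature = feature))
}

#' Functional-consequence constraint (experimental)
#'
#' Satisfied when a variant's annotated function term equals `term`, or
#' descends from it in the context's function-term hierarchy when
#' `use_hierarchy` is `TRUE`.
#'
#' @param term Consequence term (case-insensitive).
#' @param use_hierarchy Whether descendant terms also satisfy the
#'   constraint.
#' @return A `cv_constraint`.
#' @export
function_constraint <- function(term, use_hierarchy = TRUE) {
  stopifnot(is.character(term), length(term) == 1L)
  new_constraint("FUNCTION",
                 list(term = tolower(term), use_hierarchy = isTRUE(use_hierarchy)))
}

#' Adjacency constraint (experimental)
#'
#' Satisfied by adjacency variants whose two breakends satisfy the two side
#' specifications. A side given as a feature id resolves through the
#' context; a side given as a location uses containment semantics. With
#' `ordered = TRUE` (5'/3' fusion-partner semantics) breakend A must match
#' side A and breakend B side B; with `ordered = FALSE` the assignment may
#' be swapped.
#'
#' @param side_a,side_b Feature id (character) or [seq_location()].
#' @param ordered Whether side assignment is fixed.
#' @return A `cv_constraint`.
#' @export
adjacency_constraint <- function(side_a, side_b, ordered = TRUE) {
  chk <- function(s) is.character(s) && length(s) == 1L || inherits(s, "cv_location")
  stopifnot(chk(side_a), chk(side_b))
  new_constraint("ADJACENCY",
                 list(side_a = side_a, side_b = side_b, ordered = isTRUE(ordered)))
}

#' Categorical variant
#'
#' A set of genomic alterations defined intensionally: the conjunction of a
#' non-empty list of constraints. A molecular variant is a member exactly
#' when it satisfies every constraint.
#'
#' @param id Opaque identifier.
#' @param label Human-readable label.
#' @param constraints List of `cv_constraint` objects (non-empty for a
#'   valid category; emptiness is reported by
#'   [validate_categorical_variant()], not rejected here).
#' @param declared_profile Optional profile name (see [profile_registry()]).
#' @param extensions Optional named list of foreign fields to round-trip.
#' @return A `cv_catvar` object.
#' @export
categorical_variant <- function(id, label = "", constraints,
                                declared_profile = NULL, extensions = NULL) {
  stopifnot(is.character(id), length(id) == 1L, is.list(constraints))
  structure(list(id = id, label = label, constraints = constraints,
                 declared_profile = declared_profile, extensions = extensions),
            class = c("cv_catvar", "cv_object"))
}

#' @export
print.cv_catvar <- function(x, ...) {
  cat(sprintf("<CategoricalVariant %s> %s\n", x$id, x$label))
  for (i in seq_along(x$constraints)) {
    k <- x$constraints[[i]]
    cat(sprintf("  [%d] %s\n", i, if (inherits(k, "cv_constraint")) constraint_summary(k) else "<malformed>"))
  }
  invisible(x)
}

constraint_summary <- function(k) {
  switch(k$kind,
    DEFINING_ALLELE = sprintf("DefiningAllele %s:[%d,%d) -> %s",
      k$allele$location$sequence_id, k$allele$location$start,
      k$allele$location$end, if (nzchar(k$allele$state)) k$allele$state else "-"),
    DEFINING_LOCATION = sprintf("DefiningLocation %s %s:[%d,%d)", k$match_mode,
      k$location$sequence_id, k$location$start, k$location$end),
    COPY_COUNT = sprintf("CopyCount [%d,%d]", k$min, k$max),
    COPY_CHANGE = sprintf("CopyChange %s", k$code),
    FEATURE_CONTEXT = sprintf("FeatureContext %s", k$feature),
    FUNCTION = sprintf("Function %s%s", k$term, if (k$use_hierarchy) " (+descendants)" else ""),
    ADJACENCY = sprintf("Adjacency %s ~ %s%s", side_summary(k$side_a),
      side_summary(k$side_b), if (k$ordered) "" else " (unordered)"),
    paste0("? ", k$kind))
}

side_summary <- function(s) {
  if (is.character(s)) s
  else sprintf("%s:[%d,%d)", s$sequence_id, s$start, s$end)
}

#' @export
print.cv_variant <- function(x, ...) {
  cat(sprintf("<MolecularVariant %s> %s\n", x$id, x$kind))
  invisible(x)
}

# classed conditions -------------------------------------------------------

cv_error <- function(code, message) {
  structure(class = c(paste0("cv_error_", tolower(code)), "cv_error",
                      "error", "condition"),
            list(message = message, call = sys.call(-1), code = code))
}

# structural equality through the canonical serialization
cv_equal <- function(a, b) {
  identical(canonical_serialize(a), canonical_serialize(b))
}
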