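# JSON document dialect: camelCase field names, a `type` discriminator on
# every object, unknown fields preserved in an extensions bag and
# round-tripped. Writing is canonical (sorted keys, no whitespace), so
# write -> read -> write is byte-stable.

#' Convert a model object to its plain payload form
#'
#' The payload form is what serialization and digesting operate on: a
#' plain named list with camelCase keys and a `type` discriminator.
#'
#' @param x A model object.
#' @return A plain list.
#' @export
as_payload <- function(x) UseMethod("as_payload")

#' @export
as_payload.cv_location <- function(x) {
  list(type = "SequenceLocation", sequenceId = x$sequence_id,
       start = x$start, end = x$end)
}

#' @export
as_payload.cv_reference <- function(x) {
  list(type = "SequenceReference", id = x$id, length = x$length,
       alphabet = x$alphabet)
}

#' @export
as_payload.cv_allele <- function(x) {
  list(type = "Allele", location = as_payload(x$location), state = x$state)
}

#' @export
as_payload.cv_copy_number <- function(x) {
  out <- list(type = "CopyNumber", location = as_payload(x$location))
  if (!is.null(x$count)) out$count <- x$count
  if (!is.null(x$change_code)) out$copyChange <- x$change_code
  out
}

#' @export
as_payload.cv_adjacency <- function(x) {
  list(type = "Adjacency", breakendA = as_payload(x$breakend_a),
       breakendB = as_payload(x$breakend_b), orientation = x$orientation)
}

#' @export
as_payload.cv_annotation <- function(x) {
  list(type = "VariantAnnotation",
       geneSymbols = as.list(x$gene_symbols),
       functionTerms = as.list(x$function_terms))
}

#' @export
as_payload.cv_variant <- function(x) {
  out <- list(type = "MolecularVariant", id = x$id, kind = x$kind,
              payload = as_payload(x$payload))
  if (!is.null(x$annotation)) out$annotation <- as_payload(x$annotation)
  if (!is.null(x$digest_id)) out$digestId <- x$digest_id
  out
}

constraint_type_names <- c(
  DEFINING_ALLELE = "DefiningAlleleConstraint",
  DEFINING_LOCATION = "DefiningLocationConstraint",
  COPY_COUNT = "CopyCountConstraint",
  COPY_CHANGE = "CopyChangeConstraint",
  FEATURE_CONTEXT = "FeatureContextConstraint",
  FUNCTION = "FunctionConstraint",
  ADJACENCY = "AdjacencyConstraint")

#' @export
as_payload.cv_constraint <- function(x) {
  out <- switch(x$kind,
    DEFINING_ALLELE = {
      o <- list(allele = as_payload(x$allele))
      if (!is.null(x$equivalence_set)) o$equivalenceSet <- x$equivalence_set
      o
    },
    DEFINING_LOCATION = list(location = as_payload(x$location),
                             matchMode = x$match_mode),
    COPY_COUNT = list(minCopies = x$min, maxCopies = x$max),
    COPY_CHANGE = list(copyChange = x$code),
    FEATURE_CONTEXT = list(feature = x$feature),
    FUNCTION = list(term = x$term, useHierarchy = x$use_hierarchy),
    ADJACENCY = list(
      sideA = if (is.character(x$side_a)) x$side_a else as_payload(x$side_a),
      sideB = if (is.character(x$side_b)) x$side_b else as_payload(x$side_b),
      ordered = x$ordered),
    stop(cv_error("UNKNOWN_KIND", paste0("unknown constraint kind: ", x$kind))))
  out <- c(list(type = unname(constraint_type_names[[x$kind]])), out)
  if (!is.null(x$extensions)) out <- c(out, x$extensions)
  out
}

#' @export
as_payload.cv_catvar <- function(x) {
  out <- list(type = "CategoricalVariant", id = x$id, label = x$label,
              constraints = lapply(x$constraints, as_payload))
  if (!is.null(x$declared_profile)) out$declaredProfile <- x$declared_profile
  if (!is.null(x$extensions)) out <- c(out, x$extensions)
  out
}

#' @export
as_payload.default <- function(x) {
  stop(cv_error("UNSERIALIZABLE",
                paste0("no payload form for class ", paste(class(x), collapse = "/"))))
}

# parsing ------------------------------------------------------------------

need_field <- function(doc, field, type) {
  v <- doc[[field]]
  if (is.null(v))
    stop(cv_error("MISSING_FIELD", sprintf("%s requires field '%s'", type, field)))
  v
}

parse_location <- function(doc) {
  seq_location(need_field(doc, "sequenceId", "SequenceLocation"),
               need_field(doc, "start", "SequenceLocation"),
               need_field(doc, "end", "SequenceLocation"))
}

parse_allele <- function(doc) {
  allele(parse_location(need_field(doc, "location", "Allele")),
         need_field(doc, "state", "Allele"))
}

parse_side <- function(doc, field) {
  v <- need_field(doc, field, "AdjacencyConstraint")
  if (is.character(v)) v else parse_location(v)
}

known_constraint_fields <- list(
  DefiningAlleleConstraint = c("type", "allele", "equivalenceSet"),
  DefiningLocationConstraint = c("type", "location", "matchMode"),
  CopyCountConstraint = c("type", "minCopies", "maxCopies"),
  CopyChangeConstraint = c("type", "copyChange"),
  FeatureContextConstraint = c("type", "feature"),
  FunctionConstraint = c("type", "term", "useHierarchy"),
  AdjacencyConstraint = c("type", "sideA", "sideB", "ordered"))

parse_constraint <- function(doc) {
  type <- doc[["type"]]
  if (is.null(type) || !type %in% names(known_constraint_fields))
    stop(cv_error("UNKNOWN_TYPE",
                  paste0("unknown constraint type: ",
                         if (is.null(type)) "<missing>" else type)))
  k <- switch(type,
    DefiningAlleleConstraint = defining_allele(
      parse_allele(need_field(doc, "allele", type)), doc[["equivalenceSet"]]),
    DefiningLocationConstraint = defining_location(
      parse_location(need_field(doc, "location", type)),
      if (is.null(doc[["matchMode"]])) "CONTAINED" else doc[["matchMode"]]),
    CopyCountConstraint = copy_count(need_field(doc, "minCopies", type),
                                     need_field(doc, "maxCopies", type)),
    CopyChangeConstraint = copy_change(need_field(doc, "copyChange", type)),
    FeatureContextConstraint = feature_context(need_field(doc, "feature", type)),
    FunctionConstraint = function_constraint(
      need_field(doc, "term", type),
      if (is.null(doc[["useHierarchy"]])) TRUE else doc[["useHierarchy"]]),
    AdjacencyConstraint = adjacency_constraint(
      parse_side(doc, "sideA"), parse_side(doc, "sideB"),
      if (is.null(doc[["ordered"]])) TRUE else doc[["ordered"]]))
  extras <- doc[setdiff(names(doc), known_constraint_fields[[type]])]
  if (length(extras) > 0L) k$extensions <- extras
  k
}

parse_categorical_variant <- function(doc) {
  if (!is.list(doc) || is.null(doc[["type"]]) ||
      !identical(doc[["type"]], "CategoricalVariant"))
    stop(cv_error("UNKNOWN_TYPE", "document is not a CategoricalVariant"))
  constraints <- lapply(doc[["constraints"]], parse_constraint)
  known <- c("type", "id", "label", "constraints", "declaredProfile")
  extras <- doc[setdiff(names(doc), known)]
  categorical_variant(
    id = need_field(doc, "id", "CategoricalVariant"),
    label = if (is.null(doc[["label"]])) "" else doc[["label"]],
    constraints = constraints,
    declared_profile = doc[["declaredProfile"]],
    extensions = if (length(extras) > 0L) extras else NULL)
}

#' Read categorical variants from JSON
#'
#' Accepts a file path or a JSON string holding one CategoricalVariant
#' object or an array of them. The reader is total over entries: an entry
#' that fails to parse (e.g. an unknown constraint `type`) is reported and
#' skipped while the remaining entries are returned; structural-invariant
#' violations of parseable entries are reported but do not exclude them.
#' Only malformed JSON itself raises (a `cv_error_parse_error`).
#'
#' @param input File path or JSON text.
#' @param references Optional reference registry passed to validation.
#' @return A list with `catvars` (parsed categories) and `report`
#'   (a `cv_report` with an extra `entry` column).
#' @export
read_categorical_variants <- function(input, references = NULL) {
  txt <- if (length(input) == 1L && !grepl("[{\\[]", input) && file.exists(input)) {
    paste(readLines(input, warn = FALSE), collapse = "\n")
  } else paste(input, collapse = "\n")
  docs <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                   error = function(e)
                     stop(cv_error("PARSE_ERROR",
                                   paste0("malformed JSON: ", conditionMessage(e)))))
  if (is.list(docs) && !is.null(docs[["type"]])) docs <- list(docs)
  catvars <- list()
  report <- new_report()
  report$entry <- integer()
  for (i in seq_along(docs)) {
    cv <- tryCatch(parse_categorical_variant(docs[[i]]), error = identity)
    if (inherits(cv, "error")) {
      code <- if (inherits(cv, "cv_error")) cv$code else "PARSE_ERROR"
      row <- add_violation(new_report(), code, conditionMessage(cv),
                           where = sprintf("entry[%d]", i))
      row$entry <- i
      report <- structure(rbind(report, row), class = c("cv_report", "data.frame"))
      next
    }
    vr <- validate_categorical_variant(cv, references)
    if (nrow(vr) > 0L) {
      vr$entry <- i
      report <- structure(rbind(report, vr), class = c("cv_report", "data.frame"))
    }
    catvars[[length(catvars) + 1L]] <- cv
  }
  list(catvars = catvars, report = report, n_entries = length(docs))
}

#' Write categorical variants as canonical JSON
#'
#' Emits a JSON array (sorted keys, no whitespace) such that reading the
#' output and writing again reproduces the bytes exactly; extension fields
#' captured at read time are re-emitted.
#'
#' @param catvars List of [categorical_variant()] objects.
#' @param file Optional path; when `NULL` the JSON text is returned.
#' @return The JSON text, invisibly when written to a file.
#' @export
write_categorical_variants <- function(catvars, file = NULL) {
  txt <- paste0("[", paste(vapply(catvars, function(x) canonical_json(x),
                                  character(1)), collapse = ","), "]")
  if (is.null(file)) return(txt)
  cat(txt, file = file)
  invisible(txt)
}
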