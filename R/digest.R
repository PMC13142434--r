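# Canonical serialization and digest identifiers. Equal model objects must
# serialize to identical bytes on any platform, so digests of the
# serialization can stand in for structural identity.

json_escape <- function(s) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  # remaining control characters, escaped numerically
  bad <- gregexpr("[\001-\037]", s)[[1]]
  if (bad[1] != -1L) {
    chars <- strsplit(s, "")[[1]]
    for (i in bad) chars[i] <- sprintf("\\u%04x", utf8ToInt(chars[i]))
    s <- paste(chars, collapse = "")
  }
  paste0("\"", s, "\"")
}

# canonical JSON: byte-sorted keys, no whitespace, integers without
# exponent, UTF-8. Model objects are first converted to their payload form.
canonical_json <- function(x) {
  if (is.null(x)) return("null")
  if (inherits(x, "cv_object")) x <- as_payload(x)
  if (is.list(x)) {
    nm <- names(x)
    if (is.null(nm)) {
      return(paste0("[", paste(vapply(x, canonical_json, character(1)),
                               collapse = ","), "]"))
    }
    if (any(!nzchar(nm)) || anyDuplicated(nm))
      stop(cv_error("UNSERIALIZABLE", "object keys must be unique and non-empty"))
    x <- x[!vapply(x, is.null, logical(1))]
    nm <- names(x)
    ord <- order(nm, method = "radix")
    parts <- vapply(ord, function(i)
      paste0(json_escape(enc2utf8(nm[i])), ":", canonical_json(x[[i]])),
      character(1))
    return(paste0("{", paste(parts, collapse = ","), "}"))
  }
  if (length(x) != 1L) {
    return(paste0("[", paste(vapply(seq_along(x), function(i) canonical_json(x[[i]]),
                                    character(1)), collapse = ","), "]"))
  }
  if (is.character(x)) {
    if (is.na(x)) return("null")
    return(json_escape(enc2utf8(x)))
  }
  if (is.logical(x)) return(if (is.na(x)) "null" else if (x) "true" else "false")
  if (is.numeric(x)) {
    if (is.na(x)) return("null")
    if (x == trunc(x) && abs(x) < 2^53) return(sprintf("%.0f", x))
    return(format(x, digits = 15, scientific = FALSE))
  }
  stop(cv_error("UNSERIALIZABLE", paste0("cannot serialize object of class ",
                                         paste(class(x), collapse = "/"))))
}

#' Canonical serialization of a model object
#'
#' Serializes a model object (or plain named/unnamed list of scalars) to a
#' canonical JSON byte string: keys byte-sorted, no whitespace, UTF-8,
#' integers printed without exponent. Field-equal objects built in any
#' field order serialize to identical bytes, and
#' serialize-parse-serialize is a fixed point, so the bytes are a stable
#' identity for digesting.
#'
#' @param x A model object (any `cv_*` class) or plain list.
#' @return A raw vector of UTF-8 bytes.
#' @export
canonical_serialize <- function(x) {
  charToRaw(canonical_json(x))
}

#' Digest identifier of a serialized object
#'
#' Truncated SHA-256 of the canonical serialization, rendered URL-safe
#' base64 (24 characters from the first 18 hash bytes) behind a short type
#' prefix — the computed-identifier pattern used for sequence-variant
#' digests. Equal inputs give equal identifiers; distinct inputs collide
#' only with cryptographic improbability.
#'
#' @param value A model object, or a raw vector already produced by
#'   [canonical_serialize()].
#' @param type Short type prefix (default `"OBJ"`; alleles use `"VA"`).
#' @return A character identifier like `"VA.0Jp2xxQ8tMnNxEOpzMyhZUrc"`.
#' @export
compute_digest <- function(value, type = "OBJ") {
  bytes <- if (is.raw(value)) value else canonical_serialize(value)
  hash <- digest::digest(bytes, algo = "sha256", serialize = FALSE, raw = TRUE)
  b64 <- jsonlite::base64_enc(hash[1:18])
  b64 <- chartr("+/", "-_", b64)
  paste0(type, ".", b64)
}

# digest of an allele from its identifying fields only
allele_digest <- function(al) {
  compute_digest(list(
    sequenceId = al$location$sequence_id,
    start = al$location$start,
    end = al$location$end,
    state = al$state), type = "VA")
}
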