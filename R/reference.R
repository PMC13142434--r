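# Reference registries: named collections of residue strings plus
# metadata, serving subsequences to normalization and the constraint
# engine.

#' Build a reference registry
#'
#' A registry maps reference ids to entries holding the residue string and
#' a [seq_reference()] descriptor. Accepted inputs: a named character
#' vector/list of sequences, a `Biostrings::DNAStringSet` /
#' `AAStringSet`, or an existing registry (returned unchanged). Alphabets
#' are inferred from the residues when not supplied.
#'
#' @param x Sequences (see above).
#' @param alphabet Optional alphabet override (`"DNA"` or `"PROTEIN"`),
#'   recycled over entries.
#' @return A named list of class `cv_references`; entries have `$meta`
#'   (a `cv_reference`) and `$seq` (character).
#' @export
as_reference_registry <- function(x, alphabet = NULL) {
  if (inherits(x, "cv_references")) return(x)
  if (inherits(x, "XStringSet")) {
    alphabet <- if (inherits(x, "AAStringSet")) "PROTEIN" else "DNA"
    x <- stats::setNames(as.character(x), names(x))
  }
  x <- as.list(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(cv_error("BAD_REFERENCE", "reference sequences must be named"))
  out <- lapply(seq_along(x), function(i) {
    s <- toupper(as.character(x[[i]]))
    a <- if (!is.null(alphabet)) alphabet[[min(i, length(alphabet))]]
         else infer_alphabet(s)
    list(meta = seq_reference(names(x)[i], nchar(s), a), seq = s)
  })
  names(out) <- names(x)
  structure(out, class = "cv_references")
}

# DNA unless residues outside the nucleotide alphabet appear
infer_alphabet <- function(s) {
  if (!nzchar(s)) return("DNA")
  if (grepl("^[ACGTUN]*$", s)) "DNA" else "PROTEIN"
}

reference_length <- function(references, id) {
  e <- references[[id]]
  if (is.null(e)) NA_integer_ else e$meta$length
}

reference_alphabet <- function(references, id) {
  e <- references[[id]]
  if (is.null(e)) NA_character_ else e$meta$alphabet
}

# residues over [start, end), 0-based half-open. `ref` may be a character
# scalar, an XString, a registry entry, or a function(start, end).
ref_slice <- function(ref, start, end) {
  if (is.list(ref) && !is.null(ref$seq)) ref <- ref$seq
  if (is.function(ref)) return(ref(start, end))
  if (inherits(ref, "XString")) ref <- as.character(ref)
  stopifnot(is.character(ref), length(ref) == 1L)
  if (end <= start) return("")
  substr(ref, start + 1L, end)
}

ref_length <- function(ref) {
  if (is.list(ref) && !is.null(ref$seq)) ref <- ref$seq
  if (is.function(ref)) {
    len <- attr(ref, "length")
    if (is.null(len)) stop(cv_error("BAD_REFERENCE",
      "a functional reference accessor needs a 'length' attribute"))
    return(as.integer(len))
  }
  if (inherits(ref, "XString")) return(length(ref))
  nchar(ref)
}
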