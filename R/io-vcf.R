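# VCF ingestion of assayed variants. The reader is total: unparseable
# records land in a skip report with a reason, never abort the batch.

#' Derive a copy-change code from an absolute count
#'
#' Opt-in converter used when a caller supplies an explicit baseline
#' ploidy (no baseline is ever assumed): 0 copies is a complete loss,
#' below baseline a loss, above baseline a gain, more than twice the
#' baseline a high-level gain; the baseline itself maps to no code.
#'
#' @param count Absolute copy number.
#' @param baseline Baseline ploidy (e.g. 2 for autosomes).
#' @return A code from [copy_change_codes()], or `NULL` at baseline.
#' @export
copy_change_from_count <- function(count, baseline) {
  stopifnot(is.numeric(count), count >= 0, is.numeric(baseline), baseline > 0)
  if (count == 0) return("COMPLETE_LOSS")
  if (count < baseline) return("LOSS")
  if (count == baseline) return(NULL)
  if (count > 2 * baseline) return("HIGH_LEVEL_GAIN")
  "GAIN"
}

info_value <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info,
                                perl = TRUE))[[1]]
  if (length(m) < 2L) NA_character_ else m[2L]
}

#' Ingest assayed variants from a VCF
#'
#' Maps VCF records onto molecular variants. SNV/indel REF/ALT rows become
#' alleles: the 1-based `POS` is converted to inter-residue 0-based
#' coordinates and, when the contig's reference sequence is available,
#' REF-anchoring padding is trimmed by full normalization (the stored
#' allele is the fully-justified form with its digest). Symbolic
#' `<DEL>`/`<DUP>`/`<CNV>` rows with an INFO `END` (and per-sample `CN`
#' when present) become copy-number variants over `[POS, END)` in 0-based
#' terms — the padding base at `POS` is excluded from the interval —
#' with change code `LOSS` for `<DEL>`, `GAIN` for `<DUP>`, and for
#' `<CNV>` no code unless `CN` and a `baseline` ploidy are given. Paired
#' breakend (`BND`) records matched through INFO `MATEID` become one
#' adjacency per pair. Multi-allelic rows are split into one variant per
#' ALT.
#'
#' @param input Path to a VCF file, or VCF text.
#' @param references Optional reference registry
#'   ([as_reference_registry()]); with it, contigs absent from the
#'   registry are skipped with reason `MISSING_REFERENCE` and alleles are
#'   normalized.
#' @param baseline Optional baseline ploidy enabling
#'   [copy_change_from_count()] for `<CNV>` records.
#' @return A list with `variants` (list of [molecular_variant()]) and
#'   `skipped` (data frame `row`, `id`, `reason`).
#' @export
ingest_vcf <- function(input, references = NULL, baseline = NULL) {
  path <- input
  if (length(input) > 1L || grepl("\n", input[1L]) || startsWith(input[1L], "##")) {
    path <- tempfile(fileext = ".vcf")
    writeLines(input, path)
    on.exit(unlink(path))
  }
  if (!is.null(references)) references <- as_reference_registry(references)

  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) NULL)
  empty <- list(variants = list(),
                skipped = data.frame(row = integer(), id = character(),
                                     reason = character(), stringsAsFactors = FALSE))
  if (is.null(vcf) || nrow(vcf@fix) == 0L) return(empty)
  fix <- vcf@fix
  cn_mat <- tryCatch(
    suppressWarnings(vcfR::extract.gt(vcf, element = "CN", as.numeric = TRUE)),
    error = function(e) NULL)

  variants <- list()
  skipped <- list()
  bnds <- list()
  skip <- function(i, id, reason) {
    skipped[[length(skipped) + 1L]] <<- data.frame(
      row = i, id = id, reason = reason, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(fix))) {
    chrom <- unname(fix[i, "CHROM"])
    pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    vid <- unname(fix[i, "ID"])
    ref <- toupper(unname(fix[i, "REF"]))
    alt_field <- unname(fix[i, "ALT"])
    info <- unname(fix[i, "INFO"])
    if (is.na(pos) || is.na(alt_field) || !nzchar(alt_field)) {
      skip(i, vid, "MALFORMED_ROW"); next
    }
    alts <- strsplit(alt_field, ",", fixed = TRUE)[[1]]
    for (ai in seq_along(alts)) {
      alt <- toupper(alts[ai])
      rid <- if (!is.na(vid) && vid != ".") {
        if (length(alts) > 1L) paste0(vid, ".", ai) else vid
      } else paste(chrom, pos, ref, alt, sep = ":")

      if (grepl("^<.+>$", alt)) {
        sv <- strsplit(sub("^<(.+)>$", "\\1", alt), ":", fixed = TRUE)[[1]][1L]
        if (!sv %in% c("DEL", "DUP", "CNV")) { skip(i, rid, "UNSUPPORTED_ALT"); next }
        if (!is.null(references) && !chrom %in% names(references)) {
          skip(i, rid, "MISSING_REFERENCE"); next
        }
        end <- suppressWarnings(as.integer(info_value(info, "END")))
        if (is.na(end) || end < pos) { skip(i, rid, "MISSING_END"); next }
        cn <- if (!is.null(cn_mat)) suppressWarnings(as.integer(cn_mat[i, 1L])) else NA_integer_
        code <- switch(sv, DEL = "LOSS", DUP = "GAIN",
                       CNV = if (!is.na(cn) && !is.null(baseline))
                         copy_change_from_count(cn, baseline) else NULL)
        if (is.na(cn) && is.null(code)) { skip(i, rid, "MISSING_COPY_STATE"); next }
        payload <- copy_number(seq_location(chrom, pos, end),
                               count = if (!is.na(cn)) cn else NULL,
                               change_code = code)
        variants[[length(variants) + 1L]] <- molecular_variant(rid, payload)
      } else if (grepl("[][]", alt)) {
        mateid <- info_value(info, "MATEID")
        if (is.na(vid) || vid == "." || is.na(mateid)) {
          skip(i, rid, "UNPAIRED_BND"); next
        }
        bnds[[vid]] <- list(row = i, id = vid, mateid = mateid,
                            chrom = chrom, pos = pos)
      } else if (grepl("^[ACGTN]+$", alt) && grepl("^[ACGTN]+$", ref)) {
        if (!is.null(references) && !chrom %in% names(references)) {
          skip(i, rid, "MISSING_REFERENCE"); next
        }
        al <- allele(seq_location(chrom, pos - 1L, pos - 1L + nchar(ref)), alt)
        digest_id <- NULL
        if (!is.null(references)) {
          norm <- tryCatch(normalize_allele(al, references), error = identity)
          if (inherits(norm, "error")) {
            skip(i, rid, if (inherits(norm, "cv_error")) norm$code else "BAD_ALLELE")
            next
          }
          al <- norm$allele
          digest_id <- norm$digest_id
        }
        variants[[length(variants) + 1L]] <-
          molecular_variant(rid, al, digest_id = digest_id)
      } else {
        skip(i, rid, "UNSUPPORTED_ALT")
      }
    }
  }

  # pair breakends through MATEID
  done <- character()
  for (b in bnds) {
    if (b$id %in% done) next
    mate <- bnds[[b$mateid]]
    if (is.null(mate) || !identical(mate$mateid, b$id)) {
      skip(b$row, b$id, "UNPAIRED_BND"); next
    }
    done <- c(done, b$id, mate$id)
    if (!is.null(references) &&
        (!b$chrom %in% names(references) || !mate$chrom %in% names(references))) {
      skip(b$row, b$id, "MISSING_REFERENCE"); next
    }
    payload <- adjacency(seq_location(b$chrom, b$pos - 1L, b$pos),
                         seq_location(mate$chrom, mate$pos - 1L, mate$pos),
                         orientation = "AB")
    variants[[length(variants) + 1L]] <-
      molecular_variant(paste(b$id, mate$id, sep = "~"), payload)
  }

  skipped <- if (length(skipped) > 0L) do.call(rbind, skipped) else empty$skipped
  list(variants = variants, skipped = skipped)
}
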