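# Universe export/import through the public file interfaces, so the whole
# pipeline (reference FASTA, feature table, variant VCF, annotation TSV)
# is exercisable from files alone.

vcf_header <- function(references) {
  dna <- names(references)[vapply(names(references), function(i)
    references[[i]]$meta$alphabet == "DNA", logical(1))]
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", dna,
            vapply(dna, function(i) references[[i]]$meta$length, integer(1))),
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "##FORMAT=<ID=CN,Number=1,Type=Integer,Description=\"Copy number\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"))
}

vcf_row <- function(chrom, pos, id, ref, alt, info = ".", cn = ".") {
  paste(chrom, pos, id, ref, alt, ".", ".", info, "CN", cn, sep = "\t")
}

# VCF spelling of an internal allele; anchors pure indels on the
# preceding base (generated universes never place edits at position 0)
allele_vcf_row <- function(al, refseq, id) {
  loc <- al$location
  ref_part <- ref_slice(refseq, loc$start, loc$end)
  if (nzchar(ref_part) && nzchar(al$state)) {
    vcf_row(loc$sequence_id, loc$start + 1L, id, ref_part, al$state)
  } else {
    anchor <- ref_slice(refseq, loc$start - 1L, loc$start)
    vcf_row(loc$sequence_id, loc$start, id,
            paste0(anchor, ref_part), paste0(anchor, al$state))
  }
}

#' Write a universe as FASTA + feature TSV + VCF + annotation TSV
#'
#' Produces `references.fasta` (DNA), `protein.fasta` (when a protein
#' reference exists), `features.tsv` (the 0-based extended dialect of
#' [load_feature_table()]), `variants.vcf` (alleles as REF/ALT rows,
#' copy-number segments as symbolic records with `END` and a `CN` sample
#' value, adjacencies as `MATEID`-paired breakend rows),
#' `annotations.tsv`, and — when the universe has planted indels —
#' `indel_spellings.vcf` holding every equivalent spelling of each
#' planted indel (ids `<variant>.s<k>`). Symbolic records encode the
#' change-code branch only (`<DEL>`/`<DUP>`/`<CNV>`), so specialized
#' codes like a complete loss read back as the parent code.
#'
#' @param universe A `cv_universe`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  refs <- universe$references
  dna <- names(refs)[vapply(names(refs), function(i)
    refs[[i]]$meta$alphabet == "DNA", logical(1))]
  prot <- setdiff(names(refs), dna)
  dna_set <- Biostrings::DNAStringSet(vapply(dna, function(i) refs[[i]]$seq,
                                             character(1)))
  Biostrings::writeXStringSet(dna_set, file.path(dir, "references.fasta"))
  if (length(prot) > 0L) {
    aa_set <- Biostrings::AAStringSet(vapply(prot, function(i) refs[[i]]$seq,
                                             character(1)))
    Biostrings::writeXStringSet(aa_set, file.path(dir, "protein.fasta"))
  }
  write_feature_table(universe$features, file.path(dir, "features.tsv"))

  rows <- character()
  ann_rows <- list()
  for (v in universe$variants) {
    if (v$kind == "ALLELE") {
      loc <- v$payload$location
      rows <- c(rows, allele_vcf_row(v$payload, refs[[loc$sequence_id]], v$id))
    } else if (v$kind == "COPY_NUMBER") {
      loc <- v$payload$location
      code <- v$payload$change_code
      branch <- if (is.null(code)) "CNV"
                else if ("LOSS" %in% hierarchy_ancestors(code)) "DEL"
                else "DUP"
      anchor <- ref_slice(refs[[loc$sequence_id]], loc$start - 1L, loc$start)
      rows <- c(rows, vcf_row(loc$sequence_id, loc$start, v$id, anchor,
                              paste0("<", branch, ">"),
                              info = sprintf("END=%d;SVTYPE=%s", loc$end, branch),
                              cn = if (is.null(v$payload$count)) "."
                                   else v$payload$count))
    } else if (v$kind == "ADJACENCY") {
      a <- v$payload$breakend_a
      b <- v$payload$breakend_b
      ida <- paste0(v$id, "_a"); idb <- paste0(v$id, "_b")
      base_a <- ref_slice(refs[[a$sequence_id]], a$start, a$start + 1L)
      base_b <- ref_slice(refs[[b$sequence_id]], b$start, b$start + 1L)
      rows <- c(rows,
        vcf_row(a$sequence_id, a$start + 1L, ida, base_a,
                sprintf("%s[%s:%d[", base_a, b$sequence_id, b$start + 1L),
                info = paste0("SVTYPE=BND;MATEID=", idb)),
        vcf_row(b$sequence_id, b$start + 1L, idb, base_b,
                sprintf("%s]%s:%d]", base_b, a$sequence_id, a$start + 1L),
                info = paste0("SVTYPE=BND;MATEID=", ida)))
    }
    if (!is.null(v$annotation)) {
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        variant_id = v$id,
        gene_symbols = paste(v$annotation$gene_symbols, collapse = ","),
        function_terms = paste(v$annotation$function_terms, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  writeLines(c(vcf_header(refs), rows), file.path(dir, "variants.vcf"))

  ann <- if (length(ann_rows) > 0L) do.call(rbind, ann_rows)
         else data.frame(variant_id = character(), gene_symbols = character(),
                         function_terms = character(), stringsAsFactors = FALSE)
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (length(universe$indel_spellings) > 0L) {
    srows <- character()
    for (id in names(universe$indel_spellings)) {
      sp <- universe$indel_spellings[[id]]
      for (k in seq_along(sp)) {
        loc <- sp[[k]]$location
        srows <- c(srows, allele_vcf_row(sp[[k]], refs[[loc$sequence_id]],
                                         sprintf("%s.s%d", id, k)))
      }
    }
    writeLines(c(vcf_header(refs), srows), file.path(dir, "indel_spellings.vcf"))
  }
  invisible(dir)
}

#' Read a universe back from its file form
#'
#' Loads the files written by [write_universe()] into an in-memory world
#' suitable for matching and extension computation: references, feature
#' table, variants (normalized at ingest) with annotations attached.
#'
#' @param dir Directory written by [write_universe()].
#' @return A `cv_universe` (without generator-only bookkeeping such as
#'   repeat tracts), plus `$skipped` from the VCF reader.
#' @export
read_universe <- function(dir) {
  dna <- Biostrings::readDNAStringSet(file.path(dir, "references.fasta"))
  seqs <- stats::setNames(as.character(dna), sub(" .*$", "", names(dna)))
  registry <- as_reference_registry(as.list(seqs), alphabet = "DNA")
  prot_path <- file.path(dir, "protein.fasta")
  if (file.exists(prot_path)) {
    aa <- Biostrings::readAAStringSet(prot_path)
    prot <- as_reference_registry(
      stats::setNames(as.list(as.character(aa)), sub(" .*$", "", names(aa))),
      alphabet = "PROTEIN")
    registry <- structure(c(unclass(registry), unclass(prot)),
                          class = "cv_references")
  }
  features <- load_feature_table(file.path(dir, "features.tsv"))
  ing <- ingest_vcf(file.path(dir, "variants.vcf"), references = registry)
  variants <- ing$variants
  ann_path <- file.path(dir, "annotations.tsv")
  if (file.exists(ann_path)) {
    variants <- attach_annotations(variants, load_annotations(ann_path))
  }
  structure(list(references = registry, features = features,
                 variants = variants, tracts = NULL,
                 indel_spellings = list(), config = NULL,
                 seed = NA_integer_, skipped = ing$skipped),
            class = "cv_universe")
}
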