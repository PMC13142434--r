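# Feature tables (gene/exon intervals) and per-variant annotation tables.

#' Build a feature table from a data frame
#'
#' @param df Data frame with columns `id`, `symbol`, `sequence_id`,
#'   `start`, `end` (0-based half-open), optional `strand` (`+`, `-`, `.`)
#'   and `class` (`gene`, `exon`, `other`).
#' @return A `cv_feature_table` data frame.
#' @export
feature_table_from_df <- function(df) {
  if (is.null(df$strand)) df$strand <- "."
  if (is.null(df$class)) df$class <- "gene"
  if (is.null(df$symbol)) df$symbol <- df$id
  df <- df[, c("id", "symbol", "sequence_id", "start", "end", "strand", "class")]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (anyDuplicated(df$id)) {
    stop(cv_error("DUPLICATE_FEATURE",
                  paste0("duplicate feature ids: ",
                         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))))
  }
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0L | df$start > df$end)
  if (length(bad) > 0L) {
    stop(cv_error("BAD_INTERVAL",
                  paste0("malformed intervals for: ", paste(df$id[bad], collapse = ", "))))
  }
  rownames(df) <- NULL
  structure(df, class = c("cv_feature_table", "data.frame"))
}

#' Load a feature table from BED or TSV
#'
#' Two dialects are accepted. Plain BED: no header, tab-separated columns
#' `chrom start end name [score strand]`, 0-based half-open; rows load as
#' class `gene`. Extended TSV: a first pragma line `#coords=0-based` or
#' `#coords=1-based` declaring the coordinate base, then a header row with
#' columns `sequence`, `start`, `end`, `name` and optionally `strand`,
#' `class`, `symbol`; 1-based closed intervals are converted to the
#' internal 0-based half-open convention.
#'
#' @param path File path.
#' @return A `cv_feature_table`; empty input yields an empty table.
#' @export
load_feature_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- feature_table_from_df(data.frame(
    id = character(), symbol = character(), sequence_id = character(),
    start = integer(), end = integer(), strand = character(),
    class = character(), stringsAsFactors = FALSE))
  if (length(lines) == 0L) return(empty)
  if (startsWith(lines[1L], "#coords=")) {
    base <- sub("^#coords=", "", trimws(lines[1L]))
    if (!base %in% c("0-based", "1-based"))
      stop(cv_error("BAD_PRAGMA", paste0("unknown coordinate pragma: ", base)))
    df <- utils::read.table(text = lines[-1L], header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "")
    start <- df$start
    end <- df$end
    if (base == "1-based") { # closed 1-based -> half-open 0-based
      start <- start - 1L
    }
    feature_table_from_df(data.frame(
      id = as.character(df$name), symbol = as.character(
        if (is.null(df$symbol)) df$name else df$symbol),
      sequence_id = as.character(df$sequence),
      start = start, end = end,
      strand = if (is.null(df$strand)) "." else as.character(df$strand),
      class = if (is.null(df$class)) "gene" else as.character(df$class),
      stringsAsFactors = FALSE))
  } else {
    lines <- lines[!startsWith(lines, "#") &
                     !startsWith(lines, "track") & !startsWith(lines, "browser")]
    if (length(lines) == 0L) return(empty)
    df <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
                            fill = TRUE, comment.char = "")
    if (ncol(df) < 4L)
      stop(cv_error("BAD_INTERVAL", "BED input needs at least 4 columns"))
    feature_table_from_df(data.frame(
      id = as.character(df[[4L]]), symbol = as.character(df[[4L]]),
      sequence_id = as.character(df[[1L]]),
      start = df[[2L]], end = df[[3L]],
      strand = if (ncol(df) >= 6L) as.character(df[[6L]]) else ".",
      class = "gene", stringsAsFactors = FALSE))
  }
}

#' Write a feature table
#'
#' Writes the extended TSV dialect (`#coords=0-based` pragma plus header),
#' which [load_feature_table()] reads back losslessly including feature
#' class and symbol.
#'
#' @param ft A `cv_feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#coords=0-based", con)
  out <- data.frame(sequence = ft$sequence_id, start = ft$start, end = ft$end,
                    name = ft$id, strand = ft$strand, class = ft$class,
                    symbol = ft$symbol, stringsAsFactors = FALSE)
  suppressWarnings(utils::write.table(out, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  invisible(path)
}

#' Load per-variant annotations from TSV
#'
#' A tab-separated table with header columns `variant_id`, `gene_symbols`,
#' `function_terms`; the two annotation columns hold comma-separated
#' values (empty allowed).
#'
#' @param path File path.
#' @return Named list of [variant_annotation()] objects keyed by variant id.
#' @export
load_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "", na.strings = NULL)
  split_csv <- function(s) {
    if (is.na(s) || !nzchar(s)) character() else trimws(strsplit(s, ",")[[1]])
  }
  out <- lapply(seq_len(nrow(df)), function(i)
    variant_annotation(split_csv(df$gene_symbols[i]),
                       split_csv(df$function_terms[i])))
  names(out) <- df$variant_id
  out
}

#' Attach annotations to ingested variants
#'
#' @param variants List of [molecular_variant()] objects.
#' @param annotations Result of [load_annotations()] (or any named list of
#'   [variant_annotation()]s keyed by variant id).
#' @return The variant list with matching annotations attached.
#' @export
attach_annotations <- function(variants, annotations) {
  lapply(variants, function(v) {
    if (!is.null(annotations[[v$id]])) v$annotation <- annotations[[v$id]]
    v
  })
}
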