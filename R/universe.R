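# Synthetic finite universes: seeded reference sequences with planted
# repeat tracts, a feature table of non-overlapping genes with exons, and
# an enumerated variant set (SNVs, repeat-tract indels with multiple
# equivalent spellings, copy-number segments, adjacencies). Universes are
# combinatorial test beds over which brute-force category extensions are
# computable — not simulations of population genetics.

#' Universe size configuration
#'
#' Defaults give a small world (a few hundred variants) on which
#' exhaustive evaluation is instant; all sizes are configuration.
#'
#' @param n_references Number of DNA reference sequences (1-3).
#' @param ref_length Length of each reference in bases.
#' @param n_genes Total genes, spread over the references (>= 1).
#' @param exons_per_gene Exons per gene.
#' @param n_snvs,n_indels,n_cnvs,n_adjacencies Variant counts by kind.
#' @param n_repeat_tracts Planted repeat tracts per reference; indels are
#'   planted on tracts (at most two per tract), so
#'   `n_indels <= 2 * n_repeat_tracts * n_references`.
#' @param max_indel_unit Maximal repeat-unit length for planted indels.
#' @param annotate_fraction Fraction of allele variants given a
#'   functional-consequence term.
#' @param include_protein Whether to add one protein reference (used by
#'   protein-consequence categories; carries no variants).
#' @return A `cv_universe_config` list.
#' @export
universe_config <- function(n_references = 2, ref_length = 1500, n_genes = 4,
                            exons_per_gene = 2, n_snvs = 40, n_indels = 20,
                            n_cnvs = 20, n_adjacencies = 8,
                            n_repeat_tracts = 10, max_indel_unit = 3,
                            annotate_fraction = 0.6, include_protein = TRUE) {
  cfg <- list(n_references = as.integer(n_references),
              ref_length = as.integer(ref_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              n_snvs = as.integer(n_snvs), n_indels = as.integer(n_indels),
              n_cnvs = as.integer(n_cnvs),
              n_adjacencies = as.integer(n_adjacencies),
              n_repeat_tracts = as.integer(n_repeat_tracts),
              max_indel_unit = as.integer(max_indel_unit),
              annotate_fraction = annotate_fraction,
              include_protein = isTRUE(include_protein))
  with(cfg, {
    if (n_references < 1L || n_references > 3L)
      stop(cv_error("BAD_CONFIG", "need 1-3 references"))
    if (n_genes < 1L) stop(cv_error("BAD_CONFIG", "need at least one gene"))
    if (ref_length < 400L) stop(cv_error("BAD_CONFIG", "references shorter than 400 bases"))
    if (exons_per_gene < 1L || max_indel_unit < 1L || annotate_fraction < 0 ||
        annotate_fraction > 1 || min(n_snvs, n_indels, n_cnvs, n_adjacencies) < 0L)
      stop(cv_error("BAD_CONFIG", "malformed size parameter"))
    if (n_indels > 2L * n_repeat_tracts * n_references)
      stop(cv_error("BAD_CONFIG",
                    "n_indels exceeds 2 * n_repeat_tracts * n_references"))
  })
  structure(cfg, class = c("cv_universe_config", "list"))
}

#' Default functional-consequence hierarchy
#'
#' A small consequence vocabulary with parent edges (child -> parent):
#' ablation/stop/frameshift terms specialize loss of function, activating
#' specializes gain of function, and both roll up to protein-altering.
#'
#' @return Named character vector of parent edges.
#' @export
default_function_hierarchy <- function() {
  c(stop_gained = "loss_of_function",
    frameshift_variant = "loss_of_function",
    transcript_ablation = "loss_of_function",
    activating = "gain_of_function",
    loss_of_function = "protein_altering",
    gain_of_function = "protein_altering",
    missense_variant = "protein_altering")
}

function_term_vocab <- function() {
  c("loss_of_function", "gain_of_function", "stop_gained",
    "frameshift_variant", "missense_variant", "activating")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic universe
#'
#' Deterministic for a fixed `(config, seed)` pair: the same inputs
#' reproduce field-identical universes. Planted repeat tracts guarantee
#' that every planted indel admits at least two equivalent spellings
#' (recorded in `$indel_spellings` for normalization tests and VCF
#' export); allele variants are stored in fully-justified normalized form
#' with their digests.
#'
#' @param config A [universe_config()].
#' @param seed Integer seed; all draws are derived from it.
#' @return A `cv_universe`: `references` (registry), `features`
#'   (feature table), `variants` (list of [molecular_variant()]),
#'   `tracts`, `indel_spellings`, `config`, `seed`.
#' @export
generate_universe <- function(config = universe_config(), seed) {
  if (!inherits(config, "cv_universe_config")) config <- do.call(universe_config, config)
  withr::with_seed(as.integer(seed), build_universe(config, as.integer(seed)))
}

build_universe <- function(cfg, seed) {
  n <- cfg$ref_length
  seqs <- list(); tracts <- list()
  for (r in seq_len(cfg$n_references)) {
    id <- sprintf("ref%d", r)
    s <- random_dna(n)
    # plant non-overlapping repeat tracts, spaced away from the edges
    slots <- floor(seq(60, n - 80, length.out = cfg$n_repeat_tracts + 1L))
    for (t in seq_len(cfg$n_repeat_tracts)) {
      unit <- random_dna(sample.int(cfg$max_indel_unit, 1L))
      copies <- sample(4:6, 1L)
      width <- nchar(unit) * copies
      lo <- slots[t]; hi <- slots[t + 1L] - width - 5L
      if (hi <= lo) next
      start <- sample(lo:hi, 1L)
      tract_seq <- strrep(unit, copies)
      substr(s, start + 1L, start + width) <- tract_seq
      tracts[[length(tracts) + 1L]] <- data.frame(
        sequence_id = id, start = start, unit = unit, copies = copies,
        stringsAsFactors = FALSE)
    }
    seqs[[id]] <- s
  }
  tracts <- do.call(rbind, tracts)
  if (cfg$include_protein) {
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y")
    seqs[["prot1"]] <- paste(c("M", sample(aa, 149, replace = TRUE)), collapse = "")
  }
  references <- as_reference_registry(seqs)

  # genes: spread across DNA references, non-overlapping windows
  dna_ids <- names(seqs)[vapply(names(seqs), function(i)
    references[[i]]$meta$alphabet == "DNA", logical(1))]
  gene_ref <- sort(sample(rep_len(seq_along(dna_ids), cfg$n_genes)))
  feat <- list()
  gi <- 0L
  for (r in seq_along(dna_ids)) {
    k <- sum(gene_ref == r)
    if (k == 0L) next
    bounds <- floor(seq(30, n - 30, length.out = k + 1L))
    for (j in seq_len(k)) {
      gi <- gi + 1L
      lo <- bounds[j] + 5L; hi <- bounds[j + 1L] - 10L
      gs <- sample(lo:(lo + max(1L, (hi - lo) %/% 4L)), 1L)
      ge <- sample((gs + max(40L, (hi - gs) %/% 2L)):hi, 1L)
      gene_id <- sprintf("G%d", gi)
      strand <- sample(c("+", "-"), 1L)
      feat[[length(feat) + 1L]] <- data.frame(
        id = gene_id, symbol = sprintf("GENE%d", gi),
        sequence_id = dna_ids[r], start = gs, end = ge, strand = strand,
        class = "gene", stringsAsFactors = FALSE)
      ebounds <- floor(seq(gs, ge, length.out = cfg$exons_per_gene + 1L))
      for (e in seq_len(cfg$exons_per_gene)) {
        es <- ebounds[e] + 2L
        ee <- max(es + 5L, ebounds[e + 1L] - 2L)
        feat[[length(feat) + 1L]] <- data.frame(
          id = sprintf("%s.E%d", gene_id, e), symbol = sprintf("%s.E%d", gene_id, e),
          sequence_id = dna_ids[r], start = es, end = min(ee, ge), strand = strand,
          class = "exon", stringsAsFactors = FALSE)
      }
    }
  }
  features <- feature_table_from_df(do.call(rbind, feat))
  genes <- features[features$class == "gene", , drop = FALSE]

  overlapping_symbols <- function(sequence_id, start, end) {
    hit <- genes$sequence_id == sequence_id &
      genes$start < end & start < genes$end
    genes$symbol[hit]
  }
  maybe_terms <- function() {
    if (stats::runif(1) < cfg$annotate_fraction)
      sample(function_term_vocab(), 1L) else character()
  }

  variants <- list()
  add <- function(v) variants[[length(variants) + 1L]] <<- v

  for (i in seq_len(cfg$n_snvs)) {
    rid <- sample(dna_ids, 1L)
    pos <- sample.int(n - 2L, 1L)
    refb <- ref_slice(references[[rid]], pos, pos + 1L)
    altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
    al <- allele(seq_location(rid, pos, pos + 1L), altb)
    norm <- normalize_allele(al, references[[rid]])
    ann <- variant_annotation(overlapping_symbols(rid, pos, pos + 1L), maybe_terms())
    add(molecular_variant(sprintf("snv%04d", i), norm$allele, annotation = ann,
                          digest_id = norm$digest_id))
  }

  indel_spellings <- list()
  seen_digests <- character()
  if (cfg$n_indels > 0L && !is.null(tracts)) {
    for (i in seq_len(cfg$n_indels)) {
      t <- tracts[((i - 1L) %% nrow(tracts)) + 1L, ]
      deletion <- i <= nrow(tracts)
      unit_len <- nchar(t$unit)
      offsets <- t$start + unit_len * (seq_len(t$copies) - 1L)
      spellings <- lapply(offsets, function(o) {
        if (deletion) allele(seq_location(t$sequence_id, o, o + unit_len), "")
        else allele(seq_location(t$sequence_id, o, o), t$unit)
      })
      norm <- normalize_allele(spellings[[1L]], references[[t$sequence_id]])
      if (norm$digest_id %in% seen_digests || norm$is_identity) next
      seen_digests <- c(seen_digests, norm$digest_id)
      id <- sprintf("ind%04d", i)
      ann <- variant_annotation(
        overlapping_symbols(t$sequence_id, norm$allele$location$start,
                            norm$allele$location$end),
        maybe_terms())
      add(molecular_variant(id, norm$allele, annotation = ann,
                            digest_id = norm$digest_id))
      indel_spellings[[id]] <- spellings
    }
  }

  for (i in seq_len(cfg$n_cnvs)) {
    on_gene <- stats::runif(1) < 0.5 && nrow(genes) > 0L
    if (on_gene) {
      g <- genes[sample.int(nrow(genes), 1L), ]
      rid <- g$sequence_id
      s <- max(1L, g$start - sample(0:30, 1L))
      e <- min(n, g$end + sample(0:30, 1L))
    } else {
      rid <- sample(dna_ids, 1L)
      s <- sample.int(n - 320L, 1L)
      e <- s + sample(50:300, 1L)
    }
    code_only <- stats::runif(1) < 0.25
    if (code_only) {
      payload <- copy_number(seq_location(rid, s, e),
                             change_code = sample(copy_change_codes(), 1L))
    } else {
      count <- sample(0:6, 1L)
      payload <- copy_number(seq_location(rid, s, e), count = count,
                             change_code = copy_change_from_count(count, 2))
    }
    ann <- variant_annotation(overlapping_symbols(rid, s, e), character())
    add(molecular_variant(sprintf("cnv%04d", i), payload, annotation = ann))
  }

  if (cfg$n_adjacencies > 0L) {
    candidates <- rbind(
      data.frame(sequence_id = genes$sequence_id, pos = genes$start,
                 stringsAsFactors = FALSE),
      data.frame(sequence_id = genes$sequence_id, pos = genes$end,
                 stringsAsFactors = FALSE))
    for (i in seq_len(cfg$n_adjacencies)) {
      pick <- candidates[sample.int(nrow(candidates), 2L, replace = TRUE), ]
      jitter <- sample(-20:20, 2L, replace = TRUE)
      p1 <- min(max(1L, pick$pos[1L] + jitter[1L]), n - 1L)
      p2 <- min(max(1L, pick$pos[2L] + jitter[2L]), n - 1L)
      payload <- adjacency(seq_location(pick$sequence_id[1L], p1, p1 + 1L),
                           seq_location(pick$sequence_id[2L], p2, p2 + 1L))
      ann <- variant_annotation(
        unique(c(overlapping_symbols(pick$sequence_id[1L], p1, p1 + 1L),
                 overlapping_symbols(pick$sequence_id[2L], p2, p2 + 1L))),
        character())
      add(molecular_variant(sprintf("adj%04d", i), payload, annotation = ann))
    }
  }

  structure(list(references = references, features = features,
                 variants = variants, tracts = tracts,
                 indel_spellings = indel_spellings,
                 config = cfg, seed = seed),
            class = "cv_universe")
}

#' @export
print.cv_universe <- function(x, ...) {
  kinds <- table(vapply(x$variants, `[[`, character(1), "kind"))
  cat(sprintf("<Universe seed=%d> %d references, %d features, %d variants (%s)\n",
              x$seed, length(x$references), nrow(x$features), length(x$variants),
              paste(names(kinds), kinds, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Evaluation context of a universe
#'
#' @param universe A [generate_universe()] result.
#' @param ... Passed on to [evaluation_context()] (e.g.
#'   `allele_equivalences`).
#' @return A `cv_context` over the universe's features and references,
#'   with the default function hierarchy.
#' @export
build_context <- function(universe, ...) {
  evaluation_context(feature_table = universe$features,
                     references = universe$references,
                     function_hierarchy = default_function_hierarchy(), ...)
}

#' Brute-force extension of a category over a universe
#'
#' The oracle: a plain exhaustive loop over every enumerated variant,
#' evaluating each constraint directly — deliberately independent of
#' [match_batch()] or any indexed path, so those can be verified against
#' it.
#'
#' @param catvar A [categorical_variant()].
#' @param universe A [generate_universe()] result.
#' @param ctx Context from [build_context()].
#' @return Character vector of member variant ids, in universe order.
#' @export
extension <- function(catvar, universe, ctx) {
  ids <- character()
  for (v in universe$variants) {
    member <- TRUE
    for (k in catvar$constraints) {
      vd <- evaluate_constraint(k, v, ctx)
      if (vd$status != "SATISFIED") { member <- FALSE; break }
    }
    if (member) ids <- c(ids, v$id)
  }
  ids
}

#' Brute-force entailment check over a universe
#'
#' @inheritParams extension
#' @param a,b Categorical variants.
#' @return List with `holds` (is `extension(a)` a subset of
#'   `extension(b)`?) and `witness` (one counterexample variant id, or
#'   `NULL`).
#' @export
oracle_entails <- function(a, b, universe, ctx) {
  ea <- extension(a, universe, ctx)
  eb <- extension(b, universe, ctx)
  extra <- setdiff(ea, eb)
  list(holds = length(extra) == 0L,
       witness = if (length(extra) > 0L) extra[1L] else NULL)
}

#' Generate a random category over a universe
#'
#' Draws a valid categorical variant whose constraints reference only
#' entities of the universe; with `profile` given, the result validates
#' against that profile.
#'
#' @param universe A [generate_universe()] result.
#' @param seed Integer seed.
#' @param profile Optional profile name from [profile_registry()].
#' @return A [categorical_variant()].
#' @export
generate_random_category <- function(universe, seed, profile = NULL) {
  withr::with_seed(as.integer(seed), random_category(universe, seed, profile))
}

random_category <- function(universe, seed, profile) {
  refs <- universe$references
  dna_ids <- names(refs)[vapply(names(refs), function(i)
    refs[[i]]$meta$alphabet == "DNA", logical(1))]
  genes <- universe$features[universe$features$class == "gene", , drop = FALSE]
  alleles <- Filter(function(v) v$kind == "ALLELE", universe$variants)

  rand_interval <- function() {
    # anchor half the intervals on an actual variant so extensions are
    # frequently non-empty
    if (stats::runif(1) < 0.5 && length(universe$variants) > 0L) {
      v <- universe$variants[[sample.int(length(universe$variants), 1L)]]
      loc <- variant_location(v)
      if (!is.null(loc)) {
        pad <- sample(0:120, 2L, replace = TRUE)
        return(seq_location(loc$sequence_id, max(0L, loc$start - pad[1L]),
                            min(reference_length(refs, loc$sequence_id),
                                loc$end + pad[2L])))
      }
    }
    rid <- sample(dna_ids, 1L)
    len <- reference_length(refs, rid)
    s <- sample.int(len - 200L, 1L)
    seq_location(rid, s, s + sample(30:200, 1L))
  }
  makers <- list(
    defining_allele = function() {
      v <- alleles[[sample.int(length(alleles), 1L)]]
      defining_allele(v$payload)
    },
    defining_location = function() {
      defining_location(rand_interval(),
                        sample(c("CONTAINED", "CONTAINED", "CONTAINED",
                                 "OVERLAPS", "EXACT"), 1L))
    },
    copy_count = function() {
      m <- sample(0:4, 1L)
      copy_count(m, m + sample(0:3, 1L))
    },
    copy_change = function() copy_change(sample(copy_change_codes(), 1L)),
    feature_context = function()
      feature_context(universe$features$id[sample.int(nrow(universe$features), 1L)]),
    fun = function() function_constraint(sample(function_term_vocab(), 1L)),
    adj = function() {
      g <- genes$id[sample.int(nrow(genes), 2L, replace = TRUE)]
      adjacency_constraint(g[1L], g[2L], ordered = stats::runif(1) < 0.7)
    })

  cid <- sprintf("cat_s%d_%04d", seed, sample.int(9999L, 1L))
  if (is.null(profile)) {
    weights <- c(defining_allele = if (length(alleles) > 0L) 1 else 0,
                 defining_location = 3, copy_count = 2, copy_change = 2,
                 feature_context = 3, fun = 1,
                 adj = if (nrow(genes) > 0L) 1 else 0)
    nk <- sample(1:3, 1L)
    picks <- sample(names(weights), nk, replace = TRUE, prob = weights)
    return(categorical_variant(cid, "random category",
                               lapply(picks, function(p) makers[[p]]())))
  }
  switch(profile,
    CanonicalAllele = categorical_variant(cid, "random canonical allele",
      list(makers$defining_allele()), declared_profile = profile),
    ProteinSequenceConsequence = {
      prot <- names(refs)[vapply(names(refs), function(i)
        refs[[i]]$meta$alphabet == "PROTEIN", logical(1))]
      if (length(prot) == 0L)
        stop(cv_error("BAD_CONFIG", "universe has no protein reference"))
      len <- reference_length(refs, prot[1L])
      p <- sample.int(len - 1L, 1L)
      st <- sample(c("A", "G", "L", "V", "*"), 1L)
      categorical_variant(cid, "random protein consequence",
        list(defining_allele(allele(seq_location(prot[1L], p, p + 1L), st))),
        declared_profile = profile)
    },
    CategoricalCNV = {
      anchor <- if (stats::runif(1) < 0.5 && nrow(genes) > 0L)
        feature_context(genes$id[sample.int(nrow(genes), 1L)])
      else defining_location(rand_interval())
      dose <- if (stats::runif(1) < 0.5) makers$copy_count() else makers$copy_change()
      categorical_variant(cid, "random categorical CNV", list(anchor, dose),
                          declared_profile = profile)
    },
    FunctionVariant = categorical_variant(cid, "random function variant",
      list(feature_context(genes$id[sample.int(nrow(genes), 1L)]), makers$fun()),
      declared_profile = profile),
    GeneFusion = {
      ks <- if (stats::runif(1) < 0.5) list(makers$adj())
            else {
              g <- genes$id[sample.int(nrow(genes), 2L, replace = TRUE)]
              list(feature_context(g[1L]), feature_context(g[2L]),
                   adjacency_constraint(g[1L], g[2L]))
            }
      categorical_variant(cid, "random gene fusion", ks, declared_profile = profile)
    },
    stop(cv_error("UNKNOWN_PROFILE", paste0("profile not registered: ", profile))))
}

#' Universe with planted exon deletions
#'
#' A minimal scenario in the style of an "exon 19 deletions" category:
#' one gene with three exons, five planted deletion alleles of which
#' exactly three fall inside the designated exon. The ground truth is
#' recorded in `$planted` (`category`, `inside_ids`, `n_inside`) so the
#' brute-force extension can be checked against the planted counts.
#'
#' @param seed Integer seed.
#' @return A `cv_universe` with a `$planted` element.
#' @export
generate_exon_deletion_universe <- function(seed) {
  withr::with_seed(as.integer(seed), {
    n <- 1200L
    s <- random_dna(n)
    references <- as_reference_registry(list(refE = s))
    features <- feature_table_from_df(data.frame(
      id = c("G1", "G1.E1", "G1.E2", "G1.E3"),
      symbol = c("GENE1", "G1.E1", "G1.E2", "G1.E3"),
      sequence_id = "refE",
      start = c(100L, 150L, 400L, 900L),
      end = c(1100L, 250L, 700L, 1050L),
      strand = "+", class = c("gene", "exon", "exon", "exon"),
      stringsAsFactors = FALSE))
    spots <- list(inside1 = c(450L, 460L), inside2 = c(500L, 512L),
                  inside3 = c(600L, 609L), outside1 = c(200L, 210L),
                  outside2 = c(780L, 795L))
    variants <- list()
    inside_ids <- character()
    for (k in seq_along(spots)) {
      sp <- spots[[k]]
      al <- allele(seq_location("refE", sp[1L], sp[2L]), "")
      norm <- normalize_allele(al, references[["refE"]])
      id <- sprintf("del%02d", k)
      variants[[k]] <- molecular_variant(id, norm$allele,
        annotation = variant_annotation("GENE1"), digest_id = norm$digest_id)
      inside <- norm$allele$location$start >= 400L && norm$allele$location$end <= 700L
      if (inside) inside_ids <- c(inside_ids, id)
    }
    category <- categorical_variant("exon2dels", "GENE1 exon 2 deletions", list(
      feature_context("G1"),
      defining_location(seq_location("refE", 400L, 700L), "CONTAINED")))
    structure(list(references = references, features = features,
                   variants = variants, tracts = NULL,
                   indel_spellings = list(),
                   planted = list(category = category, inside_ids = inside_ids,
                                  n_inside = 3L),
                   config = NULL, seed = as.integer(seed)),
              class = "cv_universe")
  })
}
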