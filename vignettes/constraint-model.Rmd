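---
title: "Categorical variants as conjunctions of computable constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Categorical variants as conjunctions of computable constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varcat)
```

## The problem

Clinical genomics constantly refers to *categorical* variants: "EGFR exon
19 deletions", "TP53 copy-number loss", "any PTEN loss-of-function
variant". These are sets of alterations defined by shared properties, not
by enumerating members — and an assayed variant from a pipeline must be
decided *in* or *out* of such a set. varcat models each category
intensionally, as a non-empty conjunction of constraints. A molecular
variant is a member exactly when it satisfies every constraint; two
categories can be compared by entailment (is every member of one
necessarily a member of the other?).

## The model

A `molecular_variant()` is one of three payloads, all anchored to
sequence locations in inter-residue, 0-based, half-open coordinates:

* an **allele** — literal replacement of the residues at an interval;
* a **copy-number variant** — a segment with an absolute copy count, a
  relative change code, or both;
* an **adjacency** — two joined breakends, the substrate of
  rearrangements and fusions.

Seven constraint kinds filter this space: defining allele, defining
location, copy count, copy change, feature context, functional
consequence, and adjacency. Their satisfaction semantics are documented
in `?evaluate_constraint`. Three distinctions matter in practice:

* **UNSATISFIED vs INAPPLICABLE.** A verdict is INAPPLICABLE exactly when
  the variant lacks the attribute the constraint tests (an SNV has no
  copy state; an unannotated variant has no consequence term).
  Applicability is a pure function of attribute *presence* so that it can
  never flip on attribute values. Both block membership: the extension of
  a category contains only variants *demonstrably* satisfying every
  constraint (closed-world membership).
* **No assumed ploidy.** A bare copy count never satisfies a copy-change
  constraint. `copy_change_from_count()` converts counts to codes, but
  only with an explicitly supplied baseline.
* **Containment by default.** A defining-location constraint defaults to
  `CONTAINED` because categories like "deletions within exon 19" intend
  events inside the region; `OVERLAPS` (used by broad region categories
  such as the packaged TP53 copy-loss example, where a chromosome-arm
  loss should match) and `EXACT` are opt-in per constraint. A zero-width
  interval (insertion point, breakend) overlaps a region when the point
  lies within its closed bounds; without this rule an insertion strictly
  inside a gene would overlap nothing.

A category may repeat a constraint kind (two defining locations simply
conjoin); the validator flags this with an informational notice, not an
error. An *empty* constraint list is rejected: a property-free category
would denote the universal set, which has no computable meaning here.

## Normalization and digests

One alteration admits many spellings: an indel can be written at any
offset through a flanking repeat, and VCF padding adds reference context.
`normalize_allele()` trims the shared prefix then suffix, and for pure
insertions/deletions expands the interval across the maximal flanking
repeat of the edited unit — the fully-justified form. Every equivalent
spelling maps to one interval and state, so the truncated-SHA-256 digest
of the normalized `(sequence, start, end, state)` is an identity for the
alteration itself. The test suite verifies this against an independent
oracle that applies each spelling to the reference by plain string
surgery and checks the mutated strings coincide before comparing digests.

Scope choices, made once and documented as limitations:

* only single contiguous edits are justified; delins edits with internal
  matches are trimmed but not shuffled (sufficient for category
  membership; full expansion is not needed for it);
* protein alleles are trimmed only — residue-level justification
  conventions differ between communities, so no repeat shuffle is applied;
* digests are the first 18 bytes of SHA-256 over the canonical
  serialization (byte-sorted keys, no whitespace, UTF-8), rendered as 24
  URL-safe base64 characters behind a short type prefix. The truncation
  keeps identifiers readable; at 144 bits, collisions are not a practical
  concern.

Because membership should not depend on spelling, the package normalizes
alleles *at the boundary*: `ingest_vcf()` stores the fully-justified
form (with its digest) whenever the contig's sequence is available, and
the universe generator plants variants already normalized. Location
constraints then evaluate the payload location directly.

## Entailment: sound, deliberately incomplete

`entails(a, b)` returns `ENTAILS` only when every constraint of `b` is
subsumed by some constraint of `a` under a closed rule set
(`?subsumes`): digest equality, interval nesting, interval-in-feature,
same feature, copy-range inclusion, change-code specialization, and the
defining-allele-inside-region rule (sound because every spelling of an
allele lies within its fully-justified interval). Everything else stays
`UNKNOWN` rather than guessed — clinical use demands that `ENTAILS` never
be wrong, and incompleteness is the price. Supplying a finite universe
upgrades `UNKNOWN` to `NOT_ENTAILED` when a concrete counterexample
variant is found there; a missing counterexample never upgrades to
`ENTAILS`. Two deliberate conservatisms: functional and adjacency
constraints participate only in identity subsumption (the relation
between, say, a loss-of-function category and a specific frameshift
allele is knowledge, not syntax), and the allele-inside-region rule
abstains whenever a user equivalence table maps foreign digests onto the
defining allele, since equivalent alleles may live elsewhere.

## Profiles

`profile_registry()` ships five structural templates with their maturity
labels: CanonicalAllele and ProteinSequenceConsequence (trial use),
CategoricalCNV (draft), FunctionVariant and GeneFusion (in progress).
Profiles are data, not code — local implementations can load their own
registry from JSON (`read_profile_registry()`). A CategoricalCNV may
carry both a location and a feature context (the packaged TP53 example
does). The in-progress profiles, and the functional/adjacency constraint
kinds beneath them, are refused by the command-line tools without
`--experimental`. When no reference registry reveals an allele's
alphabet, the two allele profiles fall back to inferring it from the
state string (nucleotide symbols mean DNA); passing `references=` makes
the check exact.

## Synthetic universes and what passing tests mean

`generate_universe()` builds a finite world from a single integer seed:
1–3 random DNA references with planted repeat tracts, non-overlapping
genes with exons, and an enumerated variant set — SNVs, indels planted on
the tracts (each with at least two equivalent spellings, recorded for the
normalization oracle), copy-number segments with counts 0–6 and matching
codes at baseline 2, and breakend pairs near gene boundaries.
`extension()` is the oracle: a naive exhaustive loop, deliberately
independent of `match_batch()`, so the optimized paths can be checked
against it exactly.

Universes are combinatorial test beds. They emulate coordinate geometry,
repeat-induced spelling ambiguity, dosage vocabulary, and annotation
lookup; they do **not** emulate allele frequencies, mutation processes,
linkage, transcript structure or real gene models. Passing the oracle
suites therefore demonstrates logical correctness of matching and
entailment over the modeled attribute space — not calibration against
any real cohort.

The validation runs use three seeded universes of roughly 960 variants
(500 SNVs, ~100 planted indels, 300 copy-number segments, 60
adjacencies) for matcher/oracle agreement (≥1,000 randomized pairs),
entailment soundness (≥1,000 category pairs per universe plus
reflexivity and transitivity), and spelling invariance (≥100 planted
indels); monotonicity uses 100 random categories over a ~260-variant
world. These sizes make exhaustive evaluation essentially instant while
keeping every count above its contract.

## Numerical and degenerate-input choices

* Coordinates are validated as `0 <= start <= end <= reference length`
  whenever the reference is known; violations are report rows, not
  exceptions, so one malformed document never aborts a batch.
* VCF symbolic records exclude the padding base: the internal interval is
  `[POS, END)` in 0-based terms, and reconstructing the affected span
  reproduces the VCF span exactly (checked on generated files).
* Canonical JSON writing (sorted keys, fixed integer formatting) makes
  write→read→write a byte-level fixed point, which is what the
  round-trip suite asserts.
* Unknown feature ids raise a classed error (`UNKNOWN_FEATURE`) rather
  than returning a verdict: a missing feature table entry is a context
  configuration defect, not evidence about the variant.
* Identity alleles (state equal to the reference subsequence) normalize
  to an empty edit and are flagged `is_identity`; they still receive a
  digest so equality comparisons remain total.

## Known limitations

* No HGVS parsing or printing, no transcript projection or liftover;
  cross-assembly/transcript equivalence enters only through a
  user-supplied digest equivalence table.
* No disjunction or negation between constraints — categories like "any
  residue at position 600 except valine" are out of scope until a boolean
  composition layer exists.
* Entailment incompleteness: disjoint copy ranges, overlapping-location
  pairs and cross-kind relations return `UNKNOWN` at rule level even when
  a human would call them decidable; universe probing is the provided
  remedy.
* Adjacency breakend orientation (the bracket notation's strand detail)
  is carried as metadata but not used in matching; fusion side order is
  governed by the constraint's `ordered` flag.
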