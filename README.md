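# varcat

Constraint-based representation, matching and entailment of **categorical
genomic variants** in R.

Clinical genomics is full of variant *categories* rather than single
alleles: "EGFR exon 19 deletions", "TP53 copy-number loss", "any PTEN
loss-of-function variant". Regulatory approvals, trial eligibility rules
and knowledgebases all hinge on deciding whether an assayed variant
belongs to such a category — yet categories are usually described in
free text. varcat gives them a computable form:

* a **categorical variant** is a non-empty *conjunction* of constraints
  `C = c1 ∧ c2 ∧ … ∧ ck`; its extension over a variant universe `V` is
  `ext(C) = { v ∈ V : v ⊨ ci for all i }`;
* seven constraint kinds cover allele identity (via normalized digest),
  sequence location (exact / contained / overlaps), absolute copy count,
  relative copy change (with a specialization hierarchy), feature
  context, functional consequence, and breakend adjacency;
* **matching** returns a per-constraint verdict trace
  (`SATISFIED` / `UNSATISFIED` / `INAPPLICABLE`) plus the conjunctive
  membership bit;
* **entailment** decides `ext(A) ⊆ ext(B)` by sound subsumption rules —
  `ENTAILS` is only ever returned when it provably holds in *every*
  universe; undecided pairs stay `UNKNOWN`, optionally refuted with a
  counterexample from a finite probe universe;
* alleles are canonicalized to their **fully-justified** form (trim
  shared context, expand across flanking repeats) so that every VCF
  spelling of one indel gets one digest identifier;
* a **synthetic universe** generator plus a brute-force extension oracle
  make matching and entailment testable end-to-end with no downloads.

Assayed variants come in from VCF (SNVs/indels, symbolic
`<DEL>`/`<DUP>`/`<CNV>` with `END`/`CN`, paired `BND` breakends), feature
tables from BED/TSV, references from FASTA, and categories from a JSON
dialect with camelCase fields and a `type` discriminator.

## Worked example

The packaged fixture models a TP53 copy-number-loss category with three
constraints:

```r
library(varcat)

fixture <- system.file("extdata", "tp53_cnloss.json", package = "varcat")
tp53 <- read_categorical_variants(fixture)$catvars[[1]]
tp53
#> <CategoricalVariant catvar-tp53-cnloss> TP53 CNLoss
#>   [1] FeatureContext TP53
#>   [2] DefiningLocation OVERLAPS GRCh38:chr17:[7668402,7687538)
#>   [3] CopyChange LOSS
classify_profile(tp53)
#> [1] "CategoricalCNV"
```

A 17p deletion call overlapping the gene is a member; an SNV inside the
gene is not (it has no copy state, so the dosage constraint is
inapplicable — and inapplicable blocks membership):

```r
ft  <- load_feature_table(system.file("extdata", "tp53_features.bed",
                                      package = "varcat"))
ctx <- evaluation_context(feature_table = ft)

del17p <- molecular_variant("del17p",
  copy_number(seq_location("GRCh38:chr17", 6000000, 8000000),
              count = 1, change_code = "LOSS"))
match_variant(tp53, del17p, ctx)
#> <Match> catvar-tp53-cnloss vs del17p: MEMBER
#>   [1] SATISFIED    FEATURE_OVERLAP: overlaps TP53 [7668402,7687538)
#>   [2] SATISFIED    LOCATION_MATCH: [6000000,8000000) overlaps [7668402,7687538)
#>   [3] SATISFIED    CHANGE_MATCH: LOSS satisfies LOSS

snv <- molecular_variant("tp53_snv",
  allele(seq_location("GRCh38:chr17", 7675000, 7675001), "T"))
match_variant(tp53, snv, ctx)$overall
#> [1] FALSE
```

Entailment against a broader "any TP53 loss" category:

```r
broad <- categorical_variant("any-tp53-loss", "TP53 any loss", list(
  feature_context("TP53"), copy_change("LOSS")))
entails(tp53, broad, ctx)
#> <Entailment> ENTAILS
#>  b_constraint a_constraint     rule                             detail
#>             1            1 identity structurally identical constraints
#>             2            3 identity structurally identical constraints
```

And the planted "exon deletions" scenario, recovered exactly by the
brute-force oracle (five planted deletions, three inside the target
exon):

```r
u <- generate_exon_deletion_universe(seed = 9)
extension(u$planted$category, u, build_context(u))
#> [1] "del01" "del02" "del03"
```

## Command line

A thin wrapper over the same functions lives at `inst/cli/varcat.R`:

```sh
Rscript inst/cli/varcat.R validate  categories.json
Rscript inst/cli/varcat.R match     --categories c.json --vcf calls.vcf \
                                    --features genes.bed --reference ref.fasta
Rscript inst/cli/varcat.R entail    a.json b.json --features genes.bed
Rscript inst/cli/varcat.R generate  --out world/ --seed 13
Rscript inst/cli/varcat.R extension --category c.json --universe world/
```

Exit codes: 0 success, 1 data errors, 2 usage errors. In-progress
constraint kinds (functional consequence, adjacency) require
`--experimental`.

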