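# oncoannot

Tools for multi-faceted, sentence-level annotation of gene–cancer
relations, and for the analyses such a corpus supports.

A large share of what the literature knows about a gene's role in cancer
is reported as sentences like *"Cdc25B is frequently overexpressed in
human prostate cancer tissues"*. `oncoannot` represents each such mention
as an **annotation unit**: a sentence with character spans for the gene,
the expression-change keywords and the cancer terms, plus four concept
values —

| Concept | Meaning | Values |
|---|---|---|
| CGE | change in gene expression | `increased`, `decreased` |
| CCS | change in cell state | `normal->normal`, `normal->cancer`, `cancer->cancer`, `cancer->normal`, `unidentifiable` |
| IGE | initial gene expression level | `up-regulated`, `down-regulated`, `unchanged`, `unidentifiable` |
| PT | proposition type | `observation`, `causality` |

IGE and PT are skipped exactly when CCS is `unidentifiable`. On top of
this data model the package provides:

* **Rule-based gene classification.** Ten inference rules over
  (CGE, CCS, IGE, PT) assign each mention a class in
  {oncogene, tumor suppressor gene, biomarker}; no matching rule means
  *not related to cancer*. The table is also *derived* from first
  principles — enumerate all 80 value combinations, assign classes by the
  causal logic of the concepts (resolving unidentifiable IGE to the
  *weakest* implied relation), drop implausible combinations, and
  compress — and the derivation provably recreates the same ten rules
  (`derive_rule_table()`).
* **Corpus statistics.** Value distributions, pairwise contingency tables
  with expected counts and Pearson residuals ((O−E)/√E, whose squares sum
  to the χ² statistic), χ² independence tests, odds ratios, and a
  Cochran–Mantel–Haenszel test of conditional independence given CCS.
* **Inter-annotator agreement.** Simple agreement, Cohen's κ =
  (p₀−pₑ)/(1−pₑ), and the G-index (p₀−1/k)/(1−1/k) with k the
  *pre-specified* category count — robust to the heavily skewed label
  distributions these concepts produce — plus full/one/no-match scoring
  of rule-validation annotations with micro/macro agreement rates.
* **A synthetic corpus generator** whose default distributions are the
  published corpus frequencies, so every pipeline stage is testable
  without redistributing the original corpus.
* **Canonical JSONL/TSV corpus dialects** with strict validation, a
  bracket-markup renderer (`[*gene*]_g_ ... [*term*]_c_`), and a
  dictionary-based leftmost-longest cancer-term tagger.

## Worked example

```r
library(oncoannot)

s <- "Cdc25B is frequently overexpressed in human prostate cancer tissues"
u <- annotation_unit("u1", s,
  gene = span("Cdc25B", 0, 6),
  expression_keywords = list(span("overexpressed", 21, 34)),
  cancer_terms = list(span("prostate cancer", 44, 59)),
  cge = "increased", ccs = "normal->cancer",
  ige = "unchanged", pt = "observation", cancer_type = "prostate")
classify_unit(u)
#>   unit_id gene_class rule_id
#> 1      u1  biomarker       7
```

Increased expression accompanying cancer progression, with no causality
claimed, is biomarker evidence (rule 7). Corpus-level structure, from the
published pairwise CGE × CCS counts:

```r
O <- matrix(c(318, 79, 45, 76, 204, 99), nrow = 2,
            dimnames = list(c("increased", "decreased"),
                            c("normal->cancer", "cancer->normal",
                              "unidentifiable")))
ct <- contingency_table(O, "CGE", "CCS")
ct
#> <contingency_table CGE x CCS, n = 821>
#>           normal->cancer cancer->normal unidentifiable
#> increased 318 (2.65)     45 (-4.22)     204 (-0.36)
#> decreased 79 (-3.95)     76 (6.30)      99 (0.54)
chi_square_test(ct)
#> Pearson chi-square test of independence
#>   X-squared = 80.6, df = 2, p <2.2e-16
```

The parenthesized cells are Pearson residuals: increased expression is
strongly over-represented under `normal->cancer` (2.65) and decreased
expression under `cancer->normal` (6.30). A synthetic corpus drawn from
these frequencies reproduces the published gene-class shares:

```r
syn <- generate_corpus(default_generator_config(n_units = 821, seed = 1))
rule_distribution(syn)$class_percent[, "Total"]
#>           not_related             biomarker              oncogene
#>                    33                    44                    17
#> tumor_suppressor_gene
#>                     6
```

A thin command-line wrapper (`inst/cli/oncoannot`) exposes the same
functionality as `validate`, `classify`, `stats`, `agreement`, `simulate`
and `derive-rules` subcommands.

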