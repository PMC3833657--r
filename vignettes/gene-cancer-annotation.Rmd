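---
title: "Multi-faceted annotation of gene-cancer relations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-faceted annotation of gene-cancer relations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The annotation model

The unit of annotation is one *mention* of a gene expression change that
co-occurs with at least one cancer-related term in a sentence. The
sentence is the window of context; a sentence can therefore carry several
units. Each unit records character spans (0-based, half-open, in code
points) for the gene name, the expression-change keywords and the cancer
terms, and four concept values:

* **CGE** — direction of the expression change (`increased` /
  `decreased`). Always annotated.
* **CCS** — how the cell or tissue's cancerous properties change along
  with the expression change (`normal->cancer`, `cancer->normal`,
  `cancer->cancer`, `normal->normal`, `unidentifiable`).
* **IGE** — the gene's expression level *before* the change, relative to
  a normal cell (`up-regulated`, `down-regulated`, `unchanged`,
  `unidentifiable`).
* **PT** — whether causality between the expression change and the
  cell-state change is claimed (`causality`) or the two are merely
  co-reported (`observation`).

When CCS is `unidentifiable`, knowing IGE or PT adds nothing about the
gene-cancer relation, so both are *skipped*. The package keeps the skip
marker (`NA` in R, `null`/empty in the serialized dialects) strictly
distinct from the annotator judgment `unidentifiable`: conflating them
would corrupt every denominator that counts "units where the concept was
annotated". `validate_unit()` enforces the biconditional — IGE/PT are
`NA` *iff* CCS is `unidentifiable` — together with the span invariants.

The concept sets are deliberately abstract: they encode directions of
change, not the specific cancerous property altered, which is what makes
the same scheme applicable across cancer types.

## The inference rules and their derivation

Genes are classified per mention into `oncogene`, `tumor_suppressor_gene`
or `biomarker` by ten pattern rules over (CGE, CCS, IGE, PT); a mention
no rule matches is `not_related`. The classes are ordered by the strength
of the relation they assert:

    not_related < biomarker < oncogene = tumor_suppressor_gene

`builtin_rules()` is the operational table. `first_principles_class()`
re-derives the class of any tuple from the concepts' meaning alone:

* causality claimed across a cell-state change maps direction to class
  (`increased` driving `normal->cancer` is oncogenic; the three other
  direction/state combinations follow the same logic);
* under `observation`, causality can still be *deduced* when the initial
  level and the change are consistent with the gene driving the reversal
  (`up-regulated` + `decreased`, or `down-regulated` + `increased`);
* anything else crossing a cell-state change is biomarker evidence;
* `normal->normal`, `cancer->cancer` (apart from the two deduced-initial
  observations) and `unidentifiable` CCS carry no relation;
* an `unidentifiable` IGE resolves to the **weakest** class obtainable
  under the concrete IGE values — the least-committal reading of the
  sentence.

Two filters separate this assignment from the operational table. First,
`not_related` tuples produce no rule. Second, some class-bearing tuples
are essentially unreported in the literature and are tagged
`implausible_or_rare`; the package reconstructs this filter as: a
*concrete* IGE value combined with `cancer->normal` CCS, unless the
(IGE, CGE) pair is one of the two causality-deducing pairs. The
reconstruction is validated by exhaustive enumeration, not assumed:
`derive_rule_table()` enumerates all 2×5×4×2 = 80 tuples, applies the
filters, compresses the survivors into maximally wildcarded mutually
exclusive patterns (greedy, most-general-first, with an exclusivity
assertion), and the result is tuple-for-tuple equivalent to the built-in
table — same ten rules, same classes. The test suite checks this
equivalence, mutual exclusivity over all 80 tuples, and completeness on
the `normal->cancer` stratum.

Rule matching treats a multiple match as an internal assertion failure
rather than a tie-break, because exclusivity is provable for this table.
Classification is a pure function of the four values; everything else in
a unit (sentence, spans, cancer type) only feeds aggregation, where gene
identity is normalized by case-insensitive string equality — no lexicon
mapping is attempted.

One mention is one piece of evidence. `aggregate_evidence()` therefore
counts units per (gene, cancer type, class) instead of forcing a single
label per gene; deciding what several conflicting mentions mean is left
to the analyst.

## Statistics: conventions and numerical choices

* **Percentages** are rounded half up to integers
  (`round_half_up()`); this is the convention under which the reference
  distribution and rule-share tables reproduce exactly (e.g. biomarker
  43%, no-rule 37%, CGE-increased 69%).
* **Residuals** are Pearson residuals `(O − E)/√E`; their squares sum to
  the χ² statistic, and the test uses no continuity correction.
  (Adjusted/standardized residuals do not reproduce the reference cells
  2.65 and 6.30; plain Pearson residuals do.)
* **Odds ratios** are returned at full precision; the display convention
  that matches the reference values is one-decimal *truncation*
  (`truncate_decimal()`: 6.56 → 6.5, 7.87 → 7.8), not rounding. A 2×2
  with a zero denominator cell errors unless the Haldane–Anscombe +0.5
  correction is explicitly requested. Where a concept value's column is
  too sparse for a finite ratio (e.g. an IGE level observed 0 and 2
  times), the ratio is taken over the two well-populated columns.
* **p-values** below 2.2e-16 display as `<2.2e-16`
  (`format_p_value()`); the raw value is preserved.
* Contingency tables drop all-zero rows/columns (concept values never
  observed, such as `normal->normal`) before testing, and tables
  involving IGE or PT are restricted to units with identifiable CCS —
  the only units where those concepts exist.
* **Conditional independence** given CCS is tested with a
  Cochran–Mantel–Haenszel pooled test (`stats::mantelhaen.test`, no
  correction) across CCS strata; strata with a zero margin are dropped
  with a warning and counted in the result. CMH is one reasonable
  reconstruction of "independence conditioned on CCS"; the package
  documents it as such rather than claiming it reproduces any particular
  published p-value, which would require the raw per-unit data.

## Agreement metrics

Simple agreement is the proportion of agreed units. Cohen's κ uses the
empirical product-of-marginals chance term and is returned as `NA`
("N/A") when both annotators use a single category, where it is
undefined — the typical situation for IGE, whose distribution is
extremely skewed. The G-index replaces the chance term by `1/k` with `k`
the **pre-specified** category count of the concept (CGE 2, CCS 5, IGE
4, PT 2), *not* the number of categories observed in the sample; this is
the choice under which the reference agreement table reproduces (raw
agreement 0.98 on IGE gives G = 0.97 with k = 4).

Rule validation compares the engine's class against two independent
human classifications per unit: `full` (both agree), `one`, `none`. The
per-row agreement rate is `(full + one)/total`; empty rows report
`"n/a"`. The micro-average pools counts over all populated rows; the
macro-average is the unweighted mean of the defined per-row rates and
**includes** the no-rule row — with that convention the reference counts
yield micro 95% and macro 89% (integer rounding).

## The synthetic corpus generator

The generator exists so that the rule engine, the statistics and the
agreement metrics can be exercised end-to-end without redistributing the
original corpus. Its default configuration
(`default_generator_config()`) *is* the published empirical structure:

* cancer-type proportions 310/255/256 over 821 units;
* the CGE × CCS joint from the pairwise counts (318, 45, 204 / 79, 76,
  99), which also fixes the CGE margin (567/821 ≈ 0.691) and the CCS
  margin (397/121/303);
* IGE | CCS and PT | CCS from the corresponding pairwise tables, with
  IGE/PT forced to the skip marker under `unidentifiable` CCS.

IGE and PT are sampled **conditionally independent given CCS**. That is
a modelling choice, but one the data supports: the remaining pairwise
association given CCS is weak, and the choice reproduces the rule-share
structure — rule 7 fires iff CCS is `normal->cancer` and PT is
`observation`, so its expected share is 311/821 ≈ 0.379, which a
10,000-unit corpus recovers within sampling error (checked at ±0.02).
Where per-cancer-type joints are not published, the pooled joint is
reused for every type, scaled by the type proportions.

Sentence realization draws from a small template pool
(`"{GENE} is frequently {KW} in human {CANCER} tissues"`, ...) with
direction-appropriate keywords and type-appropriate cancer terms; the
offsets of every span are exact by construction. This emulates the
*structure* of real data, not its language: templates contain no
negation, hedging, coordination or multi-unit sentences, so passing
tests demonstrate correctness of the data model, rule engine and
statistics on well-formed annotations — they say nothing about
annotating real prose, which is a human task outside this package's
scope.

Randomness is a single seed split into fixed substreams (concept values;
sentence realization offset by a constant; perturbation seeded
separately), so adding a feature to one stage does not shift the draws
of another; identical `(config, seed)` yields a byte-identical serialized
corpus. `perturb_annotations()` simulates a second annotator by
replacing each value, with a per-concept flip probability, by a
uniformly random *different* admissible value (skipped concepts stay
skipped), so expected simple agreement is exactly 1 − f. Default flip
rates (0.01/0.21/0.02/0.14) mirror one minus the overall per-concept
simple agreement of the reference dual annotation.

## Problem sizes and degenerate inputs

The test suite uses 10,000-unit corpora for marginal-recovery checks
(3σ binomial bounds), 60 replicates of 600-unit corpora for the CMH
type-I-error calibration, and exhaustive enumeration (80 tuples)
wherever the space is finite — chosen to make sampling error negligible
relative to the asserted tolerances while keeping the suite fast.
Degenerate inputs are defined behavior, not crashes: empty corpora parse
and serialize to zero units; empty pair sets, empty contingency tables
after filtering and zero marginals raise errors naming the offending
label; a flip rate of 1 on a binary concept yields agreement exactly 0.

## Known limitations

* The canonical JSONL/TSV dialects are this package's own; no adapter to
  any pre-existing distribution format is provided.
* Gene normalization is string-based; synonyms ("Cdc25B" vs "CDC25B" is
  handled, "p53" vs "TP53" is not).
* The implausible-or-rare filter is a reconstruction validated by
  equivalence with the operational rule table, not an independently
  documented biological criterion.
* Agreement metrics cover exactly two annotators; no weighted κ.
* The generator's language model is a template pool; do not use it to
  benchmark NLP components.
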