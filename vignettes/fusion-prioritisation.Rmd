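---
title: "Prioritising oncogenic gene fusions from tumour RNA-seq cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritising oncogenic gene fusions from tumour RNA-seq cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionprio)
```

## The problem

Fusion callers applied to bulk tumour RNA-seq emit thousands of candidate
chimeric transcripts per cohort, most of which are read-through transcripts
between neighbouring genes, library artefacts, or chimeras also present in
normal tissue. `fusionprio` implements the downstream prioritisation that
turns those raw call tables into a short, audited list of candidate
oncogenic fusions, together with the cohort-level statistics usually
reported alongside such a list (driver-mutation mutual exclusivity,
clinicopathological associations, survival). The package starts at the
call-table level: read alignment and primary fusion discovery are upstream
of its scope.

## The filter cascade

A call survives screening when all four of the following hold (each filter
can be disabled; all four flags are always recorded so the audit trail is
complete):

1. **In frame.** The junction preserves the codon reading frame (next
   section). Out-of-frame fusions cannot produce a single chimeric protein.
2. **Absent in normal tissue.** No normal-sample call involves the same
   ordered (donor, acceptor) gene pair. Matching is at the gene-pair level
   rather than breakpoint-exact because breakpoints jitter by tens of bases
   between samples and callers, which would otherwise defeat the filter;
   orientation sensitivity is configurable.
3. **Junction-spanning reads ≥ 10.** Direct read evidence for the junction.
4. **Breakpoint separation ≥ 100 kb** for intrachromosomal calls. Short
   separations are the signature of transcriptional read-through between
   neighbouring genes. Interchromosomal calls bypass this filter — it
   exists to catch read-throughs, which are by nature intrachromosomal.

Both numeric thresholds are inclusive (a separation of exactly 100,000 bp
passes), reading the "at least" convention literally; both are
configurable in `screen_config()`. Filters are evaluated independently
rather than short-circuited, so the survivor set provably does not depend
on filter order, and every rejected call carries the complete list of
filters it failed.

## Junction phases and the reading-frame model

Genomic breakpoints are converted to coding-sequence offsets through
transcript models (exon structure plus CDS bounds, read from GTF). The
conventions, which matter and are therefore stated explicitly:

* coordinates are 1-based inclusive; the donor breakpoint is the **last
  retained base** of the donor, the acceptor breakpoint the **first
  retained base** of the acceptor;
* the **donor phase** is (retained donor coding bases) mod 3; the
  **acceptor phase** is (discarded acceptor 5′ coding bases) mod 3;
* the fusion is **in frame** iff the phases are equal — exactly the
  condition for downstream acceptor codons to be translated in their
  native frame. A label such as `2->0` reads (donor phase → acceptor
  phase).

Breakpoints outside the CDS are classified, not errored: a donor breakpoint
in the 5′ UTR contributes no coding sequence and is flagged
`promoter_swap` (in frame only when the acceptor phase is 0); a donor
breakpoint past the CDS retains the complete donor ORF
(`donor_cds_complete`); intronic or out-of-transcript breakpoints leave the
phase undefined and the fusion not-in-frame, with the reason recorded.

This arithmetic is verified two independent ways in the test suite: against
hand-counted offsets on toy transcripts, and against a brute-force
translation oracle — for a thousand random toy fusions the concatenated
coding sequence is translated with `Biostrings` and the fusion is declared
frame-preserving iff the native acceptor protein tail survives intact in
the fusion protein. The phase arithmetic and the oracle have never
disagreed; the suite asserts zero disagreements.

### Protein segments and domain retention

When the fusion is in frame, the donor contributes its complete codons
(`floor(retained_nt / 3)` amino acids) and the acceptor the remainder, so
the (possibly chimeric) junction codon is attributed to the acceptor side
and segment lengths add up to the fusion protein length exactly. Each
annotated domain of a partner protein is then **retained** (entirely inside
the retained segment), **lost**, or **truncated** with its retained
fraction. A 325-aa region of which 293 aa survive is truncated at fraction
293/325 ≈ 0.90; a 253-aa region retaining 179 aa at 179/253 ≈ 0.71 — the
two canonical tumour-suppressor truncation patterns this analysis is built
to flag.

## Consensus across callers

Calls from the same sample with the same ordered gene pair merge into one
consensus group when both breakpoints agree within a tolerance (default
50 bp, sized for sub-exon jitter between algorithms; matching across
callers is effectively at the gene-pair level). Groups are connected
components under transitive closure, making the grouping order-independent;
at tolerance 0 it degenerates to exact matching, and smaller tolerances
always refine larger ones. Cross-validation keeps groups supported by at
least `min_support` distinct callers — 2 of 3 by default, the conventional
"called by the discovery tool and confirmed by at least one independent
algorithm" rule.

## Expression outliers

The outlier criterion is deliberately conventional, because "outlier
analysis" in cohort reports rarely comes with a formula: a carrier is
flagged for a gene when its FPKM exceeds the Tukey upper fence
(Q3 + 1.5 × IQR) over the tumour samples. A z-score variant (cut 3) and a
log2(FPKM + 1) transform are provided but off by default — cohort FPKM
strip plots are conventionally read on the linear scale. Both criteria are
scale-invariant, so the flags do not depend on normalisation constants.

## The oncogenicity rule

A validated fusion is called oncogenic when any clause fires (disjunctive
by default, conjunctive available), and every verdict carries its reason
codes:

* `outlier_expression` — the carrier over-expresses donor or acceptor;
* `kinase_partner` / `oncogene_partner` — a partner gene is annotated
  kinase / oncogene;
* `suppressor_truncation` — a tumour-suppressor partner loses function in
  the product: any of its domains is lost, or truncated below a retained
  fraction of 0.9. The threshold is 0.9 rather than something smaller
  because a suppressor region can retain ~90% of its length and still be
  functionally dead when its downstream domains are lost entirely — which
  is why the `lost` clause fires independently of the fraction.

The disjunctive combination is this package's formalisation of the usual
prose ("by expression and function"); it is a declared, tested, tunable
rule, not a reconstruction of any particular study's unstated boolean.

## Somatic variants and mutual exclusivity

The variant hard-filter cascade (all thresholds in `snv_filter_config()`,
inclusive on the passing side): total depth ≥ 10, alt reads ≥ 2, allele
fraction ≥ 3%, exonic, consequential effect class (frameshift,
non-synonymous, stop-gain, stop-loss), population MAF ≤ 1% (absence from
the population catalogue passes), Fisher-strand ≤ 30 **and** qual-by-depth
≥ 2, and exclusion of sites seen in matched normals. The FS/QD rule is
implemented in the standard hard-filter direction — a variant with FS > 30
or QD < 2 is removed — since retaining such variants would invert accepted
practice. Each removed variant is attributed to the first filter it fails;
variants missing a needed field are set aside as unevaluable, never
silently dropped, so input = survivors + removals + unevaluable always.

Mutual exclusivity between fusions and oncogene mutations is tested by
label permutation: the statistic is the number of fusion-positive patients
with at least one oncogene-panel mutation, small values indicate
exclusivity, and the one-sided p-value is the add-one-smoothed fraction of
fusion-label permutations with a statistic at most the observed one.
Permuting labels preserves the mutation matrix exactly. **Known
limitation:** on a discrete statistic this p-value is conservative by
construction — its exact type-I error at α = 0.05 is ≈ 0.027 (computed
analytically) for cohorts of ~100 patients with ~15 carriers, never above
α. The test suite states the calibration band it targets and reports the
measured rate; the protective property (no anti-conservatism) always holds.

## Clinical statistics

Categorical covariates are collapsed to conventional reporting groups
(histology: well+moderately vs poorly+mucinous; depth: T1+T2 vs T3+T4;
microsatellite status: MSS+MSI-L vs MSI-H) before testing. `auto` mode
applies Fisher's exact test when any expected cell is below 5 and the
Pearson chi-square otherwise; which test produced a given published p is
usually unstated, so printed p-values are treated as significance-class
evidence rather than bit-exact targets — the suite verifies the exact-test
p against an exhaustive hypergeometric enumeration instead. Continuous
covariates use the two-sample t test (Student's by default, Welch
optional) with group means ± SE. Survival uses Kaplan–Meier estimates, the
log-rank test, and the restricted mean survival time ± SE (horizon = the
largest observed time) to mirror the "mean months ± SE" reporting
convention; mean rather than median because follow-up in such cohorts
often leaves the median undefined in one group.

## The synthetic cohort generator

`generate(sim_config())` draws a complete input bundle with the statistical
structure every stage assumes. The defaults are the study conditions the
package is tested under, chosen once:

| parameter | default | what it emulates |
|---|---|---|
| `n_patients` / `n_normals` | 147 / 47 | cohort size with matched normals |
| `n_true_fusions` / `n_fusion_patients` | 25 / 19 | genuine events over carriers |
| `caller_sensitivity` | 1.0, 0.9, 0.9 | primary discovery + two cross-validators |
| `breakpoint_jitter_sd` | 10 bp | cross-caller breakpoint disagreement |
| `artifact_rate` | 1.5 / sample | read-throughs between genes < 100 kb apart |
| `n_normal_chimeras` | 3 | chimeras also expressed in normal tissue |
| `frac_in_frame` | 0.7 | in-frame fraction among genuine fusions |
| `spanning_mu`, `spanning_size` | 30, 5 | negative-binomial junction reads |
| `outlier_multiplier` | 10 | carrier FPKM as multiple of cohort median |
| `exclusivity_strength` vs background | 0.05 vs 0.40 | fusion/oncogene exclusivity |
| `msi_enrichment` | 3.5 (odds) | MSI-H enrichment among carriers |
| `surv_rate`, `fusion_hr` | 0.01/month, 1.0 | exponential survival, no fusion effect |

The toy genome is ~20 chromosomes of a few Mb carrying 60 multi-exon coding
genes; breakpoints are planted inside CDS exons with the acceptor offset
drawn in the residue class that realises the configured in-frame fraction,
so planted phases are exact by construction and the pipeline must recover
them from coordinates alone. Caller noise is independent Bernoulli
detection plus rounded Gaussian jitter — the simplest model that exercises
the 2-of-3 logic. Roughly 30% of intergenic gaps are drawn below 100 kb so
the distance filter has genuine read-through work to do.

The manifest records every planted truth (per-event filter outcomes,
caller support, outlier flags, oncogenicity labels; per-patient carrier,
mutation and MSI status), and `ground_truth_compare()` scores pipeline
output against it stage by stage. In the noise-free limit — no artifacts
or normal chimeras, unit caller sensitivity, zero jitter and zero
expression spread (`expr_sdlog = 0`) — recovery is exact at every stage;
with any expression spread the Tukey fence has an irreducible false-flag
rate, which is a property of outlier analysis itself, not of the
implementation.

What the generator does **not** emulate, and hence what passing tests do
not show about real data: read-level errors and mapping ambiguity,
paralog-driven false calls, isoform diversity (one transcript per gene;
with several, the longest CDS represents the gene — real analyses must
choose and say so), correlated caller errors, copy-number-driven
expression, and cohort substructure beyond the planted MSI association.

## Problem sizes and numerical choices

The shipped tests run the property suites at reduced scale so the whole
suite stays fast: 100 generated cohorts of 30 patients for the
filter-cascade properties, 1,000 null cohorts of 100 patients at 1,000
permutations for calibration, 1,000 random toy fusions for the translation
oracle, and 10 default-scale cohorts (147 patients) for recovery. Ties in
representative-transcript selection break alphabetically; quantiles use
R's default type 7; all randomness flows from explicit seeds, and a bundle
is byte-reproducible from its seed.

## Known limitations

* The exclusivity p-value is conservative (see above); with very few
  carriers the add-one smoothing floors it at 1/(n_perm + 1).
* The oncogenicity rule is a declared convention; on real cohorts its
  clause set and threshold should be reported alongside results.
* Gene symbols are the join key across all tables; symbol drift between
  annotation releases is the caller's responsibility.
* The Tukey fence assumes a unimodal cohort distribution per gene;
  strongly bimodal expression (e.g. subtype-specific genes) will flag
  subtype members rather than true outliers.
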