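# fusionprio

Prioritisation of candidate gene fusions from bulk tumour RNA-seq cohorts.

Fusion callers emit thousands of candidate chimeric transcripts per cohort;
nearly all are read-through transcripts between neighbouring genes, library
artefacts, or chimeras also present in normal tissue. `fusionprio` is for
cancer-genomics analysts who have per-caller fusion-call tables (plus
transcript models, expression, somatic variants and clinical data) and need
the downstream analysis: an audited filter cascade, multi-caller consensus,
fusion-protein reconstruction, an oncogenicity classification with reason
codes, a driver-mutation mutual-exclusivity test, and the standard
clinicopathological statistics.

## The model in brief

**Screening.** A call survives when it is in frame, absent from
normal-sample calls (ordered gene-pair matching), supported by ≥ 10
junction-spanning reads, and — if intrachromosomal — its breakpoints are
≥ 100 kb apart (read-through exclusion; interchromosomal calls bypass this
filter). All four flags are recorded for every call; the survivor set is
independent of filter order.

**Reading frame.** With the donor breakpoint as the last retained base and
the acceptor breakpoint as the first, the junction phases are

    donor_phase    = (retained donor coding bases)      mod 3
    acceptor_phase = (discarded acceptor 5' coding bases) mod 3

and the fusion is in frame iff the phases are equal (a `2->0` label reads
donor phase → acceptor phase). Domain retention on each native protein is
scored as retained / truncated (with retained fraction) / lost — e.g.
293 aa surviving of a 325-aa suppressor region is truncated at fraction
293/325 ≈ 0.90.

**Consensus.** Calls from the same sample and ordered gene pair merge when
both breakpoints agree within 50 bp (transitive closure); groups supported
by ≥ 2 of 3 callers are validated.

**Oncogenicity.** A validated fusion is oncogenic when the carrier is an
expression outlier for a partner gene (Tukey upper fence over the tumour
cohort), a partner is an annotated kinase or oncogene, or a
tumour-suppressor partner loses domains (or is truncated below 0.9 retained
fraction). Every verdict carries its reason codes.

**Exclusivity.** The number of fusion-positive patients with ≥ 1
oncogene-panel mutation is compared against fusion-label permutations
(one-sided, add-one smoothed). Clinical covariates use Fisher/chi-square
(`auto` picks the exact test when an expected cell < 5), Student's t, and
Kaplan–Meier + log-rank with restricted-mean survival ± SE.

A synthetic-cohort generator (`generate(sim_config())`) plants all of this
structure — 147 tumours / 47 normals, 25 fusions over 19 carriers, caller
jitter, read-through artifacts, carrier expression outliers at 10× median,
mutation exclusivity, an MSI-H association — with a ground-truth manifest,
so the whole pipeline is testable end to end without patient data.

## Worked example

```r
library(fusionprio)

bundle <- generate(sim_config(seed = 7))              # synthetic cohort
run <- run_all(bundle, n_perm = 10000, seed = 7)
print(run)
#> <fusion_run>
#>             stage   n
#>       input_calls 236
#>  screen_survivors  16
#>   cross_validated  16
#>         oncogenic  11
#> exclusivity p = 0.0036; log-rank p = 0.897
```

236 primary-caller calls (genuine fusions plus read-throughs and
normal-tissue chimeras) funnel to 16 screened and cross-validated fusions,
11 of which are called oncogenic. The exclusivity p of 0.0036 reflects the
planted structure — none of the 14 fusion-positive patients carries an
oncogene mutation while 48 of 147 patients do — and the log-rank p of 0.897
reflects the planted hazard ratio of 1.

```r
head(report_fusion_table(run)[, c("donor_gene", "acceptor_gene",
       "in_frame_shift", "mid_distance", "support", "high_expression",
       "oncogenic")], 5)
#>   donor_gene acceptor_gene in_frame_shift mid_distance support
#> 1       G008          G009           1->1       570489       3
#> 2       G011          G016           2->2      1578734       3
#> 3       G014          G012           1->1       492282       3
#> 4       G019          G026           1->1      1844609       3
#> 5       G021          G028           0->0      1535807       3
#>      high_expression oncogenic
#> 1                        FALSE
#> 2 Donor and acceptor      TRUE
#> 3                         TRUE
#> 4 Donor and acceptor      TRUE
#> 5           Acceptor      TRUE

ground_truth_compare(run, bundle$manifest)
#>          stage tp fp fn sensitivity precision
#> 1    screening 16  0  0           1         1
#> 2    consensus 16  0  0           1         1
#> 3 oncogenicity 11  0  0           1         1
```

Every planted truth is recovered at this seed: the screen keeps exactly the
calls that should survive, consensus validates exactly the multi-caller
events, and the 11 oncogenic verdicts match the planted labels.

Single operations work standalone, e.g. the breakpoint separation of a
published STRN–ALK call:

```r
compute_mid_distance("chr2", 29446394, "chr2", 37143221)
#> [1] 7696827
```

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/run_pipeline.R simulate --seed 1 --dir bundle/
Rscript inst/scripts/run_pipeline.R run-all --dir bundle/ --out reports/
```

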