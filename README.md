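# svensemble

Ensemble merging and benchmarking of structural variant (SV) call sets
from short-read sequencing.

No single short-read SV caller detects all types and sizes of structural
variants well: split-read, read-pair and assembly-based tools each have
blind spots, and their outputs disagree in both content and format. A
common response is to run a panel of callers and combine their calls —
either demanding agreement between tools (higher precision) or taking the
union (higher recall). svensemble implements that workflow end to end for
the two SV types curated truth sets actually benchmark, deletions (DEL)
and insertions (INS):

1. **Refine** each caller's VCF: annotate SV type and length (from INFO
   keys, symbolic ALTs, sequence-resolved alleles, or breakend
   orientation), drop calls under 50 bp, collapse paired start/end records
   of the same SV onto the start record, keep only `FILTER == PASS`, and
   tag every call with its caller.
2. **Merge** the pooled panel into *neighbor groups*: calls on one contig
   with the same `SVTYPE` whose start positions lie within ±500 bp of the
   group's smallest-position member (the *representative*). A group's
   representative is emitted under the **union** strategy always, and
   under the **multiple-agreement** strategy only when ≥ 2 distinct
   callers support the group. A **direct-merge** mode concatenates
   refined call sets without grouping, for comparison.
3. **Benchmark** any call set against a truth set: a truth variant is a
   true positive (TP) if a same-type test call starts within ±500 bp;
   matching is one-to-one, greedily by distance. Then

   precision = TP / (TP + FP),  recall = TP / (TP + FN),
   F1 = 2·P·R / (P + R),

   with FP = |test| − TP and FN = |truth| − TP. Across several datasets
   the combined scores cPr, cRc, cF1 are micro-averages: the same
   formulas applied to the summed TP/FP/FN.

Because the original genome-scale inputs (multi-caller VCFs for GIAB and
HGSVC2 genomes) are large and external, the package includes a call-set
**simulator**: it generates truth sets with the benchmark-like structure
(DEL/INS, sizes 50 bp–10 kb, inter-variant spacing > 1 kb) and per-caller
call sets with configurable recall, Poisson false-positive load,
breakpoint jitter, and caller output dialects (paired breakend records,
sub-50 bp calls, non-PASS records), so the whole pipeline runs and is
testable offline.

## Worked example

Simulate a three-caller study, refine each caller's VCF, build the union
and multiple-agreement ensembles, and score everything against the truth:

```r
library(svensemble)
library(dplyr)

cfg <- sim_config(n_truth = c(DEL = 500, INS = 500), seed = 11)
sim <- simulate_study(cfg, default_caller_profiles()[c("Manta", "DELLY", "GRIDSS")],
                      "demo")

refined <- sapply(c("Manta", "DELLY", "GRIDSS"), function(nm)
  refine_vcf(file.path("demo", paste0(nm, ".vcf")), nm), simplify = FALSE)

union     <- merge_callsets(refined, panel = "III", strategy = "union")
agreement <- merge_callsets(refined, panel = "III", strategy = "multiple_agreement")

bench <- benchmark_callsets(
  c(refined, list(`III-union` = union, `III-agreement` = agreement)),
  sim$truth, dataset = "demo"
)
tidy(bench) |>
  filter(svtype == "DEL") |>
  mutate(across(c(precision, recall, f1), ~ round_half_up(.x, 2)))
#> # A tibble: 5 × 10
#>   dataset callset       svtype total    tp    fp    fn precision recall    f1
#>   <chr>   <chr>         <chr>  <int> <int> <int> <int>     <dbl>  <dbl> <dbl>
#> 1 demo    Manta         DEL      612   278   334   222      0.45   0.56  0.5
#> 2 demo    DELLY         DEL      801   251   550   249      0.31   0.5   0.39
#> 3 demo    GRIDSS        DEL      336   205   131   295      0.61   0.41  0.49
#> 4 demo    III-union     DEL     1454   442  1012    58      0.3    0.88  0.45
#> 5 demo    III-agreement DEL      244   242     2   258      0.99   0.48  0.65
```

The single callers recover roughly their configured recalls (0.55, 0.48,
0.42). The union ensemble finds 442 of 500 true deletions (recall 0.88,
more than any member) at the cost of pooling every member's false
positives, while multiple agreement keeps almost no false positives
(precision 0.99) but only the deletions at least two callers saw. That
precision/recall trade-off between the two strategies is the central
behavior the package reproduces and tests.

`glance(bench)` micro-averages counts across datasets, and
`autoplot(bench)` draws the per-call-set metric bars. `sv_run_all()` runs
the whole simulate → refine → merge → benchmark loop over several
datasets and writes every table (metrics per dataset, combined metrics,
concordance counts per caller subset, neighbor-group distances) under one
output directory, deterministically for a given seed.

A published benchmark's TP/FP/FN count tables for six callers on HG002
and three HGSVC2 genomes ship as a fixture
(`published_benchmark_counts()`); `reproduce_metric_tables()` recomputes
all precision/recall/F1 columns from those counts alone ("counts-only
mode"), which the test suite uses as an exact regression oracle for the
metric formulas.

A thin command-line wrapper over the same functions is installed at
`inst/cli/svensemble.R` with subcommands `refine`, `merge`, `bench`,
`simulate`, `tables` and `run-all`.

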