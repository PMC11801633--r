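---
title: "Multi-caller SV merging and benchmarking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-caller SV merging and benchmarking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svensemble)
library(dplyr)
```

This vignette explains the model behind the package: how raw caller VCFs
are refined into comparable call sets, how calls from a caller panel are
merged, how merged and single call sets are scored against truth sets,
what the simulator does and does not emulate, and the numerical and
design choices made where the procedure was genuinely open.

## Refinement

Short-read SV callers emit VCFs in incompatible dialects. Refinement
normalizes them in four ordered steps; the order matters and is fixed
(annotate → size filter → dedup → PASS filter), so that, for example, the
size filter sees annotated lengths and the PASS filter counts only
records that survived deduplication.

**1. Annotation.** Each record's SV type is resolved in priority order:
the INFO `SVTYPE` key when it is a recognized type; otherwise the
symbolic ALT token (`<DEL>`, `<DUP:TANDEM>`, ...); otherwise the net
REF/ALT length difference for sequence-resolved alleles (gain = INS,
loss = DEL). Breakend (`BND`) records are classified from the junction
orientation in the ALT allele. For a same-contig mate pair at positions
$p_1 < p_2$, the record at $p_1$ reads:

| ALT at $p_1$ | junction | classified as |
|---|---|---|
| `t[p2[` | right side of $p_1$ joins right of $p_2$ | DEL |
| `]p2]t` | left side joins left | DUP |
| `t]p2]`, `[p2[t` | matching sides | INV |

with the mirrored forms at $p_2$ classified identically, so both mates of
a pair agree. A mate on a different contig is a translocation (CTX).
Lengths are $|\mathrm{SVLEN}|$ when present, else $\mathrm{END} -
\mathrm{POS}$ (mate distance for breakends), else the REF/ALT length
difference. Translocations have no length; a symbolic `<INS>` without
`SVLEN` has unknown length. Records that cannot be classified (no type,
equal-length REF/ALT, no parseable mate) are dropped with a warning
counter rather than an error, because real caller output reliably
contains a few exotic records.

**2. Size exclusion.** Calls with length < 50 bp are removed — the
conventional lower bound of "structural" variation, and the lower bound
of the truth sets this pipeline targets. Records whose length is
*unknown* (CTX; symbolic INS without `SVLEN`) are kept: unknown is not
known-small, and silently discarding them would delete true calls from
callers that do not report insertion lengths.

**3. Paired-record deduplication.** Several callers report both junction
sides of one SV as two linked records. Links are recognized by `MATEID`,
by a shared `EVENT`, or by complementary `_1`/`_2` ID suffixes. For each
linked set on one contig the record with the smallest position survives
(the end-position record is removed); for inter-contig pairs the record
on the earlier contig in the VCF-header contig order (falling back to
natural sort) survives, which is deterministic and reference-agnostic. A
`MATEID` that points to a missing record leaves the survivor in place
with a warning. One guard goes beyond the bare suffix rule: an ID-stem
link is honored only when it forms an unambiguous pair — exactly two
records, suffixes `_1` and `_2`, same SV type. Without that guard,
unrelated records whose IDs merely share a prefix (sequentially numbered
IDs are common) would be collapsed, and refinement would not round-trip
its own output.

**4. PASS filtering.** Only records whose FILTER is exactly `PASS` are
kept. A missing filter (`.`) is *not* PASS: fidelity to the stated rule
over leniency, since `.` means the caller asserted nothing about the
call.

Finally every record is tagged with its caller label, serialized as the
INFO key `caller=` on output. Refinement is idempotent — re-refining a
refined VCF removes nothing — and every step reports its removal count,
which `refine_vcf()` writes as a per-step TSV.

## Neighbor groups and combination strategies

Refined call sets from a panel are pooled and clustered per (contig,
SVTYPE). The window is ±500 bp on start positions, half of the 1000 bp
spacing that curated truth sets enforce between distinct variants, so
that under that spacing a window can contain calls for at most one truth
variant.

Grouping is an **anchored sweep**, not transitive single-linkage: records
are sorted by position (ties broken by caller label then record ID, so
the result is independent of input order), the first record opens a group
and becomes its representative, and each subsequent record joins the open
group iff it lies within the window *of the representative*, else it
opens a new group. The published description of the procedure does not
say whether chaining is anchored or transitive; the anchored reading is
adopted because it is the only one under which the stated invariant —
every within-group distance lies in 0–500 bp — is guaranteed (transitive
chains can grow without bound). This is an interpretation, and it is
checked in the test suite against an independent re-scan oracle.

Records from the *same* caller may share a group: nothing in the
procedure forbids within-caller proximity, pooling without per-caller
exclusion is the simplest consistent reading, and the group-size tables
surface any effect. The group representative (smallest position) is the
emitted merged call; no breakpoint averaging is performed. Three
strategies turn groups into a merged call set:

* **multiple agreement** — representatives of groups with ≥ 2 distinct
  supporting callers (`min_support` configurable, only ≥ 2 validated);
* **union** — every group's representative;
* **direct merge** — all pooled refined records, unmerged (a comparison
  baseline; duplicates inflate the FP count by construction).

Merged records carry `caller=` (comma-joined supporting labels), `SUPP`
(distinct caller count) and `GROUP_SIZE` on output, so downstream
evaluation can stratify. Per-subset concordance counts (the Venn-diagram
numbers) and group member-to-representative distance summaries are
emitted alongside.

## Evaluation

Evaluation treats DEL and INS separately and never pools them, matching
what SV truth sets actually curate. A candidate match is a (truth, test)
pair on the same contig, same type, with start positions within ±500 bp
*inclusive*. Assignment is one-to-one and greedy by increasing distance
(ties by truth then test position). One-to-one is forced by the
arithmetic of the confusion counts: FP = |test| − TP and FN = |truth| −
TP are only simultaneously consistent if each truth and each test call is
consumed at most once. Greedy-by-distance is deterministic; on instances
where each variant has at most two candidates (guaranteed when truth
spacing exceeds twice the window, as in the simulator's defaults) it
attains the maximum matching, and on arbitrary instances it is a lower
bound — both properties are tested against a brute-force maximum-matching
oracle. SV length plays no role in matching, and contigs must agree.

Division by zero is defined as zero throughout (an empty call set scores
precision = recall = F1 = 0 rather than erroring). Reports carry
full-precision metrics plus 2-decimal display values rounded half *up*
(`round_half_up()`), the convention of the benchmark tables this package
regresses against; R's default half-to-even would differ on exact halves
such as 0.625. Micro-averaged combined metrics across datasets are the
same formulas applied to summed counts; a single dataset reproduces the
per-dataset metrics exactly, and the combined recall/precision always
lies between the per-dataset extremes.

Optional confident-region restriction (`restrict_to_regions()`) keeps
records whose start position falls in a BED interval (0-based,
half-open). It is off by default: the evaluation matches the truth set as
given unless the user opts in.

## The simulator

The simulator generates what the analysis needs and nothing more: call
*sets*, not reads or alignments. A truth set has a configurable number of
DEL and INS variants; positions are uniform per contig under a minimum
spacing constraint (default 1001 bp, adopting the curated-benchmark rule
that supported variants within 1000 bp of each other are excluded as
potentially complex), drawn by the order-statistics construction (uniform
draws on a shrunken interval plus cumulative spacing offsets) so
rejection is never needed; sizes are log-uniform on 50 bp–10 kb, the
range where benchmark SVs predominantly fall.

Each caller profile specifies per-type recall, a Poisson false-positive
load, breakpoint jitter, and dialect quirks. Design choices worth
stating:

* **Jitter** is a discretized double-geometric offset (random sign,
  geometric magnitude with mean `jitter` bp) — mostly near zero with
  occasional larger offsets, reproducing the small median
  neighbor-distances (a few bp) with heavier tails than a uniform offset
  would give. Magnitudes are clamped at 500 bp so a detected call always
  stays inside the matching window of its truth variant.
* **False positives are placed more than 1000 bp (window + maximum
  jitter) from every truth variant** and independently per caller. This
  makes recall and FP recovery exact (a detected call always matches, an
  FP never does), and makes the expected FP survival under multiple
  agreement ≈ 0, so the union-vs-agreement precision/recall trade-off is
  reproducible in silico. The positional distribution of real FPs is not
  modeled — no quantitative description of it was available — so FP
  placement is a modeling choice, not an estimate.
* **Dialect noise** (sub-50 bp records, non-PASS `q5` records, paired
  breakend emission) exists to exercise the refinement stage; the extra
  records are also placed far from truth so they cannot perturb the
  recovery properties above.
* The **default profiles** approximate the DEL/INS recalls observed for
  five widely used callers on a well-characterized benchmark genome
  (DEL recalls 0.55 / 0.48 / 0.42 / 0.12 / 0.28; two profiles detect no
  insertions ≥ 50 bp, and one emits many sub-50 bp records), with FP
  loads scaled to the default 2000-variant truth sets so each profile's
  precision lands in its namesake's observed range. Profiles are
  configuration, not code.

What the simulator does *not* emulate — and therefore what passing tests
do not show about real data: correlated errors between callers (real
callers share alignment artifacts, so their FPs are not independent),
genotype information, sequence context, size-dependent recall, and
breakpoint uncertainty beyond symmetric jitter. Conclusions about the
*ranking* of strategies on real genomes rest on the published count
tables shipped as a fixture, not on the simulation.

## Determinism and numerical conventions

All randomness flows from integer seeds through `withr::with_seed`;
derived seeds (per dataset, per caller) are deterministic functions of
the master seed kept below 2^31. A full `sv_run_all()` with a fixed seed
produces byte-identical TSV and JSON outputs across runs, which the test
suite asserts. Quartiles (length summaries, group-distance IQRs) use R's
default type-7 convention; medians of even-sized sets are the mean of the
two central values. Coordinates are VCF-convention 1-based with inclusive
`END`; BED input is 0-based half-open; SV lengths are stored as absolute
values, since sizes, not signs, are analyzed.

## Problem sizes

The shipped validation uses truth sets of 2000 DEL + 2000 INS for
parameter recovery (binomial/Poisson interval checks per caller and
type), 500 + 500 across ten seeds for the strategy-ordering checks, and
150 + 150 across two datasets for byte-level determinism; the grouping
and matching oracles run on 1000 random instances each of up to 50 pooled
calls and 20 truth/test calls. These sizes keep the full suite to a
couple of minutes while leaving the interval checks statistically
meaningful.

## Known limitations

* Genotypes (FORMAT columns) are ignored entirely; the analysis is
  call-level.
* Only DEL and INS are benchmarked; DUP/INV/CTX are refined, grouped and
  counted but never scored, because the targeted truth sets do not curate
  them.
* Breakend classification assumes well-formed mate ALTs; malformed
  breakends fall into the dropped-records counter.
* The multi-allelic split takes list-valued `SVLEN`/`END` positionally
  but inherits a shared `SVTYPE` from INFO, with the first ALT taking
  precedence in conflicts.
* Matching is position + type only by design; no sequence-similarity or
  reciprocal-overlap validation is attempted, so a nearby wrong-length
  call of the right type still counts as a TP.
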