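---
title: "Methods: clonotype-level detection of neuron-reactive CD8+ T cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonotype-level detection of neuron-reactive CD8+ T cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonoreact)
```

`clonoreact` analyzes experiments that hunt for rare autoreactive CD8+ T
cell clonotypes: a PBMC–neuron coculture read out by bulk TCR-β repertoire
sequencing, single-cell VDJ + expression profiling of the same donors, and
an NFAT-luciferase reporter assay on candidate TCRs. This vignette explains
each model and rule, the parameters that matter, the design decisions that
were genuinely open, and what the synthetic-data tests do and do not
demonstrate.

## Repertoire diversity

For clonotype frequencies $F_1 \dots F_n$ (clonotypes keyed by CDR3β
amino-acid sequence, frequencies recomputed from counts at load):

$$H = -\sum_{i=1}^{n} F_i \log_2 F_i \qquad
\text{clonality} = 1 - \frac{-\sum_i F_i \log_{10} F_i}{\log_{10} n}$$

Entropy is reported in bits; clonality is $1-$Pielou evenness, a scale-free
number in $[0,1]$. The ratio of entropies cancels the logarithm base, so
the $\log_{10}$ form equals the natural-log form exactly (tested to
$10^{-12}$). Conventions for degenerate inputs:

- Zero-frequency clonotypes are dropped before either metric; the
  $0\log 0 = 0$ convention therefore never arises explicitly.
- A single-clonotype repertoire has entropy 0 but **undefined clonality**
  (the $\log_{10} n$ denominator vanishes). `clonality()` raises an error
  rather than returning a sentinel — a silently returned 1.0 would hide a
  degenerate upstream sample; `repertoire_summary()` maps it to `NA`.
- Frequencies must sum to 1 within $10^{-9}$ and be strictly positive;
  anything else is an input error, not something to repair silently.

One property deliberately *not* asserted: merging two clonotypes always
lowers entropy (concavity), but it can lower clonality too, because the
$\log_{10} n$ normalizer shrinks along with the entropy — e.g.
$(0.98, 0.01, 0.01) \to (0.98, 0.02)$ takes clonality from 0.898 to 0.859.
Clonality comparisons are therefore only meaningful between repertoires,
not across clonotype mergings.

## Expansion calling across the coculture

For every clonotype observed at day 14, the fold change is its day-14
frequency over its ex vivo frequency. A clonotype undetected ex vivo gets
the **maximal theoretical frequency** $1/N_{\text{input}}$, where
$N_{\text{input}}$ is the number of CD8+ T cells used as sequencing input
(with $10^5$ cells: $10^{-5}$, i.e. 0.001%) — the largest frequency it
could have had while escaping detection, which makes the resulting fold a
*lower bound* and the caller conservative for rare precursors.

Three thresholds, all in `clonoreact_config()`:

| parameter | default | meaning |
|---|---|---|
| `fold_threshold` | 9 | expanded when fold ≥ 9 |
| `day14_freq_floor` | 0.005 | reportable when day-14 frequency > 0.5% |
| `control_fold_ceiling` | 2 | non-expanded control when fold < 2 |

Decisions that were open:

- The fold comparison uses **≥ 9**. The source conventions differ between a
  strict and a non-strict 9-fold cut; we adopt the non-strict form and make
  the threshold configurable. At repertoire scale the distinction touches
  only clones sitting exactly on the boundary.
- The 0.5% floor is a separate `reportable` flag rather than folded into
  `expanded`: the fold rule defines biology (growth), the floor defines
  what is worth carrying into TCR cloning.
- "Exponential increase between day 7 and day 14", used to *exclude*
  late risers from the control set, has no published number; it is
  operationalized as day14/day7 ≥ `day7_growth_ratio` (default 2),
  applied only when a day-7 sample exists.
- Ex vivo comparator frequencies are computed over all productive reads
  with no minimum-count filter; applying one would bias folds upward for
  clones near the detection limit.

Calls are sorted by descending day-14 frequency with ties broken
lexicographically by CDR3β, so output order is deterministic.

## Single-cell linkage and candidate selection

Cell QC keeps cells with exactly one productive TRB chain, ≤ 10%
mitochondrial reads and ≥ 100 detected genes — in that order, and each
removed cell carries the *first* failing reason so QC summaries are
unambiguous. Boundary semantics follow the stated rules: 10.0% mito passes,
99 genes fails. Genes are then kept when expressed in ≥ 10 of the remaining
cells (cell filter first, so presence is counted over clean cells). When
`pct_mito` is absent it is computed as 100 × (counts of `MT-` prefixed
genes)/library size.

Clonotypes are donor-scoped sets of cells sharing a CDR3β amino-acid
sequence — the same key as the bulk tables, which is what makes bulk and
single-cell results joinable. Per clonotype we tabulate cluster membership;
a clonotype is *expanded ex vivo* when seen in ≥ 2 cells. Candidates for
TCR cloning need ≥ 10 cells in the target cluster **and** > 60% of the
clonotype's cells there. Two open points, resolved as follows:

- Cells lacking a cluster label are excluded from profiles (clustering is
  upstream of this package; its failures should not silently distort
  fractions), so the 60% denominator counts labeled cells only.
- Identical CDR3β sequences in different donors remain distinct clonotypes
  in cohort totals, matching per-donor selection.

Selection is monotone by construction: raising either threshold can only
remove candidates (property-tested).

## Reporter reactivity

Replicates (duplicates in the assay design) are aggregated by arithmetic
mean — too few for a robust estimator or a per-TCR test. Each condition is
adjusted by the TCR's own mock-well mean and floored at zero; adding any
constant to all wells of a TCR cancels exactly (property-tested). The
positivity threshold (default 5000 RLU) applies to these adjusted means.

A TCR is called neuron-reactive when stimulated-neuron signal exceeds the
threshold *and* the anti-HLA-ABC blockade condition falls to or below it —
HLA dependence is required by default because it is what demonstrates
TCR-mediated recognition; `require_hla_block = FALSE` gives threshold-only
positivity. Note a deliberate asymmetry: with HLA dependence required the
single threshold bounds the stimulated signal from below and the blocked
signal from above, so the call is *not* monotone in the threshold; only the
permissive positivity rule is. PBMC cross-reactivity reuses the same
threshold (no separate published cutoff) and records whether the PBMC
signal stays below the neuron signal. TransAct wells act as a transfection
control (`transact_min`, default 5000 RLU); absent TransAct data the TCR is
treated as passing, with a warning, rather than silently dropped.

## Expression statistics

Cell-level differential expression deliberately mirrors the common
single-cell toolkit defaults: TCR segment genes (TRAV/TRAJ/TRAC/TRBV/TRBD/
TRBJ/TRBC prefixes) are removed first, since clonotype-defined groups are
trivially separable by their own receptor genes; values are
$\ln(1 + 10^4 \cdot \text{count}/\text{library size})$; genes are tested
when expressed in ≥ `min_pct` (default 0.1) of cells in at least one group.

The test is a two-sided Wilcoxon rank-sum: exact (via the Mann–Whitney null
distribution) when both groups have ≤ 25 cells and no ties, otherwise a
normal approximation with average ranks, the tie-correction variance term
and a 0.5 continuity correction. The approximation sits within 0.02 of
exact enumeration for groups of 8–25 (property-tested against a brute-force
oracle). The paired analogue, `exact_signed_rank()`, enumerates all $2^n$
sign assignments (≤ 20 nonzero pairs, zero differences dropped, average
ranks for tied magnitudes) and counts assignments whose rank sum deviates
at least as far from $n(n+1)/4$ as observed; for six uniformly signed pairs
this gives $2/64 = 0.03125$ two-sided.

The reported fold change is
$\log_2\!\frac{\bar{e}_1 + 1}{\bar{e}_2 + 1}$ on back-transformed
normalized means with pseudocount 1. Exact parity with any external
toolkit's fold change is a non-goal; the formula is the contract. The
pseudocount compresses fold changes of weakly expressed genes toward zero —
a gene must have a normalized mean above ≈ 1.4 for a true halving to clear
the 0.5 cutoff — which is why DE power is quoted for moderately expressed
genes (below).

Benjamini–Hochberg adjustment is the standard step-up over tested genes.
Two mathematical facts worth recording: adjusted values are monotone along
the sorted raw p-values (tested), but the adjustment is **not idempotent**
— re-adjusting already-adjusted values inflates any value attained from a
larger index, e.g. $(0.2, 0.9) \to (0.4, 0.9) \to (0.8, 0.9)$ — so adjusted
p-values must never be fed back through the procedure.

Sample-level analysis is a declared simplification: pseudobulk counts are
exact per-donor sums (mass conserved by integer arithmetic), scaled to
fragments per million (each sample column sums to $10^6$), and compared by
rank tests across donors — not by a negative binomial GLM, which is out of
scope here; output headers say so.

## What the synthetic generator emulates — and what it does not

All generators are pure functions of their parameters and a seed; each
draws from its own named substream of the top-level seed, so adding a
generator never perturbs existing fixtures.

- **Repertoires**: clone probabilities follow a discrete power law on ranks
  ($p_i \propto i^{-\alpha}$, default $\alpha = 2$), giving the
  few-large-clones / long-rare-tail shape of CD8+ repertoires with two
  parameters; counts are multinomial at the sequencing depth (default
  $10^5$, matching a typical $10^5$-cell input).
- **Coculture**: planted reactive clones multiply by `growth_factor`
  (default 20) per 7-day interval with renormalization and multinomial
  resampling at each timepoint, so the day-14 expected fold is roughly
  growth² ≈ 400 under deep sampling — well separated from both the 9-fold
  threshold and multinomial noise. Precursors are drawn from the window
  $[2\times10^{-5}, 10^{-4})$ of ex vivo frequency: rare (below the 0.01%
  detection scale the assay targets) yet abundant enough that two growth
  rounds carry them past the 0.5% reporting floor, which is the regime the
  coculture assay is designed to reveal.
- **Cell datasets**: 3 + 7 donors in two groups, 16 clusters,
  Dirichlet-multinomial cluster membership. Planted target-cluster
  clonotypes use expected target mass 0.93 (matching the strongly resident
  clonotypes the selection rule is meant to find, which concentrate > 90%
  of their cells in one cluster) with concentration total 150 and 30–60
  cells each; background clonotypes use a symmetric concentration with
  geometric sizes (≈ 42% seen in ≥ 2 cells). Configured fractions of cells
  fail each QC rule.
- **Counts**: negative binomial (dispersion 0.5) around lognormal gene
  means ($\text{meanlog}=\log 2$, $\text{sdlog}=0.8$) — the
  moderately-to-highly expressed genes on which cell-level testing is
  powered; the near-zero tail of a real transcriptome is mostly removed by
  the `min_pct` filter anyway and is not simulated. Planted genes scale the
  second group's mean by $2^{\text{log2FC}}$, half up and half down.
- **Reporter plates**: reactive TCRs emit lognormal signal (median 20000
  RLU above background, sdlog 0.25) that collapses to background under
  blockade; non-reactive TCRs sit at background (median 1000 RLU mock)
  everywhere; 85% of reactive TCRs also respond to PBMCs at lower median
  intensity; duplicates per condition, TransAct ≈ 80000 RLU.

Passing recovery tests on these fixtures shows the *rules compose
correctly* and that the caller's error rates are controlled under the
stated noise models. It does **not** show robustness to what the generator
omits: V/J sequence grammar, batch and plate effects, ambient RNA, doublet
contamination beyond the multi-TRB fraction, donor-level expression
heterogeneity, or empirically fitted clone-size laws.

## Problem sizes and numerical conventions

The test suite exercises the callers at the scales the methods are meant
for: 100 simulated timecourses at depth $10^5$ for expansion recovery, 50
cell datasets for selection recovery, 100 plates for reactivity accuracy,
and 20 replicates of 2000 genes × 500 cells/group for DE power (observed ≈
0.9 at $|\log_2\text{FC}| = 1$), null calibration and empirical FDR —
sizes chosen to estimate rates with small Monte-Carlo error while the whole
suite stays in the minutes range. Frequency sums are validated to
$10^{-9}$; base-invariance to $10^{-12}$; ties in sorted outputs are always
broken lexicographically by CDR3β so every table is reproducible
byte-for-byte; text I/O is UTF-8 with `.` as the decimal point, and every
output TSV carries the package version and a hash of the configuration.

## Known limitations

- Clustering, integration and ambient-RNA removal are inputs, not steps;
  cluster labels are trusted as given.
- Sample-level DE is rank-based on per-million values, not a count GLM.
- Per-TCR reactivity uses thresholded means over duplicates; no uncertainty
  is attached to individual calls.
- The clonotype key ignores V/J segments by default (an optional strict
  mode could add them); nucleotide variants converging on one amino-acid
  CDR3β are merged.
- Pseudo-frequencies make folds for undetected clones lower bounds, so the
  caller's sensitivity near the detection limit depends on the recorded
  input cell number being accurate.
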