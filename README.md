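# clonoreact

Clonotype-level identification of neuron-reactive CD8+ T cells from
coupled bulk and single-cell TCR repertoire data.

Autoreactive CD8+ T cells that recognize neurons are rare in blood and
invisible to bulk phenotyping. One way to find them is to coculture a
patient's PBMCs with autologous stem-cell-derived neurons for two weeks and
watch which T-cell receptor (TCR) β-chain clonotypes expand; to link those
clonotypes to single-cell expression clusters through their CDR3β amino-acid
sequence; and to confirm antigen recognition by transfecting candidate TCRs
into an NFAT-luciferase reporter line. `clonoreact` implements the
computational side of that workflow for immunologists analyzing such
experiments: repertoire diversity metrics, expansion calling, single-cell
QC and clonotype–cluster linkage, reporter-assay reactivity calling, and
group-wise expression statistics — plus a synthetic-data generator with
planted ground truth, so the entire pipeline runs and is tested without any
external download.

## The statistics at the core

For a repertoire of *n* clonotypes with frequencies *F₁ … Fₙ*:

- **Shannon entropy** (diversity, bits): *H = −Σᵢ Fᵢ log₂ Fᵢ*
- **Clonality** (1 − Pielou evenness): *1 − (−Σᵢ Fᵢ log₁₀ Fᵢ) / log₁₀ n* —
  0 for a perfectly even repertoire, →1 for a monoclonal one.
- **Expansion calling**: a day-14 clonotype is *expanded* when its frequency
  is ≥ 9-fold its ex vivo frequency, substituting the maximal theoretical
  *pseudo-frequency* 1/(input CD8+ cell count) when it was undetected
  ex vivo; it is *reportable* when it additionally exceeds 0.5% of the
  day-14 repertoire. Clonotypes under 2-fold are non-expanded controls.
- **Candidate selection** (single cell): clonotypes (identical CDR3β amino
  acids within a donor) with ≥ 10 cells in the target cluster and > 60% of
  their cells residing there, after keeping cells with a single productive
  TRB chain, ≤ 10% mitochondrial reads and ≥ 100 genes, and genes expressed
  in ≥ 10 cells.
- **Reactivity calling**: per-TCR background adjustment against its own
  mock wells; neuron-reactive when the adjusted signal against stimulated
  neurons exceeds 5000 RLU *and* collapses under anti-HLA-ABC blockade
  (TCR/HLA-mediated); PBMC cross-reactivity at the same threshold.
- **Differential expression**: cell-level two-sided Wilcoxon rank-sum tests
  (exact null for small groups, tie- and continuity-corrected normal
  approximation otherwise) on log-normalized counts with TCR segment genes
  removed, Benjamini–Hochberg FDR, flags at |avg log₂FC| > 0.5 and adjusted
  p < 0.05; donor-level pseudobulk sums scaled to fragments per million.

## Worked example

Simulate a 2000-clonotype repertoire sequenced at 10⁵ reads, run a 14-day
coculture in which six rare clones grow 20-fold per week, and call
expansions:

```r
library(clonoreact)
base <- simulate_repertoire(n_clonotypes = 2000, depth = 1e5, seed = 7)
repertoire_summary(base)
#>    sample_id n_clonotypes shannon_entropy_bits clonality top_clonotype_freq
#> 1 sim_exvivo          401             2.348607 0.7284049            0.60756

cc <- simulate_coculture(base, growth_factor = 20, seed = 7)
calls <- call_expansions(cc$timecourse)
subset(calls, reportable)
#>             cdr3b_aa freq_exvivo_effective pseudo_flag freq_day7 freq_day14
#> 5      CRDASWCSEHYTF                 5e-05       FALSE   0.00192    0.03246
#> 6        CCIPHMNKWDF                 6e-05       FALSE   0.00163    0.03183
#> 7         CTSKVKISMF                 8e-05       FALSE   0.00141    0.02461
#> 8  CKLTHHGIIRMGCDLHF                 6e-05       FALSE   0.00141    0.02172
#> 10     CGTKGMILWAWMF                 8e-05       FALSE   0.00105    0.01784
#> 14      CMFSLSRRKGCF                 4e-05       FALSE   0.00043    0.00739

all(cc$truth$reactive_clonotypes %in% calls$cdr3b_aa[calls$reportable])
#> [1] TRUE
```

Each reportable row is a clone that rose from the rare tail (< 0.01% of the
ex vivo repertoire) to > 0.5% of the day-14 repertoire — a several-hundred
fold increase, far beyond the ≥ 9 threshold — exactly the signature the
coculture assay is designed to amplify; the last line confirms the caller
recovered every planted reactive clone.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on the synthetic
fixture and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R                 # generate every input
Rscript analysis/02_qc_link_select.R           # cell QC, linkage, selection
Rscript analysis/03_expansion.R                # diversity + expansion calls
Rscript analysis/04_reactivity.R               # reporter reactivity calls
Rscript analysis/05_differential_expression.R  # Wilcoxon DE + pseudobulk FPM
```

Every output TSV carries a comment line with the package version and a hash
of the threshold configuration in force.

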