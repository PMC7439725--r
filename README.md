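# mpradiverge

Cis and trans regulatory divergence from massively parallel reporter
assays (MPRAs).

When the activity of a regulatory element differs between two species,
the difference can come from the DNA sequence itself (a **cis** effect)
or from the cellular environment acting on it (a **trans** effect).
MPRAs separate the two directly: clone both species' sequences into a
barcoded reporter library, assay the same library in both species' cells,
and compare

- **cis**: mouse vs human sequence, environment fixed;
- **trans**: mESC vs hESC environment, sequence fixed;
- **native**: each sequence in its own species' cells.

`mpradiverge` implements this analysis end to end for two-environment
MPRA count data on orthologous element pairs (eRNA, lncRNA and mRNA
transcription start sites), plus a synthetic-data generator with known
ground truth so every stage can be validated against planted effects.

## The model in brief

For element $i$ in environment $e$, barcode counts give a log2 activity

$$\alpha_{i,e} = \operatorname{mean}_{\text{replicates}}\ \operatorname{median}_{\text{barcodes}}\ \log_2 \frac{\mathrm{rna\ cpm} + 1}{\mathrm{dna\ cpm} + 1},$$

after dropping elements with fewer than 50% of their barcodes at ≥ 10
input-DNA counts. Elements are called active against the empirical null
of random-sequence negative controls (BH q < 0.05). Effects are mean
differences of barcode log-ratios, signed so that positive means the
mouse sequence or mESC environment is higher:

$$\mathrm{cis}_e = \alpha_{m,e} - \alpha_{h,e}, \qquad
  \mathrm{trans}_s = \alpha_{s,\mathrm{mESC}} - \alpha_{s,\mathrm{hESC}}, \qquad
  \mathrm{native} = \alpha_{m,\mathrm{mESC}} - \alpha_{h,\mathrm{hESC}},$$

so that $\mathrm{native} = \mathrm{cis}_{\mathrm{hESC}} +
\mathrm{trans}_{m}$ exactly. Significance is calibrated empirically:
pseudo-pairs of identical sequences (disjoint 13-barcode subsets of
60-barcode positive-control tiles) define the no-difference null; the
q-value cutoff is the largest at which < 10% of these null controls are
called, and significant effects must also exceed the smallest significant
null |effect|. Co-occurring cis and trans effects are classified
**compensatory** (opposite signs) or **directional** (same sign).
Motif–effect association uses three nested linear model families with
likelihood-ratio tests:

- activity: `mean(activity) ~ GC + CpG + motif present`
- cis: `|cis| ~ mean(GC) + mean(CpG) + |dGC| + |dCpG| + motif disrupted`
- trans: `trans ~ GC + CpG + motif present`

Enhancer redundancy counts TAD-co-resident transcribed enhancers and
thresholds their expression correlation with the focal element by a
modified Otsu method (100 bins on [0, 1]); conservation calls use the
maximum CAGE coverage in a ±50 bp window (≥ 10 reads, either-TSS rule
for enhancers).

## Worked example

```r
library(mpradiverge)
cfg <- simulation_config(n_pairs = 200, seed = 1)
res <- run_pipeline(cfg)
```

This simulates a 200-pair library (plus 100 negative and 4 positive
control tiles), quantifies activity, runs all five effect scans against
200 null pseudo-pairs, and prints (from `res$report`):

```
pairs tested:            200 of 200
active in hESC / mESC:   1.00 / 1.00
cis / trans / native:    0.45 / 0.35 / 0.49 significant
cis calibration:         q < 0.362, |effect| > 0.200 (null rate 0.098)
cis-trans co-occurrence: odds 1.40 (p = 0.3)
compensatory / directional pairs: 22 / 13
native |effect| smaller when compensatory: p = 0.083
motifs: 8 informative, 4 cis-associated, 10 trans-associated
TF direction agreement:  5 of 6 DE TFs
```

Reading this: every simulated pair passed the DNA filter and was active
in at least one native context; 45% were called with a cis effect at the
calibrated cutoff (40% were planted — reported fractions include the
designed ~10% per-model empirical-FDR leakage, see the methods
vignette); the null controls stayed below the 10% target; 22 of the 35
doubly significant pairs compensate (opposite cis/trans signs); and 5 of
6 differentially expressed trans-motif TFs agree in direction with their
motif's trans association. `run_pipeline(cfg, outdir = "out")`
additionally writes every stage table (TSV/BED/FASTA/MEME/JSON).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/mpradiverge.R run --outdir out --seed 7
```

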