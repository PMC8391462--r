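# ppreAlu

Discovery of Alu-embedded PPAR-responsive elements (PPREs) in gene
promoters, with the downstream cancer statistics used to characterise such
loci.

## The problem

PPARγ regulates its targets through PPREs — DR1-family nuclear-receptor
binding sites; the instance handled here is the heptamer `TGACCTC` (and
its reverse complement `GAGGTCA`). In some promoters, DNMT1's being the
canonical example, the PPRE does not sit in free sequence: it lies in the
**left arm of an Alu element**, next to the Alu's internal RNA polymerase
III B-box, and that Alu is the first element of a distinctive ordered
repeat run in the promoter:

```
5' — Alu — Alu — Low_complexity — LINE/L1 — … TSS
```

`ppreAlu` makes that observation computable, for anyone who wants to ask
"which genes carry this architecture?" of a genome plus its RepeatMasker
annotation. It provides:

- **Promoter scanning** — extract 4 kb / 2 kb windows upstream of each
  TSS (strand-aware, 0-based half-open everywhere), match the ordered
  repeat grammar with a configurable inter-element gap bound (default
  500 bp), scan PPRE motifs on both strands, and map every hit onto the
  Alu subfamily consensus by global alignment to report its arm and
  A-/B-box proximity.
- **Consensus and phylogeny** — greedy redundancy collapse, deterministic
  star multiple alignment, majority consensus with position frequency
  matrix and per-column information content (`2 − H` bits), p-distances
  (Kimura 2-parameter behind a flag), Saitou–Nei Neighbor-Joining with
  exact recovery on additive matrices, and nearest-subfamily assignment.
- **Cancer statistics** — per-cohort Pearson co-expression of
  `PPARG`/`DNMT1` with t-based significance and Fisher-z intervals
  (weak-correlation flag at |r| < 0.5); two-sample Kolmogorov–Smirnov
  comparison of observed variant evolutionary-action scores against the
  brute-force all-missense null of the same CDS; and median-split
  Kaplan–Meier survival with log-rank tests, overall and within
  chromosome-3 classes (disomy 3 vs monosomy 3), the uveal-melanoma
  setting.
- **A synthetic-data module** — genomes with planted configurations,
  expression pairs with set population correlations, mutation-score sets
  with a controllable 60–80 score-band enrichment, and survival cohorts
  with expression-linked hazards. Every generator records its ground
  truth, so each stage of the pipeline is verifiable offline.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (`Rscript analysis/01_simulate.R` … `05_survival.R`), writing tables
under `results/`. The discovery stage, condensed:

```r
library(ppreAlu)

cfg  <- sim_config(seed = 1)            # 50 genes, 10 planted configurations
gen  <- simulate_genome(cfg)
scan <- genome_scan_similar(gen$genome, gen$tss, gen$repeats,
                            window_length = 4000)
identical(scan$genes, gen$planted_genes)
#> [1] TRUE
subset(scan$hits, !is.na(alu_name),
       c(gene_id, offset, strand, consensus_offset, arm, adjacent_box))[1:3, ]
#>   gene_id offset strand consensus_offset  arm adjacent_box
#> 2 gene003   1575      +               63 left        B-box
#> 3 gene004   2194      -               62 left        B-box
#> 4 gene007    273      +               62 left        B-box
```

All ten planted genes are recovered with no false positives; each PPRE
hit maps into the Alu left arm (planted consensus offset 62, recovered up
to ±1 — see the vignette on alignment ambiguity) adjacent to the B-box at
consensus positions [72, 101). The statistics stage prints, for example:

```
CTA control n= 60 r=+0.887 p=3.86e-21
CTA tumor   n=300 r=+0.098 p=9.10e-02  [weak]
KS observed (n=107) vs all-missense null (n=1223): D=0.310 p=1.28e-08
all        high n=40 low n=40  log-rank chisq=21.08 p=4.41e-06
disomy3    high n=25 low n=26  log-rank chisq=27.17 p=1.87e-07
monosomy3  high n=14 low n=15  log-rank chisq=0.57 p=0.452
```

i.e. the control cohort keeps the strong co-expression the tumor cohort
loses, the observed mutation scores depart from the all-missense null,
and the expression effect on survival is confined to disomy 3 tumors —
the qualitative patterns the simulated conditions plant.

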