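---
title: "Methods: Alu-embedded PPRE discovery and its downstream statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Alu-embedded PPRE discovery and its downstream statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppreAlu)
```

`ppreAlu` implements a promoter-architecture discovery pipeline — find
genes whose promoters carry a PPAR-responsive element (PPRE) inside the
left arm of an Alu element that itself heads an ordered
Alu–Alu–Low_complexity–LINE/L1 repeat run — together with the statistics
used downstream of such a finding: co-expression correlation across
tumor/control cohorts, variant-score distribution comparison, and
median-split survival analysis. This vignette records the model choices,
parameter meanings, numerical conventions, and the limits of what the
synthetic-data tests can show.

## Promoter windows and coordinates

All coordinates are 0-based half-open (BED convention) in every structure
and output file; RepeatMasker `.out` input (1-based inclusive) is shifted
at parse time. A gene with TSS $t$ on the `+` strand gets the window
$[t-L, t)$; on the `-` strand, $[t+1, t+1+L)$ with the sequence
reverse-complemented, so window coordinate 0 is always the position
farthest upstream and the sequence reads 5'→3' of the gene. $L$ defaults
to 4000 bp for discovery and 2000 bp for the narrowed genome-wide scan;
windows are clipped at contig edges with a warning. `N` bases are allowed
in genomes and never match any motif position.

## The configuration grammar

A configuration is an ordered assignment of annotated repeats to the
grammar terms (`SINE/Alu`, `SINE/Alu`, `Low_complexity`, `LINE/L1` by
default): window start coordinates must strictly increase and each gap
(next start − previous end) must be at most `max_gap`. Choices made where
the qualitative description ("proximal") left the rule open:

- `max_gap = 500` bp, configurable; this is also the bound the generator
  draws planting gaps from.
- Gaps are bounded only from above — overlapping elements (negative gap)
  are tolerated, since repeat annotations routinely nest or abut.
- A repeat participates if it overlaps the window by ≥ 1 bp; elements may
  extend past window edges.
- `orientation_policy` defaults to `"any"`; `"same_strand"` is available
  but nothing in the default analysis requires configuration elements to
  share a strand.
- All alternative assignments are reported (three eligible Alus yield
  two), and a gene *qualifies* existentially: at least one configuration
  match and at least one PPRE hit starting inside an Alu of such a match.
  The matcher is tested for exact agreement with brute-force ordered
  subsequence enumeration on windows with ≤ 12 repeats.

## Motif scanning and Alu context

The PPRE is scanned as the exact heptamer `TGACCTC` plus its reverse
complement `GAGGTCA`, both strands by default, overlapping occurrences
all reported. IUPAC degeneracy is supported in the motif (e.g. a DR1-like
`TGACCTY`) but the default stays exact; degenerate DR1 half-site spacing
models and PWM scoring are out of scope.

A hit inside an annotated Alu is located on the subfamily consensus by
Needleman–Wunsch global alignment of the genomic copy to the consensus
(+1 match / −1 mismatch / −2 linear gap), mapping the hit start through
the alignment. Structure coordinates on the consensus default to A-box
$[6, 32)$, B-box $[72, 101)$, left arm $[0, 132)$, linker to 170;
"adjacent" means the hit's consensus interval lies within 10 bp of the
box. All are configurable per subfamily, since real subfamily consensi
differ slightly in their internal-promoter positions.

One mapping subtlety is worth recording: when a heptamer is spliced into
a copy, the optimal global alignment of copy against consensus is
occasionally *gapped* even with no other difference — a one-base shift
can trade two gap penalties (−4) for three or more recovered matches —
so the mapped offset can differ from the true splice position by ±1 at
zero divergence. At 10% per-base divergence the tests bound the error by
±5. Arm and box calls are insensitive to shifts of this size.

## Consensus building and phylogeny

The consensus stage mirrors the classical workflow (redundancy collapse →
multiple alignment → consensus → distance tree) with deterministic,
exactly testable components:

- **Redundancy collapse** is greedy identity clustering in input order
  (a sequence joins the first cluster whose representative it matches at
  ≥ 0.95 global identity, computed as identical columns over alignment
  length); it implements deduplication semantics, not assembly.
- **Star MSA**: the center is the sequence with the highest summed
  pairwise identity (ties to the first); all others are aligned to it
  pairwise and gaps merge under once-a-gap-always-a-gap. This is an
  approximation to progressive alignment that is adequate for
  intra-subfamily Alu divergence (substitution-dominated, ≲ 15%) and has
  the virtue of exact reproducibility; it will not produce good
  alignments for sequence sets with heavy indel structure.
- **Consensus**: columns with gap fraction > 0.5 are dropped; each
  retained column takes the majority base with alphabetical tie-break
  (IUPAC ambiguity codes are deliberately not emitted); information
  content is $2 - H$ bits with gaps excluded, so it is 2 exactly when a
  column is unanimous.
- **Distances** are p-distances over columns where both rows are
  non-gap; equal-length inputs are treated as already aligned (an MSA
  always is), and unequal-length inputs are globally aligned per pair.
  Kimura 2-parameter is available behind `model = "k2p"`; the default
  stays with the simplest defensible choice.
- **Neighbor-Joining** follows Saitou–Nei: join the pair minimizing
  $Q(i,j) = (n-2)d(i,j) - r_i - r_j$, ties broken by the lowest (row,
  column) index — which also fixes the topology for degenerate
  equidistant inputs — with branch lengths from the standard formulas,
  negative estimates clamped to 0 and counted. On additive matrices NJ
  is exact, which the tests verify by path-length equality on 50 random
  4–8-taxon trees; real p-distance matrices are not additive and no
  claim is made of reproducing any particular published tree.
- **Subfamily assignment** is minimum p-distance to the library consensi
  (alphabetical tie-break), reported together with the NJ placement of
  the candidate among the consensi.

The bundled consensus library is *synthetic*: four ~300 bp "subfamilies"
at 5–15% mutual divergence standing in for real Alu subfamily consensi
(which are data, not code); a real consensus FASTA can be supplied
anywhere the library is accepted.

## Cancer statistics

- **Co-expression**: Pearson $r$ per (cancer type, cohort) on
  log-expression, with $t = r\sqrt{n-2}/\sqrt{1-r^2}$ and a two-sided p
  on $n-2$ df; a 95% Fisher-z interval is reported alongside, and the
  weak-correlation flag marks $-0.5 < r < 0.5$. Raw p-values are
  reported, with Benjamini–Hochberg as an optional extra column.
- **Variant scores**: the null is the complete enumeration of missense
  single-nucleotide changes of the CDS (3 alternatives × every position,
  translated; stop gains and losses excluded), never a subsample. The
  two-sample KS statistic is the supremum ECDF gap; its p-value uses the
  asymptotic Kolmogorov distribution at $\sqrt{n_\mathrm{eff}}\,D$ with
  $n_\mathrm{eff} = n_1 n_2/(n_1+n_2)$, with an exact small-sample
  option delegated to `stats::ks.test`. When the observed set is itself
  resampled from the null's values (the generator's no-enrichment
  control), shared values make the test conservative — its rejection
  rate falls below the nominal level, which the tests assert as an
  upper bound rather than a two-sided uniformity band.
- **Survival**: the cohort is split at the median (`high` strictly
  above, ties low; the cutpoint quantile is configurable since published
  analyses rarely state it); Kaplan–Meier curves and the two-group
  log-rank test (hypergeometric variance, no continuity correction, 1
  df) come from the survival package behind this package's interface,
  and the same split is applied within chromosome-3 classes for the
  disomy 3 / monosomy 3 subgroup comparison.

## What the generator emulates — and what it does not

The synthetic module plants ground truth for every stage: configurations
with the exact element coordinates, PPRE position and strand (alternating
across plants), and source subfamily per copy; expression pairs with set
population correlation on the latent log scale (FPKM positivity via
exponentiation); observed score sets with a chosen fraction inside the
60–80 band; survival cohorts with exponential event times whose hazard
depends on the expression group (optionally only within one chromosome-3
class) and administrative censoring.

Deliberate non-realism, hence what green tests do *not* show: background
sequence is i.i.d. uniform (no GC structure, no CpG islands, no repeat
background beyond the planted elements — so false-positive rates on real
genomes will be driven by real repeat density, not by these tests); Alu
copies diverge by substitution only (no indels, no truncations — real
Alu copies are frequently 5'-truncated); expression is exactly
log-normal; event times are exponential. Default study conditions: 50
genes with 10 planted configurations on a 300 kb contig; 80-case
survival cohorts with 31/80 monosomy 3; 107 observed mutation draws; 500
samples per cohort where correlation recovery is measured. Calibration
properties (KS and log-rank type-I error within [0.035, 0.065] at
nominal 0.05) use 500 replicates; correlation coverage uses 1000.

## Degenerate inputs and error policy

Zero-variance vectors, empty samples, cohorts below 4 cases, subgroup
filters selecting nothing, all-gap alignment columns, CDS lengths not
divisible by 3, and correlations |r| ≥ 1 in the generator are errors,
not warnings. Unknown repeat class labels pass through with a warning
(the grammar simply never matches them); malformed FASTA records and
duplicate gene identifiers fail the read. All generators are
byte-reproducible from their seed.
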