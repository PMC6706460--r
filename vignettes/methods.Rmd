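---
title: "Methods: genome-sequencing variant analysis for fetuses with increased nuchal translucency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-sequencing variant analysis for fetuses with increased nuchal translucency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntgs)
```

# Scope

`ntgs` implements, as a reusable and fully tested pipeline, the analysis
stages of a prenatal-diagnosis study that applied ~30-fold genome
sequencing (GS) to fetuses with increased nuchal translucency (NT >= 3.5
mm): read-depth CNV detection with breakpoint refinement and mosaicism
quantification, structural-variant (SV) detection from chimeric read
pairs with a filter cascade, rule-based small-variant prioritization and
classification, cohort diagnostic-yield statistics, and qPCR copy-number
validation. Alignment, raw variant calling, and annotation are upstream
of this package: its inputs are per-window read-count tables, discordant
read-pair tables, and annotated variant tables. A synthetic-data module
generates all of these with known truth, so every stage is testable at
desk scale with no external data.

# The synthetic-data generator

The generator's defaults encode the study conditions rather than free
parameters:

* **Depth.** 30-fold coverage with 100-bp paired-end reads gives
  `30 * 5000 / 100 = 1500` expected reads per 5-kb window at copy number
  2; `mean_count = 1500` is the diploid baseline.
* **Count noise.** Windowed counts are negative binomial with dispersion
  (size) 100, i.e. ~10% coefficient of variation at baseline — mild
  overdispersion relative to Poisson, which is what windowed
  whole-genome counts typically show. No empirical dispersion is
  available for the study's data, so this is a chosen default, exposed
  in `sim_config()` (`Inf` recovers Poisson; `count_model = "expected"`
  switches noise off for exactness tests).
* **Copy number.** A window's expectation scales linearly with the local
  copy number; mosaic events contribute the mixture
  `f * cn_event + (1 - f) * cn_base`. Males carry one copy of X and Y.
* **GC bias** is an optional quadratic multiplier on the window mean,
  off by default; it exists to exercise the GC-correction path, not to
  model a specific instrument.
* **Inserts.** Read pairs around an SV junction are placed with insert
  sizes normal(350, 50) bp, inside the 300–500-bp fragment band of the
  library protocol. Supporting reads sit within one insert of the
  breakpoint with strands dictated by the junction's joining type.
* **Artifacts.** Systematic chimeric-pair artifacts are planted at
  identical coordinates in the case and the control table (they are
  generated from per-site seeds), which is precisely the redundancy the
  systematic filter exploits. Random noise pairs are uniform over the
  genome with random strands, 2000 expected per genome.
* **Genome.** The default coordinate frame is a reduced five-chromosome
  genome (three autosomes + X + Y, 10–60 Mb) with 5-Mb cytobands
  labelled outward from the centromere. Everything accepts a full
  cytoband file through `read_cytoband_map()`.

What the generator does *not* emulate: real GC content and mappability
structure, repeat-mediated ambiguous alignment, reference errors,
batch/lane effects, or annotation noise. Passing tests therefore
demonstrate the correctness of the algorithms under the stated noise
model, not performance on real sequencing data.

# Read-depth CNV calling

**Normalization.** Raw counts become copy ratios by division through the
autosomal median count; the autosomal median ratio is exactly 1.0
(diploid), and one copy corresponds to a ratio step of 0.5. A reference
panel can flatten recurrent window-level structure (division by the
panel's per-window mean ratio), but the panel reference is first
re-scaled within each chromosome so that chromosome-scale baselines — the
male X/Y single-copy level, or a genuine mosaic shift — are preserved
rather than divided away. GC correction divides out a quadratic
ratio-vs-GC fit estimated on autosomal windows. Zero-count windows are
kept with ratio 0.

**Candidate scan.** A 50-kb window sliding in 5-kb increments (a
10-window mean stepping one window) flags positions where the mean ratio
deviates from the chromosome's expected ratio by more than 0.2 —
half the heterozygous-deletion effect size, sustained over at least 3
consecutive sliding positions; overlapping hits merge into maximal
candidates. A chromosome whose median relative ratio deviates by more
than 0.08 is reported as a single chromosome-level candidate (the mosaic
aneuploidy path) and not re-scanned segment-wise; 0.08 sits just under
the 0.1 relative shift of a 20% mosaic autosomal monosomy, the lowest
mosaic level the pipeline aims to quantify (microarray platforms are
typically quoted a 20–30% mosaicism floor).

**Breakpoint refinement.** Each candidate edge is moved to the 5-kb
window boundary maximizing the coverage increment rate, defined here as
the difference between the mean ratio of the `k = 10` windows inside and
the `k` windows outside the edge, searched within `k` windows of the
candidate boundary. With noise off and grid-aligned truth this is exact;
under the default noise model the error is at most about one window.
Breakpoints are therefore reported at 5-kb precision — base-pair
precision would require split-read evidence, which is out of scope.

**Rarity screen.** The kept CNVs are those rare in a reference panel:
the case's per-window ratios in the region are compared by a two-sided
Mann–Whitney rank-sum test against *each* panel sample's ratios over the
same windows, and the reported p-value is the maximum over panel
samples, with the fixed screen p < 1e-4. An event is thus "rare" only if
its copy-ratio signature differs from every panel member; a
population-polymorphic CNV segregating in the panel fails the screen, as
it should. (Pooling all panel windows into one comparison sample — the
obvious alternative, available as `mode = "pooled"` — would flag such
polymorphisms as highly significant, because a case matching only the
carrier half of a pooled mixture still has a shifted rank distribution.)
The rank-sum p-value is computed exactly for combined sample sizes up to
40 via a dynamic-programming convolution over midranks (so ties are
handled exactly), and by the tie-corrected normal approximation with
continuity correction above that; the two-sided p is
`min(1, 2*min(P(W<=w), P(W>=w)))`. No multiple-testing correction is
applied: the threshold is a fixed screen, not an error-rate guarantee.

**Mosaicism.** For a mixture of normal cells at ratio `expected` and
aberrant cells at ratio `event`, the fraction of aberrant cells is
`f = (expected - observed) / (expected - event)`, clamped to [0, 1]. For
chromosome-Y loss in a male, `expected` is the single-copy baseline
(0.5) and `event` is 0. Fractions are reported only in [0.1, 0.9];
outside that band the call is treated as constitutional, since a
sub-10% mixture estimate is indistinguishable from baseline wobble at
this depth.

**Reportable size.** Calls shorter than 25 kb (5 windows) are dropped by
default; the study states no minimum, and 5 windows is the least the
rarity statistic can meaningfully rank.

# Chimeric-pair SV calling

A chimeric pair maps to two chromosomes, or to one chromosome with
separation strictly above 10 kb. Reads below mapping quality 30 are
dropped, and ends are canonicalized (lower chromosome/coordinate first).
The **joining type** of a pair encodes which side of each breakpoint is
fused, derived from strands: a `+` read's joined side lies downstream of
its position (`D`), a `-` read's upstream (`U`). The truth table is

| event | junction 1 | junction 2 |
|---|---|---|
| reciprocal translocation | `D`–`U` | `U`–`D` |
| inversion | `D`–`D` | `U`–`U` |
| insertion | receptor `D` – source-start `U` | receptor `U` – source-end `D` |

The cascade is fixed-order: **clustering** (single pass over
coordinate-sorted pairs; a pair joins an open cluster iff same
chromosome pair and joining type and both footprints extend by at most
1,000 bp — about twice the insert-size spread); **systematic filtering**
(drop clusters whose footprints reciprocally overlap, at >= 50% both
ways on both sides, a control cluster with the same chromosome pair and
type); **random-error filtering** on the cluster property matrix (keep
iff supporting pairs >= 4, footprint spans <= 1,500 bp, strand
consistency = 1.0, median mapping quality >= 30 — thresholds chosen here
and exposed, since the upstream publication's matrix is not
reproducible from the text); and **joining-type classification**.
Classification first groups clusters into locus components (two clusters
link when their breakpoint estimates co-locate within 2 kb on at least
one side), so independent events sharing a chromosome pair stay
separate, then applies the table above. Breakpoints are estimated from
the tightest read (`max(pos) + read length` on a `D` side, `min(pos)` on
a `U` side), which is accurate to a few tens of bases at 8–10
supporting pairs. Anything not matching a rule — a lone cluster,
incompatible joining types — is reported `complex` with a reason rather
than dropped. Insertions whose source interval is shorter than the 2-kb
co-location tolerance would be typed as translocations; resolving them
needs finer evidence than read pairs.

**Junction characterization** aligns a junction sequence against its two
reference flanks: the longest junction prefix matching a suffix of flank
A, the longest suffix matching a prefix of flank B (minimum 10-base
anchors). A gap between the anchors is a non-templated insertion, an
overlap is microhomology — mutually exclusive, as in the standard
repair-mechanism reading (non-homologous end joining vs
microhomology-mediated). Reconstruction of a shattered insertion's full
fragment order from read pairs alone is not attempted — the study
resolved its 11-fragment insertion with breakpoint-spanning Sanger
reads; the package instead offers `lost_segments()`, the interval
arithmetic that derives lost source segments from a known fragment
list.

# Small-variant prioritization and classification

A variant is retained if already reported pathogenic (ClinVar P/LP or
HGMD DM), or if it jointly satisfies: population MAF <= 5%; located in
coding sequence or an exon–intron junction; called damaging by multiple
in-silico predictors, interpreted as >= 2 of the 5 named tools
(configurable — the source text does not define "multiple"); and located
in an OMIM disease gene. Missing annotation fails the criterion it
belongs to, so retention of incompletely annotated variants happens only
through the other criteria. Each retained variant carries a trace of the
criteria that fired.

Trio genotypes resolve origin (both parents reference = de novo; one
carrier parent = that parent; both = biparental; any missing genotype =
unknown), and heterozygous variants in one recessive gene are phased
through their origins: different parents = confirmed-trans, same parent
= cis, otherwise suspected.

Classification reduces the ACMG evidence-code arithmetic to an explicit
deterministic rule table over {known status, consequence class, gene
mode, origin, phenotype match, biallelic state}: known P/LP with a
phenotype match is pathogenic (without the match, likely pathogenic); a
novel truncating variant in a dominant gene is likely pathogenic when de
novo or phenotype-consistent, a novel missense needs both; recessive
genes require a biallelic state (homozygous or confirmed-trans) before
any P/LP call — a single heterozygous variant in a recessive gene is
never reported above VOUS, a property the test suite enforces by
exhaustive enumeration. Phenotype consistency is an input flag: matching
ultrasound findings to reported phenotypes is expert judgment, not
computable here.

# Cohort statistics, nomenclature, and qPCR

**Diagnostic yield** is positives/n per clinical group with a 95%
Clopper–Pearson exact binomial interval, reported in percent to one
decimal (half-up rounding). The exact method is fixed because it
reproduces both published intervals (7.2–29.1 for 8/50 and 19.5–46.7 for
16/50) where the Wilson score interval does not. **Group comparisons**
use the chi-square test without continuity correction when all four
expected counts of the 2x2 table reach 5, and Fisher's exact test
otherwise — a selection rule inferred numerically, since it reproduces
all the published p-values (0.061 and 0.144 chi-square, 0.433 Fisher);
comparisons of two methods on the same cases are nevertheless unpaired,
matching the published values, though a paired (McNemar) design would
also have been defensible. **ISCN emission** covers the constrained
dialect the pipeline reports — del/dup/trp with band lookup, de novo
suffix, and mosaic sex-chromosome counts like `(X)x1,(Y)x0∼1` — and
round-trips through `parse_iscn()`; it is not a full ISCN 2016 grammar.
**qPCR copy ratios** follow the delta-delta-Ct model: at efficiency E,
`Ct = base - log(copies/2)/log(1+E)`, so `ratio = 2^-ddCt` with
`ddCt = (Ct_target - Ct_reference)_case - (same)_control`; replicate
SEMs propagate to the ratio by the delta method, and the statistic is
invariant to constant Ct shifts.

# Problem sizes and determinism

All simulations derive their streams from a single integer seed
(`derive_seeds()`), and identical seed + configuration gives
byte-identical outputs. The test suite exercises: 200 deletions >= 100
kb across 40 simulated genomes for CNV recall (>= 0.95) and breakpoint
accuracy (median error <= 5 kb); 50 seeds of 20 mixed SVs for cascade
recall (>= 0.9) and false events (<= 1 per genome); 50 seeds of the 40%
mosaic chromosome-Y loss for quantification accuracy (each within 5
points, mean within 2); 100 decoy tables for exact prioritizer
retention; and exhaustive small-instance parity of the rank-sum and
Fisher statistics against enumeration oracles. These sizes were chosen
as the smallest that make the binomial bounds on the stated rates
meaningful.

# Known limitations

* Breakpoints are window-grid quantities (5 kb); the study's base-pair
  breakpoints came from junction sequencing, which is out of scope.
* The rarity screen's per-sample-max design has limited power below ~10
  windows (50 kb) against small panels; smaller events rely on the
  deviation scan alone.
* The cluster property matrix and the joining-type reconstruction stand
  in for method details published elsewhere; both are isolated behind
  single functions and configuration so they can be replaced.
* The classification rule table is a deliberate simplification of the
  ACMG evidence arithmetic; it reproduces the study's reported calls on
  their printed annotations but is not a clinical classifier.
* Synthetic data cannot certify performance on real libraries; see the
  generator section for what is and is not emulated.
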