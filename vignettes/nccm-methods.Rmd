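---
title: "Non-coding constraint mutation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-coding constraint mutation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nccmscan)
```

## The problem

In tumor whole-genome cohorts the overwhelming majority of somatic
mutations fall outside coding exons, and most are neutral passengers. A
small fraction hit regulatory sequence — promoters, UTRs, intronic
elements, transcription-factor binding sites — where they can change gene
expression rather than protein sequence. Evolutionary constraint is a
practical filter for regulatory potential: a position conserved across
dozens of vertebrates is more likely to be functional, so a somatic hit at
a constrained non-coding position (an **NCCM**, non-coding constraint
mutation) is a better driver candidate than one at a neutral position.

`nccmscan` implements the full analysis around that idea:

1. **Filtration** of paired-caller somatic call sets: caller concordance,
   a panel-of-normals (PoN) filter, and germline-database removal with a
   somatic whitelist.
2. **Territories**: per-gene query regions — 5'/3' UTRs, introns, and
   ±100 kbp intergenic flanks — over which non-coding mutations are
   counted.
3. **NCCM calling**: non-coding variants at positions with a
   rejected-substitutions-style constraint score ≥ 2.
4. **Enrichment**: per-gene NCCM rates per 100 kbp, a key-gene versus
   other-protein-coding-gene (OPCG) comparison, and a control on
   constrained-site density.
5. **Regulatory annotation**, **TF binding-affinity deltas**, **promoter
   hotspot recurrence**, and **mutational-signature refitting**.

Because the real data such an analysis targets is controlled-access, the
package ships a first-class synthetic-study generator that emulates every
input and plants a known enrichment, so each stage is tested end to end
against ground truth.

## Models and conventions

### Coordinates

All internal intervals are 1-based closed, carried in
`IRanges`/`GenomicRanges` containers — the native convention of the R
genomics stack. File formats use their standard dialects: VCF and GTF are
1-based, BED and bedGraph 0-based half-open; `rtracklayer` performs those
conversions at the boundary.

### Filtration

A call is identified by the allele-specific key `(chrom, pos, ref, alt)`.
Concordance keeps exactly the keys present in both callers' output for a
sample; read counts are taken from a designated caller (A by default)
because the two callers report different count fields. The PoN filter
removes a call if its site was seen as germline in at least two normal
samples (`min_normals = 2`). The germline filter removes calls present in
any germline database unless the site is also catalogued as somatic (the
whitelist), in which case it is retained. Each step is a subset of its
input, and the per-call `filter_trail` records the outcome. Indel keys are
matched exactly; no left-normalization is performed, which is a documented
dialect limitation (the simulator emits normalized alleles).

### Territories

A gene's territory is the union of its UTRs, introns (gene span minus
exons, with UTR labels taking precedence where annotations overlap), and
two `flank` bp intergenic flanks anchored at the gene span
(TSS-to-TES extent), clipped at chromosome ends. The default flank is
100,000 bp — a deliberately conservative cis-window. Territories are built
independently per gene: in dense regions one position can belong to
several genes' territories and is counted once per gene. Flank bases that
overlap a neighboring gene's exons stay in the territory by default (the
variant classifier independently excludes coding positions); a flag
removes them from the length accounting instead, for sensitivity analysis.

### NCCM calling

A variant occurrence becomes an NCCM record for gene *g* when its anchor
(leftmost) base is outside every coding exon, inside *g*'s territory, and
its constraint score is ≥ 2 — the threshold is inclusive, and an indel's
score is read at its anchor base. Categories are `utr5`, `utr3`,
`intronic`, `intergenic` (flank); overlap with a lincRNA interval is kept
as a separate flag rather than a fifth exclusive category, so no
information is lost while categories stay a partition. VAF bins use the
contiguous partition low = [0, 0.10], mid = (0.10, 0.45],
high = (0.45, 1]; the mid/high boundary resolves two inconsistent legend
conventions ("11–45%" vs "> 46%") into a gap-free rule, and a VAF of
exactly 0 is binned low.

### Enrichment

Per gene, `rate = NCCM count / territory length × 100,000`. Genes with
zero NCCMs are included at rate 0 (a flag excludes them). The key-vs-OPCG
comparison is a two-sided Welch *t*-test on per-gene rates: group sizes
and variances are wildly unequal, so the unequal-variance form is the
defensible reading of "a *t* test". The same test applied to per-gene
constrained-base *fractions* is the control: if key genes simply sat in
more conserved sequence, the rate enrichment would be confounded, so the
control should **not** reject. Threshold ranking (≥ 1, 2, 3, 4 NCCMs per
100 kbp) is inclusive — source material prints both "> 1.0" and "≥ 1.0"
for the same quantity; we adopt ≥ and flag it. Frequently mutated genes
(FMGs) are genes with non-silent calls in ≥ 4 samples (~10% of a
39-sample cohort).

### TF binding affinity

The biophysical occupancy model converts a position frequency matrix into
mismatch energies: with pseudocounted column probabilities
\(p(b,j)\), \(E(b,j) = \frac{1}{\lambda}\ln\frac{p_{max,j}}{p(b,j)}\), so
the consensus base has energy 0. A sequence's affinity is
\(\sum_i \frac{R_0 e^{-E_i}}{1 + R_0 e^{-E_i}}\) over all offsets on both
strands, with \(\lambda = 0.7\) and \(\ln R_0 = 0.584\,W - 5.66\) — the
published defaults of the TRAP family of methods. For each variant, 41-bp
windows with the wild-type or mutant allele centered are scored against
every matrix and TFs are ranked by |affinity difference| (top 5 by
default). The original web tool's p-value machinery builds on an
unpublished background ("human promoter") model and is deliberately not
reproduced; the raw delta and a log-ratio are reported instead.

### Hotspots

Recurrence counts distinct samples per allele-specific site. Promoter
offsets are strand-aware: offset 0 is the first base of the start codon,
upstream is negative; for a minus-strand gene, positions numerically above
the ATG are upstream. This reproduces the conventional −124/−146 notation
for the two recurrent, mutually exclusive TERT-promoter sites (a pair of
sites is mutually exclusive when no sample carries both).

### Mutational signatures

Point mutations are tallied into the standard 96 pyrimidine-frame
trinucleotide channels (purine-reference substitutions are
reverse-complemented; indels excluded; contig-edge variants skipped with a
warning), per sample and per stratum (coding/non-coding,
constraint/non-constraint — each pair of stratified spectra sums exactly
to the total). Refitting solves non-negative least squares of the
normalized spectrum on a catalog whose columns sum to 1, renormalizes the
exposures to the simplex, and reports the reconstruction cosine. NNLS is
our concrete reading of a "maximum likelihood with linear regression"
refit; the packaged catalog is synthetic (five deliberately dissimilar
signatures) and any 96 × K TSV can be supplied instead.

## The synthetic study generator

`sim_config()` fixes the study conditions; everything downstream is a pure
function of the config (including its seed). Defaults:

| knob | default | why |
|---|---|---|
| genome | 2 × 1 Mbp chromosomes | megabase toy scale, seconds to generate |
| genes | 40, of which 8 "key" | enough genes for a two-group test |
| `flank` | 100,000 bp | the analysis' own cis-window |
| `constrained_block_rate` | 0.15 | ~15% of positions constrained, matching the reported score distribution |
| `base_mut_rate` | 5 × 10⁻⁵ /bp/sample | scaled up from the ~2/Mbp of a real GBM genome so a toy genome still yields cohort-level counts |
| `enrichment_factor` | 4 | planted elevation of constrained non-coding rate inside key territories |
| `n_samples` | 39 | the cohort size of the motivating study |
| depth | Poisson(75) | tumor coverage regime (median 75×) |
| `discordance_rate` | 0.1 | true somatic calls private to one caller |
| `artifact_rate` | 0.1 | caller-private false positives (what concordance removes) |
| `germline_contamination_rate` | 0.1 | germline leakage into tumor calls |

The generator writes every standard input: FASTA, GTF, lincRNA BED, a
bedGraph constraint track (block-structured: constrained elements with
scores in [2, 7] embedded in background < 2, element/gap lengths
exponential and calibrated so the realized constrained fraction matches
the target within ±2 points on a megabase), BED6 regulatory tracks with a
YAML manifest, JASPAR-format PFMs (one with a near-invariant,
high-information column), per-sample paired caller VCFs and normal VCFs,
germline-database and whitelist VCFs, and a truth table labeling every
planted record (somatic/germline/artifact, constrained, key-territory
membership, caller membership, true VAF).

What it deliberately does **not** emulate: realistic genome scale and
composition (uniform base composition, no repeats), sequencing-error and
mapping-error models, copy-number alterations, subclonal structure, or
signature-structured mutation spectra (mutations are uniform within a
stratum). Passing tests therefore demonstrate the correctness of the
pipeline's logic and statistics on data satisfying its assumptions — not
robustness to the messiness of real tumor genomes.

## Numerical and design choices

- **Indels** are 1–5 bp, anchored at their leftmost base; constraint is
  read at the anchor. Reproducible and simple; real indel scoring is
  ambiguous and unspecified upstream.
- **Germline databases** include each population site with sensitivity
  0.9; 5% of somatic sites are misfiled into a germline database and 80%
  of those are whitelisted, so the whitelist rule is exercised with both
  outcomes.
- **PoN membership is allele-specific** ("germline SNPs" are alleles);
  a position-specific mode exists behind a flag.
- **Degenerate inputs**: zero-depth calls error on VAF; zero-length
  territories error on rate computation; an empty context vector errors on
  refit; identical wt/mut windows return all-zero deltas (not an error).
- **Tie-breaks**: gene ranking sorts by decreasing rate, then
  lexicographic gene id.
- **Calibration check conditions**: the null-calibration property (an
  enrichment_factor = 1 generator should make the Welch test reject ~5% of
  the time at α = 0.05 over 200 cohorts) is run on single-chromosome
  500 kbp cohorts of 12 genes / 12 samples at `base_mut_rate` 5 × 10⁻⁴, so
  per-gene counts are large enough for per-gene rates to be approximately
  normal — with very sparse counts the *t*-test is conservative, which
  would test the asymptotics rather than the implementation. The planted
  recovery check uses 80 genes with 50 key so both groups are well
  populated.
- **Problem sizes** throughout the test-suite are megabase-scale so the
  whole suite runs in minutes on one core; they were chosen once, as the
  smallest sizes at which the statistical properties under test are
  well-conditioned.

## Known limitations

- No indel left-normalization: call sets from callers with different
  normalization conventions can under-intersect.
- The enrichment test treats genes as independent; overlapping territories
  in dense regions violate that mildly (as they do in the motivating
  analysis).
- The affinity model ranks by raw occupancy delta without a significance
  model.
- The packaged signature catalog is synthetic; exposures against it are
  demonstrations, not biological claims.
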