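---
title: "Models and methods behind g22pipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind g22pipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`g22pipe` analyzes *C. elegans* small-RNA sequencing libraries through the
lens of the piRNA surveillance pathway: PRG-1/piRNA complexes recognize
non-self transcripts and recruit RdRPs that synthesize antisense 22G-RNAs,
which silence targets through WAGO Argonautes such as the nuclear HRDE-1,
while a parallel population of CSR-1-bound 22G-RNAs marks self transcripts
as licensed. This vignette explains the models, conventions and design
choices in each module, and what the synthetic-data validation does and
does not establish.

## Coordinates, classification and normalization

All internal coordinates are 0-based half-open; conversions happen only at
file boundaries (GFF3 is 1-based inclusive, BED already 0-based). The 5′
nucleotide of a read is always reported in read orientation — for
minus-strand alignments the stored reference-forward sequence is
reverse-complemented — because the 22G-RNA definition (5′ guanine) is a
property of the RNA molecule, not of the reference strand. T and U are
interchangeable.

Reads of 17–40 nt are intersected with the annotation and classified under
a fixed precedence:

1. **structural_sense** — sense overlap with an rRNA, tRNA or snoRNA.
   These fragments are treated as degradation background and subtracted
   from the RPM denominator.
2. **mature_miRNA / mature_piRNA** — sense reads fully contained in the
   annotated locus. A single nucleotide of overhang disqualifies a read
   from being a mature small RNA.
3. **g22_antisense** — 21–23 nt, 5′ G, at least 1 nt of antisense overlap
   with a protein-coding gene, pseudogene or transposon. No minimum
   overlap fraction is imposed.
4. **sense_feature**, then **other**.

The precedence is a design choice: class definitions alone do not order
overlapping rules, and putting structural fragments first prevents rRNA
degradation products from inflating gene counts. A read overlapping two
features under its winning rule contributes its full weight to each; the
synthetic genome avoids such overlaps so recovery tests are unambiguous.

Multimapping reads are penalized by weighting each reported alignment
1/n, where n is the aligner's count of equally-best loci, so a read's
total contribution never exceeds one. Weighted counts stay fractional
everywhere except at the entrance to the Bayesian test (below). RPM =
count × 10⁶ / (total mapped − structural sense); RPKM for poly(A) mRNA
libraries = count × 10⁶ / (kb spliced length × protein-coding-mapped
total), since reads on features without poly(A) tails are likely
contaminants.

## The Bayesian two-model comparison

Libraries in this design are compared without replicates, so the test
works directly on sampling uncertainty. For a gene with k reads out of a
library total N (the same total used as the RPM denominator, so test and
fold change share one frame), two models are compared:

* **Shared**: one probability p of accumulating a read, common to both
  libraries, integrated over a Beta(a, b) prior — a beta-binomial marginal
  over the pooled counts.
* **Independent**: each library has its own p, giving the product of two
  beta-binomial marginals.

Both evidences are computed in log space from log-Beta and log-binomial
terms and are finite up to totals of 10⁸. With equal prior model odds the
posterior probability of the shared model,
`p_same = 1 / (1 + exp(log m_indep − log m_shared))`, is used as the
per-gene p-value. This is a posterior model probability, **not** a
frequentist tail probability; Bonferroni control over the tested gene set
is applied to it as the analysis prescribes, and the family-wise error
this yields on null simulations is checked empirically rather than assumed.
Defaults a = b = 1 (uniform) are exposed in `prior_spec()` and recorded in
the output attributes, since the construction leaves the hyperparameters
free.

Weighted counts are rounded half-to-even only for this test (the evidence
requires integer combinatorics); fold changes stay fractional and use a +1
RPM pseudocount on both sides so zero-count genes remain finite. A gene is
called significant when `p_same < alpha / n_tested` **and** its absolute
log2 fold change reaches the 2-fold threshold — the two criteria are
intersected, matching how significant-and-2-fold gene fractions are
reported.

A property worth knowing: with the uniform prior, the independent-model
evidence of one library is exactly 1/(N+1) regardless of k, so the
detection threshold — the count change needed for `p_same` to cross a
Bonferroni cutoff — grows roughly with log N while counts grow linearly
with depth. Deeper libraries therefore always help power; the package's
validation runs use 10⁶-read libraries for differential tests (about a
tenth of a typical real library) and 10⁵ reads where only counting or
profiling behavior matters. These problem sizes are the package's own
scaled-down study conditions, stated here so the numbers in
`scripts/acceptance.R` are interpretable.

For the mRNA-versus-22G quadrant analysis, genes are partitioned by the
signs of the two fold changes; exactly-zero values go to a separate
`boundary` category (a measure-zero event on real data, deterministic on
synthetic) so proportions always sum to one.

## Profiles

Depth is computed in spliced transcript coordinates, 5′→3′ of the
annotated mRNA (minus-strand genes are flipped), with full read coverage:
every covered position receives the read's RPM-normalized weight. Coverage
rather than 5′-end counting was chosen because per-position depth
describes where silencing machinery acts along the transcript; a 5′-end
variant would sharpen site peaks but change none of the conclusions the
profile module is used for.

Metagenes rescale every transcript to 100 bins by the floor rule
`bin = floor(position × 100 / length)`, which conserves mass exactly for
any length — the suite property-tests this against a position-by-position
oracle for lengths 1..5000.

3′-end targeting enrichment is the fraction of a transcript's 22G mass in
its last `ceiling(0.15 × length)` positions. The published class anchors
(<15%, 16–30%, >30%) leave (15%, 16%) unassigned; the boundaries are
closed as ≤0.15 / (0.15, 0.30] / >0.30 to make classification total while
preserving every printed anchor. A uniform transcript sits exactly at the
non-enriched boundary by construction.

Site-centered profiles take 100-nt windows (anchor −50 .. +49) around the
transcript position paired to piRNA nucleotide 10 and average depth per
relative position across sites. Window positions outside the transcript
are excluded from that position's mean rather than zero-filled, to avoid
suppressing edges.

## IP ratios

`log2((HRDE-1 IP RPM + ρ) / (CSR-1 IP RPM + ρ))` per gene with ρ = 0.1 RPM
by default — distinct from the differential module's 1 RPM pseudocount
because ratio distributions are compared as boxplots and zeros must stay
finite without dominating. No pseudocount or zero-handling is prescribed
for this ratio upstream, so the choice is recorded on the output. The four
classes partition the line at −2.8, −1.82 and 0; since the printed anchors
are strict at −2.8 ("< −2.8") and 0 ("> 0"), boundary values fall to the
middle classes.

## Imaging

The DoG band-pass subtracts the large-sigma blur from the small-sigma blur
(σ = 1 and 4 by default). The two sigmas are listed upstream without a
subtraction order; small-minus-large is the only order that gives puncta a
positive response, which the subsequent bright-object thresholding
requires. Filtering is per 2-D slice with circular boundary, through
explicitly constructed normalized Gaussian kernels of radius 3σ.
Thresholds are a required, recorded number ("manual and uniform" in the
original workflow). Colocalization is counted over all thresholded voxels
of the stack, and puncta are 8-connected 2-D components per slice —
touching spots merge. EBImage's labeller is 4-connected, so the package
carries its own two-pass 8-connectivity labeller.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is validated.

* **Counts** are negative-binomial (gamma-Poisson) with a single global
  size parameter, default 100 (≈10% extra-Poisson coefficient of
  variation). The upstream construction does not report an empirical
  overdispersion, and the no-replicate binomial test models sampling noise
  only, so the default describes two libraries drawn from a common
  biological pool; it is a tunable, not an estimate. Heavier
  overdispersion models biological replicates, which this test is not
  designed for — at size 50 the null family-wise error is no longer
  nominal, which the generator's defaults deliberately avoid.
* **Abundances** λ are lognormal (meanlog log 40, sdlog 0.6) with WAGO and
  CSR-1 targets carrying a 3× multiplier, reflecting that target classes
  are defined by robust 22G coverage. The dynamic range is deliberately
  narrower than real libraries (which span 3+ orders of magnitude) so that
  recovery statistics are not dominated by genes that are untestable at
  scaled-down depth — passing tests therefore show correctness of the
  machinery, not that every real gene is detectable.
* **Fold effects**: in the mutant, piRNA-dependent WAGO targets (half of
  the WAGO class) have φ = 0.25 and enhanced-HRDE-1 CSR-1 targets (15% of
  the CSR-1 class) have φ = 4, with anticorrelated mRNA effects (ψ = 2 and
  0.5). These subsets are sized so the planted up- and down-shifts roughly
  cancel in library composition, keeping RPM fold changes aligned with
  planted per-gene effects. The `reduced_hrde1` subset coincides with the
  piRNA-dependent genes — one planted mechanism.
* **Positional structure**: read positions mix a uniform head component, a
  3′-tail component with weight τ (CSR-1 targets 0.40, others 0.15 — the
  uniform expectation), and per-site Gaussian bumps (half-width 10 nt,
  mixture weight 0.15 per site) centered on piRNA-site anchors. The
  two-component tail construction makes τ itself the recoverable parameter
  of the 3′-enrichment classifier. Anchors are placed at least 80 nt from
  the transcript ends and outside the tail so windows and tail fractions
  stay clean.
* **IP enrichment** ε: HRDE-1 IP enriches WAGO targets 4× and
  enhanced-HRDE-1 CSR-1 genes 2×; CSR-1 IP enriches CSR-1 targets 4×. The
  two IPs are compositionally balanced so RPM ratios track ε ratios.
* **Multimappers**: duplicated transposon pairs share one abundance;
  every read from a pair is reported at both loci with `n_loci = 2`, so
  weight conservation is exactly testable.
* **Genes are single-exon** by default. Spliced and minus-strand handling
  is exercised by unit tests with hand-built multi-exon features; keeping
  generator genes single-exon avoids antisense reads spanning introns,
  which genomic alignments of small RNAs cannot represent.
* **Images**: Gaussian spots (σ = 2 px) on clamped [0, 1] background
  noise; a planted fraction of channel-A centers coincide with channel-B
  centers and all other centers keep a minimum 8 px separation, so the
  pixel-level colocalization of the chain equals the planted fraction up
  to boundary-pixel noise.

What the generator does **not** emulate: sequence content beyond length
and 5′ nucleotide, quality scores, adapter artifacts, overlapping genes,
isoforms, wide abundance ranges, and spatially varying image background.
Passing recovery tests on this generator demonstrates that the analysis
machinery is correct under its stated model; it does not certify
performance on real libraries where those un-modeled features matter.

## Numerical choices and degenerate inputs

* Evidence terms use `lbeta`/`lchoose` exclusively; the suite checks them
  against adaptive quadrature to 10⁻⁶ over the full small-count grid and
  at representative large counts.
* Zero-data evidence (N₁ = N₂ = 0) is exactly 0 on both sides.
* A library whose mapped reads are all structural has RPM denominator 0:
  it is flagged degenerate at counting time and normalization refuses it
  explicitly rather than emitting NaN.
* Zero-mass depth tracks classify as `missing`, never as a tail class.
* Rounding for the test is R's `round()` (half-to-even), so .5 weights
  from 2-locus multimappers do not bias upward.
* `run_pipeline` derives per-library seeds by fixed offsets from the run
  seed; identical config + seed reproduce byte-identical tables (MD5s in
  the manifest), and any stage failure aborts with the stage named.

## Known limitations

* `p_same` is a posterior model probability; its Bonferroni-corrected use
  follows the published analysis but should not be read as frequentist
  FWER control beyond what the null simulations demonstrate.
* Counting is not isoform-aware and antisense assignment requires only a
  single nucleotide of overlap.
* The IP-ratio module compares two libraries normalized on their own
  denominators; strong compositional differences between IPs shift all
  ratios coherently.
* The imaging module does no deconvolution or 3-D segmentation and fits no
  point-spread functions; it reproduces the threshold-and-count
  quantification it models.
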