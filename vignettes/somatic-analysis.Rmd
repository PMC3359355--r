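---
title: "Somatic analysis of tumor/normal pairs: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic analysis of tumor/normal pairs: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticpair)
```

This vignette is the package's account of the science it implements: the
statistical model of the genotype caller, the somatic indel and copy-number
procedures, the synthetic data the test-bed rests on, and the design
decisions taken where the underlying method descriptions were open.

## The genotype model

A diploid locus has three genotypes with expected alternate-allele
fractions 0 (hom-ref), 0.5 (het) and 1 (hom-alt). The caller is
non-parametric: it compares the sampled allele distribution of the pileup
on each strand with these expected distributions and picks the nearest.
Two choices make this concrete.

**Quality weighting.** Each retained base contributes weight
$w = 1 - 10^{-Q/10}$, the probability that the call is correct. A Q30 base
carries weight 0.999, a Q10 base 0.9, a Q2 base 0.37; a Q0 base carries no
information and is trimmed from the pileup before any comparison. The
per-strand evidence is the weighted alternate fraction
$\hat p = \sum w_i \mathbf{1}[b_i = \mathrm{alt}] / \sum w_i$. With equal
qualities this is exactly the unweighted allele fraction, and adding an
alternate observation (or raising an alternate base's quality) can never
decrease it — both properties are enforced by tests.

**The distance.** For a distribution supported on the two points
\{ref, alt\}, the Kolmogorov–Smirnov sup-distance between the sampled and
the expected distribution reduces to $D_g = |\hat p - p_g|$. We adopt this
two-point reduction as the canonical statistic: it is fully specified,
ranges over [0, 1], and inherits the non-parametric character of a KS
comparison. Ties between genotypes (possible only at $\hat p$ exactly
0.25 or 0.75) resolve toward the lower expected fraction, i.e.
conservatively toward the reference.

**Calling tiers.** A *high-quality* (standard) call requires each strand
to have at least `min_depth_per_strand` retained observations, both
strands to select the same genotype, and both distances to be at most
`strict_max_distance`. A variant call therefore always has support on both
strands, which suppresses strand-specific artifacts. The
*variant-consensus* mode, applied to the tumor sample, additionally calls
a variant when the pooled-strand fraction is within
`lenient_max_distance` of a variant genotype and each strand carries at
least `min_alt_obs_per_strand` alternate observations. We interpret the
consensus mode as relaxing the distance requirement but *not* the
two-strand principle — the per-strand alternate-observation floor is the
remaining strand test. A locus is somatic when the tumor is variant at
either tier and the normal is a high-quality homozygous reference; any
other normal state is recorded as `germline` or `ambiguous_normal`, never
silently dropped.

**Defaults.** `strict_max_distance = 0.15`, `lenient_max_distance = 0.25`,
`min_depth_per_strand = 4`, `min_alt_obs_per_strand = 2`. At 30X per
sample strand depth is ~15, so a true het (fraction 0.5) passes the strict
bound per strand with probability ≈ 0.9 and the pooled lenient bound
essentially always; a hom-ref site with a 0.1 % error rate essentially
never accumulates two alternate observations per strand of the same base.
All four are exposed through `caller_thresholds()`. The dual-caller
"compiled" step of the original workflow (two independent callers
intersected) is emulated by intersecting the standard and
variant-consensus configurations, with the union kept as a review set —
the second in-house caller was never specified beyond its existence, so
the two-configuration intersection is documented as an emulation, not a
reconstruction.

**Tri-allelic sites** evaluate only the non-reference base with the
highest pooled weight; remaining bases stay visible in the pileup but are
not genotyped.

## Somatic indels

Discovery is restricted to tumor pairs whose insert size lies strictly
inside `(50, 500)` — interval notation is read as open bounds, so 500
itself is removed — which strips anomalous pairs whose gapped alignments
would otherwise mimic indels. Candidates are distinct
(contig, position, kind, sequence) gap operations with at least
`min_support = 2` supporting reads, left-normalized with the standard
trim-and-extend procedure so that events in homopolymer or repeat context
have one canonical coordinate. The somatic test inspects the normal sample
across `[start − 5, end + 5]`, boundaries inclusive; a candidate is
somatic only when no insertion/deletion operation of any normal read
intersects the window. A window with no overlapping normal reads is
conservatively non-somatic (`no_normal_coverage`): absence of evidence in
the normal is not evidence of somatic origin.

## Clone-coverage copy number

A *clone* is the full fragment interval — both mates plus the unsequenced
interlying region. Insert statistics are estimated from proper pairs, and
pairs outside mean ± 2 SD are excluded; the method description's phrase
for this rule is self-contradictory ("within 2 standard deviations
outside"), and we fix the reading that matches its evident intent:
exclude insert-size outliers beyond two standard deviations. Per-base
clone depth is averaged over non-overlapping 2 kb windows (a terminal
partial window is kept if it spans at least half a window), and windows
are normalized by the genome-wide mode of integer per-base clone depth
over covered bases, ties broken toward the smaller depth. The mode is
taken per base rather than per window — at 2 kb a window histogram is too
coarse to have a stable mode at desk scale. Relative copy number is
`log2((tumor_norm + ε)/(normal_norm + ε))` with ε = 0.01, oriented so
positive means tumor gain; windows whose normal normalized coverage falls
below 0.1 are masked as uncallable. Because both tracks are
mode-normalized, a global scaling of either sample's depth cancels
exactly — verified by doubling-clones tests.

Segmentation is deliberately simple: windows beyond ±0.3 in log2 form
maximal runs, runs of at least 3 consecutive windows become segments, and
shorter excursions fold into the surrounding neutral state. No
segmentation rule was given for the original analysis; a threshold
run-length rule is transparent, has two interpretable knobs, and at the
simulated noise level (window-mean log2 SD ≈ 0.1) recovers 200 kb
segments with zero-window boundary error. Genes are gained/lost when at
least half the gene span overlaps a gain/loss segment.

## Coding consequences and the timeline

Codon mapping anchors at the CDS start and counts in transcription
direction; minus-strand models reverse-complement, and alternate alleles
are complemented onto the coding strand before codon substitution.
Translation uses the standard genetic code (via Biostrings); effects are
synonymous, nsSNP, nonsense (stop gain) or stop-loss, and indel
consequences inside a CDS are frameshift when the length is not a
multiple of 3. Models whose total CDS length is not divisible by 3 are
rejected with a warning rather than silently truncated.

The longitudinal matrix holds the observed codon per dated sample and
validated site, with a reference-codon footer; the mutant codon of a site
is the unique non-reference codon observed in its column, and any other
cell content is a validation error. Samples sharing a date are treated as
replicates, a mutation being present at that date if present in any
replicate — the source material treats same-date samples as concordant,
and the any-replicate rule is the weakest assumption that preserves that
reading. N/A cells are skipped in evaluation. A site is
present-at-diagnosis when the earliest evaluable date shows the mutant
codon, acquired when the earliest shows reference and a later date the
mutant, and inconsistent when a mutant observation is followed by a
reference-only date (a reversion pattern that would indicate an assay
problem rather than biology).

## The synthetic study

The generator emulates what the downstream methods need to be exercised:

* a small diploid genome (default 5 Mb over three contigs) with uniform
  base composition;
* germline SNPs at 1e-3/bp (the human heterozygosity scale), two-thirds
  heterozygous, with alternate alleles drawn with transition probability
  0.68 so the germline call set shows a Ti/Tv ratio near 2.1, and 87 %
  of sites written to a known-sites catalogue emulating a dbSNP-style
  membership fraction;
* 200 somatic SNVs at VAF 0.5 and 30 somatic plus 20 germline indels of
  1–7 bp (the size range of the motivating study's validated coding
  indels), all left-normalized at generation so truth coordinates are
  canonical;
* a copy-4 gain and a copy-1 loss segment of 200 kb each;
* paired-end 100 bp reads with fragment length Normal(325, 40) (the
  300–350 bp library target), 60X tumor / 30X normal, i.i.d. substitution
  errors at 0.1 % (the Q30 scale), per-base qualities from a
  two-component mix (Q30–Q38 with 2 % zero-quality bases, so the
  zero-quality trimming rule is always exercised), FR orientation with
  random first-in-pair, and 2 % PCR duplicate pairs sharing both mates'
  coordinates.

Haplotype structure is respected: germline SNPs are baked into two
haplotype strings and each fragment samples one haplotype, so mate pairs
are allele-concordant. Somatic events are patched per fragment with
carrier probability equal to the VAF, which keeps the observed VAF
independent of local copy number. Reads are emitted pre-aligned at their
true coordinates — alignment is out of scope, and exact coordinates make
recovery tests sharp. Indel-carrying reads encode the gap in their CIGAR
so the indel caller parses real gap operations.

Known simplifications, and hence what passing tests do *not* show about
real data: no GC or mappability bias, no error-rate dependence on cycle
or context, no chimeric pairs or translocations, no quality-coupled
errors (errors are independent of the emitted quality string), reads
starting strictly inside a deleted interval fall back to the reference
haplotype, and duplicate pairs are exact copies. Sensitivity and
false-call numbers measured here are therefore upper bounds on real-data
behavior; the package's claims are about the correctness of the
computations, not about field performance of the thresholds.

Determinism is part of the contract: every generator stage seeds its own
RNG stream derived from the configured seed, and a full pipeline re-run
with the same config and seed reproduces byte-identical outputs (checked
by md5 manifests).

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere internally; BED and
  bedGraph conversion happens only at I/O boundaries.
* Overlapping mates are counted independently in pileups — the simplest
  policy that keeps per-strand depths interpretable; with fragments ≥
  300 bp and 100 bp reads, overlap is rare in the simulated studies.
* Deletion-spanning reads contribute no base observation at deleted
  positions and are therefore absent from depth at those loci.
* An empty strand yields an *undefined-evidence* fraction (NA), distinct
  from an observed fraction of 0; a locus with no alternate observations
  at all has alternate fraction 0 on any covered strand.
* Insert-statistics estimation refuses to run below 100 proper pairs.
* A genome whose mode clone coverage is 0 is not callable and raises an
  error rather than producing unnormalized tracks.
* Genotype-distance ties (exact 0.25/0.75 fractions) go to the
  reference-ward genotype; such ties lie outside the strict threshold, so
  they can never create or destroy a high-quality call.
* `run_all` validates its assembled genome summary against the underlying
  call lists before writing, and a missing input path fails before any
  stage runs.

## Problem sizes

The reference study conditions used by the test suite and the acceptance
script are the generator defaults above (5 Mb, 60X/30X). Unit and
property tests run on 20–200 kb genomes at 10–200X; the caller/oracle
equivalence check enumerates all 125,969 strand/base/quality count
patterns with up to 12 observations. These sizes were chosen so the full
suite exercises every code path at depths representative of the
motivating study while remaining comfortable on a laptop.

## Limitations

Single-sample pair, ploidy 2, biallelic evaluation per locus; no purity
or subclonality model (the generator exposes VAF directly); no local
realignment or assembly, so indels longer than ~7 bp in repetitive
context are out of scope; no GC correction, allele-specific copy number
or breakpoint-level SV detection; one transcript per gene in annotation;
and the external effect-predictor labels carried by the validated-SNV
fixture are pass-through strings, not recomputed predictions.
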