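---
title: "Position-specific intron retention and histone-mark shifts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Position-specific intron retention and histone-mark shifts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

`retentionshift` quantifies intron retention (IR) from spliced RNA-seq
alignments, asks whether retention gains and losses between two conditions
fall at different positions along the gene body, and relates those
positional changes to a promoter-proximal redistribution of co-transcriptional
histone marks (H3K36me2/me3) measured by ChIP-seq. It also predicts which
retention events create premature termination codons (PTCs) and hence
candidate substrates of nonsense-mediated decay (NMD). Every stage is
exercised end-to-end on seeded synthetic data, so the whole pipeline is
testable on a laptop with no external files.

## The retention index

For each intron the package computes an intron retention index

IRI = FPKM(intron) / mean(FPKM(left flanking exon), FPKM(right flanking exon)),

where FPKM is fragments per kilobase of feature per million uniquely mapped
fragments. An IRI of 0 means fully spliced, 1 means the intron is covered
like its neighbours (fully retained). When the flank mean is zero the index
is undefined and reported as `NA`, never silently 0/0.

Because overlapping transcript structures can place an exon of one isoform
inside an intron of another, retention is measured only on
*non-overlapping units*: candidate introns are the gaps between consecutive
exons of each transcript merged across transcripts; every base that
overlaps any exon of the configured universe is subtracted, and fragments
shorter than `min_fragment` (default 10 bp, to avoid 1-bp slivers) are
dropped. Exon units are defined reciprocally. The exon universe defaults to
*all* annotated exons of all genes on either strand — the conservative
choice; `exon_universe = "same_gene"` restricts it.

A fragment *supports* an intron when at least one aligned block overlaps it
by at least 1 bp (configurable to a minimum overlap or full containment).
A spliced fragment whose gap spans the intron contributes nothing — a
spliced read is evidence against retention. Counting is unstranded by
default; a flag enables strand matching for stranded protocols.

## Differential retention

IRI values are averaged over replicates within each condition and compared
as `(IRI_b + eps) / (IRI_a + eps)` with `eps = 0.01`. The pseudocount only
guards zero denominators; at typical index magnitudes (0.05–1) it barely
perturbs the ratio. An intron is called *up* when the ratio is at least
2-fold and the quality filters pass, *down* symmetrically. The filters —
supporting reads ≥ 3, intron length coverage ≥ 80%, host-gene FPKM ≥ 1,
both flanking exons FPKM > 1 — are evaluated in the condition with the
higher averaged IRI, i.e. the condition asserting that retention exists;
`filter_scope = "both"` requires them in both. Calls use the fold rule
only (no per-intron test), so there is no multiple-testing correction to
make.

Genes are partitioned into up-only / down-only / both / none by their
calls, and the positional question is answered by a two-sided two-sample
Kolmogorov–Smirnov test on the gene-body positions of up vs down introns.
A position is the intron midpoint mapped to a fraction of the TSS→TTS span
(0 at TSS), mirrored on the minus strand; the 5′-end convention is
available behind a flag. The exact KS p-value is used when both groups
have ≤ 25 events, the asymptotic Kolmogorov series otherwise. Ties are
handled by the plain ECDF sup-difference without jittering.

## ChIP metagene profiles and the shift rule

Each gene longer than 500 bp is summarised as 500 bins: 100 bins over the
2-kb upstream flank, 300 over the gene body (TSS→TTS annotation span, not
merged exons), 100 over the 2-kb downstream flank. A bin's value is the
mean per-base read coverage within it; body bins use fractional bin edges
computed from the interpolated cumulative coverage, so bin means times bin
width always sum back to the total coverage regardless of gene length.
Profiles are scaled to a 10-million-read library and calibrated against
the identically binned input control by *subtraction* — the shift rule
below needs signed values around zero, so the difference is the default
and a log2-ratio mode sits behind a flag. Minus-strand profiles are
flipped so bins always run 5′→3′.

A gene's mark is called *promoter-proximally shifted* when, in the
mutant-minus-wild-type difference, at least 30% of the front-half body
bins (45 of 150) are strictly positive **and** at least 30% of the
rear-half bins are strictly negative. Flank bins are ignored and no
magnitude threshold is applied; zeros count for neither side. Genes are
then typed by which marks shift: I (me2 only), II (me3 only), III (both),
IV (neither). Difference heatmaps order genes by the number of strictly
positive body bins ("red bins"), ties broken by gene id.

## What the synthetic data emulates

The generator builds a stated world and the tests measure the pipeline
against it; its defaults were fixed up front and are not tuned per test.

*Annotation.* 60 genes on two chromosomes (one transcript each), 4–7 exons
of 150–350 bp, introns 150–350 bp, intergenic gaps 2.5–4 kb, random
strands, uniform-composition genome. One transcript per gene keeps the
intron-unit truth table in one-to-one correspondence with annotated
introns; multi-isoform unit arithmetic is tested separately on toy
annotations against a per-base oracle.

*RNA-seq.* Fragments (100 bp, single-end) are drawn per gene by Poisson
superposition over the pre-mRNA: starts on exons arise at the gene's
expression rate, starts inside intron *j* at that rate times the true
retention *r_j*, and a fragment crossing a splice junction traverses the
intron with probability *r_j* (emitting a contiguous block) or skips it
(emitting a gapped, spliced block). This is the exact marginal read
process of a mixture of molecules with independent per-intron retention,
so per-base intron coverage is *r* times exon coverage and the IRI
estimates *r* without the flank-inflation bias a naive
"extra intronic reads on top of full exonic coverage" simulator has.
Baseline retention is 0.15; planted changes move it 4-fold (0.15 to 0.6),
with IRI-up introns sampled at Beta(2,5) gene-body positions (5′-biased)
and IRI-down introns at Beta(5,2) (3′-biased), 20% of introns each.
Replicate noise is a Gamma rate multiplier with coefficient of variation
0.15 per gene and per intron per library — the scale of gene-level
biological replicate variability commonly seen in bulk RNA-seq. Default
depth (30 000 exonic fragments over 60 genes) puts ≈ 125 fragments on a
typical flanking exon, matching the "deep coverage" recovery conditions.

*ChIP-seq.* Each gene gets a per-mark shape in the mutant: `flat`
(unchanged), `reduced` (whole window times 0.25; 50% of genes), or
`shifted` (front body half times 1.5, rear half times 0.2; 25% of genes);
wild type is always flat, flanks sit at half the body level. Reads are
placed by sampling a bin proportional to intensity times width, then
uniformly within it; the input is uniform over the genome at matched
depth. Libraries are sequenced to a *fixed total depth*, so the global
loss of the mark on reduced genes inflates the remaining genes after
10-million normalization — exactly what fixed-depth sequencing of a
mutant with a globally reduced mark does. This composition effect is what
makes the sign-only shift rule specific: an unchanged (flat) gene sits
coherently *above* wild type across its whole body, so it cannot satisfy
the front-positive **and** rear-negative rule unless its gene-level noise
draw is extreme (measured false-positive rate ≈ 2% at the default noise).
A generator without the global reduction would leave flat genes centred
on zero and the sign rule would fire on most of them — the rule is only
meaningful in the biological regime it was designed for, a genuine
limitation worth knowing.

*What a green test does not establish.* The generator has no sequencing
errors, GC bias, fragment-length distribution, multi-mapping, ambient
background in ChIP, or isoform-level expression differences; genes do not
overlap. Green acceptance tests certify the estimators and callers under
the stated world, not performance on real libraries.

## Numerical and design choices

- **Containers and coordinates.** Internally everything is Bioconductor:
  `GRanges`/`GRangesList` (1-based, closed). GTF/GFF3 and BED conversions
  happen at the I/O boundary via `rtracklayer`; BAM/SAM via
  `GenomicAlignments`/`Rsamtools`. Interval subtraction is
  `GenomicRanges::setdiff`, checked against a per-base brute-force oracle
  in the tests.
- **Position statistic.** The intron midpoint (on the continuous 0-based
  axis, so mirror symmetry is exact); the annotation never states start
  vs midpoint conventions, and the midpoint is insensitive to which end
  of a long intron an overlap trimmed.
- **Flanking exons.** The genomically nearest surviving exon units of the
  same gene; an intron that loses a flank to subtraction carries `NA`
  and an undefined IRI rather than a guessed denominator.
- **Library size** is the number of uniquely mapped fragments in the
  file, not per-chromosome; FPKM is invariant under jointly doubling
  counts and library size (property-tested).
- **Differential expression** (used by the NMD caller and the class-wise
  expression comparison) is a Welch t-test on log2(FPKM + 1) across
  replicates behind a pluggable function — heavyweight external
  differential-expression tooling is deliberately not reimplemented, and
  the simple test is replaceable.
- **PTC rule.** Distance is measured in spliced coordinates from the
  *end* of the stop codon to the last exon–exon junction; `> 50 nt` is
  strict, single-exon transcripts are never PTC. Measuring from the
  stop's first base is available behind a flag and shifts distances by 2.
- **Degenerate inputs.** Empty alignment sets count zero everywhere;
  genes shorter than 500 bp are excluded from metagene profiles with a
  recorded reason; classes with fewer than two genes skip t-tests with a
  flag; constant signal defines Spearman rho as 0.

## Acceptance-scale decisions

The acceptance suite pins every criterion at the defaults above. Two
scale choices deserve a note. First, the end-to-end scenario uses a
160-gene panel (same per-gene depths as the 60-gene default): a 5%
false-positive bound on flat genes is not estimable from the default
panel's 15 flat genes, where a single tail event already reads as 6.7%.
Second, the KS calibration uses 1000 null replicates at n = 200 per
group, enough to place the type-I error within the stated window
without dominating the test budget. Simulated depths are far below a real
experiment (tens of thousands of fragments, not tens of millions); the
per-feature coverage they induce matches the "deep coverage" conditions
the recovery criteria state.

## Known limitations

- The shift caller inherits the sign-only rule's dependence on a global
  normalization offset (above); on data without a global mark change its
  false-positive rate on truly flat genes would be high.
- One transcript per simulated gene; alternative isoforms only enter via
  the unit-construction logic, not the read simulator.
- The nuclear/cytoplasmic comparison and the CHX/DMSO NMD comparison
  re-use the same two-condition machinery with relabelled inputs; no
  fraction-specific normalization is attempted.
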