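---
title: "Methods: two-population ancestry estimation and phase-switch QC"
author: "admixqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-population ancestry estimation and phase-switch QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixqc)
```

# Scope and model

`admixqc` implements the computational core of a two-way admixture analysis
for a pedigreed colony descended from two divergent source populations
(referred to throughout as *olive*, ancestry code 0, and *yellow*, ancestry
code 1, after the baboon taxa that motivate the defaults). The package
covers: genetic-map conversion; Weir–Cockerham F~ST~ and
ancestry-informative-marker (AIM) panel design; supervised and unsupervised
two-way global ancestry estimation; a hidden-Markov local-ancestry caller;
phase-switch detection and correction ("unkinking") anchored on F1 hybrids;
trio Mendelian local-ancestry audits and pedigree-label audits; and a
synthetic-data generator that produces phased genotypes with exact
ancestry-tract truth for validation.

# The synthetic-data generator

The generator emulates the statistical structure of the colony data rather
than its sequence content.

**Founder divergence.** Per-marker population frequencies follow the
Balding–Nichols model: around an ancestral frequency $p$ drawn uniformly on
$[0.05, 0.95]$, each population's frequency is an independent draw from
$\mathrm{Beta}\!\left(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\right)$, with
divergence parameter $F$ defaulting to 0.4 — the weighted F~ST~ scale
observed between the two source taxa. Bounding $p$ away from 0 and 1 avoids
degenerate Beta shapes. A configurable fraction of markers (default 0.5%) is
instead fixed for alternate alleles, mirroring the substantial number of
fixed differences between the source populations. No generative model is
claimed by the original analysis; Balding–Nichols is the simplest standard
choice whose Weir–Cockerham estimate converges to $F$.

**Founders and crosses.** Founders are Hardy–Weinberg draws from their
population's frequencies. Gametes recombine under the Haldane
(no-interference) model: per chromosome, the crossover count is Poisson with
mean the chromosome's genetic length in Morgans, crossover positions are
uniform on the genetic-distance scale, and parental haplotypes alternate
from a fair starting choice. Crossovers snap to the following inter-marker
boundary, so truth tracts are exact on the marker grid. The default genome
is 4 chromosomes of 50 Mb at a uniform 1 cM/Mb (desk-scale, while leaving
hundreds of 100-kb AIM windows per chromosome and roughly 0.5 Morgan per
chromosome). The colony's effective number of generations since admixture is
not fixed by the source material; it is an explicit plan parameter
(`makeColonyPlan(nGen = ...)`), defaulting to 2 in the bundled pipeline.

**Degradation.** Phase-switch errors are injected by exchanging the
suffixes of a sample's two haplotypes — allele sequences *and* truth
ancestry — from a chosen inter-marker boundary to the chromosome end,
exactly how statistical-phasing switch errors manifest; the injected
boundaries are returned as ground truth. Missingness is genotype-level
(both haplotype values masked jointly), as sequencing missingness appears in
a VCF.

What the generator does **not** emulate: linkage disequilibrium within
populations (markers are independent given the frequencies), mutation and
drift dynamics, imputation artefacts beyond missingness, and
sequencing-error genotypes. Consequently, passing tests demonstrate
correctness of the estimators under the declared generative model, not
robustness to every pathology of real low-coverage data.

# F~ST~ and AIM selection

Per-marker F~ST~ is the Weir–Cockerham (1984) two-population diploid
estimator, computed from marker-wise complete cases via the variance
components $a$ (among populations), $b$ (among individuals within
populations) and $c$ (within individuals); the weighted genome-wide estimate
is the ratio of sums $\sum a / \sum (a+b+c)$ over markers with defined
components, matching PLINK's weighted mean. Markers where a population has
fewer than two usable diploids are flagged rather than dropped. A marker is
*fixed* when the observed frequencies are exactly 0 and 1; at equal sample
sizes this coincides with an estimate of exactly 1.

AIM selection proceeds in four stages: (1) retain markers with F~ST~
strictly above 0.8; (2) bin survivors into non-overlapping 100-kb windows
anchored at coordinate 0 (the simplest reading of "binned") and keep the
highest-F~ST~ marker per window, ties resolved to the first marker in input
order; (3) LD-prune the kept set within each reference population separately
with window 2, step 1, r² 0.05; (4) intersect the per-population survivors
and prune once more on the combined reference samples. Intersection (rather
than union) at stage 3/4 is used because it is the only reading under which
the final panel respects the r² constraint within each population
separately.

**Pruning semantics.** `ldPrune()` makes a single pass of windows anchored
on the input marker list, resolving offending pairs within a window to
exhaustion before advancing; the removal rule — drop the lower-MAF member,
ties to the later-positioned marker — is declared rather than bit-matched to
any external tool, whose internal tie handling is undocumented. A note on
small panels: with $n$ reference samples the *chance* r² between independent
markers is of order $1/(n-1)$ (≈ 0.125 at $n = 9$), far above a 0.05
threshold, so strict pruning at reference-panel sizes removes markers
aggressively by construction. An iterated-to-fixed-point variant was
evaluated and rejected: it cascades under chance correlation until almost
nothing survives, destroying the panel's genome-wide coverage. The
single-pass panel retains enough markers that ancestry estimated from the
AIMs alone reproduces full-panel estimates with R² well above 0.95 on
cohorts of 100+ admixed individuals, which is the property the panel exists
to deliver.

# Global ancestry

The supervised estimator treats the two alleles of a genotype as independent
draws from the mixed frequency $q\,p_{0m} + (1-q)\,p_{1m}$ and maximizes the
resulting binomial log-likelihood over $q \in [0,1]$ by bracketed scalar
optimization (tolerance 1e-6), with the boundary values evaluated explicitly
so that $q = 0$ or $1$ is exact. Reference frequencies are clamped to
$[10^{-4}, 1-10^{-4}]$; missing genotypes are skipped per sample. The
likelihood is concave in $q$ for fixed frequencies, so the bracketed
optimizer finds the global optimum; dosage (not phase) is used so degraded
or unphased data still works.

The unsupervised K = 2 fit alternates the supervised $q$ update with an
EM frequency update from expected allele-origin counts, stopping when the
log-likelihood gain falls below 1e-6 (default cap 200 iterations;
non-convergence is flagged, not fatal). Label switching is resolved with
taxon labels when available, else by the first sample's majority. A
homogeneous cohort is a genuine failure mode: K = 2 then overfits sampling
noise, producing clusters separated by roughly the binomial noise floor.
The fit is therefore flagged *degenerate* when the mean cluster-frequency
separation is below twice the expected half-normal separation at the fitted
effective sample sizes — a diagnostic calibrated to sit between the
overfitting regime (~1× the floor) and genuine structure at the divergence
scales this package targets (≥3× the floor).

Tract-based global ancestry is the bp-length-weighted share of ancestry-0
tracts over both haplotypes. Length weighting (rather than marker-count
weighting) matches the karyogram intuition; on truth tracts the two
estimators agree to within 0.03 on simulated cohorts.

# Local ancestry

The two-state HMM is a deliberate, declared stand-in for a full
conditional-random-field caller: downstream phase-switch QC consumes
*tracts*, not caller internals, and the msp reader lets genuine RFMix
output be substituted. Emissions are the clamped population frequencies
(error floor ε = 0.005); the transition between consecutive markers at
genetic distance $d$ Morgans is $\mathrm{switch} = (1 - e^{-g d}) \cdot
\mathrm{prior}(\text{other})$, with $g$ the generations since admixture
(default 8, near a seven-generation colony; the bundled pipeline uses the
simulated truth of 2). Decoding is Viterbi. As $g \to \infty$ the model
collapses to independent per-marker classification; as $g \to 0$ to a single
whole-chromosome call — both limits are tested. When the two populations'
frequencies are essentially indistinguishable the output is flagged
uninformative. Tract physical bounds are `[first marker position, next
tract start)`, the terminal tract extending to the last marker position + 1.

# Phase-switch QC

In an F1 hybrid every genuine ancestry change must appear as a *joint,
complementary* switch: haplotype 0 changes X→Y exactly where haplotype 1
changes Y→X. Joint switches are therefore phase-switch candidates, and
requiring exact boundary coincidence is sound because calls live on a shared
marker grid — a tolerance window would only invite false merges. One-sided
ancestry changes are never "corrected": they may be genuine admixture (the
source colonies contain yellow founders carrying olive tracts). Unkinking
scans left to right and exchanges haplotype suffixes at each joint boundary;
it never changes the per-marker allele multiset nor tract-derived global
ancestry, and it is idempotent. Both tract counts and switch counts
(tracts − 1 per chromosome, summed) are reported, since "switches" is used
ambiguously in the field; the acceptance checks use joint switches.

The trio audit flags a marker when the offspring carries two copies of one
ancestry while at least one parent is homozygous for the other — that parent
must transmit its ancestry. Only homozygous-ancestry evidence is used;
heterozygous configurations are never flagged. Marker grids must match
exactly; silent intersection is refused. Pedigree-label audits use strict
inequalities (olive-labelled with olive ancestry < 0.90; yellow likewise;
cross-labelled with either ancestry > 0.90, "pure-like" above 0.99),
matching how such thresholds are phrased in practice.

# Numerical and I/O conventions

* Coordinates are 1-based internally and in VCF/map files; the BED-like
  tract format is 0-based half-open, converted only in the I/O layer.
  Marker indices in tracts are per-chromosome, 1-based, half-open.
* Map positions outside the mapped span clamp to the terminal cumulative cM
  (common phasing-tool behaviour); gaps in a rate map contribute 0 cM.
* All randomness flows through per-stage seeds derived from one master seed
  (`deriveSeed`), so identical configurations reproduce outputs
  byte-identically and individual stages can be replayed.
* The VCF writer emits deterministic plain text (VCF 4.2, contig headers,
  `0|1` genotypes, `./.` missing); reading uses vcfR. Multiallelic and indel
  records are skipped with a count.

# Problem sizes

The bundled validation exercises desk-scale versions of the study
conditions, chosen as the smallest sizes at which the Monte-Carlo bounds are
comfortably stable: 50,000 markers × 9 + 9 founders for weighted-F~ST~
recovery (±0.05 of the 0.4 target); 5,000 markers for supervised-$q$
recovery (mean absolute error ≤ 0.02 across true $q$ 0.1–0.9); a 20,000
marker, 4 × 50 Mb genome with 110+ admixed descendants for AIMs fidelity
(R² ≥ 0.95) and HMM accuracy (≥ 98% of markers, $g = 2$); and injected
phase switches in six F1s for detection/unkinking (≥ 90% joint-switch
reduction, allele multisets and global ancestry preserved exactly).

# Known limitations

* Two ancestries only; no K > 2, no phasing/imputation, no posterior
  (forward–backward) local-ancestry probabilities — Viterbi only.
* The HMM ignores background LD; with dense real data its raw per-marker
  accuracy will be optimistic relative to a CRF-based caller on the same
  input.
* The degeneracy diagnostic for the unsupervised fit is a heuristic; at
  divergences far below ~0.1 it will flag genuine but weak structure.
* The simulator's independence of markers given frequencies means LD-pruning
  behaviour on simulated data reflects chance correlation, not population
  LD structure.
* Because the HMM decodes the two haplotypes independently, the two sides of
  one physical phase switch can be placed a few markers apart where
  emissions are locally ambiguous; exact-coincidence joint-switch detection
  then misses that switch. With fully informative markers — or caller output
  reported on windows shared by both haplotypes, as RFMix msp files are —
  boundaries coincide and detection is exact.
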