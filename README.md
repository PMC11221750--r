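# admixqc

Ancestry estimation and phase-switch quality control for pedigreed colonies
descended from **two divergent source populations** — motivated by captive
baboon colonies founded by olive (*Papio anubis*) and yellow
(*P. cynocephalus*) baboons, but applicable to any two-way admixed pedigree
with phased biallelic genotypes.

## What it computes

* **Weir–Cockerham F<sub>ST</sub>** per marker (variance components *a*,
  *b*, *c*; estimate *a*/(*a*+*b*+*c*)) and the weighted ratio-of-sums
  genome-wide estimate; enumeration of markers fixed between the
  populations (F<sub>ST</sub> = 1).
* **AIM panel design**: F<sub>ST</sub> > 0.8 candidacy, best marker per
  100-kb window (ties to the first in input order), strict per-population
  LD pruning (window 2, step 1, r² 0.05), then a merged pruning pass.
* **Global ancestry**: the supervised two-way maximum-likelihood estimate —
  for dosages *g<sub>m</sub>* and reference frequencies *p<sub>0m</sub>*,
  *p<sub>1m</sub>*, the mixing proportion *q* maximizing
  Σ<sub>m</sub> [ *g<sub>m</sub>* log(*q p<sub>0m</sub>* + (1−*q*) *p<sub>1m</sub>*) +
  (2−*g<sub>m</sub>*) log(1 − *q p<sub>0m</sub>* − (1−*q*) *p<sub>1m</sub>*) ] —
  plus an unsupervised K = 2 block-ascent fit with purebred discovery
  (ancestry > 99%), and tract-length-based global ancestry.
* **Local ancestry**: a two-state Viterbi HMM (transition
  (1 − e<sup>−g·d</sup>)·prior at genetic distance *d*), with RFMix-style
  `.msp.tsv` input/output so an external caller can be substituted.
* **Phase-switch QC**: joint (complementary) ancestry-switch detection in
  F1 hybrids, suffix-exchange correction ("unkinking"), before/after switch
  reports, trio Mendelian local-ancestry audits, pedigree-label audits, and
  text karyograms.
* **Genetic maps**: rate intervals → cumulative cM (1 cM/Mb ≡ 1e-8 per bp),
  interpolation, PLINK and SHAPEIT map dialects.
* **A pedigree simulator** (Balding–Nichols founders, Haldane crossovers,
  injected phase switches, genotype-level missingness) with exact
  ancestry-tract truth, used by the validation suite.

## Worked example

Simulate a small colony (9 + 9 founders at F<sub>ST</sub> 0.4, six F1s, two
generations of random crossing), estimate differentiation, build an AIM
panel, estimate ancestry, and fix an injected phase switch:

```r
library(admixqc)

freqs <- simulateFounderFrequencies(nMarkers = 8000, fstTarget = 0.4,
                                    fixedFraction = 0.005, seed = 7)
gmap  <- uniformRateMap(chromLengths(freqs))        # 1 cM/Mb
plan  <- makeColonyPlan(nOlive = 9, nYellow = 9, nF1 = 6, nGen = 2,
                        nPerGen = 20, seed = 7)
sim   <- simulatePedigree(plan, freqs, gmap, seed = 7)

refs <- list(olive = paste0("O", 1:9), yellow = paste0("Y", 1:9))
fst  <- wcFstPerMarker(sim$panel, setNames(rep(0:1, each = 9), unlist(refs)))
weightedFst(fst)
#> [1] 0.409713                      # close to the simulated target 0.4
countFixedMarkers(fst)$count
#> [1] 112                           # sample-level fixed differences
aims <- selectAims(fst, sim$panel, refs = refs)
attr(aims, "stages")
#> stage1 stage2 stage3 stage4
#>    532    471    390    158       # 158 AIMs survive all four stages

q <- estimateAdmixtureSupervised(sim$panel, referenceFrequencies(sim$panel, refs))
head(subset(q, grepl("^G2", sample)), 3)
#>    sample qOlive qYellow     method nMarkers
#> 25   G2_1  0.784   0.216 likelihood     8000
#> 26   G2_2  0.000   1.000 likelihood     8000
#> 27   G2_3  0.499   0.501 likelihood     8000
```

`qOlive` is each animal's genome-wide olive ancestry proportion; grand-
offspring of random crosses scatter across [0, 1] as expected. Phase-switch
errors in an F1 appear as complementary ancestry switches on the two
haplotypes and are detected and corrected exactly:

```r
inj <- injectPhaseSwitches(sim$panel, sim$tracts, positions = data.frame(
  sample = "F1_1", chrom = c("1", "3"), boundaryIdx = c(800L, 400L)))
detectJointSwitches(inj$tracts, "F1_1")
#>   chrom boundaryIdx       bp
#> 1     1         800 20813789
#> 2     3         400  9729899
u <- unkink(inj$panel, inj$tracts, "F1_1")
u$nCorrections
#> [1] 2
cat(textKaryogram(inj$tracts, "F1_1", width = 40)[1:2], sep = "\n")
#> 1.0 oooooooooooooooooyyyyyyyyyyyyyyyyyyyyyyy
#> 1.1 yyyyyyyyyyyyyyyyyooooooooooooooooooooooo
cat(textKaryogram(u$tracts, "F1_1", width = 40)[1:2], sep = "\n")
#> 1.0 oooooooooooooooooooooooooooooooooooooooo
#> 1.1 yyyyyyyyyyyyyyyyyyyyyyyyyyyyyyyyyyyyyyyy
```

After unkinking the F1 again carries one whole olive and one whole yellow
haplotype per chromosome, while the allele content at every marker is
unchanged. `runPipeline(defaultRunConfig(), "out/", seed = 1)` chains all
stages (simulate → filter → F<sub>ST</sub>/AIMs → global → local →
phase QC → audits) and reproduces every output byte-identically under the
same seed.

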