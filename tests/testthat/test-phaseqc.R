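# Phase-switch detection and correction, tract statistics, trio audit,
# pedigree-label audit, text karyogram.

test_that("tract statistics count tracts and switches correctly", {
  w <- makeF1World(nMarkers = 300, seed = 61)
  st <- tractStatistics(w$tracts)
  # purebreds and switch-free F1s alike: one tract per chromosome per
  # haplotype, zero switches
  expect_true(all(st$perSample$nTracts == 4L))
  expect_true(all(st$perSample$nSwitches == 0L))
  # random tract sets match a brute-force enumeration
  set.seed(62)
  markers <- data.frame(chrom = rep(c("1", "2"), each = 50),
                        pos = rep(sort(sample.int(1e6, 50)), 2),
                        ref = "A", alt = "G")
  anc <- list(S1 = cbind(sample(0:1, 100, TRUE), sample(0:1, 100, TRUE)))
  ts <- admixqc:::.ancestryToTracts(anc, markers)
  st2 <- tractStatistics(ts)
  enum <- sum(vapply(c(1, 2), function(h) {
    sum(vapply(c("1", "2"), function(ch) {
      v <- anc$S1[markers$chrom == ch, h]
      length(rle(v)$values)
    }, numeric(1)))
  }, numeric(1)))
  expect_identical(st2$perSample$nTracts, as.integer(enum))
  expect_identical(st2$perSample$nSwitches, as.integer(enum - 4L))
})

test_that("joint switches are detected exactly where injected", {
  w <- makeF1World(nMarkers = 400, seed = 63)
  pos <- data.frame(sample = "F1", chrom = c("1", "2"),
                    boundaryIdx = c(50L, 120L))
  inj <- injectPhaseSwitches(w$panel, w$tracts, positions = pos)
  sw <- detectJointSwitches(inj$tracts, "F1")
  expect_identical(sw$chrom, c("1", "2"))
  expect_identical(sw$boundaryIdx, c(50L, 120L))
  # switch-free samples return nothing
  expect_identical(nrow(detectJointSwitches(w$tracts, "F1")), 0L)
  expect_identical(nrow(detectJointSwitches(w$tracts, "O1")), 0L)
})

test_that("one-sided ancestry changes are not phase-switch candidates", {
  set.seed(64)
  n <- 60L
  markers <- data.frame(chrom = "1", pos = sort(sample.int(1e6, n)),
                        ref = "A", alt = "G")
  # hap0 switches ancestry mid-chromosome, hap1 stays olive: genuine
  # admixture pattern, not a phase switch
  anc <- list(S = cbind(c(rep(0L, 30), rep(1L, 30)), rep(0L, n)))
  ts <- admixqc:::.ancestryToTracts(anc, markers)
  expect_identical(nrow(detectJointSwitches(ts, "S")), 0L)
})

test_that("unkinking inverts injected switches and restores truth", {
  w <- makeF1World(nMarkers = 500, seed = 65)
  pos <- data.frame(sample = "F1", chrom = c("1", "1", "2"),
                    boundaryIdx = c(40L, 160L, 90L))
  inj <- injectPhaseSwitches(w$panel, w$tracts, positions = pos)
  u <- unkink(inj$panel, inj$tracts, "F1")
  expect_identical(u$nCorrections, 3L)
  # haplotypes single-ancestry per chromosome again, alleles equal truth
  expect_identical(haplotypeMatrix(u$panel, 0L)[, "F1"],
                   haplotypeMatrix(w$panel, 0L)[, "F1"])
  expect_identical(haplotypeMatrix(u$panel, 1L)[, "F1"],
                   haplotypeMatrix(w$panel, 1L)[, "F1"])
  expect_identical(tracts(u$tracts), tracts(w$tracts))
  # no joint switches remain; idempotence
  expect_identical(nrow(detectJointSwitches(u$tracts, "F1")), 0L)
  u2 <- unkink(u$panel, u$tracts, "F1")
  expect_identical(u2$nCorrections, 0L)
  expect_identical(haplotypeMatrix(u2$panel, 0L), haplotypeMatrix(u$panel, 0L))
})

test_that("unkinking preserves per-marker allele multisets and global ancestry", {
  w <- makeF1World(nMarkers = 300, seed = 66)
  inj <- injectPhaseSwitches(w$panel, w$tracts, rate = 20, gmap = w$gmap,
                             samples = "F1", seed = 67)
  u <- unkink(inj$panel, inj$tracts, "F1")
  expect_gt(u$nCorrections, 0L)
  before <- haplotypeMatrix(inj$panel, 0L)[, "F1"] +
    haplotypeMatrix(inj$panel, 1L)[, "F1"]
  after <- haplotypeMatrix(u$panel, 0L)[, "F1"] +
    haplotypeMatrix(u$panel, 1L)[, "F1"]
  expect_identical(after, before)
  gb <- globalFromTracts(inj$tracts)
  ga <- globalFromTracts(u$tracts)
  expect_identical(ga$qOlive[ga$sample == "F1"],
                   gb$qOlive[gb$sample == "F1"])
})

test_that("switch reports compute percent reduction with flags", {
  before <- data.frame(sample = c("a", "b", "c"),
                       nTracts = c(10L, 8L, 4L), nSwitches = c(200L, 8L, 0L))
  after <- data.frame(sample = c("a", "b", "c"),
                      nTracts = c(7L, 8L, 4L), nSwitches = c(130L, 8L, 0L))
  rep <- f1SwitchReport(before, after)
  expect_equal(rep$perSample$reductionPct[rep$perSample$sample == "a"], 35)
  expect_equal(rep$perSample$reductionPct[rep$perSample$sample == "b"], 0)
  expect_identical(rep$perSample$flag[rep$perSample$sample == "c"],
                   "no-switches")
  expect_equal(rep$aggregate$reductionPct, 100 * (208 - 138) / 208)
})

test_that("trio audit is silent on truth and flags controlled corruption", {
  w <- makeF1World(nMarkers = 1000, seed = 68)
  mk <- markerTable(w$panel)
  # truth trio: olive sire, yellow dam, F1 offspring -> fully consistent
  trio <- trioConsistency(w$tracts, mk, "F1", "O1", "Y1")
  expect_identical(trio$fraction, 0)
  # corrupt a known fraction of offspring markers to homozygous-opposite
  anc <- admixqc:::.tractsToAncestry(w$tracts, mk)
  phi <- 0.06
  set.seed(69)
  bad <- sample(nrow(mk), round(phi * nrow(mk)))
  anc$F1[bad, ] <- 0L  # two copies of olive where the dam is yellow/yellow
  corrupted <- admixqc:::.ancestryToTracts(anc, mk)
  trio2 <- trioConsistency(corrupted, mk, "F1", "O1", "Y1")
  expect_lt(abs(trio2$fraction - phi), 0.01)
  # offspring olive/olive where dam yellow/yellow: flagged by the rule
  expect_true(all(trio2$perMarker$inconsistent[bad]))
  # differing marker grids are an error, never silently intersected
  half <- TractSet(rbind(
    tracts(subsetTracts(w$tracts, w$panel, seq_len(500)))[
      tracts(subsetTracts(w$tracts, w$panel, seq_len(500)))$sample == "F1", ],
    tracts(w$tracts)[tracts(w$tracts)$sample %in% c("O1", "Y1"), ]))
  expect_error(trioConsistency(half, mk, "F1", "O1", "Y1"), "grids differ")
})

test_that("heterozygous-ancestry configurations are never flagged", {
  set.seed(70)
  n <- 50L
  markers <- data.frame(chrom = "1", pos = sort(sample.int(1e6, n)),
                        ref = "A", alt = "G")
  # offspring het everywhere; sire het; dam hom yellow -> rule cannot fire
  anc <- list(off = cbind(rep(0L, n), rep(1L, n)),
              sire = cbind(rep(0L, n), rep(1L, n)),
              dam = cbind(rep(1L, n), rep(1L, n)))
  ts <- admixqc:::.ancestryToTracts(anc, markers)
  expect_identical(trioConsistency(ts, markers, "off", "sire", "dam")$fraction, 0)
})

test_that("pedigree-label audit applies strict thresholds by class", {
  global <- data.frame(
    sample = c("ok", "low", "edge", "ylow", "cmaj", "cpure", "cfine", "nolab"),
    qOlive = c(1.0, 0.85, 0.90, 0.95, 0.93, 0.995, 0.60, 0.5))
  global$qYellow <- 1 - global$qOlive
  ped <- Pedigree(data.frame(
    id = c("ok", "low", "edge", "ylow", "cmaj", "cpure", "cfine", "noest"),
    sire = NA_character_, dam = NA_character_, sex = "F",
    taxon = c("olive", "olive", "olive", "yellow", "cross", "cross",
              "cross", "olive"),
    generation = 0L))
  audit <- auditPedigreeLabels(global, ped, major = 0.90, pure = 0.99)
  flagOf <- function(s) audit$flag[audit$sample == s]
  expect_identical(flagOf("ok"), "none")
  expect_identical(flagOf("low"), "olive-low")
  expect_identical(flagOf("edge"), "none")       # strict: 0.90 is not < 0.90
  expect_identical(flagOf("ylow"), "yellow-low") # yellow ancestry 0.05
  expect_identical(flagOf("cmaj"), "cross-major")
  expect_identical(flagOf("cpure"), "cross-pure-like")
  expect_identical(flagOf("cfine"), "none")
  expect_identical(flagOf("nolab"), "missing")
  expect_identical(flagOf("noest"), "missing")
})

test_that("text karyograms render majority ancestry per column", {
  w <- makeF1World(nMarkers = 200, seed = 71)
  ka <- textKaryogram(w$tracts, "O1", width = 20)
  expect_length(ka, 4L)  # 2 chromosomes x 2 haplotypes
  expect_true(all(grepl("^[12]\\.[01] o{20}$", ka)))
  kf <- textKaryogram(w$tracts, "F1", width = 20)
  body <- sub("^\\S+ ", "", kf)
  expect_setequal(unique(body), c(strrep("o", 20), strrep("y", 20)))
  expect_error(textKaryogram(w$tracts, "O1", width = 0), "width")
  # column majority equals a brute-force bp scan on a random tract set
  set.seed(72)
  n <- 30L
  markers <- data.frame(chrom = "1", pos = sort(sample.int(1e5, n)),
                        ref = "A", alt = "G")
  anc <- list(S = cbind(sample(0:1, n, TRUE), sample(0:1, n, TRUE)))
  ts <- admixqc:::.ancestryToTracts(anc, markers)
  got <- sub("^\\S+ ", "", textKaryogram(ts, "S", width = 10))[1]
  tr <- tracts(ts); tr <- tr[tr$hap == 0L, ]
  lo <- min(tr$startBp); hi <- max(tr$endBp)
  edges <- seq(lo, hi, length.out = 11)
  expectChar <- vapply(1:10, function(k) {
    bp0 <- sum(pmax(0, pmin(tr$endBp, edges[k + 1]) -
                      pmax(tr$startBp, edges[k]))[tr$ancestry == 0])
    bp1 <- sum(pmax(0, pmin(tr$endBp, edges[k + 1]) -
                      pmax(tr$startBp, edges[k]))[tr$ancestry == 1])
    if (bp0 >= bp1) "o" else "y"
  }, character(1))
  expect_identical(got, paste(expectChar, collapse = ""))
})
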