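# Global ancestry (supervised and unsupervised), HMM local ancestry, msp
# round-trips, tract-based global extraction.

fixedFreqs <- function(n, chromLengths = c(`1` = 1e6)) {
  markers <- data.frame(chrom = names(chromLengths)[1],
                        pos = seq_len(n) * 100L, ref = "A", alt = "G")
  PopulationFrequencies(markers, cbind(rep(1, n), rep(0, n)),
                        chromLengths = chromLengths)
}

test_that("supervised MLE recovers the obvious boundary and symmetric cases", {
  n <- 200L
  freqs <- fixedFreqs(n)
  # heterozygous at every fixed-difference marker: perfectly admixed
  hets <- matrix(1L, n, 1, dimnames = list(NULL, "F1"))
  est <- estimateAdmixtureSupervised(hets, freqs)
  expect_lt(abs(est$qOlive - 0.5), 1e-4)
  expect_equal(est$qOlive + est$qYellow, 1)
  # matching the population-0 homozygote everywhere: boundary optimum q = 1
  hom <- matrix(2L, n, 1, dimnames = list(NULL, "pure"))
  expect_identical(estimateAdmixtureSupervised(hom, freqs)$qOlive, 1)
  # all genotypes missing is an error
  expect_error(estimateAdmixtureSupervised(
    matrix(NA_integer_, n, 1), freqs), "zero usable markers")
})

test_that("supervised MLE agrees with a fine grid-search oracle", {
  set.seed(31)
  for (rep in 1:8) {
    n <- 150L
    p0 <- runif(n); p1 <- runif(n)
    qTrue <- runif(1)
    pm <- qTrue * p0 + (1 - qTrue) * p1
    g <- rbinom(n, 2, pm)
    g[sample(n, 5)] <- NA
    markers <- data.frame(chrom = "1", pos = seq_len(n) * 10L,
                          ref = "A", alt = "G")
    freqs <- PopulationFrequencies(markers, cbind(p0, p1),
                                   chromLengths = c(`1` = 1e6))
    est <- estimateAdmixtureSupervised(matrix(g, ncol = 1), freqs)
    expect_lt(abs(est$qOlive - gridQOracle(g, p0, p1)), 5e-4)
  }
})

test_that("the admixture likelihood is concave in q", {
  set.seed(32)
  n <- 100L
  p0 <- pmin(pmax(runif(n), 1e-4), 1 - 1e-4)
  p1 <- pmin(pmax(runif(n), 1e-4), 1 - 1e-4)
  g <- rbinom(n, 2, 0.4 * p0 + 0.6 * p1)
  qs <- seq(0.01, 0.99, by = 0.01)
  ll <- vapply(qs, function(q) {
    pm <- q * p0 + (1 - q) * p1
    sum(g * log(pm) + (2 - g) * log(1 - pm))
  }, numeric(1))
  expect_true(all(diff(diff(ll)) < 1e-8))
})

test_that("supervised q tracks truth on moderately divergent simulations", {
  # quick parameter-recovery sanity at reduced scale
  f <- simulateFounderFrequencies(2000, 0.4, 0.005, c(`1` = 1e7), seed = 33)
  set.seed(34)
  p0 <- popFreq(f)[, 1]; p1 <- popFreq(f)[, 2]
  for (qTrue in c(0.2, 0.5, 0.8)) {
    pop <- runif(2000) < qTrue
    g <- rbinom(2000, 1, ifelse(pop, p0, p1)) +
      rbinom(2000, 1, ifelse(runif(2000) < qTrue, p0, p1))
    est <- estimateAdmixtureSupervised(matrix(as.integer(g), ncol = 1), f)
    expect_lt(abs(est$qOlive - qTrue), 0.04)
  }
})

test_that("unsupervised K=2 separates fixed-different homogeneous groups", {
  n <- 300L
  freqs <- fixedFreqs(n)
  fnd <- simulateFounders(freqs, c(olive = 6, yellow = 6), seed = 35)
  fit <- estimateAdmixtureUnsupervisedK2(fnd$panel, seed = 36,
    labels = setNames(c(rep("olive", 6), rep("yellow", 6)),
                      sampleIds(fnd$panel)))
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_true(all(abs(fit$global$qOlive[1:6] - 1) < 0.01))
  expect_true(all(abs(fit$global$qOlive[7:12]) < 0.01))
  pure <- discoverPurebred(fit$global, 0.99)
  expect_setequal(pure$sample[pure$population == "olive"], paste0("O", 1:6))
  expect_setequal(pure$sample[pure$population == "yellow"], paste0("Y", 1:6))
})

test_that("unsupervised fit on a single population is flagged degenerate", {
  f <- simulateFounderFrequencies(400, 0.3, 0, c(`1` = 1e7), seed = 37)
  onePop <- PopulationFrequencies(markerTable(f),
                                  cbind(popFreq(f)[, 1], popFreq(f)[, 1]),
                                  chromLengths = chromLengths(f))
  fnd <- simulateFounders(onePop, c(olive = 8, yellow = 8), seed = 38)
  fit <- estimateAdmixtureUnsupervisedK2(fnd$panel, seed = 39)
  expect_true(fit$degenerate)
})

test_that("HMM decodes a fully informative recombinant F1 haplotype exactly", {
  w <- makeF1World(nMarkers = 600, seed = 40)
  called <- hmmLocalAncestry(w$panel, w$freqs, w$gmap,
                             hmmConfig(g = 2), samples = "F1")
  truthAnc <- admixqc:::.tractsToAncestry(w$tracts, markerTable(w$panel))[["F1"]]
  callAnc <- admixqc:::.tractsToAncestry(called, markerTable(w$panel))[["F1"]]
  expect_identical(callAnc, truthAnc)
  expect_false(attr(called, "uninformative"))
})

test_that("HMM degenerates gracefully when populations are indistinguishable", {
  w <- makeF1World(nMarkers = 200, seed = 41)
  same <- PopulationFrequencies(markerTable(w$panel),
                                cbind(rep(0.5, 200), rep(0.5, 200)),
                                chromLengths = chromLengths(w$panel))
  called <- hmmLocalAncestry(w$panel, same, w$gmap, hmmConfig(), "F1")
  expect_true(attr(called, "uninformative"))
  tr <- tracts(called)
  expect_true(all(table(tr$chrom[tr$sample == "F1"], tr$hap[tr$sample == "F1"]) == 1))
})

test_that("HMM limits: per-marker calls as g grows, single call as g shrinks", {
  w <- makeF1World(nMarkers = 200, seed = 42)
  # moderately informative frequencies so individual markers disagree
  set.seed(43)
  p0 <- runif(200, 0.5, 1); p1 <- runif(200, 0, 0.5)
  freqs <- PopulationFrequencies(markerTable(w$panel), cbind(p0, p1),
                                 chromLengths = chromLengths(w$panel))
  big <- hmmLocalAncestry(w$panel, freqs, w$gmap,
                          hmmConfig(g = 1e9), samples = "O1")
  anc <- admixqc:::.tractsToAncestry(big, markerTable(w$panel))[["O1"]]
  hap <- haplotypeMatrix(w$panel, 0L)[, "O1"]
  eps <- 0.005
  e0 <- ifelse(hap == 1L, pmin(pmax(p0, eps), 1 - eps),
               1 - pmin(pmax(p0, eps), 1 - eps))
  e1 <- ifelse(hap == 1L, pmin(pmax(p1, eps), 1 - eps),
               1 - pmin(pmax(p1, eps), 1 - eps))
  expect_identical(anc[, 1], as.integer(e1 > e0))
  small <- hmmLocalAncestry(w$panel, freqs, w$gmap,
                            hmmConfig(g = 1e-9), samples = "O1")
  tr <- tracts(small)
  expect_true(all(table(tr$chrom[tr$sample == "O1"], tr$hap) == 1))
})

test_that("msp files round-trip ancestry exactly", {
  w <- makeF1World(nMarkers = 300, seed = 44)
  called <- hmmLocalAncestry(w$panel, w$freqs, w$gmap, hmmConfig(g = 2))
  path <- tempfile(fileext = ".msp.tsv")
  writeMsp(called, w$gmap, path)
  back <- readMsp(path)
  a1 <- admixqc:::.tractsToAncestry(called, markerTable(w$panel))
  a2 <- admixqc:::.tractsToAncestry(back, markerTable(w$panel))
  for (s in names(a1)) expect_identical(a2[[s]], a1[[s]])
  expect_identical(ancestryCodes(back), c(olive = 0L, yellow = 1L))
  # single-ancestry sample: one row per chromosome
  solo <- TractSet(tracts(w$tracts)[tracts(w$tracts)$sample == "O1", ])
  p2 <- tempfile()
  writeMsp(solo, w$gmap, p2)
  body <- readLines(p2)[-(1:2)]
  expect_length(body, 2L)
  # malformed header is rejected
  writeLines(c("nonsense", "#chm"), p3 <- tempfile())
  expect_error(readMsp(p3), "malformed")
})

test_that("msp rows partition at the union of all samples' boundaries", {
  set.seed(45)
  n <- 100L
  markers <- data.frame(chrom = "1", pos = sort(sample.int(1e6, n)),
                        ref = "A", alt = "G")
  # two samples with one ancestry switch each, at different boundaries
  ancA <- cbind(c(rep(0L, 29), rep(1L, n - 29)),
                c(rep(1L, 29), rep(0L, n - 29)))
  ancB <- cbind(c(rep(0L, 59), rep(1L, n - 59)),
                c(rep(1L, 59), rep(0L, n - 59)))
  two <- admixqc:::.ancestryToTracts(list(A = ancA, B = ancB), markers)
  w <- list(panel = HaplotypePanel(markers, "x",
                                   matrix(0L, n, 1), matrix(0L, n, 1)),
            gmap = uniformRateMap(c(`1` = 1e6)))
  path <- tempfile()
  writeMsp(two, w$gmap, path)
  body <- read.table(path, skip = 2, sep = "\t")
  pos <- markerTable(w$panel)$pos
  expect_true(pos[30] %in% body[[2]])
  expect_true(pos[60] %in% body[[2]])
  # rows tile: each row's epos is the next row's spos
  expect_true(all(body[[3]][-nrow(body)] == body[[2]][-1]))
})

test_that("tract-based global ancestry matches a per-bp scan", {
  w <- makeF1World(nMarkers = 300, seed = 46)
  g <- globalFromTracts(w$tracts)
  expect_identical(g$qOlive[g$sample == "O1"], 1)
  expect_identical(g$qOlive[g$sample == "F1"], 0.5)
  # random tract sets against a brute-force per-bp scan
  set.seed(47)
  for (rep in 1:5) {
    n <- 40L
    markers <- data.frame(chrom = "1", pos = sort(sample.int(1e5, n)),
                          ref = "A", alt = "G")
    anc <- list(S = cbind(sample(0:1, n, TRUE), sample(0:1, n, TRUE)))
    ts <- admixqc:::.ancestryToTracts(anc, markers)
    got <- globalFromTracts(ts)$qOlive
    # scan every bp of [first marker, last marker + 1)
    span <- seq(markers$pos[1], markers$pos[n])
    byBp <- function(hap) {
      idx <- findInterval(span, markers$pos)
      mean(anc$S[idx, hap] == 0)
    }
    expect_lt(abs(got - (byBp(1) + byBp(2)) / 2), 1e-12)
  }
})

test_that("supervised and tract-truth global estimates agree on simulations", {
  f <- simulateFounderFrequencies(4000, 0.4, 0.005,
                                  c(`1` = 1e7, `2` = 1e7), seed = 48)
  gmap <- uniformRateMap(chromLengths(f))
  plan <- makeColonyPlan(5, 5, 5, 2, 12, seed = 49)
  sim <- simulatePedigree(plan, f, gmap, seed = 50)
  sup <- estimateAdmixtureSupervised(sim$panel, f)
  tru <- globalFromTracts(sim$tracts)
  m <- merge(sup, tru, by = "sample")
  expect_lt(max(abs(m$qOlive.x - m$qOlive.y)), 0.03)
})
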