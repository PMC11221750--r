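# Shared fixture builders used across test files. All fixtures are built in
# code; nothing is read from disk except files the tests themselves write.

# A panel built directly from a dosage specification: dose is a markers x
# samples matrix of 0/1/2 (NA = missing). Heterozygotes are phased 0|1.
panelFromDosage <- function(dose, chrom = "1", startPos = 1000L, gapBp = 1000L) {
  n <- nrow(dose)
  markers <- data.frame(chrom = chrom,
                        pos = startPos + gapBp * (seq_len(n) - 1L),
                        ref = "A", alt = "G", stringsAsFactors = FALSE)
  hapA <- matrix(NA_integer_, n, ncol(dose))
  hapB <- matrix(NA_integer_, n, ncol(dose))
  hapA[dose == 0L] <- 0L; hapB[dose == 0L] <- 0L
  hapA[dose == 1L] <- 0L; hapB[dose == 1L] <- 1L
  hapA[dose == 2L] <- 1L; hapB[dose == 2L] <- 1L
  ids <- colnames(dose)
  if (is.null(ids)) ids <- paste0("S", seq_len(ncol(dose)))
  HaplotypePanel(markers, ids, hapA, hapB, degraded = anyNA(dose))
}

# Purebred founders plus one F1, on a small two-chromosome genome with fully
# informative (fixed-difference) markers. Returns panel/tracts/gmap/freqs.
makeF1World <- function(nMarkers = 400L, seed = 1L,
                        chromLengths = c(`1` = 1e7, `2` = 1e7)) {
  set.seed(seed)
  markers <- do.call(rbind, lapply(names(chromLengths), function(ch) {
    pos <- sort(sample.int(chromLengths[[ch]], nMarkers / length(chromLengths)))
    data.frame(chrom = ch, pos = pos, ref = "A", alt = "G",
               stringsAsFactors = FALSE)
  }))
  n <- nrow(markers)
  freqs <- PopulationFrequencies(markers, cbind(rep(1, n), rep(0, n)),
                                 chromLengths = chromLengths)
  fnd <- simulateFounders(freqs, c(olive = 2, yellow = 2), seed = seed)
  gmap <- uniformRateMap(chromLengths)
  cr <- simulateCross("O1", "Y1", fnd$panel, fnd$tracts, gmap,
                      seed = seed + 1L, id = "F1")
  panel <- HaplotypePanel(markers,
                          c(sampleIds(fnd$panel), "F1"),
                          cbind(haplotypeMatrix(fnd$panel, 0L),
                                haplotypeMatrix(cr$panel, 0L)),
                          cbind(haplotypeMatrix(fnd$panel, 1L),
                                haplotypeMatrix(cr$panel, 1L)),
                          chromLengths = chromLengths)
  tr <- TractSet(rbind(tracts(fnd$tracts), tracts(cr$tracts)))
  list(panel = panel, tracts = tr, gmap = gmap, freqs = freqs)
}

# Independent Weir-Cockerham two-population oracle, computed marker by
# marker with scalar arithmetic straight from the 1984 variance-component
# definitions (r = 2 populations, diploids).
wcOracle <- function(geno0, geno1) {
  geno0 <- geno0[!is.na(geno0)]; geno1 <- geno1[!is.na(geno1)]
  n <- c(length(geno0), length(geno1))
  p <- c(sum(geno0) / (2 * n[1]), sum(geno1) / (2 * n[2]))
  h <- c(mean(geno0 == 1), mean(geno1 == 1))
  r <- 2
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       fst = if (a + b + cc > 0) a / (a + b + cc) else NA_real_)
}

# Grid-search oracle for the supervised admixture MLE (step 1e-4).
gridQOracle <- function(g, p0, p1, eps = 1e-4) {
  ok <- !is.na(g)
  g <- g[ok]
  p0 <- pmin(pmax(p0[ok], eps), 1 - eps)
  p1 <- pmin(pmax(p1[ok], eps), 1 - eps)
  qs <- seq(0, 1, by = 1e-4)
  ll <- vapply(qs, function(q) {
    pm <- q * p0 + (1 - q) * p1
    sum(g * log(pm) + (2 - g) * log(1 - pm))
  }, numeric(1))
  qs[which.max(ll)]
}

# Brute-force greedy LD-pruning oracle applying the declared rule on one
# window covering the whole marker list.
ldPruneOracle <- function(dose, maf, r2Max) {
  alive <- rep(TRUE, nrow(dose))
  repeat {
    loc <- which(alive)
    if (length(loc) < 2L) break
    removed <- FALSE
    for (i in seq_len(length(loc) - 1L)) {
      for (j in (i + 1L):length(loc)) {
        x <- dose[loc[i], ]; y <- dose[loc[j], ]
        ok <- !is.na(x) & !is.na(y)
        r2 <- if (sum(ok) < 2L) NA_real_
        else if (var(x[ok]) == 0 || var(y[ok]) == 0) 0
        else cor(x[ok], y[ok])^2
        if (!is.na(r2) && r2 > r2Max) {
          drop <- if (maf[loc[i]] < maf[loc[j]]) loc[i]
                  else if (maf[loc[j]] < maf[loc[i]]) loc[j]
                  else loc[j]
          alive[drop] <- FALSE
          removed <- TRUE
          break
        }
      }
      if (removed) break
    }
    if (!removed) break
  }
  which(alive)
}
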