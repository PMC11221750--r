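# Synthetic two-population pedigree simulator with ancestry-tract truth.
#
# The generator emulates the statistical structure of a captive baboon-like
# colony: two divergent founder populations (target weighted F_ST ~ 0.4 with
# a small fraction of fixed differences), Hardy-Weinberg founders, crossover
# recombination per a genetic map (Haldane model), injected phase-switch
# errors and genotype-level missingness.

#' Default synthetic genome
#'
#' Four chromosomes of 50 Mb each: desk-scale, while leaving hundreds of
#' 100-kb AIM-selection windows per chromosome.
#'
#' @return named numeric vector of chromosome lengths (bp).
#' @export
defaultGenome <- function() stats::setNames(rep(5e7, 4), as.character(1:4))

#' Simulate founder-population allele frequencies
#'
#' Draws per-marker alternate-allele frequencies for two populations around a
#' uniform ancestral frequency on \[0.05, 0.95\] using the Balding-Nichols
#' model with divergence parameter `fstTarget`: each population's frequency
#' is Beta(p(1-F)/F, (1-p)(1-F)/F). A fraction `fixedFraction` of markers is
#' instead fixed for alternate alleles, i.e. frequencies exactly (0,1) or
#' (1,0). Marker positions are drawn uniformly per chromosome and sorted.
#'
#' @param nMarkers total marker count (>= 1), split across chromosomes
#'   proportionally to length.
#' @param fstTarget divergence parameter in (0, 1).
#' @param fixedFraction fraction of fixed-difference markers in \[0, 1\].
#' @param chromLengths named chromosome lengths in bp.
#' @param seed integer seed; output is deterministic given the seed.
#' @return A [PopulationFrequencies-class].
#' @export
simulateFounderFrequencies <- function(nMarkers, fstTarget,
                                       fixedFraction = 0,
                                       chromLengths = defaultGenome(),
                                       seed = 1L) {
  if (nMarkers < 1) stop("nMarkers must be >= 1")
  if (fstTarget <= 0 || fstTarget >= 1) stop("fstTarget must lie in (0, 1)")
  if (fixedFraction < 0 || fixedFraction > 1)
    stop("fixedFraction must lie in [0, 1]")
  withSeed(seed, {
    share <- chromLengths / sum(chromLengths)
    per <- diff(round(cumsum(c(0, share)) * nMarkers))
    markers <- do.call(rbind, lapply(seq_along(chromLengths), function(i) {
      n <- per[i]
      if (n == 0L) return(NULL)
      pos <- sort(sample.int(chromLengths[i], n))
      data.frame(chrom = names(chromLengths)[i], pos = pos,
                 ref = "A", alt = "G", stringsAsFactors = FALSE)
    }))
    n <- nrow(markers)
    pAnc <- stats::runif(n, 0.05, 0.95)
    F <- fstTarget
    shape <- (1 - F) / F
    freq <- cbind(stats::rbeta(n, pAnc * shape, (1 - pAnc) * shape),
                  stats::rbeta(n, pAnc * shape, (1 - pAnc) * shape))
    nFixed <- round(fixedFraction * n)
    if (nFixed > 0L) {
      fi <- sort(sample.int(n, nFixed))
      flip <- stats::runif(nFixed) < 0.5
      freq[fi, 1] <- ifelse(flip, 0, 1)
      freq[fi, 2] <- ifelse(flip, 1, 0)
      pAnc[fi] <- 0.5
    }
    PopulationFrequencies(markers, freq, ancestralFreq = pAnc,
                          chromLengths = chromLengths)
  })
}

#' Simulate unadmixed diploid founders
#'
#' Each haplotype allele is an independent Bernoulli draw from the founder's
#' population frequency (Hardy-Weinberg within population). Truth tracts
#' assign whole chromosomes to the founder's population; the pedigree records
#' founders at generation 0 with taxon labels and unknown parents.
#'
#' @param freqs a [PopulationFrequencies-class].
#' @param nPerPop counts per population, e.g. `c(olive = 9, yellow = 9)`.
#' @param seed integer seed.
#' @return list with elements `panel` ([HaplotypePanel-class]),
#'   `pedigree` ([Pedigree-class]) and `tracts` (truth [TractSet-class]).
#' @export
simulateFounders <- function(freqs, nPerPop = c(olive = 9, yellow = 9),
                             seed = 1L) {
  if (nrow(freqs@markers) == 0L) stop("empty frequency table")
  if (any(nPerPop < 1)) stop("need at least one founder per population")
  withSeed(seed, {
    n <- nrow(freqs@markers)
    ids <- c(paste0("O", seq_len(nPerPop[1])),
             paste0("Y", seq_len(nPerPop[2])))
    pop <- rep(0:1, nPerPop)
    hapA <- matrix(0L, n, length(ids))
    hapB <- matrix(0L, n, length(ids))
    for (j in seq_along(ids)) {
      p <- freqs@freq[, pop[j] + 1L]
      hapA[, j] <- stats::rbinom(n, 1L, p)
      hapB[, j] <- stats::rbinom(n, 1L, p)
    }
    panel <- HaplotypePanel(freqs@markers, ids, hapA, hapB,
                            chromLengths = freqs@chromLengths)
    anc <- lapply(seq_along(ids), function(j)
      matrix(pop[j], n, 2L))
    names(anc) <- ids
    tr <- .ancestryToTracts(anc, panel@markers)
    ped <- Pedigree(data.frame(
      id = ids, sire = NA_character_, dam = NA_character_,
      sex = rep_len(c("M", "F"), length(ids)),
      taxon = c("olive", "yellow")[pop + 1L],
      generation = 0L, stringsAsFactors = FALSE))
    list(panel = panel, pedigree = ped, tracts = tr)
  })
}

# Draw crossover boundary indices for one chromosome. Crossover count is
# Poisson with mean = chromosome genetic length in Morgans (Haldane, no
# interference); positions are uniform on the genetic-distance scale and then
# snapped to the following inter-marker boundary. Returns sorted local marker
# indices b (switch applies from marker b onward); collisions cancel in pairs
# via the suffix-exchange representation, so duplicates are dropped here.
.drawCrossovers <- function(gmap, chrom, markerPos) {
  nd <- gmap@nodes[gmap@nodes$chrom == chrom, , drop = FALSE]
  L <- (max(nd$cM) - min(nd$cM)) / 100
  k <- stats::rpois(1L, L)
  if (k == 0L || length(markerPos) < 2L) return(integer(0))
  u <- stats::runif(k, min(nd$cM), max(nd$cM))
  bp <- .bpFromCm(gmap, chrom, u)
  b <- findInterval(bp, markerPos) + 1L     # first marker after crossover
  b <- b[b >= 2L & b <= length(markerPos)]
  sort(unique(b))
}

# Build one gamete (alleles + ancestry) from a parent's two haplotypes.
.makeGamete <- function(hapPair, ancPair, markers, gmap) {
  chromIdx <- .chromIndex(markers)
  allele <- integer(nrow(markers))
  anc <- integer(nrow(markers))
  for (ch in names(chromIdx)) {
    gidx <- chromIdx[[ch]]
    b <- .drawCrossovers(gmap, ch, markers$pos[gidx])
    cur <- sample.int(2L, 1L)              # fair starting haplotype
    bounds <- c(1L, b, length(gidx) + 1L)
    for (s in seq_len(length(bounds) - 1L)) {
      loc <- seq.int(bounds[s], bounds[s + 1L] - 1L)
      allele[gidx[loc]] <- hapPair[[cur]][gidx[loc]]
      anc[gidx[loc]] <- ancPair[[cur]][gidx[loc]]
      cur <- 3L - cur
    }
  }
  list(allele = allele, ancestry = anc)
}

#' Simulate one offspring of two parents
#'
#' Each gamete is built per chromosome by drawing a crossover count from a
#' Poisson with mean equal to the chromosome's genetic length in Morgans
#' (Haldane model, no interference), placing crossovers uniformly on the
#' genetic-distance scale, and alternating the parental haplotypes starting
#' from a fair random choice. Offspring truth tracts are the parental tracts
#' split at the crossovers.
#'
#' @param parent1,parent2 sample ids present in `panel`.
#' @param panel a [HaplotypePanel-class] containing both parents.
#' @param truth truth [TractSet-class] for the parents.
#' @param gmap a [GeneticMap-class] covering all marker positions.
#' @param seed integer seed.
#' @param id offspring sample id (default `"offspring"`).
#' @return list with one-sample `panel` and truth `tracts` for the offspring.
#' @export
simulateCross <- function(parent1, parent2, panel, truth, gmap, seed = 1L,
                          id = "offspring") {
  for (p in c(parent1, parent2))
    if (!p %in% panel@samples) stop("parent not found in panel: ", p)
  sp <- range(gmap@nodes$pos[gmap@nodes$chrom %in% panel@markers$chrom])
  if (min(panel@markers$pos) < sp[1] - 1 || max(panel@markers$pos) > sp[2])
    stop("genetic map does not span the marker range")
  anc <- .tractsToAncestry(truth, panel@markers)
  withSeed(seed, {
    g1 <- .makeGamete(list(panel@hapA[, parent1], panel@hapB[, parent1]),
                      list(anc[[parent1]][, 1], anc[[parent1]][, 2]),
                      panel@markers, gmap)
    g2 <- .makeGamete(list(panel@hapA[, parent2], panel@hapB[, parent2]),
                      list(anc[[parent2]][, 1], anc[[parent2]][, 2]),
                      panel@markers, gmap)
    off <- HaplotypePanel(panel@markers, id,
                          matrix(g1$allele, ncol = 1),
                          matrix(g2$allele, ncol = 1),
                          chromLengths = panel@chromLengths)
    tr <- .ancestryToTracts(stats::setNames(
      list(cbind(g1$ancestry, g2$ancestry)), id),
      panel@markers, codes = truth@codes)
    list(panel = off, tracts = tr)
  })
}

#' Simulate a multi-generation admixed pedigree
#'
#' Applies [simulateFounders()] and then [simulateCross()] per entry of the
#' breeding plan. Cross offspring get taxon label `"cross"` and generation
#' `max(parent generations) + 1`. The truth global ancestry of each sample is
#' the length-weighted ancestry of its truth tracts.
#'
#' @param design list with `founders` (counts, e.g. `c(olive=9, yellow=9)`)
#'   and `crosses`, a data.frame with columns id, sire, dam referencing only
#'   previously created individuals (see [makeColonyPlan()]).
#' @param freqs a [PopulationFrequencies-class].
#' @param gmap a [GeneticMap-class].
#' @param seed integer seed.
#' @return list with `panel`, `pedigree`, `tracts` as in [simulateFounders()].
#' @export
simulatePedigree <- function(design, freqs, gmap, seed = 1L) {
  fnd <- simulateFounders(freqs, design$founders, seed = deriveSeed(seed, "founders"))
  panel <- fnd$panel
  ped <- fnd$pedigree@records
  anc <- .tractsToAncestry(fnd$tracts, panel@markers)
  crosses <- design$crosses
  if (!is.null(crosses) && nrow(crosses) > 0L) {
    hapA <- panel@hapA; hapB <- panel@hapB
    nm <- nrow(panel@markers)
    hapA <- cbind(hapA, matrix(NA_integer_, nm, nrow(crosses)))
    hapB <- cbind(hapB, matrix(NA_integer_, nm, nrow(crosses)))
    ids <- c(panel@samples, rep(NA_character_, nrow(crosses)))
    for (i in seq_len(nrow(crosses))) {
      sire <- crosses$sire[i]; dam <- crosses$dam[i]; cid <- crosses$id[i]
      if (cid %in% ids) stop("duplicate individual id in plan: ", cid)
      for (p in c(sire, dam)) if (!p %in% ids)
        stop("cross ", cid, " references unknown parent ", p)
      j1 <- match(sire, ids); j2 <- match(dam, ids)
      s <- deriveSeed(seed, paste0("cross:", cid))
      withSeed(s, {
        g1 <- .makeGamete(list(hapA[, j1], hapB[, j1]),
                          list(anc[[sire]][, 1], anc[[sire]][, 2]),
                          panel@markers, gmap)
        g2 <- .makeGamete(list(hapA[, j2], hapB[, j2]),
                          list(anc[[dam]][, 1], anc[[dam]][, 2]),
                          panel@markers, gmap)
        k <- length(panel@samples) + i
        hapA[, k] <- g1$allele
        hapB[, k] <- g2$allele
        ids[k] <- cid
        anc[[cid]] <- cbind(g1$ancestry, g2$ancestry)
      })
      gen <- max(ped$generation[ped$id == sire],
                 ped$generation[ped$id == dam]) + 1L
      ped <- rbind(ped, data.frame(
        id = cid, sire = sire, dam = dam,
        sex = if (i %% 2L == 0L) "F" else "M",
        taxon = "cross", generation = gen, stringsAsFactors = FALSE))
    }
    panel <- HaplotypePanel(panel@markers, ids, hapA, hapB,
                            chromLengths = panel@chromLengths)
  }
  list(panel = panel, pedigree = Pedigree(ped),
       tracts = .ancestryToTracts(anc[panel@samples], panel@markers))
}

#' Random colony breeding plan
#'
#' Generation 1 pairs olive with yellow founders (F1 hybrids); later
#' generations mate individuals drawn at random from all previous
#' generations, which spreads truth ancestry across \[0, 1\].
#'
#' @param nOlive,nYellow founder counts.
#' @param nF1 number of F1 crosses.
#' @param nGen total generations of crossing (>= 1).
#' @param nPerGen offspring per generation after the first.
#' @param seed integer seed.
#' @return a design list for [simulatePedigree()].
#' @export
makeColonyPlan <- function(nOlive = 9, nYellow = 9, nF1 = 10, nGen = 2,
                           nPerGen = 30, seed = 1L) {
  withSeed(seed, {
    olive <- paste0("O", seq_len(nOlive))
    yellow <- paste0("Y", seq_len(nYellow))
    crosses <- data.frame(id = character(0), sire = character(0),
                          dam = character(0), stringsAsFactors = FALSE)
    prev <- c(olive, yellow)
    f1 <- paste0("F1_", seq_len(nF1))
    crosses <- rbind(crosses, data.frame(
      id = f1,
      sire = sample(olive, nF1, replace = TRUE),
      dam = sample(yellow, nF1, replace = TRUE),
      stringsAsFactors = FALSE))
    prev <- c(prev, f1)
    if (nGen >= 2) for (g in 2:nGen) {
      ids <- paste0("G", g, "_", seq_len(nPerGen))
      pars <- t(vapply(seq_len(nPerGen),
                       function(i) sample(prev, 2L), character(2)))
      crosses <- rbind(crosses, data.frame(
        id = ids, sire = pars[, 1], dam = pars[, 2],
        stringsAsFactors = FALSE))
      prev <- c(prev, ids)
    }
    list(founders = c(olive = nOlive, yellow = nYellow), crosses = crosses)
  })
}

#' Inject phase-switch errors
#'
#' At each selected inter-marker boundary the suffixes of a sample's two
#' haplotypes -- allele sequences AND truth ancestry -- are exchanged from
#' that boundary to the chromosome end, exactly as a statistical-phasing
#' switch error manifests. The returned switch table is ground truth for
#' detection tests. Applying the same switch twice restores the original.
#'
#' @param panel a phased [HaplotypePanel-class].
#' @param truth truth [TractSet-class] aligned to the panel.
#' @param rate switches per Morgan (Poisson per sample per chromosome);
#'   ignored when `positions` is given.
#' @param positions optional explicit data.frame (sample, chrom, boundaryIdx)
#'   where boundaryIdx is the local 1-based index of the first marker after
#'   the switch (2 .. markers on the chromosome).
#' @param samples restrict random injection to these samples (default all).
#' @param gmap a [GeneticMap-class]; required when `rate` is used.
#' @param seed integer seed.
#' @return list with modified `panel`, `tracts` and the `switches` table.
#' @export
injectPhaseSwitches <- function(panel, truth, rate = NULL, positions = NULL,
                                samples = NULL, gmap = NULL, seed = 1L) {
  if (!panel@phased) stop("panel must be phased")
  chromIdx <- .chromIndex(panel@markers)
  if (is.null(positions)) {
    if (is.null(rate) || is.null(gmap))
      stop("either positions or both rate and gmap must be given")
    if (is.null(samples)) samples <- panel@samples
    morgans <- .chromMorgans(gmap)
    positions <- withSeed(seed, {
      out <- list(); k <- 0L
      for (s in samples) for (ch in names(chromIdx)) {
        m <- length(chromIdx[[ch]])
        if (m < 2L) next
        nSw <- stats::rpois(1L, rate * morgans[[ch]])
        if (nSw == 0L) next
        b <- sample(2:m, min(nSw, m - 1L))
        k <- k + 1L
        out[[k]] <- data.frame(sample = s, chrom = ch, boundaryIdx = b,
                               stringsAsFactors = FALSE)
      }
      if (k == 0L) data.frame(sample = character(0), chrom = character(0),
                              boundaryIdx = integer(0))
      else do.call(rbind, out)
    })
  }
  anc <- .tractsToAncestry(truth, panel@markers)
  hapA <- panel@hapA; hapB <- panel@hapB
  for (i in seq_len(nrow(positions))) {
    s <- positions$sample[i]; ch <- positions$chrom[i]
    b <- positions$boundaryIdx[i]
    gidx <- chromIdx[[ch]]
    if (is.null(gidx) || b < 2L || b > length(gidx))
      stop("switch boundary outside marker range")
    rows <- gidx[seq.int(b, length(gidx))]
    j <- match(s, panel@samples)
    tmp <- hapA[rows, j]; hapA[rows, j] <- hapB[rows, j]; hapB[rows, j] <- tmp
    tmp <- anc[[s]][rows, 1]
    anc[[s]][rows, 1] <- anc[[s]][rows, 2]
    anc[[s]][rows, 2] <- tmp
  }
  positions$bp <- vapply(seq_len(nrow(positions)), function(i)
    as.numeric(panel@markers$pos[chromIdx[[positions$chrom[i]]][positions$boundaryIdx[i]]]),
    numeric(1))
  list(panel = HaplotypePanel(panel@markers, panel@samples, hapA, hapB,
                              phased = TRUE, degraded = panel@degraded,
                              chromLengths = panel@chromLengths),
       tracts = .ancestryToTracts(anc, panel@markers, codes = truth@codes),
       switches = positions)
}

#' Degrade genotypes with genotype-level missingness
#'
#' Each sample-by-marker genotype is set to missing independently with
#' probability `missingRate`; both haplotype values are masked jointly, as
#' sequencing missingness manifests in a VCF.
#'
#' @param panel a [HaplotypePanel-class].
#' @param missingRate probability in \[0, 1).
#' @param seed integer seed.
#' @return A degraded [HaplotypePanel-class].
#' @export
degradeGenotypes <- function(panel, missingRate, seed = 1L) {
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must lie in [0, 1)")
  if (missingRate == 0) return(panel)
  withSeed(seed, {
    mask <- matrix(stats::runif(length(panel@hapA)) < missingRate,
                   nrow(panel@hapA))
    hapA <- panel@hapA; hapB <- panel@hapB
    hapA[mask] <- NA_integer_; hapB[mask] <- NA_integer_
    HaplotypePanel(panel@markers, panel@samples, hapA, hapB,
                   phased = panel@phased, degraded = TRUE,
                   chromLengths = panel@chromLengths)
  })
}
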