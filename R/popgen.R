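# Weir-Cockerham F_ST, marker filtering, LD pruning and AIMs selection.

#' Per-marker Weir-Cockerham F_ST (two populations, diploid)
#'
#' Computes the Weir & Cockerham (1984) variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals) from sample sizes, alternate-allele frequencies and observed
#' heterozygote frequencies, using marker-wise complete cases. The point
#' estimate is a / (a + b + c); it is exactly 1 when the two populations are
#' fixed for different alleles, and undefined (NA, flagged "monomorphic")
#' when the denominator is not positive. Markers where either population has
#' fewer than two usable diploids are flagged "insufficient", not dropped.
#'
#' @param panel a [HaplotypePanel-class].
#' @param popAssignment named vector (sample id -> 0 or 1) covering a subset
#'   of the panel's samples; unassigned samples are ignored.
#' @return data.frame (one row per marker): chrom, pos, ref, alt, n0, n1,
#'   p0, p1, h0, h1, num (a), den (a+b+c), fst, flag ("ok", "monomorphic" or
#'   "insufficient").
#' @export
wcFstPerMarker <- function(panel, popAssignment) {
  pops <- sort(unique(popAssignment))
  if (length(pops) != 2L) stop("exactly two populations are required")
  dose <- dosageMatrix(panel)
  idx0 <- match(names(popAssignment)[popAssignment == pops[1]], panel@samples)
  idx1 <- match(names(popAssignment)[popAssignment == pops[2]], panel@samples)
  if (anyNA(idx0) || anyNA(idx1)) stop("unknown sample in popAssignment")
  G0 <- dose[, idx0, drop = FALSE]; G1 <- dose[, idx1, drop = FALSE]
  n0 <- rowSums(!is.na(G0)); n1 <- rowSums(!is.na(G1))
  p0 <- rowSums(G0, na.rm = TRUE) / (2 * n0)
  p1 <- rowSums(G1, na.rm = TRUE) / (2 * n1)
  h0 <- rowSums(G0 == 1L, na.rm = TRUE) / n0
  h1 <- rowSums(G1 == 1L, na.rm = TRUE) / n1

  r <- 2
  nbar <- (n0 + n1) / 2
  nc <- (r * nbar - (n0^2 + n1^2) / (r * nbar)) / (r - 1)
  pbar <- (n0 * p0 + n1 * p1) / (r * nbar)
  s2 <- (n0 * (p0 - pbar)^2 + n1 * (p1 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n0 * h0 + n1 * h1) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  den <- a + b + cc
  fst <- ifelse(den > 0, a / den, NA_real_)

  flag <- rep("ok", nrow(dose))
  flag[!is.na(den) & den <= 0] <- "monomorphic"
  insuff <- n0 < 2 | n1 < 2
  flag[insuff] <- "insufficient"
  a[insuff] <- NA_real_; den[insuff] <- NA_real_; fst[insuff] <- NA_real_
  data.frame(chrom = panel@markers$chrom, pos = panel@markers$pos,
             ref = panel@markers$ref, alt = panel@markers$alt,
             n0 = n0, n1 = n1, p0 = p0, p1 = p1, h0 = h0, h1 = h1,
             num = a, den = den, fst = fst, flag = flag,
             stringsAsFactors = FALSE)
}

#' Weighted (ratio-of-sums) F_ST over a marker table
#'
#' The weighted estimate divides the summed among-population variance
#' component by the summed total, over markers with defined components
#' (PLINK's weighted mean). Invariant to marker order.
#'
#' @param table output of [wcFstPerMarker()].
#' @return scalar weighted F_ST.
#' @export
weightedFst <- function(table) {
  ok <- !is.na(table$num) & !is.na(table$den)
  if (!any(ok)) stop("all markers have undefined F_ST components")
  sum(table$num[ok]) / sum(table$den[ok])
}

#' Count markers fixed for different alleles
#'
#' A marker is fixed when the observed allele frequencies are exactly 0 and
#' 1 in the two populations (equivalently, F_ST exactly 1 with no
#' within-population variance).
#'
#' @param table output of [wcFstPerMarker()].
#' @return list with `count` and `markers` (the fixed rows of the table).
#' @export
countFixedMarkers <- function(table) {
  fixed <- !is.na(table$p0) & !is.na(table$p1) &
    ((table$p0 == 0 & table$p1 == 1) | (table$p0 == 1 & table$p1 == 0)) &
    table$flag != "insufficient"
  list(count = sum(fixed), markers = table[fixed, , drop = FALSE])
}

#' Filter markers on missingness and minor allele frequency
#'
#' Retains markers whose missing-genotype fraction is at most `maxMissing`
#' and whose minor-allele frequency, computed on non-missing genotypes, is at
#' least `minMaf`. Marker order is preserved.
#'
#' @param panel a [HaplotypePanel-class].
#' @param maxMissing maximum tolerated missing fraction in \[0, 1\]
#'   (0 removes any marker with a single missing genotype).
#' @param minMaf minimum minor allele frequency in \[0, 0.5\].
#' @return integer vector of retained marker indices.
#' @export
filterMarkers <- function(panel, maxMissing = 0, minMaf = 0.05) {
  dose <- dosageMatrix(panel)
  missFrac <- rowMeans(is.na(dose))
  nOb <- rowSums(!is.na(dose))
  p <- rowSums(dose, na.rm = TRUE) / (2 * pmax(nOb, 1L))
  maf <- pmin(p, 1 - p)
  which(missFrac <= maxMissing & nOb > 0 & maf >= minMaf)
}

# minor allele frequency per marker (complete cases)
.maf <- function(dose) {
  nOb <- rowSums(!is.na(dose))
  p <- rowSums(dose, na.rm = TRUE) / (2 * pmax(nOb, 1L))
  pmin(p, 1 - p)
}

#' Squared dosage correlation between two markers
#'
#' r-squared is the squared Pearson correlation of diploid dosage (0/1/2)
#' across complete-case samples; 0 by convention when either marker has zero
#' variance, NA (undefined) with fewer than two complete cases.
#'
#' @param panel a [HaplotypePanel-class].
#' @param i,j marker row indices.
#' @return r-squared in \[0, 1\], or NA.
#' @export
ldR2 <- function(panel, i, j) {
  dose <- dosageMatrix(panel)
  x <- dose[i, ]; y <- dose[j, ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  stats::cor(x, y)^2
}

# Pairwise r2 matrix of a dosage matrix (markers x samples), pairwise
# complete cases. Zero-variance or <2-case pairs come out NA; callers treat
# NA as "not above threshold", which matches the ldR2 convention of 0 for
# zero variance.
.r2Matrix <- function(dose) {
  suppressWarnings(stats::cor(t(dose), use = "pairwise.complete.obs")^2)
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `window` markers advanced by `step` markers over the
#' position-sorted marker list, in a single pass. Within each window, while
#' any surviving pair has r-squared above `r2Max`, the pair member with the
#' lower minor allele frequency is removed (ties broken by removing the
#' later-positioned marker). The procedure is deterministic. Note that with
#' few samples the chance r-squared between independent markers is of order
#' `1 / (nSamples - 1)`, so a strict threshold prunes heavily.
#' `window = 2, step = 1, r2Max = 0.05` reproduces strict pairwise pruning
#' of adjacent markers.
#'
#' @param panel a [HaplotypePanel-class].
#' @param markers integer marker indices to prune (position-sorted; default
#'   all markers).
#' @param window window size in markers (>= 2).
#' @param step step size in markers (>= 1).
#' @param r2Max maximum tolerated r-squared.
#' @return integer vector of surviving marker indices.
#' @export
ldPrune <- function(panel, markers = seq_len(nMarkers(panel)),
                    window, step = 1L, r2Max) {
  if (window < 2L) stop("window must be >= 2 markers")
  markers <- as.integer(markers)
  n <- length(markers)
  if (n < 2L) return(markers)
  dose <- dosageMatrix(panel)[markers, , drop = FALSE]
  maf <- .maf(dose)
  alive <- rep(TRUE, n)
  # single pass of windows anchored on the input list, as the field's
  # pruning tools do; within each window offending pairs are resolved to
  # exhaustion before the window advances
  for (ws in seq(1L, n, by = step)) {
    we <- min(ws + window - 1L, n)
    if (we <= ws) next
    loc0 <- (ws:we)[alive[ws:we]]
    if (length(loc0) < 2L) next
    r2 <- .r2Matrix(dose[loc0, , drop = FALSE])
    repeat {
      loc <- loc0[alive[loc0]]
      if (length(loc) < 2L) break
      removed <- FALSE
      for (i in seq_len(length(loc) - 1L)) {
        for (j in (i + 1L):length(loc)) {
          v <- r2[match(loc[i], loc0), match(loc[j], loc0)]
          if (!is.na(v) && v > r2Max) {
            # remove lower-MAF member; tie -> later-positioned marker
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
  }
  markers[alive]
}

#' Select an ancestry-informative marker (AIM) panel
#'
#' Four stages: (1) keep markers with F_ST strictly greater than `fstMin`;
#' (2) bin the survivors into non-overlapping `windowBp` windows anchored at
#' coordinate 0 on each chromosome and keep the highest-F_ST marker per
#' window, ties broken by the first marker in input order; (3) LD-prune the
#' kept set within each reference population separately using `popPrune` =
#' (window, step, r2max); (4) merge the stage-3 survivors and LD-prune once
#' more on the combined reference samples with the same parameters.
#'
#' @param table output of [wcFstPerMarker()] aligned to `panel`'s markers.
#' @param panel a [HaplotypePanel-class].
#' @param fstMin F_ST candidacy threshold (default 0.8, strict).
#' @param windowBp window width in bp (default 100000).
#' @param popPrune numeric length-3 `(window, step, r2max)` for the pruning
#'   stages (default `c(2, 1, 0.05)`).
#' @param refs list with per-population reference sample ids, e.g.
#'   `list(olive = ..., yellow = ...)`.
#' @return data.frame of retained markers (chrom, pos, ref, alt, fst,
#'   windowId, markerIdx) with a `stages` attribute recording survivor counts
#'   per stage. Empty when no marker passes stage 1.
#' @export
selectAims <- function(table, panel, fstMin = 0.8, windowBp = 100000L,
                       popPrune = c(2, 1, 0.05), refs) {
  if (nrow(table) != nMarkers(panel))
    stop("F_ST table must align with the panel's markers")
  cand <- which(!is.na(table$fst) & table$fst > fstMin)
  stages <- c(stage1 = length(cand))
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      fst = numeric(0), windowId = integer(0),
                      markerIdx = integer(0), stringsAsFactors = FALSE)
  if (length(cand) == 0L) {
    attr(empty, "stages") <- stages
    return(empty)
  }
  # stage 2: best marker per 100-kb bin, bins [k*windowBp, (k+1)*windowBp)
  win <- (table$pos[cand] - 1L) %/% as.integer(windowBp)
  key <- paste(table$chrom[cand], win)
  keep2 <- vapply(split(seq_along(cand), key), function(ii) {
    cand[ii][which.max(table$fst[cand[ii]])]   # which.max keeps first on tie
  }, integer(1))
  keep2 <- sort(unname(keep2))
  stages <- c(stages, stage2 = length(keep2))
  # stage 3: within-population pruning
  surv <- keep2
  for (popIds in refs) {
    sub <- subsetSamples(panel, popIds)
    surv <- intersect(surv, ldPrune(sub, keep2, window = popPrune[1],
                                    step = popPrune[2], r2Max = popPrune[3]))
  }
  stages <- c(stages, stage3 = length(surv))
  # stage 4: merged panel, prune once more
  merged <- subsetSamples(panel, unlist(refs, use.names = FALSE))
  surv <- ldPrune(merged, sort(surv), window = popPrune[1],
                  step = popPrune[2], r2Max = popPrune[3])
  stages <- c(stages, stage4 = length(surv))
  out <- data.frame(chrom = table$chrom[surv], pos = table$pos[surv],
                    ref = table$ref[surv], alt = table$alt[surv],
                    fst = table$fst[surv],
                    windowId = (table$pos[surv] - 1L) %/% as.integer(windowBp),
                    markerIdx = surv, stringsAsFactors = FALSE)
  attr(out, "stages") <- stages
  out
}
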