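# Tract statistics, F1-based phase-switch detection and correction
# ("unkinking"), trio Mendelian local-ancestry auditing, pedigree-label
# auditing and a text karyogram.

#' Per-sample tract and switch statistics
#'
#' Switches are counted as tracts-minus-one per chromosome per haplotype,
#' summed; the tract counts themselves are also reported since both
#' statistics are in common use.
#'
#' @param tractset a [TractSet-class].
#' @return list with `perChrom` (sample, hap, chrom, nTracts) and `perSample`
#'   (sample, nTracts, nSwitches).
#' @export
tractStatistics <- function(tractset) {
  tr <- tractset@tracts
  key <- interaction(tr$sample, tr$hap, tr$chrom, drop = TRUE)
  perChrom <- do.call(rbind, lapply(split(seq_len(nrow(tr)), key),
    function(ii) data.frame(sample = tr$sample[ii[1]], hap = tr$hap[ii[1]],
                            chrom = tr$chrom[ii[1]], nTracts = length(ii),
                            stringsAsFactors = FALSE)))
  rownames(perChrom) <- NULL
  perSample <- do.call(rbind, lapply(split(seq_len(nrow(perChrom)),
                                           perChrom$sample),
    function(ii) data.frame(sample = perChrom$sample[ii[1]],
                            nTracts = sum(perChrom$nTracts[ii]),
                            nSwitches = sum(perChrom$nTracts[ii] - 1L),
                            stringsAsFactors = FALSE)))
  rownames(perSample) <- NULL
  list(perChrom = perChrom, perSample = perSample)
}

#' Detect joint (complementary) ancestry switches in one sample
#'
#' A phase-switch candidate is an inter-marker boundary where haplotype 0
#' changes ancestry X to Y AND haplotype 1 changes Y to X at the same
#' boundary. In an F1 hybrid every genuine ancestry change must be of this
#' joint complementary form, so these boundaries indicate phasing errors.
#' One-sided ancestry changes are never returned: they may be genuine
#' admixture.
#'
#' @param tractset a [TractSet-class].
#' @param sample sample id.
#' @return data.frame (chrom, boundaryIdx, bp) of joint-switch boundaries;
#'   boundaryIdx is the local index of the first marker after the switch.
#' @export
detectJointSwitches <- function(tractset, sample) {
  tr <- tractset@tracts
  tr <- tr[tr$sample == sample, , drop = FALSE]
  if (nrow(tr) == 0L) stop("unknown sample: ", sample)
  out <- list(); k <- 0L
  for (ch in unique(tr$chrom)) {
    h0 <- tr[tr$hap == 0L & tr$chrom == ch, , drop = FALSE]
    h1 <- tr[tr$hap == 1L & tr$chrom == ch, , drop = FALSE]
    h0 <- h0[order(h0$startIdx), ]; h1 <- h1[order(h1$startIdx), ]
    b0 <- h0$startIdx[-1L]; b1 <- h1$startIdx[-1L]
    for (b in intersect(b0, b1)) {
      i0 <- match(b, h0$startIdx); i1 <- match(b, h1$startIdx)
      # complementary: hap0 X->Y and hap1 Y->X
      if (h0$ancestry[i0 - 1L] == h1$ancestry[i1] &&
          h1$ancestry[i1 - 1L] == h0$ancestry[i0]) {
        k <- k + 1L
        out[[k]] <- data.frame(chrom = ch, boundaryIdx = b,
                               bp = h0$startBp[i0], stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) return(data.frame(chrom = character(0),
                                 boundaryIdx = integer(0), bp = numeric(0)))
  do.call(rbind, out)
}

#' Correct phase-switch errors by unkinking one sample
#'
#' Scans each chromosome left to right and, at every joint-switch boundary,
#' exchanges the two haplotypes' suffixes (alleles and ancestry) from that
#' boundary to the chromosome end. After processing no joint switches remain.
#' Unkinking never changes the multiset of alleles at any marker (it only
#' re-partitions them between the haplotypes) and never changes the sample's
#' tract-derived global ancestry. The operation is idempotent.
#'
#' @param panel a phased [HaplotypePanel-class].
#' @param tractset a [TractSet-class] containing `sample`.
#' @param sample sample id.
#' @return list with corrected `panel`, `tracts` (all samples, the corrected
#'   one replaced) and `nCorrections`.
#' @export
unkink <- function(panel, tractset, sample) {
  sw <- detectJointSwitches(tractset, sample)
  anc <- .tractsToAncestry(tractset, panel@markers)
  chromIdx <- .chromIndex(panel@markers)
  hapA <- panel@hapA; hapB <- panel@hapB
  j <- match(sample, panel@samples)
  if (is.na(j)) stop("sample not in panel: ", sample)
  if (nrow(sw) > 0L) {
    sw <- sw[order(match(sw$chrom, names(chromIdx)), sw$boundaryIdx), ,
             drop = FALSE]
    for (i in seq_len(nrow(sw))) {
      gidx <- chromIdx[[sw$chrom[i]]]
      rows <- gidx[seq.int(sw$boundaryIdx[i], length(gidx))]
      tmp <- hapA[rows, j]; hapA[rows, j] <- hapB[rows, j]
      hapB[rows, j] <- tmp
      tmp <- anc[[sample]][rows, 1]
      anc[[sample]][rows, 1] <- anc[[sample]][rows, 2]
      anc[[sample]][rows, 2] <- tmp
    }
  }
  newPanel <- HaplotypePanel(panel@markers, panel@samples, hapA, hapB,
                             phased = panel@phased, degraded = panel@degraded,
                             chromLengths = panel@chromLengths)
  newTracts <- .ancestryToTracts(anc, panel@markers, codes = tractset@codes)
  list(panel = newPanel, tracts = newTracts, nCorrections = nrow(sw))
}

#' Summarize switch counts before and after correction
#'
#' Per-sample and aggregate switch counts with the percent reduction
#' `100 * (before - after) / before`; a sample with zero switches before
#' correction reports 0 with a flag.
#'
#' @param before,after `perSample` tables from [tractStatistics()] (or the
#'   lists themselves) on the same samples.
#' @return list with `perSample` (sample, before, after, reductionPct,
#'   flag) and `aggregate` (totals and overall reduction).
#' @export
f1SwitchReport <- function(before, after) {
  if (is.list(before) && !is.data.frame(before)) before <- before$perSample
  if (is.list(after) && !is.data.frame(after)) after <- after$perSample
  m <- merge(before[, c("sample", "nSwitches")],
             after[, c("sample", "nSwitches")], by = "sample",
             suffixes = c("Before", "After"))
  red <- ifelse(m$nSwitchesBefore > 0,
                100 * (m$nSwitchesBefore - m$nSwitchesAfter) /
                  m$nSwitchesBefore, 0)
  per <- data.frame(sample = m$sample, before = m$nSwitchesBefore,
                    after = m$nSwitchesAfter, reductionPct = red,
                    flag = ifelse(m$nSwitchesBefore == 0, "no-switches", ""),
                    stringsAsFactors = FALSE)
  tb <- sum(per$before); ta <- sum(per$after)
  agg <- data.frame(before = tb, after = ta,
                    reductionPct = if (tb > 0) 100 * (tb - ta) / tb else 0,
                    flag = if (tb == 0) "no-switches" else "")
  list(perSample = per, aggregate = agg)
}

# per-marker count of ancestry-0 copies (0/1/2) for one sample
.ancestryDosage <- function(tractset, markers, sample) {
  anc <- .tractsToAncestry(tractset, markers)
  if (!sample %in% names(anc)) stop("unknown sample: ", sample)
  m <- anc[[sample]]
  (m[, 1] == 0L) + (m[, 2] == 0L)
}

#' Trio Mendelian local-ancestry audit
#'
#' At each marker, the offspring is flagged inconsistent when it carries two
#' copies of ancestry X while at least one parent carries two copies of the
#' other ancestry (that parent must transmit its ancestry, so the offspring
#' must carry at least one copy of it). Only homozygous-ancestry evidence is
#' used; heterozygous configurations are never flagged. Marker grids of the
#' three samples must be identical: a mismatch is an error, not a silent
#' intersection.
#'
#' @param tractset a [TractSet-class] containing all three samples.
#' @param markers the marker table the tracts are indexed against.
#' @param offspring,sire,dam sample ids.
#' @return list with `perMarker` (chrom, pos, offCopies, sireCopies,
#'   damCopies, inconsistent) and `fraction` (flagged / total).
#' @export
trioConsistency <- function(tractset, markers, offspring, sire, dam) {
  tr <- tractset@tracts
  for (s in c(offspring, sire, dam))
    if (!any(tr$sample == s)) stop("unknown sample: ", s)
  covered <- function(s) {
    sub <- tr[tr$sample == s, ]
    out <- stats::aggregate(list(n = sub$endIdx), list(chrom = sub$chrom,
                                                       hap = sub$hap), max)
    out[order(out$chrom, out$hap), ]
  }
  if (!identical(covered(offspring)[, c("chrom", "hap", "n")],
                 covered(sire)[, c("chrom", "hap", "n")]) ||
      !identical(covered(offspring)[, c("chrom", "hap", "n")],
                 covered(dam)[, c("chrom", "hap", "n")]))
    stop("marker grids differ between trio members")
  offD <- .ancestryDosage(tractset, markers, offspring)
  sireD <- .ancestryDosage(tractset, markers, sire)
  damD <- .ancestryDosage(tractset, markers, dam)
  # offspring hom ancestry-0 while a parent is hom ancestry-1, or vice versa
  bad <- (offD == 2L & (sireD == 0L | damD == 0L)) |
         (offD == 0L & (sireD == 2L | damD == 2L))
  perMarker <- data.frame(chrom = markers$chrom, pos = markers$pos,
                          offCopies = offD, sireCopies = sireD,
                          damCopies = damD, inconsistent = bad,
                          stringsAsFactors = FALSE)
  list(perMarker = perMarker, fraction = mean(bad))
}

#' Audit pedigree taxon labels against global ancestry estimates
#'
#' Flags (strict inequalities): (i) olive-labelled samples with olive
#' ancestry below `major`; (ii) yellow-labelled samples with yellow ancestry
#' below `major`; (iii) cross-labelled samples with either ancestry above
#' `major`, sub-flagged `"pure-like"` when above `pure`. Samples missing a
#' label or an estimate are listed separately, not flagged.
#'
#' @param global GlobalAncestry data.frame (sample, qOlive, qYellow).
#' @param pedigree a [Pedigree-class].
#' @param major majority-ancestry threshold (default 0.90).
#' @param pure purity threshold (default 0.99).
#' @return data.frame: sample, taxon, qOlive, flag in
#'   `{"olive-low", "yellow-low", "cross-major", "cross-pure-like", "none",
#'   "missing"}`.
#' @export
auditPedigreeLabels <- function(global, pedigree, major = 0.90, pure = 0.99) {
  rec <- pedigree@records
  all <- union(global$sample, rec$id)
  q <- global$qOlive[match(all, global$sample)]
  taxon <- rec$taxon[match(all, rec$id)]
  flag <- rep("none", length(all))
  flag[is.na(q) | is.na(taxon)] <- "missing"
  ok <- flag != "missing"
  flag[ok & taxon == "olive" & q < major] <- "olive-low"
  flag[ok & taxon == "yellow" & (1 - q) < major] <- "yellow-low"
  isCross <- ok & taxon == "cross"
  flag[isCross & pmax(q, 1 - q) > major] <- "cross-major"
  flag[isCross & pmax(q, 1 - q) > pure] <- "cross-pure-like"
  data.frame(sample = all, taxon = taxon, qOlive = q, flag = flag,
             stringsAsFactors = FALSE)
}

#' Text karyogram of one sample's local ancestry
#'
#' Renders two character rows per chromosome (one per haplotype); each
#' column spans an equal share of the chromosome's tract span and shows the
#' majority-bp ancestry within that span (first letter of the ancestry name).
#'
#' @param tractset a [TractSet-class].
#' @param sample sample id.
#' @param width number of character columns (>= 1).
#' @return character vector of lines, printed nicely by `cat()`.
#' @export
textKaryogram <- function(tractset, sample, width = 60L) {
  if (width < 1L) stop("width must be >= 1")
  tr <- tractset@tracts
  tr <- tr[tr$sample == sample, , drop = FALSE]
  if (nrow(tr) == 0L) stop("unknown sample: ", sample)
  chars <- substr(names(tractset@codes), 1L, 1L)
  names(chars) <- as.character(tractset@codes)
  lines <- character(0)
  for (ch in unique(tr$chrom)) {
    for (hap in 0:1) {
      sub <- tr[tr$chrom == ch & tr$hap == hap, , drop = FALSE]
      lo <- min(sub$startBp); hi <- max(sub$endBp)
      edges <- seq(lo, hi, length.out = width + 1L)
      row <- vapply(seq_len(width), function(k) {
        a <- edges[k]; b <- edges[k + 1L]
        ov <- pmax(0, pmin(sub$endBp, b) - pmax(sub$startBp, a))
        bpPer <- tapply(ov, sub$ancestry, sum)
        names(which.max(bpPer))
      }, character(1))
      lines <- c(lines, paste0(ch, ".", hap, " ",
                               paste(chars[row], collapse = "")))
    }
  }
  lines
}
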