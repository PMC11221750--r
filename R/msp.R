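# RFMix-v2-style msp.tsv input/output for local-ancestry tracts.

#' Write tracts as an RFMix-style msp file
#'
#' Emits one row per maximal constant-ancestry segment across all samples:
#' segment boundaries are the union of every haplotype's tract boundaries.
#' Line 1 lists the subpopulation codes; line 2 is the column header
#' (`#chm spos epos sgpos egpos n snps` followed by two columns per sample).
#' Genetic positions come from `gmap`.
#'
#' @param tractset a [TractSet-class].
#' @param gmap a [GeneticMap-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeMsp <- function(tractset, gmap, path) {
  tr <- tractset@tracts
  codes <- tractset@codes
  samples <- unique(tr$sample)
  hdr1 <- paste0("#Subpopulation order/codes: ",
                 paste(names(codes), codes, sep = "=", collapse = "\t"))
  hdr2 <- paste(c("#chm", "spos", "epos", "sgpos", "egpos", "n snps",
                  paste(rep(samples, each = 2), 0:1, sep = ".")),
                collapse = "\t")
  lines <- c(hdr1, hdr2)
  for (ch in unique(tr$chrom)) {
    sub <- tr[tr$chrom == ch, , drop = FALSE]
    # union of all haplotypes' boundaries, in local marker indices
    cuts <- sort(unique(c(sub$startIdx, max(sub$endIdx))))
    for (k in seq_len(length(cuts) - 1L)) {
      sIdx <- cuts[k]; eIdx <- cuts[k + 1L]
      row <- sub[sub$startIdx <= sIdx & sub$endIdx >= eIdx, , drop = FALSE]
      key <- paste(row$sample, row$hap)
      anc <- row$ancestry[match(paste(rep(samples, each = 2), 0:1), key)]
      # every cut coincides with some tract's start (or terminal end), so
      # the segment's physical bounds can be read off those tracts
      spos <- min(sub$startBp[sub$startIdx == sIdx])
      epos <- max(sub$endBp[sub$endIdx == eIdx])
      sg <- interpolateCm(gmap, ch, spos)
      eg <- interpolateCm(gmap, ch, epos)
      lines <- c(lines, paste(c(ch, format(spos, scientific = FALSE),
                                format(epos, scientific = FALSE),
                                sprintf("%.5f", sg), sprintf("%.5f", eg),
                                eIdx - sIdx, anc), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an RFMix-style msp file into a TractSet
#'
#' Consecutive rows with equal ancestry code merge into tracts per
#' haplotype; marker indices are rebuilt from the cumulative `n snps`
#' column. Round-tripping [writeMsp()] then `readMsp()` preserves every
#' haplotype's per-position ancestry.
#'
#' @param path msp file path.
#' @return A [TractSet-class].
#' @export
readMsp <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1], "#Subpopulation"))
    stop("malformed msp header")
  codeTxt <- sub("^#Subpopulation order/codes:\\s*", "", lines[1])
  pairs <- strsplit(strsplit(codeTxt, "\t")[[1]], "=")
  codes <- stats::setNames(as.integer(vapply(pairs, `[`, "", 2)),
                           vapply(pairs, `[`, "", 1))
  cols <- strsplit(lines[2], "\t")[[1]]
  hapCols <- cols[-(1:6)]
  sampleOf <- sub("\\.[01]$", "", hapCols)
  hapOf <- as.integer(sub("^.*\\.", "", hapCols))
  body <- strsplit(lines[-(1:2)], "\t")
  ncol <- length(cols)
  if (any(vapply(body, length, 1L) != ncol)) stop("ragged msp rows")
  chm <- vapply(body, `[`, "", 1)
  spos <- as.numeric(vapply(body, `[`, "", 2))
  epos <- as.numeric(vapply(body, `[`, "", 3))
  nsnp <- as.integer(vapply(body, `[`, "", 6))
  anc <- t(vapply(body, function(x) as.integer(x[-(1:6)]), integer(ncol - 6L)))
  if (any(!(anc %in% codes))) stop("unknown ancestry code in msp body")
  rows <- list(); k <- 0L
  for (ci in seq_along(hapCols)) {
    for (ch in unique(chm)) {
      sel <- which(chm == ch)
      v <- anc[sel, ci]
      r <- rle(v)
      endRow <- cumsum(r$lengths); startRow <- c(1L, head(endRow, -1L) + 1L)
      cumSnp <- cumsum(nsnp[sel])
      startIdx <- c(1L, head(cumSnp, -1L) + 1L)
      k <- k + 1L
      rows[[k]] <- data.frame(
        sample = sampleOf[ci], hap = hapOf[ci], chrom = ch,
        startBp = spos[sel][startRow], endBp = epos[sel][endRow],
        startIdx = startIdx[startRow], endIdx = cumSnp[endRow] + 1L,
        ancestry = r$values, stringsAsFactors = FALSE)
    }
  }
  TractSet(do.call(rbind, rows), codes = codes)
}
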