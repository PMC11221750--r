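# Recombination-map handling: rate intervals -> cumulative cM, interpolation,
# and PLINK / SHAPEIT map file dialects.

#' Build a cumulative genetic map from recombination-rate intervals
#'
#' Each interval contributes `(end - start) * rate * 100` centimorgans
#' (1 cM/Mb corresponds to a rate of 1e-8 per bp); the cumulative distance is
#' the running sum along the chromosome. Gaps between intervals contribute
#' 0 cM, i.e. are treated as rate-0 regions. Cumulative cM is 0 at the start
#' of each chromosome's first interval.
#'
#' @param intervals data.frame with columns chrom, start, end (bp, half-open)
#'   and rate (recombination probability per bp, >= 0).
#' @return A [GeneticMap-class].
#' @examples
#' gm <- cmFromRate(data.frame(chrom = "1", start = 0, end = 1e6, rate = 1e-8))
#' mapNodes(gm)  # 1 Mb at 1e-8/bp = 1 cM
#' @export
cmFromRate <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end", "rate") %in% names(intervals)))
  if (any(intervals$rate < 0)) stop("negative recombination rate")
  if (any(intervals$end < intervals$start)) stop("interval end before start")
  intervals <- intervals[order(match(intervals$chrom,
                                     unique(intervals$chrom)),
                               intervals$start), , drop = FALSE]
  nodes <- lapply(unique(intervals$chrom), function(ch) {
    sub <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("overlapping rate intervals on chromosome ", ch)
    len <- (sub$end - sub$start) * sub$rate * 100
    cmEnd <- cumsum(len)
    cmStart <- c(0, cmEnd[-length(cmEnd)])
    pos <- c(rbind(sub$start, sub$end))
    cM <- c(rbind(cmStart, cmEnd))
    keep <- !duplicated(pos)       # shared interval endpoints collapse
    data.frame(chrom = ch, pos = pos[keep], cM = cM[keep],
               stringsAsFactors = FALSE)
  })
  GeneticMap(do.call(rbind, nodes))
}

#' Interpolate cumulative genetic position
#'
#' Linear interpolation of cumulative cM between map nodes; positions at a
#' node return the node value exactly, and positions outside the mapped span
#' clamp to the terminal cM values.
#'
#' @param gmap a [GeneticMap-class].
#' @param chrom chromosome id.
#' @param pos physical position(s) in bp (vectorised).
#' @return numeric cumulative cM value(s).
#' @export
interpolateCm <- function(gmap, chrom, pos) {
  nd <- gmap@nodes[gmap@nodes$chrom == chrom, , drop = FALSE]
  if (nrow(nd) == 0L) stop("unknown chromosome: ", chrom)
  if (nrow(nd) == 1L) return(rep(nd$cM, length(pos)))
  stats::approx(nd$pos, nd$cM, xout = pos, rule = 2, ties = "ordered")$y
}

# Inverse lookup: genetic position (cM) -> physical bp on one chromosome.
# Flat (zero-rate) stretches are skipped; a cM value falling exactly on a
# flat stretch maps to its left edge.
.bpFromCm <- function(gmap, chrom, cm) {
  nd <- gmap@nodes[gmap@nodes$chrom == chrom, , drop = FALSE]
  if (nrow(nd) == 0L) stop("unknown chromosome: ", chrom)
  cm <- .clamp(cm, min(nd$cM), max(nd$cM))
  vapply(cm, function(x) {
    i <- findInterval(x, nd$cM, rightmost.closed = TRUE)
    i <- max(1L, min(i, nrow(nd) - 1L))
    dcm <- nd$cM[i + 1L] - nd$cM[i]
    if (dcm <= 0) return(nd$pos[i])
    nd$pos[i] + (x - nd$cM[i]) / dcm * (nd$pos[i + 1L] - nd$pos[i])
  }, numeric(1))
}

# Total genetic length (Morgans) per chromosome.
.chromMorgans <- function(gmap) {
  nd <- gmap@nodes
  vapply(split(nd$cM, nd$chrom)[unique(nd$chrom)],
         function(x) (max(x) - min(x)) / 100, numeric(1))
}

#' Read a tab-separated recombination-rate map
#'
#' Expects columns chrom, start, end, rate (per bp); a header line is
#' detected and skipped automatically.
#'
#' @param path file path.
#' @return data.frame of rate intervals suitable for [cmFromRate()].
#' @export
readRateMap <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t")[[1]][2])))
  df <- utils::read.table(path, sep = "\t", header = hasHeader,
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "rate")
  df$chrom <- as.character(df$chrom)
  df
}

#' Write marker genetic positions in PLINK or SHAPEIT dialect
#'
#' PLINK dialect: four headerless columns (chrom, marker id, cM, bp).
#' SHAPEIT dialect: three columns with header `pos chr cM`. Marker cM values
#' come from [interpolateCm()], so positions outside the map clamp.
#'
#' @param gmap a [GeneticMap-class].
#' @param markers marker data.frame (chrom, pos; an `id` column is used if
#'   present, else ids are `chrom:pos`).
#' @param dialect `"plink"` or `"shapeit"`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeGeneticMap <- function(gmap, markers, dialect = c("plink", "shapeit"),
                            path) {
  dialect <- match.arg(dialect)
  lines <- character(0)
  if (nrow(markers) > 0L) {
    cm <- unlist(lapply(unique(markers$chrom), function(ch)
      interpolateCm(gmap, ch, markers$pos[markers$chrom == ch])))
    id <- if ("id" %in% names(markers)) markers$id else .markerKey(markers)
    cmTxt <- sprintf("%.8f", cm)
    lines <- if (dialect == "plink") {
      paste(markers$chrom, id, cmTxt, markers$pos, sep = "\t")
    } else {
      paste(markers$pos, markers$chrom, cmTxt, sep = "\t")
    }
  }
  if (dialect == "shapeit") lines <- c("pos\tchr\tcM", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a PLINK- or SHAPEIT-style genetic map file
#'
#' The markers in the file become the nodes of a piecewise-linear
#' [GeneticMap-class]; non-monotone cM values are an error.
#'
#' @param path file path.
#' @param dialect `"plink"` or `"shapeit"`.
#' @return A [GeneticMap-class].
#' @export
readGeneticMap <- function(path, dialect = c("plink", "shapeit")) {
  dialect <- match.arg(dialect)
  if (dialect == "plink") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    nodes <- data.frame(chrom = as.character(df[[1]]), pos = df[[4]],
                        cM = df[[3]], stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    nodes <- data.frame(chrom = as.character(df$chr), pos = df$pos,
                        cM = df$cM, stringsAsFactors = FALSE)
  }
  for (ch in unique(nodes$chrom)) {
    if (is.unsorted(nodes$cM[nodes$chrom == ch]))
      stop("non-monotone cM values on chromosome ", ch)
  }
  GeneticMap(nodes)
}

#' Uniform-rate map for a set of chromosomes
#'
#' Convenience constructor used by the simulator: one constant-rate interval
#' spanning each chromosome.
#'
#' @param chromLengths named chromosome lengths in bp.
#' @param rate recombination rate per bp (default 1e-8, i.e. 1 cM/Mb).
#' @return A [GeneticMap-class].
#' @export
uniformRateMap <- function(chromLengths, rate = 1e-8) {
  cmFromRate(data.frame(chrom = names(chromLengths), start = 0,
                        end = as.numeric(chromLengths), rate = rate,
                        stringsAsFactors = FALSE))
}
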