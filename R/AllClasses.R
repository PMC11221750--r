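#' @import methods
NULL

# ---------------------------------------------------------------------------
#' PopulationFrequencies: per-marker allele frequencies of two source
#' populations
#'
#' Holds an ordered marker table together with the alternate-allele frequency
#' of each marker in two reference populations (column 1 = population 0,
#' "olive-like"; column 2 = population 1, "yellow-like") and the ancestral
#' frequency used by the divergence simulator.
#'
#' @slot markers data.frame with columns chrom, pos (1-based), ref, alt.
#' @slot freq numeric matrix, nMarkers x 2, values in \[0, 1\].
#' @slot ancestralFreq numeric vector of ancestral frequencies in \[0, 1\].
#' @slot chromLengths named numeric vector of chromosome lengths in bp.
#' @exportClass PopulationFrequencies
setClass("PopulationFrequencies",
  representation(markers = "data.frame", freq = "matrix",
                 ancestralFreq = "numeric", chromLengths = "numeric"))

setValidity("PopulationFrequencies", function(object) {
  n <- nrow(object@markers)
  if (nrow(object@freq) != n || ncol(object@freq) != 2L)
    return("freq must be an nMarkers x 2 matrix")
  if (length(object@ancestralFreq) != n)
    return("ancestralFreq length must equal marker count")
  if (any(object@freq < 0 | object@freq > 1, na.rm = TRUE))
    return("frequencies must lie in [0, 1]")
  if (any(object@ancestralFreq < 0 | object@ancestralFreq > 1))
    return("ancestral frequencies must lie in [0, 1]")
  for (ch in unique(object@markers$chrom)) {
    p <- object@markers$pos[object@markers$chrom == ch]
    if (any(diff(p) <= 0))
      return(paste0("positions not strictly increasing on chromosome ", ch))
  }
  if (!all(object@markers$chrom %in% names(object@chromLengths)))
    return("all marker chromosomes must appear in chromLengths")
  TRUE
})

#' Construct a PopulationFrequencies object
#' @param markers marker data.frame (chrom, pos, ref, alt).
#' @param freq nMarkers x 2 matrix of alternate-allele frequencies.
#' @param ancestralFreq ancestral frequencies (defaults to the row mean).
#' @param chromLengths named chromosome lengths in bp.
#' @return A [PopulationFrequencies-class] object.
#' @export
PopulationFrequencies <- function(markers, freq, ancestralFreq = NULL,
                                  chromLengths = NULL) {
  if (is.null(chromLengths)) {
    chromLengths <- tapply(markers$pos, markers$chrom, max)
    chromLengths <- stats::setNames(as.numeric(chromLengths), names(chromLengths))
  }
  markers <- .checkMarkers(markers, names(chromLengths))
  if (is.null(ancestralFreq)) ancestralFreq <- rowMeans(freq)
  new("PopulationFrequencies", markers = markers, freq = freq,
      ancestralFreq = as.numeric(ancestralFreq),
      chromLengths = chromLengths)
}

# ---------------------------------------------------------------------------
#' HaplotypePanel: phased binary haplotypes over a marker set
#'
#' Two integer matrices (markers x samples) hold haplotype 0 and haplotype 1
#' of every sample; entries are 0 (reference allele), 1 (alternate) or NA
#' (missing, permitted only after genotype degradation).
#'
#' @slot markers marker data.frame (chrom, pos, ref, alt).
#' @slot samples character vector of sample identifiers.
#' @slot hapA,hapB integer matrices, markers x samples.
#' @slot phased logical; TRUE when haplotypes carry phase information.
#' @slot degraded logical; TRUE once missingness has been introduced.
#' @slot chromLengths named numeric chromosome lengths in bp.
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
  representation(markers = "data.frame", samples = "character",
                 hapA = "matrix", hapB = "matrix",
                 phased = "logical", degraded = "logical",
                 chromLengths = "numeric"))

setValidity("HaplotypePanel", function(object) {
  n <- nrow(object@markers); s <- length(object@samples)
  for (nm in c("hapA", "hapB")) {
    h <- slot(object, nm)
    if (nrow(h) != n || ncol(h) != s)
      return(paste0(nm, " must be markers x samples"))
    bad <- !(h %in% c(0L, 1L, NA))
    if (any(bad)) return("haplotype entries must be 0, 1 or NA")
  }
  if (!object@degraded && (anyNA(object@hapA) || anyNA(object@hapB)))
    return("missing haplotype values require the degraded flag")
  if (anyDuplicated(object@samples)) return("duplicate sample ids")
  TRUE
})

#' Construct a HaplotypePanel
#' @param markers marker data.frame.
#' @param samples sample identifiers.
#' @param hapA,hapB integer matrices (markers x samples) of phased alleles.
#' @param phased,degraded logical flags.
#' @param chromLengths named chromosome lengths (bp); defaults to max
#'   observed position per chromosome.
#' @return A [HaplotypePanel-class] object.
#' @export
HaplotypePanel <- function(markers, samples, hapA, hapB, phased = TRUE,
                           degraded = FALSE, chromLengths = NULL) {
  if (is.null(chromLengths)) {
    chromLengths <- tapply(markers$pos, markers$chrom, max)
    chromLengths <- stats::setNames(as.numeric(chromLengths), names(chromLengths))
  }
  markers <- .checkMarkers(markers, names(chromLengths))
  storage.mode(hapA) <- "integer"; storage.mode(hapB) <- "integer"
  colnames(hapA) <- samples; colnames(hapB) <- samples
  new("HaplotypePanel", markers = markers, samples = as.character(samples),
      hapA = hapA, hapB = hapB, phased = phased, degraded = degraded,
      chromLengths = chromLengths)
}

# ---------------------------------------------------------------------------
#' GeneticMap: cumulative genetic distance along chromosomes
#'
#' Piecewise-linear map from physical position (bp) to cumulative genetic
#' distance (cM), stored as ordered nodes per chromosome. Positions outside
#' the node span clamp to the terminal values.
#'
#' @slot nodes data.frame with columns chrom, pos (bp), cM (cumulative).
#' @exportClass GeneticMap
setClass("GeneticMap", representation(nodes = "data.frame"))

setValidity("GeneticMap", function(object) {
  nd <- object@nodes
  if (!all(c("chrom", "pos", "cM") %in% names(nd)))
    return("nodes need columns chrom, pos, cM")
  if (any(nd$cM < 0)) return("cumulative cM must be non-negative")
  for (ch in unique(nd$chrom)) {
    sub <- nd[nd$chrom == ch, ]
    if (is.unsorted(sub$pos, strictly = TRUE))
      return(paste0("node positions not strictly increasing on ", ch))
    if (is.unsorted(sub$cM)) return(paste0("cM not non-decreasing on ", ch))
  }
  TRUE
})

#' Construct a GeneticMap from a node table
#' @param nodes data.frame with columns chrom, pos, cM.
#' @return A [GeneticMap-class] object.
#' @export
GeneticMap <- function(nodes) {
  nodes <- nodes[order(match(nodes$chrom, unique(nodes$chrom)), nodes$pos), ]
  rownames(nodes) <- NULL
  new("GeneticMap", nodes = nodes)
}

# ---------------------------------------------------------------------------
#' TractSet: runs of constant local ancestry
#'
#' One row per maximal run of constant ancestry on one haplotype of one
#' sample. Marker indices are per-chromosome, 1-based and half-open
#' (\code{[startIdx, endIdx)}); physical bounds are \code{[startBp, endBp)}
#' with the terminal tract extended to the last marker position + 1.
#'
#' @slot tracts data.frame with columns sample, hap (0/1), chrom, startBp,
#'   endBp, startIdx, endIdx, ancestry (integer code).
#' @slot codes named integer vector mapping ancestry names to codes.
#' @exportClass TractSet
setClass("TractSet",
  representation(tracts = "data.frame", codes = "integer"))

setValidity("TractSet", function(object) {
  tr <- object@tracts
  need <- c("sample", "hap", "chrom", "startBp", "endBp",
            "startIdx", "endIdx", "ancestry")
  if (!all(need %in% names(tr))) return("missing tract columns")
  if (!all(tr$hap %in% c(0L, 1L))) return("hap must be 0 or 1")
  key <- paste(tr$sample, tr$hap, tr$chrom)
  for (k in unique(key)) {
    sub <- tr[key == k, , drop = FALSE]
    sub <- sub[order(sub$startBp), , drop = FALSE]
    if (any(diff(sub$startBp) <= 0)) return("tracts overlap or unsorted")
    if (nrow(sub) > 1L) {
      if (any(sub$endBp[-nrow(sub)] != sub$startBp[-1L]))
        return("tracts must tile without gap or overlap")
      if (any(sub$ancestry[-nrow(sub)] == sub$ancestry[-1L]))
        return("adjacent tracts must differ in ancestry")
      if (!anyNA(sub$startIdx) &&
          any(sub$endIdx[-nrow(sub)] != sub$startIdx[-1L]))
        return("marker indices must tile half-open")
    }
  }
  TRUE
})

#' Construct a TractSet
#' @param tracts tract data.frame (see [TractSet-class]).
#' @param codes named integer ancestry code table.
#' @return A [TractSet-class] object.
#' @export
TractSet <- function(tracts, codes = c(olive = 0L, yellow = 1L)) {
  tracts$hap <- as.integer(tracts$hap)
  tracts$ancestry <- as.integer(tracts$ancestry)
  tracts$startBp <- as.numeric(tracts$startBp)
  tracts$endBp <- as.numeric(tracts$endBp)
  rownames(tracts) <- NULL
  new("TractSet", tracts = tracts, codes = codes)
}

# ---------------------------------------------------------------------------
#' Pedigree: individual/sire/dam records with taxon labels
#'
#' @slot records data.frame with columns id, sire, dam (NA = unknown), sex,
#'   taxon (olive / yellow / cross), generation (integer >= 0).
#' @exportClass Pedigree
setClass("Pedigree", representation(records = "data.frame"))

setValidity("Pedigree", function(object) {
  rec <- object@records
  need <- c("id", "sire", "dam", "sex", "taxon", "generation")
  if (!all(need %in% names(rec))) return("missing pedigree columns")
  if (anyDuplicated(rec$id)) return("duplicate individual ids")
  known <- c(rec$sire, rec$dam)
  known <- known[!is.na(known)]
  if (!all(known %in% rec$id)) return("sire/dam ids must exist in the table")
  # generation ordering rules out ancestor cycles
  for (i in seq_len(nrow(rec))) {
    for (p in c(rec$sire[i], rec$dam[i])) {
      if (!is.na(p)) {
        g <- rec$generation[rec$id == p]
        if (g >= rec$generation[i])
          return("parents must precede offspring in generation number")
      }
    }
  }
  if (any(rec$generation == 0L & (!is.na(rec$sire) | !is.na(rec$dam))))
    return("founders (generation 0) must have unknown parents")
  TRUE
})

#' Construct a Pedigree
#' @param records pedigree data.frame (id, sire, dam, sex, taxon, generation).
#' @return A [Pedigree-class] object.
#' @export
Pedigree <- function(records) {
  records$id <- as.character(records$id)
  records$sire <- as.character(records$sire)
  records$dam <- as.character(records$dam)
  records$generation <- as.integer(records$generation)
  rownames(records) <- NULL
  new("Pedigree", records = records)
}

# ---------------------------------------------------------------------------
#' HmmConfig: parameters of the two-state local-ancestry HMM
#'
#' @slot g numeric; generations since admixture (> 0). Scales the switch
#'   probability between consecutive markers.
#' @slot eps numeric allele-error floor in (0, 0.5); emission probabilities
#'   are clamped to \[eps, 1 - eps\].
#' @slot prior numeric length-2 state prior (sums to 1).
#' @exportClass HmmConfig
setClass("HmmConfig",
  representation(g = "numeric", eps = "numeric", prior = "numeric"))

setValidity("HmmConfig", function(object) {
  if (object@g <= 0) return("g must be > 0")
  if (object@eps <= 0 || object@eps >= 0.5) return("eps must lie in (0, 0.5)")
  if (length(object@prior) != 2L || abs(sum(object@prior) - 1) > 1e-9)
    return("prior must be two probabilities summing to 1")
  TRUE
})

#' Construct an HmmConfig
#' @param g generations since admixture (default 8).
#' @param eps allele-error floor (default 0.005).
#' @param prior state prior (default uniform).
#' @return An [HmmConfig-class] object.
#' @export
hmmConfig <- function(g = 8, eps = 0.005, prior = c(0.5, 0.5)) {
  new("HmmConfig", g = g, eps = eps, prior = prior)
}

# ---------------------------------------------------------------------------
# show methods

setMethod("show", "PopulationFrequencies", function(object) {
  cat("PopulationFrequencies:", nrow(object@markers), "markers on",
      length(unique(object@markers$chrom)), "chromosome(s)\n")
  d <- abs(object@freq[, 1] - object@freq[, 2])
  cat("  mean |freq0 - freq1|:", format(mean(d), digits = 4),
      "| fixed differences:", sum(d == 1), "\n")
})

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", length(object@samples), "samples x",
      nrow(object@markers), "markers",
      if (object@phased) "(phased)" else "(unphased)",
      if (object@degraded) "[degraded]" else "", "\n")
})

setMethod("show", "GeneticMap", function(object) {
  nd <- object@nodes
  for (ch in unique(nd$chrom)) {
    sub <- nd[nd$chrom == ch, ]
    cat("  ", ch, ": ", nrow(sub), " nodes, ",
        format(max(sub$cM), digits = 6), " cM\n", sep = "")
  }
})

setMethod("show", "TractSet", function(object) {
  tr <- object@tracts
  cat("TractSet:", nrow(tr), "tracts,", length(unique(tr$sample)),
      "sample(s); codes:",
      paste(names(object@codes), object@codes, sep = "=", collapse = ", "),
      "\n")
})

setMethod("show", "Pedigree", function(object) {
  rec <- object@records
  cat("Pedigree:", nrow(rec), "individuals,",
      max(rec$generation) + 1L, "generation(s);",
      sum(rec$taxon == "cross"), "crosses\n")
})
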