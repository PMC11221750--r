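# Accessor generics and methods. Slot access from user code is discouraged;
# these are the supported surface.

#' @rdname accessors
#' @param x an admixqc object.
#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setGeneric("popFreq", function(x) standardGeneric("popFreq"))

#' @rdname accessors
#' @export
setGeneric("ancestralFreq", function(x) standardGeneric("ancestralFreq"))

#' @rdname accessors
#' @export
setGeneric("dosageMatrix", function(x) standardGeneric("dosageMatrix"))

#' @rdname accessors
#' @param hap haplotype index, 0 or 1.
#' @export
setGeneric("haplotypeMatrix", function(x, hap) standardGeneric("haplotypeMatrix"))

#' @rdname accessors
#' @export
setGeneric("tracts", function(x) standardGeneric("tracts"))

#' @rdname accessors
#' @export
setGeneric("ancestryCodes", function(x) standardGeneric("ancestryCodes"))

#' @rdname accessors
#' @export
setGeneric("mapNodes", function(x) standardGeneric("mapNodes"))

#' @rdname accessors
#' @export
setGeneric("pedRecords", function(x) standardGeneric("pedRecords"))

#' Accessors for admixqc classes
#'
#' `markerTable` returns the ordered marker data.frame; `sampleIds` the
#' sample identifiers; `dosageMatrix` the diploid alternate-allele dosage
#' (0/1/2, NA when missing); `haplotypeMatrix` one haplotype's allele matrix;
#' `tracts` the tract data.frame of a [TractSet-class]; `mapNodes` the node
#' table of a [GeneticMap-class]; `pedRecords` the pedigree records.
#'
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
setMethod("markerTable", "HaplotypePanel", function(x) x@markers)
#' @rdname accessors
setMethod("markerTable", "PopulationFrequencies", function(x) x@markers)
#' @rdname accessors
setMethod("sampleIds", "HaplotypePanel", function(x) x@samples)
#' @rdname accessors
setMethod("nMarkers", "HaplotypePanel", function(x) nrow(x@markers))
#' @rdname accessors
setMethod("nMarkers", "PopulationFrequencies", function(x) nrow(x@markers))
#' @rdname accessors
setMethod("chromLengths", "HaplotypePanel", function(x) x@chromLengths)
#' @rdname accessors
setMethod("chromLengths", "PopulationFrequencies", function(x) x@chromLengths)
#' @rdname accessors
setMethod("popFreq", "PopulationFrequencies", function(x) x@freq)
#' @rdname accessors
setMethod("ancestralFreq", "PopulationFrequencies", function(x) x@ancestralFreq)
#' @rdname accessors
setMethod("dosageMatrix", "HaplotypePanel", function(x) x@hapA + x@hapB)
#' @rdname accessors
setMethod("haplotypeMatrix", "HaplotypePanel", function(x, hap) {
  stopifnot(hap %in% c(0L, 1L))
  if (hap == 0L) x@hapA else x@hapB
})
#' @rdname accessors
setMethod("tracts", "TractSet", function(x) x@tracts)
#' @rdname accessors
setMethod("ancestryCodes", "TractSet", function(x) x@codes)
#' @rdname accessors
setMethod("mapNodes", "GeneticMap", function(x) x@nodes)
#' @rdname accessors
setMethod("pedRecords", "Pedigree", function(x) x@records)

#' Subset a panel to a set of markers
#'
#' Returns a new panel restricted to `idx` (integer marker row indices into
#' `markerTable(panel)`, kept in genomic order).
#'
#' @param panel a [HaplotypePanel-class].
#' @param idx integer marker indices to retain.
#' @return A [HaplotypePanel-class].
#' @export
subsetMarkers <- function(panel, idx) {
  idx <- sort(unique(as.integer(idx)))
  HaplotypePanel(panel@markers[idx, , drop = FALSE], panel@samples,
                 panel@hapA[idx, , drop = FALSE],
                 panel@hapB[idx, , drop = FALSE],
                 phased = panel@phased, degraded = panel@degraded,
                 chromLengths = panel@chromLengths)
}

#' Subset a panel to a set of samples
#' @param panel a [HaplotypePanel-class].
#' @param samples sample ids to retain.
#' @return A [HaplotypePanel-class].
#' @export
subsetSamples <- function(panel, samples) {
  keep <- match(samples, panel@samples)
  if (anyNA(keep)) stop("unknown sample(s): ",
                        paste(samples[is.na(keep)], collapse = ", "))
  HaplotypePanel(panel@markers, panel@samples[keep],
                 panel@hapA[, keep, drop = FALSE],
                 panel@hapB[, keep, drop = FALSE],
                 phased = panel@phased, degraded = panel@degraded,
                 chromLengths = panel@chromLengths)
}

#' Subset a TractSet to marker indices of a panel
#'
#' Re-expresses truth tracts on a reduced marker grid (e.g. after marker
#' filtering) by expanding to per-marker ancestry and re-encoding runs.
#'
#' @param tractset a [TractSet-class] aligned to `panel`'s markers.
#' @param panel the original [HaplotypePanel-class].
#' @param idx marker indices retained (as for [subsetMarkers()]).
#' @return A [TractSet-class] on the reduced grid.
#' @export
subsetTracts <- function(tractset, panel, idx) {
  idx <- sort(unique(as.integer(idx)))
  anc <- .tractsToAncestry(tractset, panel@markers)
  anc <- lapply(anc, function(m) m[idx, , drop = FALSE])
  .ancestryToTracts(anc, panel@markers[idx, , drop = FALSE],
                    codes = tractset@codes)
}
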