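# File I/O: phased VCF, pedigree tables, BED-like tract files.
#
# Coordinate conventions are centralized here: VCF and map files are
# 1-based; the BED-like tract format is 0-based half-open. Internally all
# positions are 1-based marker coordinates with half-open marker indices.

#' Read phased genotypes from a VCF file
#'
#' Parses biallelic SNP records with a GT field into a
#' [HaplotypePanel-class]. Phased genotypes (`0|1`) populate the two
#' haplotypes; `./.` yields a missing genotype on both haplotypes. Unphased
#' separators (`/`) are an error unless `allowUnphased = TRUE`, in which
#' case the panel is marked unphased. Multiallelic and indel records are
#' skipped and counted. Chromosome lengths come from contig header lines
#' when present.
#'
#' @param path VCF file path.
#' @param allowUnphased accept `/`-separated genotypes (default FALSE).
#' @return A [HaplotypePanel-class] with attribute `skipped` (record count).
#' @export
readPhasedVcf <- function(path, allowUnphased = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (is.null(v@gt) || ncol(v@gt) < 2L)
    stop("VCF has no genotype (GT) section")
  keep <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  skipped <- sum(!keep)
  fix <- fix[keep, , drop = FALSE]
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  samples <- colnames(gt)
  if (any(grepl("/", gt, fixed = TRUE) & gt != "./.") && !allowUnphased)
    stop("unphased genotypes present; set allowUnphased = TRUE to accept")
  phased <- !any(grepl("/", gt, fixed = TRUE) & gt != "./.")
  a <- sub("[|/].*$", "", gt); b <- sub("^.*[|/]", "", gt)
  toInt <- function(x) { x[x == "."] <- NA; suppressWarnings(
    matrix(as.integer(x), nrow(gt), ncol(gt))) }
  hapA <- toInt(a); hapB <- toInt(b)
  bad <- !(hapA %in% c(0L, 1L, NA)) | !(hapB %in% c(0L, 1L, NA))
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, 1]
    stop("malformed GT at record ", i, " (", fix[i, "CHROM"], ":",
         fix[i, "POS"], ")")
  }
  markers <- data.frame(chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"],
                        stringsAsFactors = FALSE)
  # contig lengths from the header when declared
  meta <- v@meta
  contig <- grep("^##contig=", meta, value = TRUE)
  chromLengths <- NULL
  if (length(contig)) {
    ids <- sub('.*ID=([^,>]+).*', "\\1", contig)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1",
                                            contig)))
    if (!anyNA(lens)) chromLengths <- stats::setNames(lens, ids)
  }
  degraded <- anyNA(hapA) || anyNA(hapB)
  out <- HaplotypePanel(markers, samples, hapA, hapB, phased = phased,
                        degraded = degraded, chromLengths = chromLengths)
  attr(out, "skipped") <- skipped
  out
}

#' Write a HaplotypePanel as a phased VCF 4.2 file
#'
#' Emits contig header lines, phased `0|1`-style genotypes and `./.` for
#' missing genotypes. Byte output is deterministic for fixed input.
#'
#' @param panel a [HaplotypePanel-class] (markers must be sorted; they are
#'   by construction).
#' @param path output path.
#' @return The path, invisibly.
#' @export
writePhasedVcf <- function(panel, path) {
  mk <- panel@markers
  for (ch in unique(mk$chrom))
    if (any(diff(mk$pos[mk$chrom == ch]) <= 0)) stop("unsorted markers")
  sep <- if (panel@phased) "|" else "/"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=admixqc",
           sprintf("##contig=<ID=%s,length=%d>", names(panel@chromLengths),
                   as.integer(panel@chromLengths)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel@samples), collapse = "\t"))
  gtOf <- function(a, b) {
    out <- paste(a, b, sep = sep)
    out[is.na(a) | is.na(b)] <- "./."
    out
  }
  if (nrow(mk) > 0L && length(panel@samples) > 0L) {
    gt <- matrix("", nrow(mk), length(panel@samples))
    for (j in seq_along(panel@samples))
      gt[, j] <- gtOf(panel@hapA[, j], panel@hapB[, j])
    body <- paste(mk$chrom, mk$pos, .markerKey(mk), mk$ref, mk$alt,
                  ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write / read a pedigree table
#'
#' Tab-separated with header columns id, sire, dam, sex, taxon, generation;
#' unknown parents are written as `"0"`.
#'
#' @param pedigree a [Pedigree-class].
#' @param path file path.
#' @return `writePedigreeFile` the path invisibly; `readPedigreeFile` a
#'   [Pedigree-class].
#' @export
writePedigreeFile <- function(pedigree, path) {
  rec <- pedigree@records
  rec$sire[is.na(rec$sire)] <- "0"
  rec$dam[is.na(rec$dam)] <- "0"
  utils::write.table(rec, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePedigreeFile
#' @export
readPedigreeFile <- function(path) {
  rec <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = list(id = "character",
                                             sire = "character",
                                             dam = "character"))
  rec$sire[rec$sire == "0"] <- NA_character_
  rec$dam[rec$dam == "0"] <- NA_character_
  Pedigree(rec)
}

#' Write / read tracts in a BED-like format
#'
#' Tab-separated columns sample, hap, chrom, start, end, ancestry with
#' 0-based half-open physical coordinates (internal coordinates are 1-based;
#' the conversion happens here and only here). Marker indices are not part
#' of the format; tracts read back carry NA indices.
#'
#' @param tractset a [TractSet-class].
#' @param path file path.
#' @return `writeTractsBed` the path invisibly; `readTractsBed` a
#'   [TractSet-class].
#' @export
writeTractsBed <- function(tractset, path) {
  tr <- tractset@tracts
  out <- data.frame(sample = tr$sample, hap = tr$hap, chrom = tr$chrom,
                    start = format(tr$startBp - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(tr$endBp - 1, scientific = FALSE,
                                 trim = TRUE),
                    ancestry = tr$ancestry, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTractsBed
#' @export
readTractsBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = list(sample = "character",
                                            chrom = "character"))
  TractSet(data.frame(sample = df$sample, hap = df$hap, chrom = df$chrom,
                      startBp = df$start + 1, endBp = df$end + 1,
                      startIdx = NA_integer_, endIdx = NA_integer_,
                      ancestry = df$ancestry, stringsAsFactors = FALSE))
}
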