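# Internal helpers shared across modules.

#' Run code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded operations compose
#' without disturbing the global stream.
#' @noRd
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stage sub-seed from a master seed
#'
#' Stages of a pipeline each receive a distinct, reproducible seed derived
#' from a single user-supplied one. Kept within the 32-bit integer range.
#' @param seed master integer seed.
#' @param tag  character stage tag.
#' @return integer seed.
#' @export
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) %% 1000003L) * 2011L + (h %% 65521L) * 31L + 1L)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.markerKey <- function(markers) paste(markers$chrom, markers$pos, sep = ":")

# Validate and order a marker table: chrom (character), pos (integer),
# ref/alt single bases. Ordering follows `chromOrder` then position.
.checkMarkers <- function(markers, chromOrder = NULL) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(markers)))
    stop("marker table needs columns: ", paste(need, collapse = ", "))
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  if (is.null(chromOrder)) chromOrder <- unique(markers$chrom)
  o <- order(match(markers$chrom, chromOrder), markers$pos)
  markers <- markers[o, , drop = FALSE]
  rownames(markers) <- NULL
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  markers
}

# Per-chromosome 1-based marker index offsets for a marker table.
.chromIndex <- function(markers) {
  split(seq_len(nrow(markers)), markers$chrom)[unique(markers$chrom)]
}

# --- ancestry-matrix <-> tract conversions ---------------------------------
# The simulator and the unkinking code operate on dense per-marker ancestry
# matrices (nMarkers x 2, one column per haplotype); tracts are the
# run-length-encoded view. Both directions are exact.

# tracts (TractSet) -> named list of nMarkers x 2 integer matrices
.tractsToAncestry <- function(tracts, markers) {
  tr <- tracts@tracts
  chromIdx <- .chromIndex(markers)
  out <- list()
  for (s in unique(tr$sample)) {
    m <- matrix(NA_integer_, nrow(markers), 2L)
    rs <- tr[tr$sample == s, , drop = FALSE]
    for (i in seq_len(nrow(rs))) {
      gidx <- chromIdx[[rs$chrom[i]]]
      loc <- seq.int(rs$startIdx[i], rs$endIdx[i] - 1L)
      m[gidx[loc], rs$hap[i] + 1L] <- rs$ancestry[i]
    }
    out[[s]] <- m
  }
  out
}

# named list of ancestry matrices -> TractSet
.ancestryToTracts <- function(anc, markers, codes = c(olive = 0L, yellow = 1L)) {
  chromIdx <- .chromIndex(markers)
  rows <- vector("list", length(anc) * 2L * length(chromIdx))
  k <- 0L
  for (s in names(anc)) {
    for (hap in 0:1) {
      v <- anc[[s]][, hap + 1L]
      for (ch in names(chromIdx)) {
        gidx <- chromIdx[[ch]]
        vv <- v[gidx]
        r <- rle(vv)
        endIdx <- cumsum(r$lengths)            # inclusive local end
        startIdx <- c(1L, head(endIdx, -1L) + 1L)
        pos <- markers$pos[gidx]
        startBp <- pos[startIdx]
        endBp <- c(pos[startIdx[-1L]], pos[length(pos)] + 1L)
        k <- k + 1L
        rows[[k]] <- data.frame(
          sample = s, hap = hap, chrom = ch,
          startBp = startBp, endBp = endBp,
          startIdx = as.integer(startIdx), endIdx = as.integer(endIdx + 1L),
          ancestry = as.integer(r$values), stringsAsFactors = FALSE)
      }
    }
  }
  TractSet(do.call(rbind, rows[seq_len(k)]), codes = codes)
}
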