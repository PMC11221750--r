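# Two-state local-ancestry HMM (Viterbi decoding).
#
# This is a deliberately simple local-ancestry caller for phased haplotypes:
# emissions are the clamped reference allele frequencies, transitions follow
# an exponential switch model on genetic distance scaled by the number of
# generations since admixture. RFMix-style msp output from an external
# caller can be consumed instead via readMsp().

# Viterbi decoding for one chromosome of one haplotype.
# alleles: 0/1/NA; p0/p1: emission P(allele = 1 | state) already clamped;
# dM: genetic distance in Morgans between consecutive markers (length m-1).
.viterbiChrom <- function(alleles, p0, p1, dM, g, prior) {
  m <- length(alleles)
  # emission log-probs per state; missing alleles are uninformative
  le <- cbind(ifelse(is.na(alleles), 0,
                     ifelse(alleles == 1L, log(p0), log1p(-p0))),
              ifelse(is.na(alleles), 0,
                     ifelse(alleles == 1L, log(p1), log1p(-p1))))
  delta <- log(prior) + le[1, ]
  back <- matrix(1L, m, 2L)
  if (m > 1L) for (t in 2:m) {
    s <- 1 - exp(-g * dM[t - 1L])
    # P(i -> j) = s * prior[j] for j != i; P(i -> i) = 1 - s * prior[other]
    lt <- matrix(c(log1p(-s * prior[2]), log(s * prior[1]),
                   log(s * prior[2]), log1p(-s * prior[1])), 2L, 2L,
                 byrow = TRUE)   # rows: from-state, cols: to-state
    for (j in 1:2) {
      cand <- delta + lt[, j]
      back[t, j] <- which.max(cand)
      lt[1, j] <- max(cand)      # reuse as scratch
    }
    delta <- c(lt[1, 1], lt[1, 2]) + le[t, ]
  }
  path <- integer(m)
  path[m] <- which.max(delta)
  if (m > 1L) for (t in (m - 1L):1L) path[t] <- back[t + 1L, path[t + 1L]]
  path - 1L   # ancestry codes 0/1
}

#' Local ancestry by a two-state HMM
#'
#' Decodes each haplotype of the requested samples with a two-state Viterbi
#' HMM. Emission probability of the alternate allele under state k at marker
#' m is the reference frequency clamped to \[eps, 1 - eps\]. The transition
#' probability between consecutive markers at genetic distance d Morgans is
#' `switch = (1 - exp(-g * d)) * prior(other state)` and `stay = 1 - switch`.
#' Consecutive equal states merge into tracts with physical bounds
#' `[marker position, next tract start)`, the terminal tract extending to the
#' last marker position + 1. When the two populations' frequencies are
#' essentially identical the call is uninformative: the result (a single
#' tract of the prior-preferred state per chromosome) carries attribute
#' `uninformative = TRUE`.
#'
#' @param panel a phased [HaplotypePanel-class].
#' @param freqs a [PopulationFrequencies-class] aligned to the panel.
#' @param gmap a [GeneticMap-class] (off-map markers clamp to terminal cM).
#' @param cfg an [HmmConfig-class] (see [hmmConfig()]).
#' @param samples sample ids to decode (default all).
#' @return A [TractSet-class] with attribute `uninformative`.
#' @export
hmmLocalAncestry <- function(panel, freqs, gmap, cfg = hmmConfig(),
                             samples = NULL) {
  if (nrow(freqs@markers) != nrow(panel@markers))
    stop("frequency table must align with the panel")
  if (is.null(samples)) samples <- panel@samples
  chromIdx <- .chromIndex(panel@markers)
  if (length(chromIdx) == 0L) stop("panel has no markers")
  p0 <- .clamp(freqs@freq[, 1], cfg@eps, 1 - cfg@eps)
  p1 <- .clamp(freqs@freq[, 2], cfg@eps, 1 - cfg@eps)
  uninformative <- mean(abs(freqs@freq[, 1] - freqs@freq[, 2])) < 2 * cfg@eps
  cm <- unlist(lapply(names(chromIdx), function(ch)
    interpolateCm(gmap, ch, panel@markers$pos[chromIdx[[ch]]])),
    use.names = FALSE)
  anc <- list()
  for (s in samples) {
    j <- match(s, panel@samples)
    if (is.na(j)) stop("unknown sample: ", s)
    m <- matrix(NA_integer_, nrow(panel@markers), 2L)
    for (ch in names(chromIdx)) {
      gidx <- chromIdx[[ch]]
      dM <- diff(cm[gidx]) / 100
      m[gidx, 1] <- .viterbiChrom(panel@hapA[gidx, j], p0[gidx], p1[gidx],
                                  dM, cfg@g, cfg@prior)
      m[gidx, 2] <- .viterbiChrom(panel@hapB[gidx, j], p0[gidx], p1[gidx],
                                  dM, cfg@g, cfg@prior)
    }
    anc[[s]] <- m
  }
  out <- .ancestryToTracts(anc, panel@markers)
  attr(out, "uninformative") <- uninformative
  out
}
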