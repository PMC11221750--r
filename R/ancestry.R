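# Two-way global ancestry estimation by maximum likelihood.
#
# The supervised model treats the two alleles of a genotype as independent
# draws from the mixed allele frequency q*p0 + (1-q)*p1 (the standard
# supervised ADMIXTURE likelihood); phase is not used, so degraded or
# unphased dosage data still works.

# Maximize the binomial admixture log-likelihood over q in [0, 1] for one
# sample. g = dosage (0/1/2, NA skipped), p0/p1 = clamped reference
# frequencies. Bracketed scalar optimization to 1e-6, with the boundary
# values checked explicitly so boundary optima are exact.
.fitQ <- function(g, p0, p1) {
  ok <- !is.na(g)
  if (!any(ok)) stop("sample has zero usable markers")
  g <- g[ok]; p0 <- p0[ok]; p1 <- p1[ok]
  ll <- function(q) {
    pm <- q * p0 + (1 - q) * p1
    sum(g * log(pm) + (2 - g) * log1p(-pm))
  }
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(opt$maximum, 0, 1)
  vals <- c(opt$objective, ll(0), ll(1))
  list(q = cand[which.max(vals)], logLik = max(vals), n = length(g))
}

#' Supervised two-way global ancestry estimation
#'
#' For each sample, finds the mixing proportion q (ancestry 0, "olive") that
#' maximizes the binomial likelihood of its diploid dosages given the two
#' reference populations' allele frequencies. Reference frequencies are
#' clamped to \[1e-4, 1 - 1e-4\]; missing genotypes are skipped per sample;
#' boundary optima (q = 0 or 1) are allowed.
#'
#' @param x a [HaplotypePanel-class] or a dosage matrix (markers x samples,
#'   values 0/1/2/NA) aligned to `freqs`' markers.
#' @param freqs a [PopulationFrequencies-class].
#' @param eps frequency clamp (default 1e-4).
#' @return data.frame with columns sample, qOlive, qYellow, method
#'   (`"likelihood"`), nMarkers.
#' @export
estimateAdmixtureSupervised <- function(x, freqs, eps = 1e-4) {
  dose <- if (methods::is(x, "HaplotypePanel")) dosageMatrix(x) else x
  if (nrow(dose) != nrow(freqs@markers))
    stop("dosage rows must align with the frequency table")
  p0 <- .clamp(freqs@freq[, 1], eps, 1 - eps)
  p1 <- .clamp(freqs@freq[, 2], eps, 1 - eps)
  ids <- colnames(dose)
  if (is.null(ids)) ids <- paste0("S", seq_len(ncol(dose)))
  fits <- lapply(seq_len(ncol(dose)), function(j) .fitQ(dose[, j], p0, p1))
  data.frame(sample = ids,
             qOlive = vapply(fits, `[[`, numeric(1), "q"),
             qYellow = 1 - vapply(fits, `[[`, numeric(1), "q"),
             method = "likelihood",
             nMarkers = vapply(fits, `[[`, numeric(1), "n"),
             stringsAsFactors = FALSE)
}

#' Unsupervised K = 2 admixture estimation
#'
#' Block-coordinate ascent on the same binomial likelihood: alternate
#' (i) per-sample q updates by the supervised maximizer given the current
#' cluster frequencies and (ii) per-marker frequency updates by expected
#' weighted allele counts given the current q. Stops when the log-likelihood
#' gain drops below `tol` or after `maxIter` iterations (non-convergence is
#' flagged, not an error). Label switching is resolved by fixing population 0
#' as the cluster with the higher mean q among samples labelled `"olive"`
#' when labels are supplied, else by the first sample's majority ancestry.
#' A fit where the two clusters' frequencies are nearly identical is flagged
#' degenerate.
#'
#' @param panel a [HaplotypePanel-class] (LD-pruned input recommended).
#' @param seed integer seed for initialisation.
#' @param maxIter maximum iterations (default 200).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param labels optional named taxon labels (sample -> "olive"/"yellow"/...)
#'   used only to orient the two clusters.
#' @return list with `global` (as [estimateAdmixtureSupervised()], method
#'   `"likelihood"`), `freqs` (fitted [PopulationFrequencies-class]),
#'   `logLik`, `converged`, `degenerate`.
#' @export
estimateAdmixtureUnsupervisedK2 <- function(panel, seed = 1L, maxIter = 200L,
                                            tol = 1e-6, labels = NULL) {
  if (length(panel@samples) < 2L) stop("need at least two samples")
  dose <- dosageMatrix(panel)
  n <- nrow(dose); S <- ncol(dose)
  eps <- 1e-4
  obsP <- rowSums(dose, na.rm = TRUE) / (2 * pmax(rowSums(!is.na(dose)), 1L))
  init <- withSeed(seed, {
    jit <- stats::runif(n, 0.05, 0.3)
    list(p0 = .clamp(obsP + jit, eps, 1 - eps),
         p1 = .clamp(obsP - jit, eps, 1 - eps),
         q = stats::runif(S))
  })
  p0 <- init$p0; p1 <- init$p1; q <- init$q
  llTotal <- function(p0, p1, q) {
    pm <- outer(p0, q) + outer(p1, 1 - q)
    sum(dose * log(pm) + (2 - dose) * log1p(-pm), na.rm = TRUE)
  }
  prev <- -Inf; converged <- FALSE
  for (it in seq_len(maxIter)) {
    # (i) q update via the supervised maximizer
    q <- vapply(seq_len(S), function(j) .fitQ(dose[, j], p0, p1)$q,
                numeric(1))
    # (ii) frequency update from expected allele-origin counts (EM step)
    Q <- matrix(q, n, S, byrow = TRUE)
    r0 <- Q * p0 / (Q * p0 + (1 - Q) * p1)            # alt allele from pop0
    s0 <- Q * (1 - p0) / (Q * (1 - p0) + (1 - Q) * (1 - p1))  # ref from pop0
    alt0 <- rowSums(dose * r0, na.rm = TRUE)
    ref0 <- rowSums((2 - dose) * s0, na.rm = TRUE)
    alt1 <- rowSums(dose * (1 - r0), na.rm = TRUE)
    ref1 <- rowSums((2 - dose) * (1 - s0), na.rm = TRUE)
    p0 <- .clamp(alt0 / pmax(alt0 + ref0, 1e-12), eps, 1 - eps)
    p1 <- .clamp(alt1 / pmax(alt1 + ref1, 1e-12), eps, 1 - eps)
    cur <- llTotal(p0, p1, q)
    if (is.finite(prev) && cur - prev < tol) { converged <- TRUE; break }
    prev <- cur
  }
  # orient clusters
  flip <- FALSE
  if (!is.null(labels)) {
    ol <- names(labels)[labels == "olive"]
    ol <- intersect(ol, panel@samples)
    if (length(ol) > 0L) flip <- mean(q[match(ol, panel@samples)]) < 0.5
  } else flip <- q[1] < 0.5
  if (flip) { q <- 1 - q; tmp <- p0; p0 <- p1; p1 <- tmp }
  # degeneracy: on a homogeneous cohort the two clusters differ only by
  # binomial sampling noise, so compare the mean frequency separation with
  # its expected value under no structure (half-normal mean of the
  # two-cluster frequency difference at the fitted effective sample sizes)
  nEff0 <- max(2 * sum(q), 1); nEff1 <- max(2 * sum(1 - q), 1)
  pb <- (p0 * nEff0 + p1 * nEff1) / (nEff0 + nEff1)
  noiseFloor <- sqrt(2 / pi) *
    mean(sqrt(pmax(pb * (1 - pb), 0) * (1 / nEff0 + 1 / nEff1)))
  degenerate <- mean(abs(p0 - p1)) < 2 * noiseFloor
  global <- data.frame(sample = panel@samples, qOlive = q, qYellow = 1 - q,
                       method = "likelihood",
                       nMarkers = colSums(!is.na(dose)),
                       stringsAsFactors = FALSE)
  fitted <- PopulationFrequencies(panel@markers, cbind(p0, p1),
                                  chromLengths = panel@chromLengths)
  list(global = global, freqs = fitted, logLik = prev,
       converged = converged, degenerate = degenerate)
}

#' Discover purebred reference individuals
#'
#' Applies the threshold rule used to build reference panels: individuals
#' whose estimated ancestry for either population is strictly greater than
#' `threshold` (default 0.99) are reported as purebred for that population.
#'
#' @param global a GlobalAncestry data.frame (columns sample, qOlive).
#' @param threshold purity threshold (default 0.99).
#' @return data.frame with columns sample, population (`"olive"`/`"yellow"`).
#' @export
discoverPurebred <- function(global, threshold = 0.99) {
  pop <- ifelse(global$qOlive > threshold, "olive",
                ifelse(global$qOlive < 1 - threshold, "yellow", NA))
  data.frame(sample = global$sample[!is.na(pop)],
             population = pop[!is.na(pop)], stringsAsFactors = FALSE)
}

#' Global ancestry from local-ancestry tracts
#'
#' The proportion of ancestry 0 is the summed physical length (bp) of
#' ancestry-0 tracts over both haplotypes divided by twice the total genome
#' length covered by tracts.
#'
#' @param tractset a [TractSet-class] tiling the genome.
#' @return data.frame with columns sample, qOlive, qYellow, method
#'   (`"tracts"`), bpCovered.
#' @export
globalFromTracts <- function(tractset) {
  tr <- tractset@tracts
  if (nrow(tr) == 0L) stop("empty tract set")
  len <- tr$endBp - tr$startBp
  out <- do.call(rbind, lapply(split(seq_len(nrow(tr)), tr$sample),
    function(ii) {
      tot <- sum(len[ii])
      q0 <- sum(len[ii][tr$ancestry[ii] == 0L]) / tot
      data.frame(qOlive = q0, bpCovered = tot / 2)
    }))
  data.frame(sample = rownames(out), qOlive = out$qOlive,
             qYellow = 1 - out$qOlive, method = "tracts",
             bpCovered = out$bpCovered, stringsAsFactors = FALSE,
             row.names = NULL)
}
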