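# End-to-end pipeline: simulate -> filter -> fst/aims -> global -> local ->
# phase QC -> pedigree audit. Every stage receives a derived sub-seed so
# stages are individually reproducible; outputs are byte-identical on re-run
# with the same configuration.

#' Default run configuration
#'
#' All tunables of [runPipeline()] with their defaults: a 4 x 50 Mb genome,
#' 20,000 markers, founder divergence 0.4 with 0.5% fixed differences, 9 + 9
#' founders, 10 F1s and two generations of random crossing, 2% genotype
#' missingness, phase switches injected at 0.5 per Morgan, marker filters
#' (5% missingness, 5% MAF), AIM selection (F_ST > 0.8, 100-kb windows,
#' strict 2/1/0.05 pruning) and an HMM with g = 2.
#'
#' @return named list of parameters.
#' @export
defaultRunConfig <- function() {
  list(
    nMarkers = 20000L, fstTarget = 0.4, fixedFraction = 0.005,
    chromLengthBp = 5e7, nChrom = 4L, recombRate = 1e-8,
    nOlive = 9L, nYellow = 9L, nF1 = 10L, nGen = 2L, nPerGen = 30L,
    missingRate = 0.02, switchRate = 0.5,
    maxMissing = 0.05, minMaf = 0.05,
    aimsFstMin = 0.8, aimsWindowBp = 1e5, aimsPrune = c(2, 1, 0.05),
    hmmG = 2, hmmEps = 0.005,
    auditMajor = 0.90, auditPure = 0.99)
}

#' Read a run configuration file
#'
#' YAML key/value file overriding [defaultRunConfig()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path (NULL for pure defaults).
#' @return named list of parameters.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg
}

#' Run the full synthetic-data pipeline
#'
#' Simulates a two-population pedigree, degrades and phase-corrupts it,
#' filters markers, computes per-marker and weighted F_ST, selects an AIMs
#' panel, estimates global ancestry (supervised, against founder-estimated
#' frequencies), decodes local ancestry with the HMM, detects and unkinks
#' phase switches in the F1s, audits trio consistency and pedigree labels,
#' and writes all artifacts plus a run log to `outDir`.
#'
#' @param config list from [defaultRunConfig()] / [readRunConfig()].
#' @param outDir output directory (created if needed).
#' @param seed master integer seed; all stage seeds derive from it.
#' @return invisible list of in-memory artifacts.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir, seed = 1L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logLines <- c(sprintf("admixqc %s", as.character(utils::packageVersion("admixqc"))),
                sprintf("seed %d", as.integer(seed)),
                vapply(names(config), function(k)
                  paste(k, paste(format(config[[k]]), collapse = ","),
                        sep = "="), character(1)))
  chromLengths <- stats::setNames(rep(config$chromLengthBp, config$nChrom),
                                  as.character(seq_len(config$nChrom)))
  gmap <- uniformRateMap(chromLengths, config$recombRate)

  # --- simulate ------------------------------------------------------------
  freqs <- simulateFounderFrequencies(config$nMarkers, config$fstTarget,
                                      config$fixedFraction, chromLengths,
                                      seed = deriveSeed(seed, "freqs"))
  plan <- makeColonyPlan(config$nOlive, config$nYellow, config$nF1,
                         config$nGen, config$nPerGen,
                         seed = deriveSeed(seed, "plan"))
  sim <- simulatePedigree(plan, freqs, gmap, seed = deriveSeed(seed, "sim"))
  inj <- injectPhaseSwitches(sim$panel, sim$tracts, rate = config$switchRate,
                             gmap = gmap, seed = deriveSeed(seed, "switch"))
  panel <- degradeGenotypes(inj$panel, config$missingRate,
                            seed = deriveSeed(seed, "degrade"))
  writePhasedVcf(panel, file.path(outDir, "panel.vcf"))
  writePedigreeFile(sim$pedigree, file.path(outDir, "pedigree.tsv"))
  writeTractsBed(sim$tracts, file.path(outDir, "truth_tracts.bed"))
  writeGeneticMap(gmap, markerTable(panel), "plink",
                  file.path(outDir, "markers.plink.map"))
  writeGeneticMap(gmap, markerTable(panel), "shapeit",
                  file.path(outDir, "markers.shapeit.map"))
  logLines <- c(logLines, sprintf("markers simulated %d", nMarkers(panel)),
                sprintf("samples %d", length(sampleIds(panel))),
                sprintf("switches injected %d", nrow(inj$switches)))

  # --- filter --------------------------------------------------------------
  keep <- filterMarkers(panel, config$maxMissing, config$minMaf)
  fpanel <- subsetMarkers(panel, keep)
  ffreqs <- PopulationFrequencies(markerTable(fpanel),
                                  popFreq(freqs)[keep, , drop = FALSE],
                                  ancestralFreq(freqs)[keep],
                                  chromLengths)
  ftruth <- subsetTracts(inj$tracts, panel, keep)
  logLines <- c(logLines, sprintf("markers after filter %d", length(keep)))

  # --- fst / aims ----------------------------------------------------------
  ped <- pedRecords(sim$pedigree)
  founders <- ped$id[ped$generation == 0L]
  popAssign <- stats::setNames(ifelse(startsWith(founders, "O"), 0L, 1L),
                               founders)
  fst <- wcFstPerMarker(fpanel, popAssign)
  wFst <- weightedFst(fst)
  fixed <- countFixedMarkers(fst)
  utils::write.table(fst, file.path(outDir, "fst.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  refs <- list(olive = founders[popAssign == 0L],
               yellow = founders[popAssign == 1L])
  aims <- selectAims(fst, fpanel, config$aimsFstMin, config$aimsWindowBp,
                     config$aimsPrune, refs)
  utils::write.table(aims, file.path(outDir, "aims.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  logLines <- c(logLines, sprintf("weighted fst %.6f", wFst),
                sprintf("fixed markers %d", fixed$count),
                sprintf("aims selected %d", nrow(aims)))

  # --- global ancestry -----------------------------------------------------
  refFreq <- referenceFrequencies(fpanel, refs)
  global <- estimateAdmixtureSupervised(fpanel, refFreq)
  utils::write.table(global, file.path(outDir, "global_ancestry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- local ancestry ------------------------------------------------------
  cfg <- hmmConfig(g = config$hmmG, eps = config$hmmEps)
  local <- hmmLocalAncestry(fpanel, refFreq, gmap, cfg)
  writeMsp(local, gmap, file.path(outDir, "local_ancestry.msp.tsv"))
  tractGlobal <- globalFromTracts(local)
  utils::write.table(tractGlobal, file.path(outDir, "global_from_tracts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- phase QC on F1s -----------------------------------------------------
  f1 <- ped$id[!is.na(ped$sire) &
                 ped$sire %in% refs$olive & ped$dam %in% refs$yellow]
  before <- tractStatistics(local)
  cur <- list(panel = fpanel, tracts = local)
  nCorr <- 0L
  for (s in f1) {
    u <- unkink(cur$panel, cur$tracts, s)
    cur <- list(panel = u$panel, tracts = u$tracts)
    nCorr <- nCorr + u$nCorrections
  }
  after <- tractStatistics(cur$tracts)
  rep <- f1SwitchReport(before$perSample[before$perSample$sample %in% f1, ],
                        after$perSample[after$perSample$sample %in% f1, ])
  utils::write.table(rep$perSample, file.path(outDir, "switch_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logLines <- c(logLines, sprintf("f1 corrections %d", nCorr),
                sprintf("f1 switch reduction %.2f%%",
                        rep$aggregate$reductionPct))

  # --- trio audit (first F1 with both parents present) ---------------------
  if (length(f1) > 0L) {
    o <- f1[1]
    trio <- trioConsistency(cur$tracts, markerTable(fpanel), o,
                            ped$sire[ped$id == o], ped$dam[ped$id == o])
    logLines <- c(logLines, sprintf("trio inconsistency %.4f%%",
                                    100 * trio$fraction))
  }

  # --- pedigree-label audit ------------------------------------------------
  audit <- auditPedigreeLabels(global, sim$pedigree, config$auditMajor,
                               config$auditPure)
  utils::write.table(audit, file.path(outDir, "pedigree_audit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logLines <- c(logLines, sprintf("pedigree flags %d",
                                  sum(!audit$flag %in% c("none", "missing"))))
  writeLines(logLines, file.path(outDir, "run_log.txt"))
  invisible(list(panel = panel, filtered = fpanel, freqs = freqs,
                 truth = ftruth, pedigree = sim$pedigree, fst = fst,
                 weightedFst = wFst, fixed = fixed, aims = aims,
                 global = global, local = local, corrected = cur,
                 switchReport = rep, audit = audit))
}

#' Allele frequencies estimated from reference samples
#'
#' Builds a [PopulationFrequencies-class] from the observed alternate-allele
#' frequencies of two reference sample sets (complete cases per marker), the
#' way a supervised analysis derives its reference panel frequencies.
#'
#' @param panel a [HaplotypePanel-class].
#' @param refs list of two character vectors of sample ids (population 0
#'   first).
#' @return A [PopulationFrequencies-class].
#' @export
referenceFrequencies <- function(panel, refs) {
  dose <- dosageMatrix(panel)
  pOf <- function(ids) {
    d <- dose[, match(ids, panel@samples), drop = FALSE]
    rowSums(d, na.rm = TRUE) / (2 * pmax(rowSums(!is.na(d)), 1L))
  }
  PopulationFrequencies(panel@markers,
                        cbind(pOf(refs[[1]]), pOf(refs[[2]])),
                        chromLengths = panel@chromLengths)
}
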