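## Config-driven pipeline runners: the neutral-null simulation study
## (simulate -> ascertain -> genotypes -> panel frequencies -> HMM dosage ->
## mean track -> outlier summary -> region-length null) and the admixture
## characterisation report (f3 + F4 ratio + weighted-LD dating).

#' Named pipeline presets
#'
#' `"solomon"` is the standard neutral null (recombination 1.3e-8);
#' `"solomon-hla"` is the low-recombination variant (8.5e-9) matching the
#' HLA region's HapMap rate.  Both carry the default demography of
#' [demographyConfig()].
#'
#' @param name preset name
#' @return a [demographyConfig()]
#' @export
pipelinePreset <- function(name = c("solomon", "solomon-hla")) {
  name <- match.arg(name)
  switch(name,
         "solomon" = demographyConfig(),
         "solomon-hla" = demographyConfig(rec = 8.5e-9))
}

.stageSeed <- function(seed, k) (as.integer(seed) %% 100000L) * 13L + k

#' Run the neutral-null local-ancestry simulation study
#'
#' Chains the full pipeline under a preset demography: coalescent windows,
#' MAF-matched ascertainment to the genome-wide SNP density, diploid
#' genotypes, source-panel frequencies, HMM ancestry dosages for the admixed
#' individuals, the population mean track, its outlier summary, and the
#' contiguous excess-region length statistics of the null.  Fully
#' deterministic given `seed` (stage seeds derive from it by a fixed
#' counter scheme).
#'
#' @param preset preset name or a [demographyConfig()]
#' @param nWindows number of 2 Mb windows to simulate; the SNP target scales
#'   as `n_snps_target * nWindows / n_windows`
#' @param seed master seed
#' @param generations admixture generations for the HMM (default 77)
#' @param emSteps EM passes (default 20)
#' @param sdMultiplier region-calling threshold (default 3)
#' @param outDir optional directory for TSV track / JSON summary artifacts
#' @param verbose log stage timings to stderr
#' @return list: cfg, trackSummary ([summarizeTrack()]), nullSummary
#'   ([regionLengthNull()]), meanTrack, fittedM, nSites
#' @export
runNeutralNullStudy <- function(preset = "solomon", nWindows = 300,
                                seed = 1, generations = 77, emSteps = 20,
                                sdMultiplier = 3, outDir = NULL,
                                verbose = FALSE) {
  cfg <- if (is.character(preset)) pipelinePreset(preset) else preset
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  set.seed(.stageSeed(seed, 1L))
  wins <- simulateWindows(cfg, nWindows)
  say("simulated %d windows [%.1fs]", nWindows,
      as.numeric(Sys.time() - t0, units = "secs"))

  nTarget <- round(cfg$n_snps_target * nWindows / cfg$n_windows)
  set.seed(.stageSeed(seed, 2L))
  wins <- ascertainVariants(wins, defaultMAFTargetHist(), nTarget)
  G <- haplotypesToGenotypes(wins)
  say("ascertained %d sites [%.1fs]", nVariants(G),
      as.numeric(Sys.time() - t0, units = "secs"))

  pops <- names(cfg$chroms)
  panelP <- panelFrequencies(G, pops[1])
  panelA <- panelFrequencies(G, pops[3])
  Gadm <- subsetSamples(G, population = pops[2])
  model <- laiModel(panelP, panelA, generations = generations,
                    emSteps = emSteps)
  track <- fitDosage(Gadm, model)
  say("HMM dosages fitted, m = %.4f [%.1fs]", track@m,
      as.numeric(Sys.time() - t0, units = "secs"))

  mt <- populationMeanTrack(track)
  summ <- summarizeTrack(mt)
  nullSumm <- regionLengthNull(mt, sdMultiplier = sdMultiplier)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.table(mt, file.path(outDir, "mean_track.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    regions <- rbind(callRegions(mt, summ, "high", sdMultiplier),
                     callRegions(mt, summ, "low", sdMultiplier))
    # BED is 0-based half-open; internal coordinates are 1-based inclusive
    if (nrow(regions))
      write.table(data.frame(regions$chrom, regions$start - 1L,
                             regions$end, regions$side),
                  file.path(outDir, "regions.bed"), sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(
      list(preset = if (is.character(preset)) preset else "custom",
           seed = seed, nWindows = nWindows, nSites = nVariants(G),
           mean = summ$mean, sd = summ$sd, fittedM = track@m,
           highMeanLength = nullSumm$high$meanLength,
           highMaxLength = nullSumm$high$maxLength),
      file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  list(cfg = cfg, trackSummary = summ, nullSummary = nullSumm,
       meanTrack = mt, fittedM = track@m, nSites = nVariants(G))
}

#' Admixture characterisation report: f3, F4 ratio, weighted-LD dating
#'
#' Computes the three-population test for the target against each pair of
#' source proxies, the F4-ratio ancestry proportion when an outgroup and an
#' Asian-source proxy are available (skipped with a warning otherwise), and
#' the weighted-LD admixture date.  The f3 table mirrors the standard
#' report columns (f3, std.err, Z, SNPs).
#'
#' @param G a [GenotypeMatrix-class] with all populations
#' @param target admixed population label
#' @param sourcePairs list of c(asianProxy, papuanProxy) label pairs
#' @param outgroup optional outgroup label for the F4 ratio
#' @param asianSourceProxy optional true-source proxy for the F4 ratio
#' @param blockBp jackknife block size (default 5 Mb)
#' @param dating compute the weighted-LD date (default TRUE)
#' @param gposCm optional genetic positions for the dating curve
#' @return list: f3Table (data.frame), ratio (or NULL), dating (or NULL)
#' @export
runAdmixtureCharacterization <- function(G, target, sourcePairs,
                                         outgroup = NULL,
                                         asianSourceProxy = NULL,
                                         blockBp = 5e6, dating = TRUE,
                                         gposCm = NULL) {
  if (!is.list(sourcePairs)) sourcePairs <- list(sourcePairs)
  f3Table <- do.call(rbind, lapply(sourcePairs, function(sp) {
    r <- f3Test(G, target, sp[1], sp[2], blockBp)
    data.frame(target = target, sourceA = sp[1], sourceB = sp[2],
               f3 = r$estimate, std.err = r$stdErr, Z = r$z,
               SNPs = r$nSnps, significant = r$significant,
               stringsAsFactors = FALSE)
  }))
  ratio <- NULL
  if (!is.null(outgroup) && !is.null(asianSourceProxy)) {
    ratio <- f4Ratio(G, outgroup, sourcePairs[[1]][1], sourcePairs[[1]][2],
                     target, asianSourceProxy, blockBp)
  } else if (!is.null(outgroup) || !is.null(asianSourceProxy)) {
    warning("F4 ratio skipped: both an outgroup and an Asian-source proxy ",
            "are required")
  }
  dres <- NULL
  if (dating) {
    sp <- sourcePairs[[1]]
    Gadm <- subsetSamples(G, population = target)
    panelA <- panelFrequencies(G, sp[1])
    panelB <- panelFrequencies(G, sp[2])
    dres <- tryCatch(
      fitDecay(weightedLDCurve(Gadm, panelA, panelB, gposCm = gposCm)),
      error = function(e) {
        warning("admixture dating failed: ", conditionMessage(e))
        NULL
      })
  }
  list(f3Table = f3Table, ratio = ratio, dating = dres)
}
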