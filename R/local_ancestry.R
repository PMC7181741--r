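## Two-way local-ancestry inference on unphased genotypes of admixed
## individuals: a 3-state (unordered diploid ancestry pair) forward-backward
## HMM with EM refinement of the mixture proportion.  The observation unit
## is the unphased genotype dosage, matching array-data reality; emissions
## come from pseudocount-smoothed source-panel frequencies.

#' Local-ancestry HMM model settings
#'
#' @param panelP Papuan-side [AlleleFrequencyPanel-class]
#' @param panelA Asian-side [AlleleFrequencyPanel-class] (same variants)
#' @param generations generations since admixture `T` (a user setting, not
#'   EM-updated; runs at 50/77/100/150 probe sensitivity)
#' @param m initial Papuan mixture proportion (EM-updated)
#' @param emSteps number of EM passes updating `m` (default 20)
#' @param pseudocount emission smoothing per allele (default 0.5)
#' @param cmPerMb constant-rate genetic map (default 1 cM = 1 Mb)
#' @return an `LAIModel` list
#' @export
laiModel <- function(panelP, panelA, generations = 77, m = 0.5,
                     emSteps = 20, pseudocount = 0.5, cmPerMb = 1) {
  stopifnot(generations > 0, m > 0, m < 1, emSteps >= 1, pseudocount > 0)
  vP <- variants(panelP)
  stopifnot(identical(vP$chrom, variants(panelA)$chrom),
            identical(vP$pos, variants(panelA)$pos))
  structure(list(panelP = panelP, panelA = panelA,
                 generations = generations, m = m, emSteps = emSteps,
                 pseudocount = pseudocount, cmPerMb = cmPerMb),
            class = "LAIModel")
}

#' Fit posterior Papuan-ancestry dosages with the diploid HMM
#'
#' Hidden state per site is the unordered ancestry pair \{PP, PA, AA\} with
#' initial distribution (m^2, 2m(1-m), (1-m)^2).  Each chromosome of an
#' individual switches ancestry between consecutive sites at genetic
#' distance d Morgans with probability `1 - exp(-T d)` into the stationary
#' draw (m, 1-m); the diploid transition is the product over the two
#' independent chromosomes.  The emission of genotype g given a state is the
#' convolution of two Bernoulli draws from the smoothed panel frequency of
#' each chromosome's ancestry; missing genotypes emit likelihood 1.
#' Posteriors come from scaled forward-backward, run per chromosome
#' independently; after each full pass `m` is re-estimated as the mean
#' posterior dosage / 2 over all sites and individuals, `emSteps` times.
#'
#' @param G a [GenotypeMatrix-class] of the admixed individuals, aligned to
#'   the model's panels (same chrom/pos)
#' @param model an [laiModel()]
#' @return an [AncestryDosageTrack-class]
#' @export
fitDosage <- function(G, model) {
  v <- variants(G)
  vP <- variants(model$panelP)
  if (!identical(v$chrom, vP$chrom) || !identical(v$pos, vP$pos))
    stop("panels are not aligned to the genotype variants")
  fP <- smoothedFreq(model$panelP, model$pseudocount)
  fA <- smoothedFreq(model$panelA, model$pseudocount)
  cc <- calls(G)
  chroms <- unique(v$chrom)
  idx <- lapply(chroms, function(ci) which(v$chrom == ci))
  dM <- lapply(idx, function(j)
    c(0, diff(v$pos[j])) * model$cmPerMb / 1e8)

  m <- model$m
  T <- model$generations
  dos <- matrix(NA_real_, nrow(cc), ncol(cc))
  ll <- NA_real_
  for (step in seq_len(model$emSteps)) {
    ll <- 0
    for (k in seq_along(idx)) {
      j <- idx[[k]]
      r <- .hmm_dosage_cpp(cc[, j, drop = FALSE], fP[j], fA[j], dM[[k]],
                           T, m)
      dos[, j] <- r$dosage
      ll <- ll + r$loglik
    }
    m <- min(max(mean(dos) / 2, 1e-6), 1 - 1e-6)
  }
  new("AncestryDosageTrack", dosage = dos, variants = v,
      samples = sampleInfo(G), m = m, generations = T, loglik = ll)
}

#' Population mean ancestry track
#'
#' Per-variant mean of dosage/2 across individuals: the average Papuan
#' fraction at each genomic position.
#'
#' @param track an [AncestryDosageTrack-class]
#' @return a `MeanAncestryTrack` data.frame (chrom, pos, ancestry)
#' @export
populationMeanTrack <- function(track) {
  if (nrow(dosage(track)) < 1) stop("track has no individuals")
  out <- data.frame(variants(track)[, c("chrom", "pos")],
                    ancestry = colMeans(dosage(track)) / 2)
  class(out) <- c("MeanAncestryTrack", "data.frame")
  out
}
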