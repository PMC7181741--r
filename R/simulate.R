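## Synthetic data: coalescent windows under a three-population
## pulse-admixture history, SNP-array-like ascertainment, and a fast
## tract-copying admixture generator with known ancestry truth.

#' Demographic configuration for the neutral coalescent null
#'
#' Defaults describe the study conditions the null model assumes: two source
#' populations (a Papuan-side and an Asian-side panel) split `t_div = 1667`
#' generations ago (50,000 years at 30 years/generation) from one ancestral
#' population, and an admixed deme formed by a single pulse `t_adm = 77`
#' generations ago with Papuan fraction `m_papuan = 0.5137`.  All demes have
#' diploid size `Ne = 1000`.  Windows of `window_bp = 2` Mb are simulated
#' independently (`n_windows = 1500` corresponds to a 3 Gb genome), with
#' mutation rate 1.2e-8 and recombination rate 1.3e-8 per base per
#' generation (8.5e-9 for the low-recombination HLA-region variant).
#' Sampled chromosome counts default to 48 (Papuan panel), 40 (admixed) and
#' 90 (Asian panel); `n_snps_target = 146090` is the array-like SNP count
#' ascertainment aims at over the full 1500 windows.
#'
#' @param Ne diploid population size of every deme
#' @param t_div split time of the two source populations, generations
#' @param t_adm admixture pulse time, generations (`t_adm < t_div`)
#' @param m_papuan Papuan-side fraction of the admixed deme at the pulse
#' @param mu mutation rate per base per generation
#' @param rec recombination rate per base per generation
#' @param window_bp window length in bp
#' @param n_windows number of independent windows
#' @param chroms named haploid sample sizes, in the order Papuan-side panel,
#'   admixed population, Asian-side panel
#' @param n_snps_target total SNP count ascertainment aims at over
#'   `n_windows` windows
#' @param outgroup_chroms haploid sample size of an optional outgroup deme
#' @param t_outgroup split time of the outgroup (default `4 * t_div`)
#' @param asian_proxy_chroms haploid sample size of an optional sister deme
#'   splitting from the Asian side at `t_asian_proxy` -- the source-proxy
#'   phylogeny an F4-ratio assumes (labelled "AsianProxy")
#' @param t_asian_proxy split time of the source-proxy deme (default
#'   `t_adm`, i.e. a sister of the admixture pulse's Asian source)
#' @param seed optional seed applied by [simulateWindows()]
#' @return a `DemographyConfig` list
#' @export
demographyConfig <- function(Ne = 1000, t_div = 1667, t_adm = 77,
                             m_papuan = 0.5137, mu = 1.2e-8, rec = 1.3e-8,
                             window_bp = 2e6, n_windows = 1500,
                             chroms = c(Gidra = 48, Munda = 40, CHB = 90),
                             n_snps_target = 146090,
                             outgroup_chroms = 0, t_outgroup = 4 * t_div,
                             asian_proxy_chroms = 0, t_asian_proxy = t_adm,
                             seed = NULL) {
  stopifnot(t_adm < t_div || (t_adm == 0 && t_div == 0),
            m_papuan >= 0, m_papuan <= 1,
            mu >= 0, rec >= 0, Ne > 0, window_bp >= 1,
            length(chroms) == 3, !is.null(names(chroms)))
  cfg <- list(Ne = Ne, t_div = t_div, t_adm = t_adm, m_papuan = m_papuan,
              mu = mu, rec = rec, window_bp = window_bp,
              n_windows = n_windows, chroms = chroms,
              n_snps_target = n_snps_target,
              outgroup_chroms = outgroup_chroms, t_outgroup = t_outgroup,
              asian_proxy_chroms = asian_proxy_chroms,
              t_asian_proxy = t_asian_proxy, seed = seed)
  class(cfg) <- "DemographyConfig"
  cfg
}

#' @export
print.DemographyConfig <- function(x, ...) {
  cat("DemographyConfig\n")
  cat(sprintf("  Ne=%g  split=%g gen  pulse=%g gen  m_papuan=%g\n",
              x$Ne, x$t_div, x$t_adm, x$m_papuan))
  cat(sprintf("  mu=%g  rec=%g  window=%g bp x %d  target SNPs=%d\n",
              x$mu, x$rec, x$window_bp, x$n_windows, x$n_snps_target))
  cat("  chromosomes:",
      paste(sprintf("%s=%d", names(x$chroms), x$chroms), collapse = " "),
      if (x$outgroup_chroms > 0)
        sprintf(" Outgroup=%d (split %g gen)", x$outgroup_chroms,
                x$t_outgroup) else "", "\n")
  invisible(x)
}

#' Simulate coalescent windows under the pulse-admixture history
#'
#' Each window is an independent realisation of the standard coalescent with
#' recombination under the configured three-population history (ancestral
#' population splits at `t_div`; at `t_adm` the admixed deme's lineages trace
#' back to the Papuan side with probability `m_papuan`, else the Asian side).
#' Derived alleles are coded 1; every site is segregating in the pooled
#' sample.  Reproducible via `cfg$seed` or an external `set.seed()`.
#'
#' @param cfg a [demographyConfig()]
#' @param nWindows number of windows (defaults to `cfg$n_windows`)
#' @return list of `SimWindow` objects (fields: index, chrom, positions,
#'   haplotypes, pop, windowBp, recRate)
#' @export
simulateWindows <- function(cfg, nWindows = cfg$n_windows) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pops <- rep(c(names(cfg$chroms)[c(1, 2, 3)], "Outgroup", "AsianProxy"),
              c(cfg$chroms[1], cfg$chroms[2], cfg$chroms[3],
                cfg$outgroup_chroms, cfg$asian_proxy_chroms))
  lapply(seq_len(nWindows), function(i) {
    sim <- .sim_window_cpp(cfg$window_bp, cfg$Ne, cfg$mu, cfg$rec,
                           cfg$t_adm, cfg$m_papuan, cfg$t_div,
                           as.integer(cfg$chroms[1]),
                           as.integer(cfg$chroms[2]),
                           as.integer(cfg$chroms[3]),
                           as.integer(cfg$outgroup_chroms),
                           cfg$t_outgroup,
                           as.integer(cfg$asian_proxy_chroms),
                           cfg$t_asian_proxy)
    truth <- if (length(sim$tractHap))
      data.frame(hap = sim$tractHap, start = sim$tractL, end = sim$tractR,
                 papuan = sim$tractAnc)
    else NULL
    structure(list(index = i, chrom = sprintf("win%04d", i),
                   positions = sim$positions, haplotypes = sim$haplotypes,
                   pop = pops, windowBp = cfg$window_bp, recRate = cfg$rec,
                   admixedPop = names(cfg$chroms)[2], truth = truth),
              class = "SimWindow")
  })
}

#' @export
print.SimWindow <- function(x, ...) {
  cat(sprintf("SimWindow %s: %d segregating sites, %d haplotypes over %g bp\n",
              x$chrom, length(x$positions), nrow(x$haplotypes), x$windowBp))
  invisible(x)
}

#' Default ascertainment target: flat MAF histogram with a rare-variant taper
#'
#' A stand-in array spectrum over 0.01-wide folded-MAF bins on (0, 0.5]:
#' flat above 0.05 with a linear taper below (array content is depleted for
#' rare variants relative to the neutral spectrum).  Replace with a measured
#' histogram when one is available.
#'
#' @return data.frame with columns lower, upper, mass (mass sums to 1)
#' @export
defaultMAFTargetHist <- function() {
  w <- c(seq_len(5) / 5, rep(1, 45))
  data.frame(lower = (0:49) / 100, upper = (1:50) / 100, mass = w / sum(w))
}

.pooledFoldedMAF <- function(win) {
  f <- colMeans(win$haplotypes)
  pmin(f, 1 - f)
}

#' Ascertain simulated variants to a target MAF histogram
#'
#' Emulates SNP-array ascertainment: sites are sampled without replacement so
#' that per-bin counts follow `targetHist` (largest-remainder rounding), the
#' bin of a site being its pooled-sample folded MAF.  Bins whose demand
#' exceeds the available supply are rescaled with a warning and the shortfall
#' is redistributed over the remaining bins.  Genotypes at retained sites are
#' untouched.  Deterministic given the RNG state.
#'
#' @param windows list of `SimWindow` from [simulateWindows()]
#' @param targetHist data.frame(lower, upper, mass) over 0.01-wide bins on
#'   (0, 0.5]; see [defaultMAFTargetHist()]
#' @param nTarget total number of sites to retain
#' @return the windows with only the retained sites
#' @export
ascertainVariants <- function(windows, targetHist = defaultMAFTargetHist(),
                              nTarget) {
  stopifnot(nTarget >= 0, abs(sum(targetHist$mass) - 1) < 1e-8)
  maf <- lapply(windows, .pooledFoldedMAF)
  bin <- lapply(maf, function(m) pmin(pmax(ceiling(m * 100), 1L), 50L))
  widx <- rep(seq_along(windows), lengths(bin))
  sidx <- unlist(lapply(bin, seq_along))
  binAll <- unlist(bin)
  supply <- tabulate(binAll, 50L)
  if (nTarget > sum(supply))
    stop("nTarget exceeds the number of available sites")

  # largest-remainder quota, then redistribute shortfall over unsaturated bins
  quota <- function(nT, mass) {
    raw <- nT * mass
    q <- floor(raw)
    rem <- nT - sum(q)
    if (rem > 0) {
      o <- order(raw - q, decreasing = TRUE)
      q[o[seq_len(rem)]] <- q[o[seq_len(rem)]] + 1
    }
    q
  }
  demand <- quota(nTarget, targetHist$mass)
  take <- pmin(demand, supply)
  short <- sum(demand) - sum(take)
  if (short > 0) {
    warning(sprintf(
      "ascertainment: %d bin(s) undersupplied; %d site(s) redistributed",
      sum(demand > supply), short))
    while (short > 0) {
      room <- supply - take
      open <- room > 0 & targetHist$mass > 0
      if (!any(open)) open <- room > 0
      if (!any(open)) break
      extra <- quota(short, (targetHist$mass * open) /
                       sum(targetHist$mass * open))
      extra <- pmin(extra, room)
      if (sum(extra) == 0) {
        i <- which(open)[1]
        extra[i] <- min(short, room[i])
      }
      take <- take + extra
      short <- short - sum(extra)
    }
  }

  pick <- logical(length(binAll))
  for (b in which(take > 0)) {
    inb <- which(binAll == b)
    pick[inb[sample.int(length(inb), take[b])]] <- TRUE
  }
  for (i in seq_along(windows)) {
    keep <- sidx[pick & widx == i]
    windows[[i]]$positions <- windows[[i]]$positions[keep]
    windows[[i]]$haplotypes <- windows[[i]]$haplotypes[, keep, drop = FALSE]
  }
  windows
}

.windowVariants <- function(win) {
  data.frame(chrom = win$chrom, pos = win$positions,
             id = sprintf("%s:%d", win$chrom, win$positions),
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

#' Collapse simulated haplotypes into diploid genotypes
#'
#' Consecutive haplotype pairs within each population form individuals;
#' the dosage is the pair sum and no missingness is introduced.  A list of
#' windows is concatenated variant-wise, each window becoming its own
#' chromosome.
#'
#' @param windows a `SimWindow` or list of them (identical sample layout)
#' @return a [GenotypeMatrix-class]
#' @export
haplotypesToGenotypes <- function(windows) {
  if (inherits(windows, "SimWindow")) windows <- list(windows)
  pops <- windows[[1]]$pop
  cnt <- table(factor(pops, unique(pops)))
  if (any(cnt %% 2 != 0))
    stop("odd haplotype count in population(s): ",
         paste(names(cnt)[cnt %% 2 != 0], collapse = ", "))
  idx1 <- seq(1, length(pops), by = 2)
  samplePop <- pops[idx1]
  samples <- data.frame(
    id = paste0(samplePop, "_", stats::ave(seq_along(samplePop), samplePop,
                                           FUN = seq_along)),
    pop = samplePop, stringsAsFactors = FALSE)
  gm <- do.call(cbind, lapply(windows, function(w) {
    h <- w$haplotypes
    h[idx1, , drop = FALSE] + h[idx1 + 1, , drop = FALSE]
  }))
  vv <- do.call(rbind, lapply(windows, .windowVariants))
  GenotypeMatrix(gm, vv, samples)
}

#' True Papuan-ancestry dosage of the admixed individuals in a window
#'
#' Reconstructs, from the ancestry recorded at the admixture pulse, the true
#' diploid Papuan dosage of every admixed individual at the window's
#' (possibly ascertained) positions -- the oracle for validating the
#' local-ancestry HMM on coalescent data.
#'
#' @param win a `SimWindow` from [simulateWindows()] with an admixed deme
#' @return integer matrix (individuals x sites) of true dosages in 0..2
#' @export
trueAncestryDosage <- function(win) {
  if (is.null(win$truth)) stop("window carries no ancestry truth")
  adm <- which(win$pop == win$admixedPop)
  nAdm <- length(adm)
  S <- length(win$positions)
  hapAnc <- matrix(NA_integer_, nAdm, S)
  x <- win$positions - 0.5          # site positions on the continuous scale
  tr <- win$truth
  for (k in seq_len(nrow(tr))) {
    j <- which(x >= tr$start[k] & x < tr$end[k])
    if (length(j)) hapAnc[tr$hap[k], j] <- tr$papuan[k]
  }
  if (anyNA(hapAnc)) stop("ancestry truth does not tile the window")
  i1 <- seq(1, nAdm, by = 2)
  hapAnc[i1, , drop = FALSE] + hapAnc[i1 + 1, , drop = FALSE]
}

#' Extract one simulated window as a HaplotypeMatrix
#'
#' The derived allele is the alt allele and the ancestral allele is known by
#' construction, so the result is directly usable by [ihsScan()].  Genetic
#' positions use the window's uniform recombination rate.
#'
#' @param win a `SimWindow`
#' @param population optional population label to restrict haplotypes to
#' @return a [HaplotypeMatrix-class]
#' @export
asHaplotypeMatrix <- function(win, population = NULL) {
  rows <- if (is.null(population)) seq_along(win$pop)
          else which(win$pop %in% population)
  if (!length(rows)) stop("no haplotypes in population: ", population)
  v <- .windowVariants(win)
  HaplotypeMatrix(win$haplotypes[rows, , drop = FALSE], v,
                  ancestral = v$ref,
                  gposCm = win$positions * win$recRate * 100)
}

#' Simulate diverged allele-frequency panels
#'
#' Draws an ancestral frequency per variant from Uniform(0.05, 0.95) and two
#' descendant panel frequencies from the Balding-Nichols Beta distribution at
#' divergence `fst`.  Convenience generator for tests and examples that need
#' a Papuan-like / Asian-like panel pair with known divergence.
#'
#' @param nVariants number of variants
#' @param fst Balding-Nichols divergence of each panel from the ancestor
#' @param spacingBp physical spacing between consecutive variants
#' @param chrom chromosome label(s); variants are split evenly across them
#' @param nObs haploid panel sizes recorded in the two panels
#' @return list with elements `panelP` and `panelA`
#' @export
simulateDivergedPanels <- function(nVariants, fst = 0.2, spacingBp = 20000,
                                   chrom = "1", nObs = c(48, 90)) {
  perChrom <- ceiling(nVariants / length(chrom))
  ch <- rep(chrom, each = perChrom)[seq_len(nVariants)]
  pos <- unlist(lapply(rle(ch)$lengths, function(n) seq_len(n) * spacingBp))
  p0 <- runif(nVariants, 0.05, 0.95)
  bn <- function(p) {
    if (fst <= 0) return(p)
    a <- p * (1 - fst) / fst
    b <- (1 - p) * (1 - fst) / fst
    rbeta(length(p), a, b)
  }
  v <- data.frame(chrom = ch, pos = pos,
                  id = sprintf("%s:%d", ch, pos), ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  list(panelP = AlleleFrequencyPanel(v, bn(p0), rep(nObs[1], nVariants)),
       panelA = AlleleFrequencyPanel(v, bn(p0), rep(nObs[2], nVariants)))
}

#' Draw diploid genotypes from a frequency panel
#'
#' Dosages are Binomial(2, freq) per variant, independent across variants:
#' a linkage-equilibrium population with the panel's allele frequencies.
#'
#' @param panel an [AlleleFrequencyPanel-class]
#' @param nInd number of individuals
#' @param pop population label for the samples
#' @return a [GenotypeMatrix-class]
#' @export
samplePanelGenotypes <- function(panel, nInd, pop) {
  f <- panelFreq(panel)
  f[is.na(f)] <- 0.5
  gm <- matrix(rbinom(nInd * length(f), 2, rep(f, each = nInd)),
               nrow = nInd)
  GenotypeMatrix(gm, variants(panel),
                 data.frame(id = paste0(pop, "_", seq_len(nInd)), pop = pop,
                            stringsAsFactors = FALSE))
}

#' Tract-copying admixture generator with known ancestry truth
#'
#' Fast generator of admixed diploid genotypes `T` generations after a pulse
#' with Papuan fraction `m`: along the genetic map each haplotype switches
#' ancestry at Poisson(`T` per Morgan) points, the ancestry after every
#' switch drawn Papuan with probability `m`; alleles are then drawn
#' Bernoulli from the local ancestry's panel frequency.  The realised tracts
#' and the true diploid Papuan dosage are returned as the oracle for
#' local-ancestry validation.
#'
#' @param panelP,panelA [AlleleFrequencyPanel-class] pair sharing variants
#' @param generations generations since the pulse (`T > 0`)
#' @param m Papuan mixture fraction in (0, 1) (0/1 allowed for degenerate
#'   single-ancestry draws)
#' @param nInd number of admixed diploid individuals
#' @param cmPerMb genetic map as a constant rate (default 1 cM = 1 Mb)
#' @param pop population label for the generated samples
#' @return list with `genotypes` (a [GenotypeMatrix-class]), `trueDosage`
#'   (individuals x variants matrix in \{0,1,2\}) and `tracts` (per-haplotype
#'   data.frames of chrom, start_bp, end_bp, ancestry)
#' @export
simulateTractAdmixture <- function(panelP, panelA, generations, m, nInd,
                                   cmPerMb = 1, pop = "admixed") {
  v <- variants(panelP)
  stopifnot(identical(v$chrom, variants(panelA)$chrom),
            identical(v$pos, variants(panelA)$pos),
            generations > 0, m >= 0, m <= 1)
  fP <- panelFreq(panelP); fA <- panelFreq(panelA)
  nHap <- 2 * nInd
  chroms <- unique(v$chrom)
  hap <- matrix(0L, nHap, nrow(v))
  hapAnc <- matrix(0L, nHap, nrow(v))   # 1 = Papuan
  tracts <- vector("list", nHap)
  for (ci in chroms) {
    j <- which(v$chrom == ci)
    pos <- v$pos[j]
    gposM <- pos * cmPerMb / 1e8        # Morgans
    lenM <- max(gposM)
    for (h in seq_len(nHap)) {
      nSw <- rpois(1, generations * lenM)
      sw <- sort(runif(nSw, 0, lenM))
      anc <- as.integer(runif(nSw + 1) < m)
      seg <- findInterval(gposM, c(0, sw))
      hapAnc[h, j] <- anc[seg]
      f <- ifelse(anc[seg] == 1L, fP[j], fA[j])
      hap[h, j] <- as.integer(runif(length(j)) < f)
      # maximal tracts: merge consecutive segments with the same ancestry
      bnd <- c(1, floor(sw / (cmPerMb / 1e8)) + 1, max(pos))
      keep <- c(TRUE, diff(anc) != 0L)
      starts <- bnd[seq_len(nSw + 1)][keep]
      ends <- c(starts[-1], max(pos))
      tracts[[h]] <- rbind(tracts[[h]], data.frame(
        chrom = ci, start_bp = starts, end_bp = ends,
        ancestry = ifelse(anc[keep] == 1L, "P", "A"),
        stringsAsFactors = FALSE))
    }
  }
  i1 <- seq(1, nHap, by = 2)
  gm <- hap[i1, , drop = FALSE] + hap[i1 + 1, , drop = FALSE]
  truth <- hapAnc[i1, , drop = FALSE] + hapAnc[i1 + 1, , drop = FALSE]
  G <- GenotypeMatrix(gm, v, data.frame(id = paste0(pop, "_", seq_len(nInd)),
                                        pop = pop, stringsAsFactors = FALSE))
  list(genotypes = G, trueDosage = truth, tracts = tracts)
}
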