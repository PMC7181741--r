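## EHH/iHS scan for recent positive selection on phased haplotypes, with
## frequency-bin standardisation and two-sided Gaussian p-values.

.derivedMatrix <- function(H) {
  anc <- H@ancestral
  v <- variants(H)
  d <- haplotypes(H)
  flip <- !is.na(anc) & anc == v$alt     # alt is ancestral -> derived = ref
  d[, flip] <- 1L - d[, flip]
  d
}

#' Derived-allele indicator matrix
#'
#' Applies the ancestral-allele polarity: entries are 1 where the haplotype
#' carries the derived allele.  Columns with unknown polarity keep the
#' alt-allele coding and are flagged by `attr(, "polarized")`.
#'
#' @param H a [HaplotypeMatrix-class]
#' @return integer matrix with attribute `polarized` (logical per variant)
#' @export
derivedMatrix <- function(H) {
  d <- .derivedMatrix(H)
  attr(d, "polarized") <- !is.na(H@ancestral)
  d
}

#' Extended haplotype homozygosity around a core variant
#'
#' Starting from the carriers of `allele` at the core,
#' `EHH(x) = sum_h n_h (n_h - 1) / (n_c (n_c - 1))` over the distinct
#' carrier-haplotype prefixes extending from the core out to flank x,
#' computed separately leftward and rightward; `EHH(core) = 1`.  Haplotypes
#' with a missing call inside the extending window are dropped from the
#' homozygosity count at that and all further flanks (pairwise-complete
#' convention).
#'
#' @param H a [HaplotypeMatrix-class]
#' @param core variant index of the core SNP
#' @param allele `"derived"` or `"ancestral"` (requires known polarity at
#'   the core)
#' @param truncateAt stop the outward walk after EHH first falls below this
#'   value (0 = full curve to the chromosome edge); [ihsScan()] truncates at
#'   its integration cutoff since the integral ignores anything beyond
#' @return an `EHHCurve` list: `left` and `right` data.frames (index, gposCm,
#'   ehh; first row is the core itself), `core`, `allele`, `nCarriers`
#' @export
ehh <- function(H, core, allele = c("derived", "ancestral"),
                truncateAt = 0) {
  allele <- match.arg(allele)
  if (is.na(H@ancestral[core]))
    stop("ancestral allele unknown at the core variant")
  d <- .derivedMatrix(H)
  want <- if (allele == "derived") 1L else 0L
  carriers <- which(!is.na(d[, core]) & d[, core] == want)
  nC <- length(carriers)
  if (nC < 2)
    stop("undefined EHH: fewer than 2 carriers of the ", allele,
         " allele at the core")
  v <- variants(H)
  onChrom <- which(v$chrom == v$chrom[core])
  walk <- function(idx) {
    nOut <- length(idx) + 1L
    outIdx <- integer(nOut)
    outEhh <- numeric(nOut)
    outIdx[1] <- core
    outEhh[1] <- 1
    grp <- rep(1L, nC)
    active <- rep(TRUE, nC)
    used <- 1L
    for (j in idx) {
      a <- d[carriers, j]
      active <- active & !is.na(a)
      used <- used + 1L
      outIdx[used] <- j
      if (sum(active) < 2) {
        outEhh[used] <- 0
      } else {
        key <- grp[active] * 2L + a[active]
        grp[active] <- match(key, unique(key))
        nh <- tabulate(grp[active])
        outEhh[used] <- sum(nh * (nh - 1)) / (nC * (nC - 1))
      }
      if (outEhh[used] < truncateAt) break
    }
    data.frame(index = outIdx[seq_len(used)],
               gposCm = H@gposCm[outIdx[seq_len(used)]],
               ehh = outEhh[seq_len(used)])
  }
  left <- walk(rev(onChrom[onChrom < core]))
  right <- walk(onChrom[onChrom > core])
  structure(list(left = left, right = right, core = core, allele = allele,
                 nCarriers = nC),
            class = "EHHCurve")
}

.integrateSide <- function(side, cutoff) {
  # trapezoids over consecutive points while both ends are >= cutoff;
  # integration stops at the first point below cutoff (no interpolation)
  x <- abs(side$gposCm - side$gposCm[1]) / 100   # Morgans from the core
  y <- side$ehh
  area <- 0
  truncated <- FALSE
  if (length(y) >= 2) {
    for (k in 2:length(y)) {
      if (y[k] < cutoff) { truncated = TRUE; break }
      area <- area + (x[k] - x[k - 1]) * (y[k] + y[k - 1]) / 2
    }
  }
  if (y[1] < cutoff) area <- 0                   # curve starting below cutoff
  list(area = area, edge = !truncated)
}

#' Integrated EHH (iHH)
#'
#' Trapezoidal integral of the EHH curve over genetic distance (Morgans),
#' truncated where EHH first drops below `cutoff` on each side; the left and
#' right integrals are summed.  If EHH never drops below the cutoff before
#' the chromosome edge the `edgeTruncated` flag is set (such cores are
#' excluded from standardisation by [ihsScan()]).
#'
#' @param curve an `EHHCurve` from [ehh()]
#' @param cutoff EHH truncation threshold (default 0.05)
#' @return list: value (Morgans), left, right, edgeTruncated
#' @export
ihh <- function(curve, cutoff = 0.05) {
  L <- .integrateSide(curve$left, cutoff)
  R <- .integrateSide(curve$right, cutoff)
  list(value = L$area + R$area, left = L$area, right = R$area,
       edgeTruncated = L$edge || R$edge)
}

#' Genome-wide iHS scan
#'
#' For every polarised core variant with folded frequency >= `minMAF` and at
#' least two carriers of each allele, computes iHH for the ancestral and
#' derived alleles, the unstandardised score `u = ln(iHH_A / iHH_D)`, and
#' standardises within derived-allele-frequency bins of width `binWidth`
#' (bins with fewer than 10 cores are merged with their neighbour), giving
#' scores with mean 0 and SD 1 per bin by construction.  The two-sided
#' Gaussian p-value is `2 * pnorm(-|iHS|)`.  Cores whose EHH hits a
#' chromosome edge before the cutoff are flagged and excluded from
#' standardisation.
#'
#' @param H a [HaplotypeMatrix-class] with phased haplotypes and polarity
#' @param minMAF minimum folded allele frequency for a core (default 0.01)
#' @param cutoff EHH integration cutoff (default 0.05)
#' @param binWidth derived-frequency standardisation bin width (default 0.02)
#' @return a `SelectionScanResult` data.frame: chrom, pos, id, derivedFreq,
#'   ihhA, ihhD, uniHS, bin, iHS, pValue, edgeTruncated
#' @export
ihsScan <- function(H, minMAF = 0.01, cutoff = 0.05, binWidth = 0.02) {
  d <- .derivedMatrix(H)
  v <- variants(H)
  polar <- !is.na(H@ancestral)
  dFreq <- colMeans(d == 1L, na.rm = TRUE)
  nDer <- colSums(d == 1L, na.rm = TRUE)
  nAnc <- colSums(d == 0L, na.rm = TRUE)
  cores <- which(polar & pmin(dFreq, 1 - dFreq) >= minMAF &
                   nDer >= 2 & nAnc >= 2)
  if (!length(cores)) stop("no scorable core variants")
  rows <- lapply(cores, function(j) {
    iA <- ihh(ehh(H, j, "ancestral", truncateAt = cutoff), cutoff)
    iD <- ihh(ehh(H, j, "derived", truncateAt = cutoff), cutoff)
    u <- if (iA$value > 0 && iD$value > 0) log(iA$value / iD$value)
         else NA_real_
    data.frame(chrom = v$chrom[j], pos = v$pos[j], id = v$id[j],
               derivedFreq = dFreq[j], ihhA = iA$value, ihhD = iD$value,
               uniHS = u,
               edgeTruncated = iA$edgeTruncated || iD$edgeTruncated,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)

  usable <- !res$edgeTruncated & is.finite(res$uniHS)
  if (!any(usable))
    stop("all cores edge-truncated before the EHH cutoff; ",
         "chromosome too short for this cutoff")
  bin <- floor(res$derivedFreq / binWidth)
  bin <- pmin(bin, max(bin[usable]))
  # merge sparse bins (< 10 usable cores) into their left neighbour
  repeat {
    tb <- table(bin[usable])
    small <- names(tb)[tb < 10]
    if (!length(small) || length(tb) == 1) break
    b <- as.integer(small[1])
    lev <- sort(unique(bin[usable]))
    tgt <- if (b == min(lev)) lev[which(lev > b)[1]] else max(lev[lev < b])
    bin[bin == b] <- tgt
  }
  res$bin <- bin
  res$iHS <- NA_real_
  for (b in unique(bin[usable])) {
    k <- usable & bin == b
    mu <- mean(res$uniHS[k])
    sg <- sd(res$uniHS[k])
    if (is.finite(sg) && sg > 0)
      res$iHS[k] <- (res$uniHS[k] - mu) / sg
  }
  res$pValue <- 2 * pnorm(-abs(res$iHS))
  class(res) <- c("SelectionScanResult", "data.frame")
  res
}
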