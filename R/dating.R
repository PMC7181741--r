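## Admixture dating from the decay of ancestry-weighted LD.
##
## For every intra-chromosome variant pair (i, j) at genetic distance d, the
## pair's LD is summarised by the sample correlation rho_ij of dosages in the
## admixed population and weighted by the product of the source-panel
## frequency differences w = a - b.  Binned over distance, the statistic
## A(d) = sum(w_i w_j rho_ij) / sum(|w_i w_j|) decays as exp(-n d) with n the
## number of generations since the pulse (d in Morgans).

#' Ancestry-weighted LD decay curve
#'
#' Computes `A(d)` in bins of `binCm` up to `maxCm` (the ROLLOFF-style
#' settings: 0.1 cM bins to 20 cM).  Genetic distance defaults to the
#' 1 cM = 1 Mb map; supply `gposCm` to override.  Pairs with undefined
#' dosage correlation (monomorphic or insufficient overlap) are skipped.
#' Swapping the two panels leaves the curve unchanged (weights negate
#' pairwise).
#'
#' @param G a [GenotypeMatrix-class] of the admixed population only
#' @param panelA,panelB [AlleleFrequencyPanel-class] pair aligned to `G`'s
#'   variants
#' @param binCm bin width in cM
#' @param maxCm maximum pair distance in cM
#' @param gposCm optional genetic positions in cM (default `pos / 1e6`)
#' @return an `LDDecayCurve` data.frame (binCenter, A, nPairs) carrying
#'   per-chromosome bin sums for jackknifing
#' @export
weightedLDCurve <- function(G, panelA, panelB, binCm = 0.1, maxCm = 20,
                            gposCm = NULL) {
  v <- variants(G)
  va <- variants(panelA)
  stopifnot(identical(v$chrom, va$chrom), identical(v$pos, va$pos),
            identical(v$pos, variants(panelB)$pos))
  if (is.null(gposCm)) gposCm <- v$pos / 1e6
  w <- panelFreq(panelA) - panelFreq(panelB)
  nb <- as.integer(ceiling(maxCm / binCm))
  chroms <- unique(v$chrom)
  num <- den <- cnt <- matrix(0, length(chroms), nb,
                              dimnames = list(chroms, NULL))
  for (ci in seq_along(chroms)) {
    j <- which(v$chrom == chroms[ci])
    if (length(j) < 2) next
    g <- t(calls(G)[, j, drop = FALSE])
    rho <- suppressWarnings(cor(t(g), use = "pairwise.complete.obs"))
    d <- abs(outer(gposCm[j], gposCm[j], "-"))
    ww <- outer(w[j], w[j])
    up <- upper.tri(d)
    ok <- up & d > 0 & d <= maxCm & is.finite(rho) & is.finite(ww)
    if (!any(ok)) next
    b <- pmin(ceiling(d[ok] / binCm), nb)
    sums <- rowsum(cbind(ww[ok] * rho[ok], abs(ww[ok])), b)
    bi <- as.integer(rownames(sums))
    num[ci, bi] <- num[ci, bi] + sums[, 1]
    den[ci, bi] <- den[ci, bi] + sums[, 2]
    cnt[ci, ] <- cnt[ci, ] + tabulate(b, nb)
  }
  # zero total weight with populated bins (identical panels) gives A = 0
  A <- ifelse(colSums(den) > 0, colSums(num) / colSums(den),
              ifelse(colSums(cnt) > 0, 0, NA_real_))
  out <- data.frame(binCenter = (seq_len(nb) - 0.5) * binCm, A = A,
                    nPairs = colSums(cnt))
  attr(out, "perChromNum") <- num
  attr(out, "perChromDen") <- den
  attr(out, "binCm") <- binCm
  attr(out, "maxCm") <- maxCm
  if (sum(out$nPairs) == 0) stop("no usable variant pairs within maxCm")
  class(out) <- c("LDDecayCurve", "data.frame")
  out
}

#' Fit an exponential decay to a weighted-LD curve
#'
#' Least-squares fit of `A(d) = A0 * exp(-n d / 100) + c` over bins with
#' data in `[fitMinCm, maxCm]` (d in cM, so n is per Morgan = generations
#' since admixture).  The fit starts at 0.5 cM by default, excluding the
#' shortest distances where background LD contaminates the admixture signal.
#' An optional leave-one-chromosome-out jackknife gives the standard error.
#'
#' @param curve an `LDDecayCurve` from [weightedLDCurve()]
#' @param fitMinCm smallest bin center used in the fit
#' @param jackknife recompute the fit per deleted chromosome for a SE
#'   (needs >= 2 chromosomes)
#' @return a `DatingResult` list: generations, stdErr, years (at 30
#'   years/generation), amplitude, offset, fitRangeCm
#' @export
fitDecay <- function(curve, fitMinCm = 0.5, jackknife = FALSE) {
  maxCm <- attr(curve, "maxCm")
  df <- curve[curve$nPairs > 0 & !is.na(curve$A) &
                curve$binCenter >= fitMinCm, , drop = FALSE]
  if (nrow(df) < 5)
    stop("fewer than 5 usable bins in the fit range")
  fit1 <- function(d, A) {
    c0 <- min(A)
    a0 <- max(A) - c0
    if (a0 <= 0) stop("decay fit failed: no amplitude above the offset")
    pos <- pmax(A - c0, a0 * 1e-3)
    n0 <- max(1, -coef(stats::lm(log(pos) ~ d))[2] * 100)
    fit <- minpack.lm::nlsLM(A ~ a * exp(-n * d / 100) + c,
                             data = data.frame(d = d, A = A),
                             start = list(a = a0, n = n0, c = c0),
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200))
    cf <- coef(fit)
    if (cf[["a"]] <= 0 || cf[["n"]] <= 0)
      stop("decay fit failed: non-decaying optimum (A0 <= 0 or n <= 0)")
    cf
  }
  cf <- fit1(df$binCenter, df$A)
  se <- NA_real_
  if (jackknife) {
    num <- attr(curve, "perChromNum")
    den <- attr(curve, "perChromDen")
    if (!is.null(num) && nrow(num) >= 2) {
      loo <- vapply(seq_len(nrow(num)), function(k) {
        A <- colSums(num[-k, , drop = FALSE]) /
          colSums(den[-k, , drop = FALSE])
        keep <- is.finite(A) & curve$binCenter >= fitMinCm
        tryCatch(fit1(curve$binCenter[keep], A[keep])[["n"]], error =
                   function(e) NA_real_)
      }, 0)
      loo <- loo[is.finite(loo)]
      B <- length(loo)
      if (B >= 2) se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
    }
  }
  structure(list(generations = unname(cf[["n"]]), stdErr = se,
                 years = 30 * unname(cf[["n"]]),
                 amplitude = unname(cf[["a"]]), offset = unname(cf[["c"]]),
                 fitRangeCm = c(fitMinCm, maxCm)),
            class = "DatingResult")
}

#' @export
print.DatingResult <- function(x, ...) {
  cat(sprintf(
    "Admixture date: %.1f generations%s (~%.0f years at 30 y/gen)\n",
    x$generations,
    if (is.finite(x$stdErr)) sprintf(" +/- %.1f", x$stdErr) else "",
    x$years))
  invisible(x)
}
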