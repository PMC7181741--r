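## f-statistics: f3 admixture test, f4, and the F4-ratio ancestry-proportion
## estimator, all with leave-one-block-out jackknife standard errors over
## contiguous genomic blocks (default 5 Mb, i.e. 5 cM under a 1 cM = 1 Mb
## map -- comfortably beyond the LD scale of array data).

.blockIds <- function(variants, blockBp) {
  paste(variants$chrom, (variants$pos - 1) %/% blockBp, sep = "_")
}

.jackknifeMean <- function(terms, blocks) {
  ub <- unique(blocks)
  if (length(ub) < 2) stop("fewer than 2 jackknife blocks; widen the data ",
                           "or reduce blockBp")
  est <- mean(terms)
  loo <- vapply(ub, function(b) mean(terms[blocks != b]), 0)
  B <- length(ub)
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  list(estimate = est, se = se, nBlocks = B)
}

.popFreqPair <- function(G, pop) {
  cc <- calls(G)[sampleInfo(G)$pop == pop, , drop = FALSE]
  n <- 2 * colSums(!is.na(cc))
  list(f = ifelse(n > 0, colSums(cc, na.rm = TRUE) / n, NA_real_), n = n)
}

.checkPops <- function(G, pops) {
  miss <- setdiff(pops, populations(G))
  if (length(miss))
    stop("population(s) absent from the data: ", paste(miss, collapse = ", "))
}

.fstatResult <- function(statistic, jk, nSnps, zThreshold = -2.33) {
  z <- jk$estimate / jk$se
  structure(list(statistic = statistic, estimate = jk$estimate,
                 stdErr = jk$se, z = z, nSnps = nSnps, nBlocks = jk$nBlocks,
                 significant = is.finite(z) && z < zThreshold,
                 zThreshold = zThreshold),
            class = "FStatResult")
}

#' @export
print.FStatResult <- function(x, ...) {
  cat(sprintf("%s = %.5g  std.err = %.3g  Z = %.3g  SNPs = %d  blocks = %d%s\n",
              x$statistic, x$estimate, x$stdErr, x$z, x$nSnps, x$nBlocks,
              if (isTRUE(x$significant)) "  *" else ""))
  invisible(x)
}

#' Three-population test of admixture
#'
#' f3(C; A, B) is the mean over variants of
#' `(c - a)(c - b) - c(1 - c) / (n_C - 1)`, where a, b, c are the sample
#' alt-allele frequencies of the two sources and the target and `n_C` is the
#' target's non-missing allele count (the finite-sample correction for the
#' target's sampling variance).  A significantly negative f3 indicates that
#' C descends from a mixture of populations related to A and B; the one-tailed
#' significance rule flags Z < -2.33 (the 1% level).
#'
#' Variants with any undefined frequency among the three populations, a
#' target allele count below 2, or monomorphic across the pooled three
#' populations are skipped.
#'
#' @param G a [GenotypeMatrix-class] containing all three populations
#' @param target population label C
#' @param sourceA,sourceB source-proxy population labels
#' @param blockBp jackknife block length in bp (default 5 Mb)
#' @param zThreshold one-tailed significance threshold on Z (default -2.33)
#' @return an `FStatResult`: estimate, stdErr, z, nSnps, nBlocks, significant
#' @export
f3Test <- function(G, target, sourceA, sourceB, blockBp = 5e6,
                   zThreshold = -2.33) {
  .checkPops(G, c(target, sourceA, sourceB))
  A <- .popFreqPair(G, sourceA)
  B <- .popFreqPair(G, sourceB)
  C <- .popFreqPair(G, target)
  pooled <- (A$f * A$n + B$f * B$n + C$f * C$n) / (A$n + B$n + C$n)
  use <- !is.na(A$f) & !is.na(B$f) & !is.na(C$f) & C$n >= 2 &
    !is.na(pooled) & pooled > 0 & pooled < 1
  if (!any(use)) stop("no usable variants for f3")
  terms <- (C$f - A$f) * (C$f - B$f) - C$f * (1 - C$f) / (C$n - 1)
  jk <- .jackknifeMean(terms[use], .blockIds(variants(G), blockBp)[use])
  .fstatResult("f3", jk, sum(use), zThreshold)
}

.f4terms <- function(G, A, B, C, D) {
  fa <- .popFreqPair(G, A); fb <- .popFreqPair(G, B)
  fc <- .popFreqPair(G, C); fd <- .popFreqPair(G, D)
  pooled <- (fa$f * fa$n + fb$f * fb$n + fc$f * fc$n + fd$f * fd$n) /
    (fa$n + fb$n + fc$n + fd$n)
  use <- !is.na(fa$f) & !is.na(fb$f) & !is.na(fc$f) & !is.na(fd$f) &
    !is.na(pooled) & pooled > 0 & pooled < 1
  list(terms = (fa$f - fb$f) * (fc$f - fd$f), use = use)
}

#' Four-population f4 statistic
#'
#' Mean over variants of `(a - b)(c - d)`; block-jackknife SE and Z as in
#' [f3Test()] (no finite-sample correction is needed because the four
#' frequencies enter linearly).  Exactly antisymmetric under swapping A/B or
#' C/D.
#'
#' @inheritParams f3Test
#' @param A,B,C,D population labels
#' @return an `FStatResult`
#' @export
f4Test <- function(G, A, B, C, D, blockBp = 5e6) {
  .checkPops(G, c(A, B, C, D))
  ft <- .f4terms(G, A, B, C, D)
  if (!any(ft$use)) stop("no usable variants for f4")
  jk <- .jackknifeMean(ft$terms[ft$use],
                       .blockIds(variants(G), blockBp)[ft$use])
  .fstatResult("f4", jk, sum(ft$use), zThreshold = -Inf)
}

#' F4-ratio estimate of the admixture proportion
#'
#' Estimates the Asian-related ancestry fraction alpha of the admixed
#' population as
#' `f4(asianProxy, outgroup; admixed, papuanProxy) /
#'  f4(asianProxy, outgroup; asianSourceProxy, papuanProxy)`.
#' The standard error jackknifes the ratio itself: both f4 sums are
#' recomputed with each genomic block deleted in turn.  The denominator must
#' be bounded away from zero (|Z| > 3), otherwise the assumed phylogeny is
#' uninformative for the ratio and an error is raised.
#'
#' @param G a [GenotypeMatrix-class] containing all five populations
#' @param outgroup outgroup population label
#' @param asianProxy proxy for the Asian-related ancestor
#' @param papuanProxy proxy for the Papuan-related ancestor
#' @param admixed the admixed target population
#' @param asianSourceProxy population standing in for the true Asian source
#' @param blockBp jackknife block length in bp
#' @return a `RatioResult` list: alpha, stdErr, numerator, denominator
#' @export
f4Ratio <- function(G, outgroup, asianProxy, papuanProxy, admixed,
                    asianSourceProxy, blockBp = 5e6) {
  .checkPops(G, c(outgroup, asianProxy, papuanProxy, admixed,
                  asianSourceProxy))
  den <- f4Test(G, asianProxy, outgroup, asianSourceProxy, papuanProxy,
                blockBp)
  if (!is.finite(den$z) || abs(den$z) <= 3)
    stop("denominator f4 is consistent with 0 (|Z| <= 3): the assumed ",
         "phylogeny is uninformative for an admixture proportion")
  num <- f4Test(G, asianProxy, outgroup, admixed, papuanProxy, blockBp)

  nt <- .f4terms(G, asianProxy, outgroup, admixed, papuanProxy)
  dt <- .f4terms(G, asianProxy, outgroup, asianSourceProxy, papuanProxy)
  use <- nt$use & dt$use
  blocks <- .blockIds(variants(G), blockBp)[use]
  ntu <- nt$terms[use]; dtu <- dt$terms[use]
  alpha <- mean(ntu) / mean(dtu)
  ub <- unique(blocks)
  if (length(ub) < 2) stop("fewer than 2 jackknife blocks")
  loo <- vapply(ub, function(b) {
    k <- blocks != b
    mean(ntu[k]) / mean(dtu[k])
  }, 0)
  B <- length(ub)
  se <- sqrt((B - 1) / B * sum((loo - mean(loo))^2))
  structure(list(alpha = alpha, stdErr = se, nSnps = sum(use),
                 nBlocks = B, numerator = num, denominator = den),
            class = "RatioResult")
}

#' @export
print.RatioResult <- function(x, ...) {
  cat(sprintf("F4 ratio: alpha = %.4f +/- %.4f (%d SNPs, %d blocks)\n",
              x$alpha, x$stdErr, x$nSnps, x$nBlocks))
  invisible(x)
}
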