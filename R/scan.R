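## Genome-wide ancestry-excess scan: summarise the mean ancestry track, flag
## outlier positions beyond +/-2 and +/-3 SD, call contiguous excess regions,
## Grubbs' test for single extreme positions, and compare observed region
## lengths against a simulated neutral null.

.trackValues <- function(track) {
  if (is.data.frame(track)) {
    stopifnot(all(c("chrom", "pos", "ancestry") %in% names(track)))
    track
  } else {
    data.frame(chrom = "1", pos = seq_along(track), ancestry = as.numeric(track))
  }
}

#' Summarise a mean ancestry track
#'
#' Genome-wide mean and SD (population form, denominator N) of the
#' per-position mean Papuan fraction, the mean +/- 2 SD and +/- 3 SD
#' thresholds, and a per-variant flag assigning each position to the most
#' extreme threshold it crosses (strict inequality): `within`, `>+2SD`,
#' `>+3SD`, `<-2SD`, `<-3SD`.
#'
#' @param track a `MeanAncestryTrack` data.frame (chrom, pos, ancestry) from
#'   [populationMeanTrack()], or a bare numeric vector
#' @return a `ScanSummary` list: mean, sd, thresholds, flags, n
#' @export
summarizeTrack <- function(track) {
  tv <- .trackValues(track)
  x <- tv$ancestry
  if (!length(x)) stop("empty track")
  mu <- mean(x)
  sdev <- sqrt(mean((x - mu)^2))
  thr <- c(lower3 = mu - 3 * sdev, lower2 = mu - 2 * sdev,
           upper2 = mu + 2 * sdev, upper3 = mu + 3 * sdev)
  flags <- rep("within", length(x))
  flags[x > thr["upper2"]] <- ">+2SD"
  flags[x > thr["upper3"]] <- ">+3SD"
  flags[x < thr["lower2"]] <- "<-2SD"
  flags[x < thr["lower3"]] <- "<-3SD"
  structure(list(mean = mu, sd = sdev, thresholds = thr, flags = flags,
                 n = length(x)),
            class = "ScanSummary")
}

#' @export
print.ScanSummary <- function(x, ...) {
  cat(sprintf("ScanSummary: mean = %.4f, SD = %.4f over %d positions\n",
              x$mean, x$sd, x$n))
  tb <- table(factor(x$flags,
                     c("<-3SD", "<-2SD", "within", ">+2SD", ">+3SD")))
  cat("  flags:", paste(sprintf("%s:%d", names(tb), tb), collapse = "  "),
      "\n")
  invisible(x)
}

#' Grubbs' test for a single outlier
#'
#' `G = max |x_i - mean| / s` (two-sided; one tail on request), with the
#' p-value from the t-quantile relation
#' `tau = sqrt(N (N-2) G^2 / ((N-1)^2 - N G^2))`,
#' `p = min(1, N P(t_{N-2} >= tau))`, doubled for the two-sided test.  When
#' G sits at its algebraic maximum the p-value is 0.  On strongly
#' autocorrelated ancestry tracks the nominal p-value ignores the
#' autocorrelation; treat the simulated neutral null as the calibrated test.
#'
#' @param x numeric values (N >= 3, non-constant)
#' @param side `"two"`, `"upper"` or `"lower"`
#' @return a `GrubbsResult` list: G, pValue, index, side
#' @export
grubbsTest <- function(x, side = c("two", "upper", "lower")) {
  side <- match.arg(side)
  n <- length(x)
  if (n < 3) stop("Grubbs' test needs at least 3 values")
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("degenerate input: zero variance")
  dev <- x - mean(x)
  i <- switch(side,
              two = which.max(abs(dev)),
              upper = which.max(dev),
              lower = which.min(dev))
  G <- switch(side, two = abs(dev[i]), upper = dev[i], lower = -dev[i]) / s
  denom <- (n - 1)^2 - n * G^2
  if (G <= 0) {
    p <- 1
  } else if (denom <= 0) {
    p <- 0
  } else {
    tau <- sqrt(n * (n - 2) * G^2 / denom)
    p <- min(1, (if (side == "two") 2 else 1) *
               n * pt(tau, df = n - 2, lower.tail = FALSE))
  }
  structure(list(G = G, pValue = p, index = i, side = side),
            class = "GrubbsResult")
}

#' @export
print.GrubbsResult <- function(x, ...) {
  cat(sprintf("Grubbs' test (%s-sided): G = %.3f, p %s at index %d\n",
              x$side, x$G,
              if (x$pValue < 2.2e-16) "< 2.2e-16"
              else sprintf("= %.3g", x$pValue), x$index))
  invisible(x)
}

#' Call contiguous ancestry-excess regions
#'
#' A region is a maximal run of consecutive same-chromosome positions whose
#' track value lies strictly beyond `mean + sdMultiplier * SD` (side
#' `"high"`) or strictly below `mean - sdMultiplier * SD` (side `"low"`),
#' with gap tolerance 0.  Singleton runs are retained as zero-length regions
#' with `nVariants = 1`.  Region length = end - start in bp.
#'
#' @param track a `MeanAncestryTrack` data.frame (chrom, pos, ancestry)
#' @param summary a [summarizeTrack()] result; recomputed from `track` when
#'   NULL.  Pass the observed-track summary to evaluate another track against
#'   observed thresholds
#' @param side `"high"` (Papuan excess) or `"low"` (Asian excess)
#' @param sdMultiplier SD multiplier for the threshold (default 3)
#' @return data.frame: chrom, start, end, length, nVariants, extremeValue,
#'   extremePos, side
#' @export
callRegions <- function(track, summary = NULL, side = c("high", "low"),
                        sdMultiplier = 3) {
  side <- match.arg(side)
  tv <- .trackValues(track)
  if (is.null(summary)) summary <- summarizeTrack(tv)
  thr <- if (side == "high") summary$mean + sdMultiplier * summary$sd
         else summary$mean - sdMultiplier * summary$sd
  beyond <- if (side == "high") tv$ancestry > thr else tv$ancestry < thr
  out <- list()
  for (ci in unique(tv$chrom)) {
    j <- which(tv$chrom == ci)
    r <- rle(beyond[j])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      jj <- j[starts[k]:ends[k]]
      ex <- if (side == "high") which.max(tv$ancestry[jj])
            else which.min(tv$ancestry[jj])
      out[[length(out) + 1]] <- data.frame(
        chrom = ci, start = tv$pos[jj[1]], end = tv$pos[jj[length(jj)]],
        length = tv$pos[jj[length(jj)]] - tv$pos[jj[1]],
        nVariants = length(jj), extremeValue = tv$ancestry[jj[ex]],
        extremePos = tv$pos[jj[ex]], side = side,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer(),
                      nVariants = integer(), extremeValue = numeric(),
                      extremePos = integer(), side = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Region-length statistics of a simulated neutral null
#'
#' Thresholds (mean +/- `sdMultiplier` SD) are computed from the simulated
#' tracks themselves; regions are then called per window (windows are
#' independent chromosomes, so regions never span windows).  Returns the
#' mean and maximum contiguous region length and counts per side, with all
#' null lengths retained for empirical exceedance computations.
#'
#' @param tracks a `MeanAncestryTrack` data.frame whose chrom column labels
#'   the simulation windows, or a list of such tracks (rbind-ed)
#' @param sdMultiplier SD multiplier (default 3)
#' @return a `NullSummary` list: mean, sd, high/low (lengths, meanLength,
#'   maxLength, count), sdMultiplier
#' @export
regionLengthNull <- function(tracks, sdMultiplier = 3) {
  if (is.list(tracks) && !is.data.frame(tracks))
    tracks <- do.call(rbind, tracks)
  tv <- .trackValues(tracks)
  summ <- summarizeTrack(tv)
  sideStats <- function(side) {
    reg <- callRegions(tv, summ, side, sdMultiplier)
    list(lengths = reg$length,
         meanLength = if (nrow(reg)) mean(reg$length) else NA_real_,
         maxLength = if (nrow(reg)) max(reg$length) else NA_real_,
         count = nrow(reg))
  }
  structure(list(mean = summ$mean, sd = summ$sd,
                 high = sideStats("high"), low = sideStats("low"),
                 sdMultiplier = sdMultiplier),
            class = "NullSummary")
}

#' @export
print.NullSummary <- function(x, ...) {
  cat(sprintf("NullSummary: track mean = %.4f, SD = %.4f (+/-%g SD regions)\n",
              x$mean, x$sd, x$sdMultiplier))
  for (s in c("high", "low"))
    cat(sprintf("  %s: %d region(s), mean length %.0f bp, max %.0f bp\n",
                s, x[[s]]$count, x[[s]]$meanLength, x[[s]]$maxLength))
  invisible(x)
}

#' Compare observed excess regions against the simulated null
#'
#' Per observed region: whether its length exceeds the null maximum on the
#' same side, and the fraction of null regions at least as long (empirical
#' exceedance proportion).  An empty null yields NA with `noNullRegions`
#' set, not an error.
#'
#' @param observed region data.frame from [callRegions()]
#' @param null a `NullSummary` from [regionLengthNull()] at the same
#'   `sdMultiplier`
#' @return the observed data.frame plus columns exceedsNullMax,
#'   exceedanceFraction, noNullRegions
#' @export
compareObservedToNull <- function(observed, null) {
  if (!nrow(observed)) {
    out <- observed
    out$exceedsNullMax <- logical(0)
    out$exceedanceFraction <- numeric(0)
    out$noNullRegions <- logical(0)
    return(out)
  }
  res <- lapply(seq_len(nrow(observed)), function(i) {
    nl <- null[[observed$side[i]]]$lengths
    if (!length(nl))
      return(data.frame(exceedsNullMax = NA, exceedanceFraction = NA_real_,
                        noNullRegions = TRUE))
    data.frame(exceedsNullMax = observed$length[i] > max(nl),
               exceedanceFraction = mean(nl >= observed$length[i]),
               noNullRegions = FALSE)
  })
  cbind(observed, do.call(rbind, res))
}
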