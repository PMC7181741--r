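test_that("track summary uses the population SD and strict flags", {
  # constant track: zero SD, no flags
  s <- summarizeTrack(rep(0.5, 100))
  expect_equal(s$sd, 0)
  expect_true(all(s$flags == "within"))
  # closed form on a synthetic Gaussian track
  set.seed(61)
  x <- rnorm(5000, 0.5, 0.1)
  s2 <- summarizeTrack(x)
  expect_equal(s2$mean, mean(x))
  expect_equal(s2$sd, sqrt(mean((x - mean(x))^2)))
  expect_equal(unname(s2$thresholds["upper3"]), s2$mean + 3 * s2$sd)
  # flags partition and match direct recomputation
  expect_identical(s2$flags == ">+3SD", x > s2$mean + 3 * s2$sd)
  expect_identical(s2$flags %in% c(">+2SD", ">+3SD"), x > s2$mean + 2 * s2$sd)
  # ~0.27% of iid Gaussian values lie beyond 3 SD
  frac <- mean(s2$flags %in% c(">+3SD", "<-3SD"))
  expect_lt(abs(frac - 0.0027), 3 * sqrt(0.0027 / 5000) + 5e-4)
})

test_that("Grubbs' statistic and p-value follow the t-quantile formula", {
  g <- grubbsTest(c(-1, 0, 1))
  expect_equal(g$G, 1)
  expect_equal(g$pValue, 1)

  x <- c(1, 2, 3, 4, 100)
  g2 <- grubbsTest(x)
  expect_equal(g2$G, (100 - mean(x)) / sd(x))
  n <- 5
  tau <- sqrt(n * (n - 2) * g2$G^2 / ((n - 1)^2 - n * g2$G^2))
  expect_equal(g2$pValue, min(1, 2 * n * pt(tau, n - 2, lower.tail = FALSE)))
  expect_lt(g2$pValue, 0.05)
  expect_equal(g2$index, 5L)

  # an extreme spike on a large track underflows to the printed floor
  set.seed(62)
  y <- rnorm(20000, 0.5, 0.1)
  y[123] <- 0.5 + 12 * 0.1
  expect_lt(grubbsTest(y)$pValue, 2.2e-16)
  expect_output(print(grubbsTest(y)), "< 2.2e-16")

  expect_error(grubbsTest(rep(1, 10)), "zero variance")
  expect_error(grubbsTest(c(1, 2)), "at least 3")
  # one-sided variants pick the correct tail
  expect_equal(grubbsTest(x, "upper")$index, 5L)
  expect_equal(grubbsTest(x, "lower")$index, 1L)
})

test_that("region calling equals a run-length-encoding oracle", {
  # worked example: beyond at positions 100, 300, 500 flanked by within
  tr <- data.frame(chrom = "1", pos = c(50L, 100L, 300L, 500L, 600L),
                   ancestry = c(0.5, 0.95, 0.96, 0.99, 0.5))
  s <- structure(list(mean = 0.5, sd = 0.1), class = "ScanSummary")
  reg <- callRegions(tr, s, "high", 3)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 100)
  expect_equal(reg$end, 500)
  expect_equal(reg$length, 400)
  expect_equal(reg$nVariants, 3)
  expect_equal(reg$extremePos, 500)
  # no flagged variant: empty result
  expect_equal(nrow(callRegions(tr, structure(list(mean = 0.5, sd = 10),
                                              class = "ScanSummary"),
                                "high", 3)), 0)

  # random flag vectors vs a brute-force scan, including singletons
  set.seed(63)
  for (rep in 1:20) {
    nv <- 150
    tr2 <- data.frame(
      chrom = sample(c("a", "b"), nv, replace = TRUE),
      pos = 0L, ancestry = rnorm(nv, 0.5, 0.1))
    tr2 <- tr2[order(tr2$chrom), ]
    tr2$pos <- unlist(lapply(table(tr2$chrom)[unique(tr2$chrom)],
                             function(n) sort(sample(1:10000, n)) * 100L))
    s2 <- summarizeTrack(tr2)
    reg2 <- callRegions(tr2, s2, "high", 1.5)
    # oracle: explicit element walk
    beyond <- tr2$ancestry > s2$mean + 1.5 * s2$sd
    runs <- list()
    cur <- NULL
    for (i in seq_len(nv)) {
      newChrom <- i == 1 || tr2$chrom[i] != tr2$chrom[i - 1]
      if (beyond[i] && (newChrom || !beyond[i - 1])) cur <- i
      if (beyond[i]) {
        last <- i == nv || tr2$chrom[i] != tr2$chrom[i + 1]
        if (last || !beyond[i + 1]) {
          runs[[length(runs) + 1]] <- c(cur, i)
          cur <- NULL
        }
      }
    }
    expect_equal(nrow(reg2), length(runs))
    for (k in seq_along(runs)) {
      expect_equal(reg2$start[k], tr2$pos[runs[[k]][1]])
      expect_equal(reg2$end[k], tr2$pos[runs[[k]][2]])
      expect_equal(reg2$nVariants[k], runs[[k]][2] - runs[[k]][1] + 1L)
    }
    # singleton runs are zero-length but retained
    expect_true(all(reg2$length[reg2$nVariants == 1] == 0))
  }
})

test_that("region calling is invariant to affine transforms and deterministic", {
  set.seed(64)
  tr <- data.frame(chrom = "w", pos = sort(sample(1:100000, 300)) * 10L,
                   ancestry = rnorm(300, 0.5, 0.12))
  r1 <- callRegions(tr, side = "high", sdMultiplier = 2)
  tr2 <- tr
  tr2$ancestry <- 3 * tr$ancestry + 1
  r2 <- callRegions(tr2, side = "high", sdMultiplier = 2)
  expect_equal(r1[, c("chrom", "start", "end", "nVariants")],
               r2[, c("chrom", "start", "end", "nVariants")])
  expect_identical(callRegions(tr, side = "high", sdMultiplier = 2), r1)
})

test_that("null region summary and observed comparison behave per contract", {
  # single window, one flagged run of known span: mean = max = span
  tr <- data.frame(chrom = "w1",
                   pos = c(100L, 200L, 300L, 400L, 500L, 600L),
                   ancestry = c(0.5, 0.5, 0.95, 0.97, 0.5, 0.5))
  # thresholds from the track itself: mean ~0.645, sd ~0.2 -> use multiplier 1
  nl <- regionLengthNull(tr, sdMultiplier = 1)
  expect_equal(nl$high$count, 1)
  expect_equal(nl$high$meanLength, nl$high$maxLength)
  expect_equal(nl$high$meanLength, 100)

  obs <- data.frame(chrom = "chr6", start = 32233886L, end = 33976742L,
                    length = 1742856L, nVariants = 50,
                    extremeValue = 0.88, extremePos = 32430975L,
                    side = "high", stringsAsFactors = FALSE)
  null <- structure(list(mean = 0.5, sd = 0.1,
                         high = list(lengths = c(1, 2, 3) * 1e5,
                                     meanLength = 2e5, maxLength = 3e5,
                                     count = 3),
                         low = list(lengths = numeric(), meanLength = NA,
                                    maxLength = NA, count = 0),
                         sdMultiplier = 3), class = "NullSummary")
  cmp <- compareObservedToNull(obs, null)
  expect_true(cmp$exceedsNullMax)
  expect_equal(cmp$exceedanceFraction, 0)
  # exceedance fraction counts null regions at least as long
  obs2 <- obs
  obs2$length <- 2e5
  expect_equal(compareObservedToNull(obs2, null)$exceedanceFraction, 2 / 3)
  # empty observed set: empty report
  expect_equal(nrow(compareObservedToNull(obs[0, ], null)), 0)
  # empty null: flagged, not an error
  obs3 <- obs
  obs3$side <- "low"
  cmp3 <- compareObservedToNull(obs3, null)
  expect_true(cmp3$noNullRegions)
  expect_true(is.na(cmp3$exceedsNullMax))
})
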