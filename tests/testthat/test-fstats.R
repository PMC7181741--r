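# Brute-force per-variant oracles recompute the f-statistics directly from
# population frequencies; the package path must agree exactly.

bruteF3 <- function(G, target, a, b) {
  pop <- sampleInfo(G)$pop
  terms <- vapply(seq_len(nVariants(G)), function(j) {
    fr <- function(p) {
      cc <- calls(G)[pop == p, j]
      c(sum(cc, na.rm = TRUE) / (2 * sum(!is.na(cc))), 2 * sum(!is.na(cc)))
    }
    fa <- fr(a); fb <- fr(b); fc <- fr(target)
    pool <- (fa[1] * fa[2] + fb[1] * fb[2] + fc[1] * fc[2]) /
      (fa[2] + fb[2] + fc[2])
    if (anyNA(c(fa, fb, fc)) || fc[2] < 2 || pool <= 0 || pool >= 1)
      return(NA_real_)
    (fc[1] - fa[1]) * (fc[1] - fb[1]) - fc[1] * (1 - fc[1]) / (fc[2] - 1)
  }, 0)
  mean(terms, na.rm = TRUE)
}

test_that("f3 agrees with a term-by-term recount and flags admixture", {
  set.seed(31)
  pan <- simulateDivergedPanels(4000, fst = 0.25, spacingBp = 5e4,
                                chrom = paste0("c", 1:8))
  adm <- simulateTractAdmixture(pan$panelP, pan$panelA, generations = 77,
                                m = 0.5, nInd = 15, pop = "Munda")
  srcP <- samplePanelGenotypes(pan$panelP, 20, "Gidra")
  srcA <- samplePanelGenotypes(pan$panelA, 40, "CHB")
  G <- GenotypeMatrix(rbind(calls(adm$genotypes), calls(srcP), calls(srcA)),
                      variants(adm$genotypes),
                      rbind(sampleInfo(adm$genotypes), sampleInfo(srcP),
                            sampleInfo(srcA)))
  r <- f3Test(G, "Munda", "CHB", "Gidra", blockBp = 5e6)
  expect_equal(r$estimate, bruteF3(G, "Munda", "CHB", "Gidra"))
  # admixed target: negative and significant at the one-tailed 1% rule
  expect_lt(r$estimate, 0)
  expect_lt(r$z, -2.33)
  expect_true(r$significant)

  # unadmixed, independently drifted target: f3 >= 0 in expectation
  tgt <- samplePanelGenotypes(pan$panelP, 15, "Target")
  G2 <- GenotypeMatrix(rbind(calls(tgt), calls(srcP), calls(srcA)),
                       variants(tgt),
                       rbind(sampleInfo(tgt), sampleInfo(srcP),
                             sampleInfo(srcA)))
  r2 <- f3Test(G2, "Target", "CHB", "Gidra")
  expect_gt(r2$z, -2.33)
  expect_false(r2$significant)

  expect_error(f3Test(G, "nope", "CHB", "Gidra"), "absent")
  expect_error(f3Test(G[, 1:30], "Munda", "CHB", "Gidra", blockBp = 5e6),
               "blocks")
})

test_that("the one-tailed significance rule keys on Z < -2.33", {
  mk <- function(z) structure(list(statistic = "f3", estimate = z * 1e-3,
                                   stdErr = 1e-3, z = z, nSnps = 10,
                                   nBlocks = 5, significant = z < -2.33,
                                   zThreshold = -2.33), class = "FStatResult")
  expect_true(mk(-3.00)$significant)
  expect_false(mk(-2.13)$significant)
})

test_that("f4 is exactly antisymmetric and matches a naive loop", {
  set.seed(32)
  G <- randomG(24, 400, rep(c("A", "B", "C", "D"), each = 6),
               missRate = 0.05, nChrom = 4)
  r <- f4Test(G, "A", "B", "C", "D", blockBp = 3e5)
  # naive loop
  pop <- sampleInfo(G)$pop
  fr <- function(p, j) {
    cc <- calls(G)[pop == p, j]
    sum(cc, na.rm = TRUE) / (2 * sum(!is.na(cc)))
  }
  terms <- vapply(seq_len(nVariants(G)), function(j)
    (fr("A", j) - fr("B", j)) * (fr("C", j) - fr("D", j)), 0)
  pool <- vapply(seq_len(nVariants(G)), function(j) {
    cc <- calls(G)[, j]
    f <- sum(cc, na.rm = TRUE) / (2 * sum(!is.na(cc)))
    f > 0 && f < 1
  }, TRUE)
  expect_equal(r$estimate, mean(terms[is.finite(terms) & pool]))
  # antisymmetry is exact
  expect_equal(f4Test(G, "B", "A", "C", "D", blockBp = 3e5)$estimate,
               -r$estimate)
  expect_equal(f4Test(G, "A", "B", "D", "C", blockBp = 3e5)$estimate,
               -r$estimate)
  # C = D (same population twice) gives exactly zero
  sI <- sampleInfo(G)
  sI$pop[sI$pop == "D"] <- "C"
  G2 <- GenotypeMatrix(calls(G), variants(G), sI)
  expect_identical(f4Test(G2, "A", "B", "C", "C", blockBp = 3e5)$estimate, 0)
})

test_that("jackknife SE scales like 1/sqrt(blocks) on iid variants", {
  set.seed(33)
  nv <- 1200
  calls <- matrix(rbinom(20 * nv, 2, rep(runif(nv, 0.2, 0.8), each = 20)),
                  20, nv)
  G <- makeG(calls, rep(c("A", "B", "C"), times = c(6, 6, 8)),
             pos = seq_len(nv) * 10000L)
  seWide <- f3Test(G, "C", "A", "B", blockBp = 3e6)    # 4 blocks
  seFine <- f3Test(G, "C", "A", "B", blockBp = 3e5)    # 40 blocks
  expect_equal(seWide$nBlocks, 4)
  expect_equal(seFine$nBlocks, 40)
  # same estimate, SE ratio within a loose band of 1
  expect_equal(seWide$estimate, seFine$estimate)
  expect_lt(seWide$stdErr / seFine$stdErr, 3)
  expect_gt(seWide$stdErr / seFine$stdErr, 1 / 3)
})

test_that("F4 ratio hits its degenerate endpoints and needs an informative denominator", {
  set.seed(34)
  pan <- simulateDivergedPanels(3000, fst = 0.3, spacingBp = 5e4,
                                chrom = paste0("c", 1:6))
  srcP <- samplePanelGenotypes(pan$panelP, 20, "Gidra")
  srcA <- samplePanelGenotypes(pan$panelA, 30, "CHB")
  tw <- samplePanelGenotypes(pan$panelA, 20, "Taiwan")
  og <- samplePanelGenotypes(
    AlleleFrequencyPanel(variants(pan$panelA),
                         runif(nVariants(pan$panelA), 0.05, 0.95),
                         panelObs(pan$panelA)), 20, "YRI")
  base <- rbind(calls(srcP), calls(srcA), calls(tw), calls(og))
  baseS <- rbind(sampleInfo(srcP), sampleInfo(srcA), sampleInfo(tw),
                 sampleInfo(og))
  # admixed identical to the papuan proxy -> alpha = 0
  cp <- calls(srcP)[1:10, , drop = FALSE]
  G0 <- GenotypeMatrix(rbind(base, cp), variants(srcP),
                       rbind(baseS, data.frame(id = paste0("m", 1:10),
                                               pop = "Munda")))
  r0 <- f4Ratio(G0, "YRI", "CHB", "Gidra", "Munda", "Taiwan", blockBp = 5e6)
  expect_lt(abs(r0$alpha), 3 * r0$stdErr + 0.02)
  # admixed identical to the asian-source proxy -> alpha = 1
  ct <- calls(tw)[1:10, , drop = FALSE]
  G1 <- GenotypeMatrix(rbind(base, ct), variants(srcP),
                       rbind(baseS, data.frame(id = paste0("m", 1:10),
                                               pop = "Munda")))
  r1 <- f4Ratio(G1, "YRI", "CHB", "Gidra", "Munda", "Taiwan", blockBp = 5e6)
  expect_lt(abs(r1$alpha - 1), 3 * r1$stdErr + 0.02)
  # uninformative denominator: the "papuan proxy" is just another fresh
  # draw from the same Asian panel, so f4(CHB, YRI; Taiwan, FakeP) ~ 0
  fakeP <- samplePanelGenotypes(pan$panelA, 20, "FakeP")
  G2 <- GenotypeMatrix(rbind(base, calls(fakeP), calls(srcP)[1:10, ]),
                       variants(srcP),
                       rbind(baseS, sampleInfo(fakeP),
                             data.frame(id = paste0("m", 1:10),
                                        pop = "Munda")))
  expect_error(
    f4Ratio(G2, "YRI", "CHB", "FakeP", "Munda", "Taiwan", blockBp = 5e6),
    "uninformative")
})
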