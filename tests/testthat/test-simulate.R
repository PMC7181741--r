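test_that("coalescent engine matches Watterson's prediction in one population", {
  # single-population reduction: n = 10, L = 1e5, Ne = 1000
  cfg <- demographyConfig(t_div = 0, t_adm = 0, m_papuan = 0,
                          window_bp = 1e5,
                          chroms = c(P = 10, M = 0, A = 0))
  set.seed(101)
  wins <- simulateWindows(cfg, 400)
  S <- vapply(wins, function(w) length(w$positions), 0L)
  expS <- 4 * 1000 * 1.2e-8 * 1e5 * sum(1 / (1:9))   # ~13.6
  expect_lt(abs(mean(S) - expS) / expS, 0.08)
  # neutral folded SFS is skewed toward rare variants
  maf <- unlist(lapply(wins, function(w)
    pmin(colMeans(w$haplotypes), 1 - colMeans(w$haplotypes))))
  h <- table(cut(maf, c(0, 0.1, 0.2, 0.3, 0.4, 0.5)))
  expect_true(h[1] > h[3] && h[3] > h[5])
})

test_that("zero mutation rate gives zero segregating sites", {
  cfg <- demographyConfig(mu = 0, window_bp = 1e5,
                          chroms = c(G = 4, M = 4, C = 4))
  set.seed(1)
  w <- simulateWindows(cfg, 1)[[1]]
  expect_identical(length(w$positions), 0L)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- demographyConfig(window_bp = 2e5, chroms = c(G = 8, M = 6, C = 8),
                          seed = 99)
  w1 <- simulateWindows(cfg, 3)
  w2 <- simulateWindows(cfg, 3)
  expect_identical(lapply(w1, `[[`, "positions"),
                   lapply(w2, `[[`, "positions"))
  expect_identical(lapply(w1, `[[`, "haplotypes"),
                   lapply(w2, `[[`, "haplotypes"))
  expect_identical(lapply(w1, `[[`, "truth"), lapply(w2, `[[`, "truth"))
})

test_that("source populations have symmetric heterozygosity", {
  cfg <- demographyConfig(window_bp = 5e5, chroms = c(G = 40, M = 0, A = 40))
  set.seed(7)
  wins <- simulateWindows(cfg, 60)
  het <- function(w, rows) {
    f <- colMeans(w$haplotypes[rows, , drop = FALSE])
    mean(2 * f * (1 - f))
  }
  h1 <- mean(vapply(wins, het, 0, rows = 1:40))
  h2 <- mean(vapply(wins, het, 0, rows = 41:80))
  expect_lt(abs(h1 - h2) / ((h1 + h2) / 2), 0.1)
})

test_that("ascertainment matches the target histogram and conserves genotypes", {
  cfg <- demographyConfig(window_bp = 5e5, chroms = c(G = 20, M = 10, C = 20))
  set.seed(11)
  wins <- simulateWindows(cfg, 120)
  before <- lapply(wins, `[[`, "haplotypes")

  # all mass in (0.45, 0.50]
  hi <- defaultMAFTargetHist()
  hi$mass <- c(rep(0, 45), rep(0.2, 5))
  wa <- suppressWarnings(ascertainVariants(wins, hi, 200))
  maf <- unlist(lapply(wa, function(w) {
    f <- colMeans(w$haplotypes)
    pmin(f, 1 - f)
  }))
  expect_true(all(maf > 0.45 & maf <= 0.5))

  # n_target = 0 retains nothing
  w0 <- ascertainVariants(wins, defaultMAFTargetHist(), 0)
  expect_identical(sum(vapply(w0, function(w) length(w$positions), 0L)), 0L)

  # default histogram: retained MAF histogram close to target in TV distance
  # (full sample design, so every 0.01 bin is populated)
  cfg2 <- demographyConfig(window_bp = 1e6)
  set.seed(12)
  wins2 <- simulateWindows(cfg2, 160)
  wt <- ascertainVariants(wins2, defaultMAFTargetHist(), 10000)
  maft <- unlist(lapply(wt, function(w) {
    f <- colMeans(w$haplotypes)
    pmin(f, 1 - f)
  }))
  binned <- tabulate(pmin(pmax(ceiling(maft * 100), 1L), 50L), 50)
  emp <- binned / sum(binned)
  tv <- sum(abs(emp - defaultMAFTargetHist()$mass)) / 2
  expect_lt(tv, 0.02)

  # conservation: retained sites carry their original genotype columns
  w1 <- wt[[1]]
  orig <- wins2[[1]]
  keep <- match(w1$positions, orig$positions)
  expect_identical(w1$haplotypes, orig$haplotypes[, keep, drop = FALSE])
})

test_that("haplotype pairing into genotypes conserves allele counts", {
  cfg <- demographyConfig(window_bp = 2e5)
  set.seed(13)
  w <- simulateWindows(cfg, 1)[[1]]
  G <- haplotypesToGenotypes(w)
  # 48 + 40 + 90 chromosomes -> 24 + 20 + 45 individuals
  expect_identical(as.integer(table(sampleInfo(G)$pop)[c("Gidra", "Munda",
                                                         "CHB")]),
                   c(24L, 20L, 45L))
  expect_identical(unname(colSums(calls(G))), unname(colSums(w$haplotypes)))
  # (0,1) haplotype pair at a site gives dosage 1
  expect_identical(calls(G)[1, ], w$haplotypes[1, ] + w$haplotypes[2, ])

  wodd <- w
  wodd$haplotypes <- w$haplotypes[-1, , drop = FALSE]
  wodd$pop <- w$pop[-1]
  expect_error(haplotypesToGenotypes(wodd), "odd haplotype count")
})

test_that("tract generator obeys its exponential tract-length law", {
  set.seed(17)
  pan <- simulateDivergedPanels(2000, fst = 0.3, spacingBp = 5e4)  # 100 cM
  # m = 1: everything Papuan
  sim1 <- simulateTractAdmixture(pan$panelP, pan$panelA, generations = 77,
                                 m = 1, nInd = 4)
  expect_true(all(sim1$trueDosage == 2L))

  sim <- simulateTractAdmixture(pan$panelP, pan$panelA, generations = 77,
                                m = 0.5137, nInd = 60)
  # genome-wide true ancestry near m (Monte-Carlo tolerance ~3 SE)
  expect_lt(abs(mean(sim$trueDosage) / 2 - 0.5137), 0.04)
  # mean Papuan tract genetic length ~ 1/(T(1-m)) Morgans = 2.67 cM,
  # excluding edge-censored tracts
  tr <- do.call(rbind, sim$tracts)
  trP <- tr[tr$ancestry == "P", ]
  maxEnd <- tapply(tr$end_bp, tr$chrom, max)
  inner <- trP$start_bp > 1 & trP$end_bp < maxEnd[trP$chrom]
  cmLen <- (trP$end_bp[inner] - trP$start_bp[inner]) / 1e6
  expEff <- 100 / (77 * (1 - 0.5137))
  expect_lt(abs(mean(cmLen) - expEff) / expEff, 0.2)
  # tracts tile each chromosome without gaps/overlap and alternate ancestry
  one <- sim$tracts[[1]]
  for (ci in unique(one$chrom)) {
    seg <- one[one$chrom == ci, ]
    expect_identical(seg$start_bp[-1], seg$end_bp[-nrow(seg)])
    expect_true(all(seg$ancestry[-1] != seg$ancestry[-nrow(seg)]))
  }
})

test_that("coalescent ancestry truth tiles windows and centres on m", {
  cfg <- demographyConfig(window_bp = 5e5)
  set.seed(19)
  wins <- simulateWindows(cfg, 40)
  doses <- lapply(wins, trueAncestryDosage)   # errors if tiling is broken
  expect_true(all(vapply(doses, function(d) all(d %in% 0:2), TRUE)))
  expect_lt(abs(mean(unlist(doses)) / 2 - 0.5137), 0.03)
})
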