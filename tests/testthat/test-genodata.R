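test_that("PED/MAP reading encodes dosages, missing calls and errors", {
  map <- data.frame(chrom = "1", id = c("v1", "v2", "v3"), cm = 0,
                    pos = c(100L, 200L, 300L))
  rows <- c("P1 s1 0 0 1 0  A A  A G  G G",
            "P1 s2 0 0 2 0  A G  0 0  G G")
  f <- writePedMap(rows, map)
  G <- readPlinkText(f["ped"], f["map"])
  # alt = minor allele: v1 alt G (0 copies in s1), v3 alt A
  expect_identical(calls(G)[1, ], c(0L, 1L, 0L))
  expect_identical(calls(G)[2, ], c(1L, NA_integer_, 0L))
  expect_identical(sampleInfo(G)$pop, c("P1", "P1"))
  # AA, AG, GG column read as dosage 0,1,2 of G at a G-minor variant
  rows2 <- c("P 1 0 0 1 0  A A  A A  A A",
             "P 2 0 0 1 0  A G  A G  A G",
             "P 3 0 0 1 0  A G  G G  G G")
  G2 <- readPlinkText(writePedMap(rows2, map)["ped"],
                      writePedMap(rows2, map)["map"])
  expect_identical(calls(G2)[, 1], c(0L, 1L, 1L))

  badRows <- c("P1 s1 0 0 1 0  A A  A G  G G  T T")   # 8 allele columns
  f3 <- writePedMap(badRows, map)
  expect_error(readPlinkText(f3["ped"], f3["map"]), "malformed")

  triRows <- c("P1 s1 0 0 1 0  A C  A G  G G",
               "P1 s2 0 0 1 0  A T  A G  G G")
  f4 <- writePedMap(triRows, map)
  expect_error(readPlinkText(f4["ped"], f4["map"]), "triallelic")
})

test_that("package TSV dialect round-trips calls, coordinates and labels", {
  set.seed(1)
  G <- randomG(6, 40, pops = rep(c("A", "B"), each = 3), nChrom = 3)
  f <- tempfile(fileext = ".tsv")
  writeGenoTSV(G, f)
  G2 <- readGenoTSV(f)
  expect_identical(calls(G2), calls(G))
  expect_identical(variants(G2), variants(G))
  expect_identical(sampleInfo(G2), sampleInfo(G))
})

test_that("call-rate filter matches a brute-force recount and is idempotent", {
  set.seed(2)
  pops <- rep(c("A", "B", "C"), times = c(5, 7, 4))
  G <- randomG(16, 120, pops, missRate = 0.25)
  Gf <- suppressWarnings(filterVariantCallRate(G, 0.8, perPopulation = TRUE))
  # brute force over the original matrix
  keep <- vapply(seq_len(nVariants(G)), function(j) {
    all(vapply(unique(pops), function(p) {
      cc <- calls(G)[pops == p, j]
      mean(!is.na(cc)) > 0.8
    }, TRUE))
  }, TRUE)
  expect_identical(variants(Gf)$id, variants(G)$id[keep])
  expect_identical(nSamples(Gf), nSamples(G))
  # idempotent
  expect_identical(calls(suppressWarnings(
    filterVariantCallRate(Gf, 0.8, perPopulation = TRUE))), calls(Gf))
  # a variant fully missing in one population is removed per-population
  cc <- calls(G)
  cc[pops == "B", 1] <- NA
  G3 <- makeG(cc, pops)
  G3f <- suppressWarnings(filterVariantCallRate(G3, 0.5, perPopulation = TRUE))
  expect_false("v1" %in% variants(G3f)$id)
  # overall mode keeps it when the pooled rate clears the bar
  G3o <- filterVariantCallRate(G3, 0.5, perPopulation = FALSE)
  expect_equal("v1" %in% variants(G3o)$id,
               mean(!is.na(cc[, 1])) > 0.5)
})

test_that("MAF filter reproduces the folded-frequency recount", {
  set.seed(3)
  G <- randomG(20, 1000, rep("X", 20), missRate = 0.15)
  Gf <- filterMAF(G, 0.1)
  maf <- vapply(seq_len(nVariants(G)), function(j) {
    cc <- calls(G)[, j]
    f <- sum(cc, na.rm = TRUE) / (2 * sum(!is.na(cc)))
    min(f, 1 - f)
  }, 0)
  expect_identical(variants(Gf)$id, variants(G)$id[!is.na(maf) & maf >= 0.1])
  # monomorphic and sub-threshold variants go
  G2 <- makeG(rbind(c(0L, 0L, 2L), c(0L, 0L, 2L), c(0L, 1L, 2L)),
              rep("X", 3))
  expect_identical(variants(filterMAF(G2, 0.01))$id, "v2")
  expect_identical(calls(filterMAF(filterMAF(G2, 0.01), 0.01)),
                   calls(filterMAF(G2, 0.01)))
})

test_that("panel frequencies equal the naive loop and pool correctly", {
  G <- makeG(rbind(c(0L, NA), c(1L, NA), c(2L, NA)), rep("P", 3))
  p <- panelFrequencies(G, "P")
  expect_equal(panelFreq(p)[1], 0.5)
  expect_identical(panelObs(p)[1], 6L)
  expect_identical(panelObs(p)[2], 0L)
  expect_true(is.na(panelFreq(p)[2]))
  expect_error(panelFrequencies(G, "nope"), "unknown population")

  set.seed(4)
  G2 <- randomG(12, 60, rep(c("A", "B"), each = 6), missRate = 0.2)
  pA <- panelFrequencies(G2, "A")
  for (j in c(1, 17, 60)) {
    cc <- calls(G2)[sampleInfo(G2)$pop == "A", j]
    expect_equal(panelFreq(pA)[j],
                 sum(cc, na.rm = TRUE) / (2 * sum(!is.na(cc))))
  }
  # pooled-count property: merged population = weighted, not averaged
  pB <- panelFrequencies(G2, "B")
  sI <- sampleInfo(G2); sI$pop <- "AB"
  pAB <- panelFrequencies(GenotypeMatrix(calls(G2), variants(G2), sI), "AB")
  pooled <- (panelFreq(pA) * panelObs(pA) + panelFreq(pB) * panelObs(pB)) /
    (panelObs(pA) + panelObs(pB))
  expect_equal(panelFreq(pAB), pooled)

  # smoothed view is strictly inside (0, 1)
  sm <- smoothedFreq(pA)
  expect_true(all(sm > 0 & sm < 1))
})

test_that("variant intersection recodes flipped alleles and drops palindromes", {
  v1 <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                   id = c("a", "b", "c"),
                   ref = c("A", "A", "C"), alt = c("G", "T", "T"))
  v2 <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                   id = c("a", "b", "c"),
                   ref = c("G", "A", "C"), alt = c("A", "T", "T"))
  G1 <- GenotypeMatrix(matrix(c(0L, 1L, 2L), 1), v1,
                       data.frame(id = "x", pop = "X"))
  G2 <- GenotypeMatrix(matrix(c(2L, 1L, 2L), 1), v2,
                       data.frame(id = "y", pop = "Y"))
  out <- intersectOnVariants(G1, G2)
  # the A/T palindrome at pos 200 is gone; C/T kept; A/G flipped 2 -> 0
  expect_identical(variants(out[[1]])$pos, c(100L, 300L))
  expect_identical(calls(out[[2]])[1, ], c(0L, 2L))
  expect_identical(variants(out[[2]])$alt, variants(out[[1]])$alt)

  # set oracle on random overlap
  set.seed(5)
  posA <- sort(sample(1:500, 120)) * 10L
  posB <- sort(sample(1:500, 140)) * 10L
  mkv <- function(pos) data.frame(chrom = "1", pos = pos,
                                  id = paste0("s", pos), ref = "A",
                                  alt = "C")
  GA <- GenotypeMatrix(matrix(0L, 2, 120), mkv(posA),
                       data.frame(id = c("a1", "a2"), pop = "A"))
  GB <- GenotypeMatrix(matrix(0L, 2, 140), mkv(posB),
                       data.frame(id = c("b1", "b2"), pop = "B"))
  out2 <- intersectOnVariants(GA, GB)
  expect_identical(variants(out2[[1]])$pos, intersect(posA, posB))
  expect_same_variants(out2[[1]], out2[[2]])

  expect_error(intersectOnVariants(G1[, 2], G2[, 3]), "no shared variants")
})

test_that("GenotypeMatrix validity rejects malformed objects", {
  expect_error(makeG(matrix(3L, 1, 1), "X"), "dosages")
  v <- data.frame(chrom = "1", pos = c(200L, 100L), id = c("a", "b"),
                  ref = "A", alt = "G")
  expect_error(GenotypeMatrix(matrix(0L, 1, 2), v,
                              data.frame(id = "s", pop = "P")),
               "strictly increasing")
})
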