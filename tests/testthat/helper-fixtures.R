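# Small fixtures built in code.

# GenotypeMatrix from a plain matrix, default one chromosome, 10 kb spacing
makeG <- function(calls, pops, chrom = NULL, pos = NULL) {
  nv <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", nv)
  if (is.null(pos)) pos <- stats::ave(seq_len(nv), chrom,
                                      FUN = function(i) seq_along(i) * 10000L)
  v <- data.frame(chrom = chrom, pos = as.integer(pos),
                  id = paste0("v", seq_len(nv)), ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  s <- data.frame(id = paste0("s", seq_along(pops)), pop = pops,
                  stringsAsFactors = FALSE)
  GenotypeMatrix(calls, v, s)
}

# write a toy PED/MAP pair, returning the two paths
writePedMap <- function(genoRows, map) {
  ped <- tempfile(fileext = ".ped")
  mapf <- tempfile(fileext = ".map")
  writeLines(genoRows, ped)
  write.table(map, mapf, quote = FALSE, row.names = FALSE, col.names = FALSE)
  c(ped = ped, map = mapf)
}

# random genotype matrix with missingness
randomG <- function(n, v, pops, missRate = 0.1, nChrom = 1) {
  calls <- matrix(sample(0:2, n * v, replace = TRUE), n, v)
  calls[runif(n * v) < missRate] <- NA
  chrom <- sort(rep_len(paste0("c", seq_len(nChrom)), v))
  makeG(calls, pops, chrom = chrom)
}

expect_same_variants <- function(a, b) {
  expect_identical(variants(a)$chrom, variants(b)$chrom)
  expect_identical(variants(a)$pos, variants(b)$pos)
}
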