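## Genotype I/O, QC filters and panel frequencies.

.orderVariants <- function(variants) {
  order(factor(variants$chrom, unique(variants$chrom)), variants$pos)
}

#' Read genotypes from PLINK text PED/MAP files
#'
#' Alleles are encoded as dosages of the alt-like allele.  When no
#' `alleleKey` is supplied the alt allele is the minor allele observed in the
#' file, ties broken lexicographically (the larger allele character wins the
#' alt slot only on an exact 50/50 tie, where the lexicographically smaller
#' allele is taken as ref).  "0 0" genotypes become NA.
#'
#' @param pedFile path to a whitespace-delimited PED file (6 metadata columns
#'   followed by two allele columns per variant)
#' @param mapFile path to the matching MAP file (chrom, id, cM, pos)
#' @param alleleKey optional data.frame with columns id, ref, alt fixing the
#'   allele orientation per variant
#' @return a [GenotypeMatrix-class]; the population label is the PED family id
#' @export
readPlinkText <- function(pedFile, mapFile, alleleKey = NULL) {
  map <- read.table(mapFile, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cm", "pos"))
  nv <- nrow(map)
  lines <- readLines(pedFile)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nc <- lengths(toks)
  bad <- which(nc != 6 + 2 * nv)
  if (length(bad))
    stop(sprintf("malformed PED: row %d has %d columns, expected %d",
                 bad[1], nc[bad[1]], 6 + 2 * nv))
  ped <- do.call(rbind, toks)
  a1 <- ped[, 6 + 2 * seq_len(nv) - 1, drop = FALSE]
  a2 <- ped[, 6 + 2 * seq_len(nv), drop = FALSE]

  ref <- alt <- character(nv)
  for (j in seq_len(nv)) {
    obs <- c(a1[, j], a2[, j])
    obs <- obs[obs != "0"]
    al <- sort(unique(obs))
    if (length(al) > 2)
      stop(sprintf("triallelic variant '%s': alleles %s", map$id[j],
                   paste(al, collapse = "/")))
    if (!is.null(alleleKey)) {
      k <- match(map$id[j], alleleKey$id)
      if (is.na(k)) stop("variant '", map$id[j], "' missing from alleleKey")
      ref[j] <- alleleKey$ref[k]; alt[j] <- alleleKey$alt[k]
      next
    }
    if (length(al) == 0) { ref[j] <- "N"; alt[j] <- "X"; next }
    if (length(al) == 1) { ref[j] <- al; alt[j] <- "X"; next }
    cnt <- c(sum(obs == al[1]), sum(obs == al[2]))
    if (cnt[1] == cnt[2]) { ref[j] <- al[1]; alt[j] <- al[2] }
    else if (cnt[1] > cnt[2]) { ref[j] <- al[1]; alt[j] <- al[2] }
    else { ref[j] <- al[2]; alt[j] <- al[1] }
  }

  n <- nrow(ped)
  gm <- matrix(NA_integer_, n, nv)
  for (j in seq_len(nv)) {
    miss <- a1[, j] == "0" | a2[, j] == "0"
    d <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
    d[miss] <- NA_integer_
    ok <- !miss & (a1[, j] %in% c(ref[j], alt[j])) &
      (a2[, j] %in% c(ref[j], alt[j]))
    d[!ok & !miss] <- NA_integer_
    gm[, j] <- d
  }
  variants <- data.frame(chrom = as.character(map$chrom), pos = map$pos,
                         id = map$id, ref = ref, alt = alt,
                         stringsAsFactors = FALSE)
  samples <- data.frame(id = ped[, 2], pop = ped[, 1],
                        stringsAsFactors = FALSE)
  o <- .orderVariants(variants)
  GenotypeMatrix(gm[, o, drop = FALSE], variants[o, ], samples)
}

#' Write a GenotypeMatrix in the package TSV dialect
#'
#' One row per sample; first two columns are `sample` and `population`,
#' followed by one column per variant named `chrom:pos:id:ref:alt` and
#' holding dosages in \{0, 1, 2, NA\}.  [readGenoTSV()] round-trips the
#' object exactly.
#'
#' @param G a [GenotypeMatrix-class]
#' @param file output path
#' @return `file`, invisibly
#' @export
writeGenoTSV <- function(G, file) {
  v <- variants(G)
  hdr <- sprintf("%s:%d:%s:%s:%s", v$chrom, v$pos, v$id, v$ref, v$alt)
  df <- data.frame(sample = sampleInfo(G)$id, population = sampleInfo(G)$pop,
                   calls(G), check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("sample", "population", hdr)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read genotypes from the package TSV dialect
#'
#' @param file path written by [writeGenoTSV()]
#' @return a [GenotypeMatrix-class]
#' @export
readGenoTSV <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  hdr <- names(df)[-(1:2)]
  parts <- strsplit(hdr, ":", fixed = TRUE)
  if (any(lengths(parts) != 5))
    stop("malformed variant header; expected chrom:pos:id:ref:alt")
  variants <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                         pos = as.integer(vapply(parts, `[`, "", 2L)),
                         id = vapply(parts, `[`, "", 3L),
                         ref = vapply(parts, `[`, "", 4L),
                         alt = vapply(parts, `[`, "", 5L),
                         stringsAsFactors = FALSE)
  gm <- as.matrix(df[, -(1:2), drop = FALSE])
  dimnames(gm) <- NULL
  GenotypeMatrix(gm, variants,
                 data.frame(id = as.character(df$sample),
                            pop = as.character(df$population),
                            stringsAsFactors = FALSE))
}

#' Filter variants on genotyping call rate
#'
#' Retains variants whose non-missing call fraction is strictly greater than
#' `minRate`, either within every population (`perPopulation = TRUE`, the
#' array-QC convention) or overall.  The sample set is unchanged and the
#' filter is idempotent.
#'
#' @param G a [GenotypeMatrix-class]
#' @param minRate minimum call-rate fraction in \[0, 1\] (default 0.95)
#' @param perPopulation apply the threshold within every population
#' @return the filtered [GenotypeMatrix-class]
#' @export
filterVariantCallRate <- function(G, minRate = 0.95, perPopulation = TRUE) {
  stopifnot(minRate >= 0, minRate <= 1)
  obs <- !is.na(calls(G))
  if (perPopulation) {
    keep <- rep(TRUE, nVariants(G))
    for (p in populations(G)) {
      rows <- sampleInfo(G)$pop == p
      keep <- keep & colMeans(obs[rows, , drop = FALSE]) > minRate
    }
  } else {
    keep <- colMeans(obs) > minRate
  }
  if (!any(keep)) warning("no variants survive the call-rate filter")
  G[, which(keep)]
}

#' Filter variants on minor allele frequency
#'
#' Retains variants whose folded (minor) allele frequency, computed over
#' non-missing calls across all samples, is at least `minMAF`.  Monomorphic
#' and fully-missing variants are removed for any `minMAF > 0`.
#'
#' @param G a [GenotypeMatrix-class]
#' @param minMAF minimum folded allele frequency in \[0, 0.5\]
#' @return the filtered [GenotypeMatrix-class]
#' @export
filterMAF <- function(G, minMAF = 0.01) {
  stopifnot(minMAF >= 0, minMAF <= 0.5)
  cc <- calls(G)
  nObs <- 2 * colSums(!is.na(cc))
  f <- colSums(cc, na.rm = TRUE) / nObs
  maf <- pmin(f, 1 - f)
  keep <- !is.na(maf) & maf >= minMAF
  G[, which(keep)]
}

#' Compute panel allele frequencies for one population
#'
#' `freq = sum(dosage) / (2 * non-missing samples)` per variant; variants
#' with no calls in the population get `nObs = 0` and `freq = NA`.
#'
#' @param G a [GenotypeMatrix-class]
#' @param population population label present in `G`
#' @return an [AlleleFrequencyPanel-class]
#' @export
panelFrequencies <- function(G, population) {
  if (!population %in% populations(G))
    stop("unknown population label: ", population)
  cc <- calls(G)[sampleInfo(G)$pop == population, , drop = FALSE]
  nObs <- 2L * colSums(!is.na(cc))
  f <- ifelse(nObs > 0, colSums(cc, na.rm = TRUE) / nObs, NA_real_)
  AlleleFrequencyPanel(variants(G), f, nObs)
}

.isPalindromic <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  toupper(alt) == unname(comp[toupper(ref)]) & toupper(ref) %in% names(comp)
}

#' Intersect two genotype matrices on shared variants
#'
#' Variants are matched on (chrom, pos) and an identical unordered allele
#' pair.  When the second matrix records the alleles in the opposite
#' orientation its dosages are recoded (d -> 2 - d) so the counted allele
#' matches the first matrix.  Strand-ambiguous (A/T, C/G) variants are
#' dropped rather than strand-guessed.
#'
#' @param G1,G2 [GenotypeMatrix-class] objects sorted by (chrom, pos)
#' @return list of the two matrices restricted to the shared variants
#' @export
intersectOnVariants <- function(G1, G2) {
  v1 <- variants(G1); v2 <- variants(G2)
  key <- function(v) {
    al <- cbind(toupper(v$ref), toupper(v$alt))
    pair <- paste(pmin(al[, 1], al[, 2]), pmax(al[, 1], al[, 2]), sep = "/")
    paste(v$chrom, v$pos, pair, sep = ":")
  }
  k1 <- key(v1); k2 <- key(v2)
  shared <- intersect(k1, k2)
  pal <- .isPalindromic(v1$ref[match(shared, k1)], v1$alt[match(shared, k1)])
  shared <- shared[!pal]
  if (!length(shared)) stop("no shared variants after allele matching")
  i1 <- match(shared, k1); i2 <- match(shared, k2)
  out1 <- G1[, i1]
  out2 <- G2[, i2]
  flip <- toupper(v2$alt[i2]) != toupper(v1$alt[i1])
  if (any(flip)) {
    cc <- calls(out2)
    cc[, flip] <- 2L - cc[, flip]
    vv <- variants(out2)
    vv$ref[flip] <- variants(out1)$ref[flip]
    vv$alt[flip] <- variants(out1)$alt[flip]
    out2 <- GenotypeMatrix(cc, vv, sampleInfo(out2))
  }
  list(out1, out2)
}
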