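## Phased-VCF input/output for the selection scan.

#' Read phased haplotypes from a VCF
#'
#' Reads biallelic SNPs with a phased GT field into a
#' [HaplotypeMatrix-class] (two haplotype rows per sample).  Ancestral
#' alleles come from the INFO `AA` tag or from a sidecar table with columns
#' chrom, pos, aa; variants without ancestral information keep NA polarity
#' and are skipped as iHS cores.
#'
#' @param file path to a VCF (plain or bgzipped)
#' @param aa optional data.frame (chrom, pos, aa) of ancestral alleles,
#'   overriding the INFO AA tag
#' @param requirePhased error on any unphased genotype (default TRUE)
#' @return a [HaplotypeMatrix-class]
#' @export
readPhasedVcf <- function(file, aa = NULL, requirePhased = TRUE) {
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE)
  if (!any(snp)) stop("no biallelic SNPs in VCF")
  gt <- vcfR::extract.gt(vcf, "GT")[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  if (requirePhased && any(grepl("/", gt, fixed = TRUE), na.rm = TRUE))
    stop("unphased genotypes present; the selection scan needs phased data")
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  toInt <- function(a) {
    x <- suppressWarnings(as.integer(a))
    x[!a %in% c("0", "1")] <- NA_integer_
    x
  }
  nV <- nrow(fix)
  nS <- ncol(gt)
  haps <- matrix(NA_integer_, 2 * nS, nV)
  haps[seq(1, 2 * nS, 2), ] <- t(matrix(toInt(a1), nV, nS))
  haps[seq(2, 2 * nS, 2), ] <- t(matrix(toInt(a2), nV, nS))
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     paste0(fix$CHROM, ":", fix$POS),
                                     fix$ID),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  anc <- rep(NA_character_, nV)
  if (!is.null(fix$INFO)) {
    m <- regmatches(fix$INFO, regexpr("AA=[ACGTacgt]", fix$INFO))
    hasAA <- grepl("AA=[ACGTacgt]", fix$INFO)
    anc[hasAA] <- toupper(sub("AA=", "", m))
  }
  if (!is.null(aa)) {
    k <- match(paste(variants$chrom, variants$pos),
               paste(aa$chrom, aa$pos))
    anc[!is.na(k)] <- toupper(aa$aa[k[!is.na(k)]])
  }
  anc[!is.na(anc) & anc != variants$ref & anc != variants$alt] <- NA
  o <- order(factor(variants$chrom, unique(variants$chrom)), variants$pos)
  dup <- duplicated(paste(variants$chrom[o], variants$pos[o]))
  o <- o[!dup]
  HaplotypeMatrix(haps[, o, drop = FALSE], variants[o, ],
                  ancestral = anc[o], gposCm = variants$pos[o] / 1e6)
}

#' Write a HaplotypeMatrix as a phased VCF
#'
#' Minimal VCFv4.2 writer with the ancestral allele in the INFO `AA` tag;
#' consecutive haplotype pairs become one diploid sample.  Round-trips
#' through [readPhasedVcf()].
#'
#' @param H a [HaplotypeMatrix-class] with an even number of haplotypes
#' @param file output path
#' @param sampleIds optional sample names (defaults to hap pair index)
#' @return `file`, invisibly
#' @export
writePhasedVcf <- function(H, file, sampleIds = NULL) {
  h <- haplotypes(H)
  if (nrow(h) %% 2 != 0) stop("odd haplotype count; cannot pair into samples")
  nS <- nrow(h) / 2
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(nS))
  v <- variants(H)
  gtc <- function(x) ifelse(is.na(x), ".", as.character(x))
  gt <- matrix("", nrow(v), nS)
  for (s in seq_len(nS))
    gt[, s] <- paste0(gtc(h[2 * s - 1, ]), "|", gtc(h[2 * s, ]))
  info <- ifelse(is.na(H@ancestral), ".", paste0("AA=", H@ancestral))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sampleIds), collapse = "\t")), con)
  body <- cbind(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", info, "GT",
                gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(file)
}
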