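## Central S4 containers.  Coordinates are 1-based inclusive throughout
## (PLINK/VCF convention); region length = end - start in bp.  MISSING
## genotypes are NA, never 0: a dosage of 0 is informative.

.checkVariants <- function(v) {
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!is.data.frame(v) || !all(need %in% names(v)))
    return("variants must be a data.frame with columns chrom, pos, id, ref, alt")
  if (nrow(v)) {
    if (any(v$pos < 1)) return("variant positions must be >= 1")
    if (any(v$ref == v$alt)) return("ref and alt alleles must differ")
    bad <- unlist(lapply(split(v$pos, factor(v$chrom, unique(v$chrom))),
                         function(p) any(diff(p) <= 0)))
    if (any(bad))
      return("positions must be strictly increasing within each chromosome")
  }
  TRUE
}

#' GenotypeMatrix: diploid genotype dosages with variant and sample metadata
#'
#' Samples-by-variants matrix of alt-allele dosages in \{0, 1, 2, NA\}.
#' `variants` holds chrom / pos (1-based bp) / id / ref / alt; `samples`
#' holds sample ids and population labels.  Variants are strictly sorted by
#' position within each chromosome.
#'
#' @slot calls integer matrix, rows = samples, columns = variants; NA = missing
#' @slot variants data.frame with columns chrom, pos, id, ref, alt
#' @slot samples data.frame with columns id, pop
#' @export
setClass("GenotypeMatrix",
         representation(calls = "matrix", variants = "data.frame",
                        samples = "data.frame"),
         validity = function(object) {
           msg <- character()
           v <- .checkVariants(object@variants)
           if (!isTRUE(v)) msg <- c(msg, v)
           s <- object@samples
           if (!all(c("id", "pop") %in% names(s)))
             msg <- c(msg, "samples must have columns id, pop")
           else if (nrow(s) && (any(is.na(s$pop)) || any(!nzchar(s$pop))))
             msg <- c(msg, "population labels must be non-empty")
           if (nrow(object@calls) != nrow(s) ||
               ncol(object@calls) != nrow(object@variants))
             msg <- c(msg, "calls dimensions must match samples x variants")
           cc <- object@calls
           if (length(cc) && !all(cc[!is.na(cc)] %in% 0:2))
             msg <- c(msg, "calls must be dosages in {0, 1, 2, NA}")
           if (length(msg)) msg else TRUE
         })

#' Construct a GenotypeMatrix
#'
#' @param calls integer matrix of dosages (samples x variants), NA = missing
#' @param variants data.frame with columns chrom, pos, id, ref, alt
#' @param samples data.frame with columns id, pop
#' @return a [GenotypeMatrix-class] object
#' @export
GenotypeMatrix <- function(calls, variants, samples) {
  storage.mode(calls) <- "integer"
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  new("GenotypeMatrix", calls = calls,
      variants = as.data.frame(variants), samples = as.data.frame(samples))
}

#' AlleleFrequencyPanel: reference-panel alt-allele frequencies
#'
#' Per-variant alt-allele frequency with the number of observed (non-missing)
#' alleles.  Variants with no observations carry `nObs = 0` and `freq = NA`.
#' [smoothedFreq()] returns a pseudocount-smoothed view strictly inside
#' (0, 1), used by HMM emissions.
#'
#' @slot variants data.frame with columns chrom, pos, id, ref, alt
#' @slot freq numeric alt-allele frequency in \[0, 1\] (NA when unobserved)
#' @slot nObs integer count of observed alleles per variant
#' @export
setClass("AlleleFrequencyPanel",
         representation(variants = "data.frame", freq = "numeric",
                        nObs = "integer"),
         validity = function(object) {
           msg <- character()
           v <- .checkVariants(object@variants)
           if (!isTRUE(v)) msg <- c(msg, v)
           if (length(object@freq) != nrow(object@variants) ||
               length(object@nObs) != nrow(object@variants))
             msg <- c(msg, "freq and nObs must match the variant count")
           f <- object@freq
           if (any(!is.na(f) & (f < 0 | f > 1)))
             msg <- c(msg, "frequencies must lie in [0, 1]")
           if (any(object@nObs < 0)) msg <- c(msg, "nObs must be >= 0")
           if (any(is.na(f) & object@nObs > 0))
             msg <- c(msg, "freq may be NA only when nObs is 0")
           if (length(msg)) msg else TRUE
         })

#' Construct an AlleleFrequencyPanel
#'
#' @param variants data.frame with columns chrom, pos, id, ref, alt
#' @param freq numeric alt-allele frequencies
#' @param nObs integer observed allele counts
#' @return an [AlleleFrequencyPanel-class] object
#' @export
AlleleFrequencyPanel <- function(variants, freq, nObs) {
  rownames(variants) <- NULL
  new("AlleleFrequencyPanel", variants = as.data.frame(variants),
      freq = as.numeric(freq), nObs = as.integer(nObs))
}

#' HaplotypeMatrix: phased binary haplotypes with ancestral-allele polarity
#'
#' Rows are haplotypes (two consecutive rows per individual when read from a
#' phased VCF), columns are variants; entries are alt-allele indicators in
#' \{0, 1, NA\}.  `ancestral` records, per variant, which allele (ref or alt)
#' is ancestral; NA means polarity unknown and the variant cannot serve as an
#' iHS core.
#'
#' @slot haps integer matrix of 0/1 alt indicators, rows = haplotypes
#' @slot variants data.frame with columns chrom, pos, id, ref, alt
#' @slot ancestral character vector of ancestral alleles (NA if unknown)
#' @slot gposCm numeric genetic positions in cM
#' @export
setClass("HaplotypeMatrix",
         representation(haps = "matrix", variants = "data.frame",
                        ancestral = "character", gposCm = "numeric"),
         validity = function(object) {
           msg <- character()
           v <- .checkVariants(object@variants)
           if (!isTRUE(v)) msg <- c(msg, v)
           nv <- nrow(object@variants)
           if (ncol(object@haps) != nv)
             msg <- c(msg, "haps columns must match the variant count")
           if (length(object@ancestral) != nv || length(object@gposCm) != nv)
             msg <- c(msg, "ancestral and gposCm must match the variant count")
           h <- object@haps
           if (length(h) && !all(h[!is.na(h)] %in% 0:1))
             msg <- c(msg, "haplotype entries must be 0/1/NA")
           known <- !is.na(object@ancestral)
           if (nv && any(known &
                         object@ancestral != object@variants$ref &
                         object@ancestral != object@variants$alt))
             msg <- c(msg, "ancestral allele must be the ref or the alt allele")
           if (length(msg)) msg else TRUE
         })

#' Construct a HaplotypeMatrix
#'
#' @param haps integer matrix of 0/1 alt-allele indicators (haplotypes x variants)
#' @param variants data.frame with columns chrom, pos, id, ref, alt
#' @param ancestral character vector of ancestral alleles; defaults to ref
#' @param gposCm genetic positions in cM; defaults to the 1 cM = 1 Mb map
#' @return a [HaplotypeMatrix-class] object
#' @export
HaplotypeMatrix <- function(haps, variants, ancestral = variants$ref,
                            gposCm = variants$pos / 1e6) {
  storage.mode(haps) <- "integer"
  rownames(variants) <- NULL
  new("HaplotypeMatrix", haps = haps, variants = as.data.frame(variants),
      ancestral = as.character(ancestral), gposCm = as.numeric(gposCm))
}

#' AncestryDosageTrack: posterior Papuan-ancestry dosages
#'
#' Per-individual, per-variant posterior Papuan dosage in \[0, 2\] from the
#' local-ancestry HMM, together with the fitted mixture proportion.
#'
#' @slot dosage numeric matrix (individuals x variants) of posterior dosages
#' @slot variants data.frame with columns chrom, pos, id, ref, alt
#' @slot samples data.frame of the individuals the track was fitted on
#' @slot m fitted Papuan mixture proportion after EM
#' @slot generations admixture generations the HMM was run at
#' @slot loglik total data log-likelihood of the final EM pass
#' @export
setClass("AncestryDosageTrack",
         representation(dosage = "matrix", variants = "data.frame",
                        samples = "data.frame", m = "numeric",
                        generations = "numeric", loglik = "numeric"),
         validity = function(object) {
           msg <- character()
           if (ncol(object@dosage) != nrow(object@variants))
             msg <- c(msg, "dosage columns must match the variant count")
           d <- object@dosage
           if (length(d) && (any(d < -1e-9) || any(d > 2 + 1e-9)))
             msg <- c(msg, "dosages must lie in [0, 2]")
           if (length(msg)) msg else TRUE
         })

## ---- generics & accessors ------------------------------------------------

#' Accessors for admixscan containers
#'
#' `variants()`, `sampleInfo()`, `calls()`, `haplotypes()`, `dosage()`,
#' `nVariants()`, `nSamples()` and `populations()` extract the corresponding
#' pieces of the S4 containers without touching slots directly.
#'
#' @param x an admixscan container
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))
#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' Pseudocount-smoothed panel frequencies
#'
#' Returns `(freq * nObs + pseudocount) / (nObs + 2 * pseudocount)`, which is
#' strictly inside (0, 1) for any finite panel, so that HMM emissions never
#' hit zero likelihood at panel-fixed sites.  Unobserved variants (nObs = 0)
#' smooth to 0.5.
#'
#' @param x an [AlleleFrequencyPanel-class]
#' @param pseudocount added to each allele count (default 0.5, Jeffreys-like)
#' @return numeric vector of smoothed frequencies
#' @export
setGeneric("smoothedFreq", function(x, pseudocount = 0.5)
  standardGeneric("smoothedFreq"))

#' @rdname accessors
setMethod("variants", "GenotypeMatrix", function(x) x@variants)
#' @rdname accessors
setMethod("variants", "AlleleFrequencyPanel", function(x) x@variants)
#' @rdname accessors
setMethod("variants", "HaplotypeMatrix", function(x) x@variants)
#' @rdname accessors
setMethod("variants", "AncestryDosageTrack", function(x) x@variants)
#' @rdname accessors
setMethod("sampleInfo", "GenotypeMatrix", function(x) x@samples)
#' @rdname accessors
setMethod("sampleInfo", "AncestryDosageTrack", function(x) x@samples)
#' @rdname accessors
setMethod("calls", "GenotypeMatrix", function(x) x@calls)
#' @rdname accessors
setMethod("haplotypes", "HaplotypeMatrix", function(x) x@haps)
#' @rdname accessors
setMethod("dosage", "AncestryDosageTrack", function(x) x@dosage)
#' @rdname accessors
setMethod("nVariants", "GenotypeMatrix", function(x) nrow(x@variants))
#' @rdname accessors
setMethod("nVariants", "AlleleFrequencyPanel", function(x) nrow(x@variants))
#' @rdname accessors
setMethod("nVariants", "HaplotypeMatrix", function(x) nrow(x@variants))
#' @rdname accessors
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@samples))
#' @rdname accessors
setMethod("populations", "GenotypeMatrix", function(x) unique(x@samples$pop))

setMethod("smoothedFreq", "AlleleFrequencyPanel", function(x, pseudocount = 0.5) {
  f <- ifelse(is.na(x@freq), 0.5 * x@nObs, x@freq * x@nObs)
  (f + pseudocount) / (x@nObs + 2 * pseudocount)
})

#' Panel allele frequency accessor
#' @param x an [AlleleFrequencyPanel-class]
#' @return numeric raw alt-allele frequencies (NA when unobserved)
#' @export
setGeneric("panelFreq", function(x) standardGeneric("panelFreq"))
#' @rdname panelFreq
setMethod("panelFreq", "AlleleFrequencyPanel", function(x) x@freq)

#' Observed allele counts of a panel
#' @param x an [AlleleFrequencyPanel-class]
#' @return integer non-missing allele counts
#' @export
setGeneric("panelObs", function(x) standardGeneric("panelObs"))
#' @rdname panelObs
setMethod("panelObs", "AlleleFrequencyPanel", function(x) x@nObs)

## ---- subsetting ----------------------------------------------------------

#' Subset a GenotypeMatrix by samples (i) and/or variants (j)
#' @param x a [GenotypeMatrix-class]
#' @param i sample index
#' @param j variant index
#' @param ... ignored
#' @param drop ignored (never drops)
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@calls))
  if (missing(j)) j <- seq_len(ncol(x@calls))
  GenotypeMatrix(x@calls[i, j, drop = FALSE], x@variants[j, , drop = FALSE],
                 x@samples[i, , drop = FALSE])
})

#' Subset samples of a GenotypeMatrix by id or population label
#'
#' @param G a [GenotypeMatrix-class]
#' @param samples character sample ids to keep (optional)
#' @param population character population labels to keep (optional)
#' @return the subsetted [GenotypeMatrix-class]
#' @export
subsetSamples <- function(G, samples = NULL, population = NULL) {
  keep <- rep(TRUE, nSamples(G))
  if (!is.null(samples)) keep <- keep & G@samples$id %in% samples
  if (!is.null(population)) {
    if (!all(population %in% G@samples$pop))
      stop("unknown population label(s): ",
           paste(setdiff(population, G@samples$pop), collapse = ", "))
    keep <- keep & G@samples$pop %in% population
  }
  G[which(keep), ]
}

## ---- show methods --------------------------------------------------------

setMethod("show", "GenotypeMatrix", function(object) {
  v <- object@variants
  cat("GenotypeMatrix:", nrow(object@samples), "samples x", nrow(v),
      "variants\n")
  cat("  populations:",
      paste(sprintf("%s(%d)", names(table(object@samples$pop)),
                    table(object@samples$pop)), collapse = " "), "\n")
  if (nrow(v))
    cat("  chromosomes:", length(unique(v$chrom)),
        sprintf(" missing rate: %.3f", mean(is.na(object@calls))), "\n")
})

setMethod("show", "AlleleFrequencyPanel", function(object) {
  cat("AlleleFrequencyPanel:", nrow(object@variants), "variants,",
      "median alleles observed:", stats::median(object@nObs), "\n")
})

setMethod("show", "HaplotypeMatrix", function(object) {
  cat("HaplotypeMatrix:", nrow(object@haps), "haplotypes x",
      nrow(object@variants), "variants;",
      sum(!is.na(object@ancestral)), "with known ancestral allele\n")
})

setMethod("show", "AncestryDosageTrack", function(object) {
  cat("AncestryDosageTrack:", nrow(object@dosage), "individuals x",
      ncol(object@dosage), "variants\n")
  cat(sprintf("  fitted m (Papuan fraction): %.4f at T = %g generations\n",
              object@m, object@generations))
})
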