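#' @import methods
#' @importFrom stats rnorm runif rchisq rpois rbinom cor sd var qnorm
#' @importFrom utils head write.table read.table
NULL

#' Genotype matrix with marker map
#'
#' Container for biallelic SNP genotypes coded as the count of allele A
#' (0 = BB, 1 = AB, 2 = AA, `NA` = missing) together with the marker map.
#' Rows are animals, columns are markers.
#'
#' @slot codes integer matrix, animals x SNPs, values in \{0, 1, 2, NA\};
#'   rownames are animal ids, colnames are marker ids.
#' @slot markers data.frame with one row per marker: `snp` (id), `chrom`
#'   (character label), `bp` (1-based position, strictly increasing within
#'   a chromosome), `alleleA`, `alleleB`.
#'
#' @export
setClass("GenotypeData",
  representation(codes = "matrix", markers = "data.frame"))

setValidity("GenotypeData", function(object) {
  msg <- character()
  cd <- object@codes
  mk <- object@markers
  if (ncol(cd) != nrow(mk))
    msg <- c(msg, "number of code columns must equal number of marker rows")
  need <- c("snp", "chrom", "bp", "alleleA", "alleleB")
  if (!all(need %in% names(mk)))
    msg <- c(msg, paste("markers must have columns:", paste(need, collapse = ", ")))
  if (nrow(cd) > 0 && is.null(rownames(cd)))
    msg <- c(msg, "codes must have animal ids as rownames")
  vals <- cd[!is.na(cd)]
  if (length(vals) && !all(vals %in% 0:2))
    msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  if (all(need %in% names(mk)) && nrow(mk) > 1) {
    bad <- vapply(split(mk$bp, mk$chrom),
                  function(p) any(diff(p) <= 0), logical(1))
    if (any(bad))
      msg <- c(msg, "bp positions must be strictly increasing within a chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param codes animals x SNPs matrix of codes 0/1/2/NA (count of allele A),
#'   with animal ids as rownames.
#' @param markers data.frame with columns `snp`, `chrom`, `bp`, `alleleA`,
#'   `alleleB`; `chrom` is coerced to character.
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(codes, markers) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  markers$chrom <- as.character(markers$chrom)
  markers$snp <- as.character(markers$snp)
  markers$bp <- as.numeric(markers$bp)
  if (is.null(colnames(codes))) colnames(codes) <- markers$snp
  rownames(markers) <- NULL
  new("GenotypeData", codes = codes, markers = markers)
}

#' Pseudo-SNP (haplotype allele) copy-count matrix
#'
#' One column per haplotype allele of an LD block; cells count the copies
#' (0/1/2) carried by each animal's most probable diplotype, `NA` where the
#' diplotype could not be called.
#'
#' @slot codes animals x haplotype-allele matrix with values \{0, 1, 2, NA\}.
#' @slot columns data.frame per column: `block` (block id), `chrom`,
#'   `startBp`, `endBp`, `haplotype` (string over A/B), `freq` (population
#'   frequency from the EM fit).
#' @export
setClass("PseudoSNPData",
  representation(codes = "matrix", columns = "data.frame"))

setValidity("PseudoSNPData", function(object) {
  msg <- character()
  if (ncol(object@codes) != nrow(object@columns))
    msg <- c(msg, "column metadata must match code columns")
  vals <- object@codes[!is.na(object@codes)]
  if (length(vals) && !all(vals %in% 0:2))
    msg <- c(msg, "pseudo-SNP codes must be 0, 1, 2 or NA")
  if (nrow(object@columns) && any(object@columns$freq < 0))
    msg <- c(msg, "haplotype frequencies must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Runs-of-homozygosity incidence matrix
#'
#' Binary animals x pooled-locus matrix: 1 where the animal contributed a
#' ROH segment to the pooled locus. Animals without any segment are absent.
#'
#' @slot incidence 0/1 matrix, animals x loci.
#' @slot loci data.frame per locus: `chrom`, `start`, `end` (consensus
#'   region, 1-based inclusive; start > end flags an empty intersection of
#'   a chained cluster), `nCarriers`.
#' @export
setClass("ROHIncidence",
  representation(incidence = "matrix", loci = "data.frame"))

setValidity("ROHIncidence", function(object) {
  msg <- character()
  if (ncol(object@incidence) != nrow(object@loci))
    msg <- c(msg, "locus metadata must match incidence columns")
  if (length(object@incidence) && !all(object@incidence %in% 0:1))
    msg <- c(msg, "incidence must be 0/1")
  if (ncol(object@incidence) && any(colSums(object@incidence) < 1))
    msg <- c(msg, "every pooled locus must have at least one carrier")
  if (nrow(object@incidence) && ncol(object@incidence) &&
      any(rowSums(object@incidence) < 1))
    msg <- c(msg, "every retained animal must carry at least one ROH")
  if (length(msg)) msg else TRUE
})

#' Genomic relationship kernel
#'
#' An n x n symmetric positive semidefinite similarity matrix among
#' animals, used as the covariance structure of a random genetic effect.
#'
#' @slot matrix n x n numeric symmetric matrix, animal ids as dimnames.
#' @slot kind `"linear"` or `"gaussian"`.
#' @slot source feature set the kernel was built from (`"SNP"`, `"HAP"`,
#'   `"ROH"`, or free text).
#' @slot param named list: `k` (feature-count divisor, linear kernels) or
#'   `h` (bandwidth, Gaussian kernels); may record dropped column counts.
#' @export
setClass("GenomicKernel",
  representation(matrix = "matrix", kind = "character",
                 source = "character", param = "list"))

setValidity("GenomicKernel", function(object) {
  msg <- character()
  K <- object@matrix
  if (nrow(K) != ncol(K)) msg <- c(msg, "kernel must be square")
  if (nrow(K) && max(abs(K - t(K))) > 1e-10)
    msg <- c(msg, "kernel must be symmetric within 1e-10")
  if (!object@kind %in% c("linear", "gaussian"))
    msg <- c(msg, "kind must be 'linear' or 'gaussian'")
  if (is.null(rownames(K)))
    msg <- c(msg, "kernel must carry animal ids as dimnames")
  if (length(msg)) msg else TRUE
})

#' Posterior summary of a (multi-)kernel Bayesian mixed model
#'
#' @slot varComponents data.frame, one row per kernel: `source`, posterior
#'   `mean` and `sd` of the genetic variance, `pctMean` and `pctSd`
#'   (percentage of the total genetic variance, computed per draw).
#' @slot residual named numeric: posterior mean and sd of the residual
#'   variance.
#' @slot totalGenetic named numeric: posterior mean and sd of the summed
#'   genetic variance (zero-length model: both 0).
#' @slot heritability named numeric: posterior mean and sd of
#'   h2 = sum(sigma2_j) / (sum(sigma2_j) + sigma2_e), computed per draw.
#' @slot fixedEffects named numeric vector of posterior means.
#' @slot nRetained number of retained (post burn-in, thinned) draws.
#' @export
setClass("PosteriorSummary",
  representation(varComponents = "data.frame", residual = "numeric",
                 totalGenetic = "numeric", heritability = "numeric",
                 fixedEffects = "numeric", nRetained = "integer"))

setValidity("PosteriorSummary", function(object) {
  msg <- character()
  vc <- object@varComponents
  if (nrow(vc)) {
    if (abs(sum(vc$pctMean) - 100) > 1e-6)
      msg <- c(msg, "kernel percentages must sum to 100")
  }
  h2 <- object@heritability[["mean"]]
  if (h2 < 0 || h2 > 1) msg <- c(msg, "heritability must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---- accessors ------------------------------------------------------------

#' @describeIn GenotypeData-class number of animals
#' @param object,x a KernelPred object
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))

#' @export
setGeneric("kernelKind", function(x) standardGeneric("kernelKind"))

#' @export
setGeneric("kernelSource", function(x) standardGeneric("kernelSource"))

#' @export
setGeneric("rohLoci", function(x) standardGeneric("rohLoci"))

#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))

#' Animal identifiers
#' @param x object
#' @rdname animalIds
#' @export
setMethod("animalIds", "GenotypeData", function(x) rownames(x@codes))
#' @rdname animalIds
#' @export
setMethod("animalIds", "PseudoSNPData", function(x) rownames(x@codes))
#' @rdname animalIds
#' @export
setMethod("animalIds", "ROHIncidence", function(x) rownames(x@incidence))
#' @rdname animalIds
#' @export
setMethod("animalIds", "GenomicKernel", function(x) rownames(x@matrix))

#' Genotype / pseudo-SNP / incidence codes
#' @param x object
#' @rdname genotypes
#' @export
setMethod("genotypes", "GenotypeData", function(x) x@codes)
#' @rdname genotypes
#' @export
setMethod("genotypes", "PseudoSNPData", function(x) x@codes)
#' @rdname genotypes
#' @export
setMethod("genotypes", "ROHIncidence", function(x) x@incidence)

#' Marker / column metadata
#' @param x object
#' @rdname markers
#' @export
setMethod("markers", "GenotypeData", function(x) x@markers)
#' @rdname markers
#' @export
setMethod("markers", "PseudoSNPData", function(x) x@columns)

#' @rdname kernelMatrix
#' @param x a GenomicKernel
#' @export
setMethod("kernelMatrix", "GenomicKernel", function(x) x@matrix)
#' @rdname kernelMatrix
#' @export
setMethod("kernelKind", "GenomicKernel", function(x) x@kind)
#' @rdname kernelMatrix
#' @export
setMethod("kernelSource", "GenomicKernel", function(x) x@source)

#' @rdname rohLoci
#' @param x a ROHIncidence
#' @export
setMethod("rohLoci", "ROHIncidence", function(x) x@loci)

#' @rdname varComponents
#' @param x a PosteriorSummary
#' @export
setMethod("varComponents", "PosteriorSummary", function(x) x@varComponents)

#' Heritability summary of a fitted model
#' @param x a PosteriorSummary
#' @return named numeric with posterior `mean` and `sd` of h2.
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

#' @rdname heritability
#' @export
setMethod("heritability", "PosteriorSummary", function(x) x@heritability)

## ---- show -----------------------------------------------------------------

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@codes), "animals x",
      ncol(object@codes), "SNPs on",
      length(unique(object@markers$chrom)), "chromosome(s)\n")
  nm <- sum(is.na(object@codes))
  if (nm) cat("  missing calls:", nm, "\n")
})

setMethod("show", "PseudoSNPData", function(object) {
  cat("PseudoSNPData:", nrow(object@codes), "animals x",
      ncol(object@codes), "haplotype alleles in",
      length(unique(object@columns$block)), "block(s)\n")
})

setMethod("show", "ROHIncidence", function(object) {
  cat("ROHIncidence:", nrow(object@incidence), "animals x",
      ncol(object@incidence), "pooled ROH loci\n")
})

setMethod("show", "GenomicKernel", function(object) {
  p <- object@param
  extra <- if (object@kind == "linear") paste0("k = ", p$k)
           else paste0("h = ", p$h)
  cat(sprintf("GenomicKernel (%s, source %s, n = %d, %s)\n",
              object@kind, object@source, nrow(object@matrix), extra))
})

setMethod("show", "PosteriorSummary", function(object) {
  cat("PosteriorSummary (", object@nRetained, "retained draws )\n")
  if (nrow(object@varComponents)) {
    vc <- object@varComponents
    for (i in seq_len(nrow(vc)))
      cat(sprintf("  %-4s var %.4g +- %.3g  (%.1f%% of genetic)\n",
                  vc$source[i], vc$mean[i], vc$sd[i], vc$pctMean[i]))
  }
  cat(sprintf("  residual var %.4g +- %.3g\n",
              object@residual[["mean"]], object@residual[["sd"]]))
  cat(sprintf("  h2 = %.3f +- %.3f\n",
              object@heritability[["mean"]], object@heritability[["sd"]]))
})
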