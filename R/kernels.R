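## Genomic relationship kernels: linear (VanRaden-style ZZ'/k on centered,
## standardized features) and Gaussian on ROH incidence, plus alignment of
## kernels and phenotypes to a common animal index.

## mean-impute missing cells per column
.meanImpute <- function(x) {
  if (!anyNA(x)) return(x)
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- mu[idx[, 2]]
  x
}

#' Linear genomic kernel K = Z Z' / k
#'
#' Columns are mean-imputed, centered to mean zero and scaled to unit
#' population standard deviation (divide-by-n convention, so a single
#' standardized column gives diagonal mean 1); zero-variance columns are
#' dropped and `k` adjusted accordingly.
#'
#' @param features animals x features numeric matrix (e.g. SNP codes or
#'   pseudo-SNP copy counts), animal ids as rownames; or a
#'   [GenotypeData-class]/[PseudoSNPData-class].
#' @param source label recorded in the kernel (`"SNP"`, `"HAP"`, ...).
#' @param center_standardize set `FALSE` to use the features as given.
#' @return A [GenomicKernel-class] of kind `"linear"` with `param$k` the
#'   number of columns used and `param$dropped` the zero-variance count.
#' @export
linearKernel <- function(features, source = "SNP", center_standardize = TRUE) {
  if (is(features, "GenotypeData") || is(features, "PseudoSNPData"))
    features <- genotypes(features)
  Z <- .meanImpute(apply(features, 2, as.numeric))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = nrow(features))
  rownames(Z) <- rownames(features)
  n <- nrow(Z)
  if (n < 2) stop("a kernel needs at least 2 animals")
  dropped <- 0L
  if (center_standardize) {
    mu <- colMeans(Z)
    Z <- sweep(Z, 2, mu)
    s <- sqrt(colMeans(Z^2))              # population SD
    keep <- s > 1e-12
    dropped <- sum(!keep)
    Z <- sweep(Z[, keep, drop = FALSE], 2, s[keep], "/")
  }
  k <- ncol(Z)
  if (k == 0) stop("no polymorphic feature columns left for the kernel")
  K <- tcrossprod(Z) / k
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(features), rownames(features))
  new("GenomicKernel", matrix = K, kind = "linear", source = source,
      param = list(k = k, dropped = dropped))
}

#' Gaussian ROH kernel
#'
#' K_ij = exp(-h d2_ij / mean(d2)) where d2 is the squared Euclidean
#' distance between the animals' ROH incidence rows and the normalizer is
#' the mean of d2 over all unordered distinct pairs, so the overall
#' distance scale is adjusted.  The diagonal is exactly 1.
#'
#' @param incidence a [ROHIncidence-class] or a 0/1 animals x loci matrix.
#' @param h bandwidth (default 1.5).
#' @param source label recorded in the kernel.
#' @return A [GenomicKernel-class] of kind `"gaussian"`.
#' @export
gaussianRohKernel <- function(incidence, h = 1.5, source = "ROH") {
  R <- if (is(incidence, "ROHIncidence")) genotypes(incidence) else
    as.matrix(incidence)
  n <- nrow(R)
  if (n < 2) stop("a kernel needs at least 2 animals")
  storage.mode(R) <- "double"
  sq <- rowSums(R^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(R)
  D2[D2 < 0] <- 0
  meanD2 <- mean(D2[upper.tri(D2)])
  if (!is.finite(meanD2) || meanD2 <= 0)
    stop("all animals have identical ROH profiles: the distance ",
         "normalizer is degenerate; check pooling or drop the ROH kernel")
  K <- exp(-h * D2 / meanD2)
  diag(K) <- 1
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(R), rownames(R))
  new("GenomicKernel", matrix = K, kind = "gaussian", source = source,
      param = list(h = h))
}

#' Align kernels and phenotypes to a common animal index
#'
#' Intersects the animal sets of all kernels and the phenotype table and
#' reorders everything to the (phenotype-ordered) common index; only
#' animals with all genomic and phenotypic information remain.
#'
#' @param kernels list of [GenomicKernel-class] objects.
#' @param pheno data.frame with an `animal_id` column.
#' @param min_common error when fewer than this many animals are shared.
#' @return list with `kernels` (reordered principal submatrices) and
#'   `pheno` (filtered, same order).
#' @export
kernelAlign <- function(kernels, pheno, min_common = 10) {
  ids <- pheno$animal_id
  for (K in kernels) ids <- intersect(ids, animalIds(K))
  if (length(ids) < min_common)
    stop("only ", length(ids), " animals shared by all kernels and the ",
         "phenotypes (need at least ", min_common, ")")
  ph <- pheno[match(ids, pheno$animal_id), , drop = FALSE]
  rownames(ph) <- NULL
  ks <- lapply(kernels, function(K) {
    M <- kernelMatrix(K)[ids, ids]
    new("GenomicKernel", matrix = M, kind = kernelKind(K),
        source = kernelSource(K), param = K@param)
  })
  list(kernels = ks, pheno = ph)
}

#' Check a kernel for positive semidefiniteness
#'
#' @param kernel a [GenomicKernel-class].
#' @param tol eigenvalues above `-tol` count as non-negative.
#' @return TRUE/FALSE.
#' @export
isPSD <- function(kernel, tol = 1e-8) {
  ev <- eigen(kernelMatrix(kernel), symmetric = TRUE, only.values = TRUE)
  min(ev$values) >= -tol * max(1, abs(max(ev$values)))
}

#' Bandwidth grid search for the Gaussian ROH kernel
#'
#' Scores each candidate bandwidth by the mean cross-validated prediction
#' correlation of a single-kernel model and returns the grid with scores.
#'
#' @param incidence a [ROHIncidence-class].
#' @param pheno phenotype data.frame (see [fitMKModel()]).
#' @param grid candidate bandwidths.
#' @param mcmc MCMC settings passed to [modelSpec()].
#' @param k_folds folds for the internal CV.
#' @param seed RNG seed for folds and chains.
#' @return data.frame of `h` and mean CV correlation, plus the best `h` as
#'   attribute `"best"`.
#' @export
bandwidthGrid <- function(incidence, pheno, grid = c(0.5, 1, 1.5, 2, 3),
                          mcmc = list(n_iter = 2000, burn_in = 500,
                                      thin = 5, seed = 1),
                          k_folds = 5, seed = 1) {
  scores <- vapply(grid, function(h) {
    K <- gaussianRohKernel(incidence, h = h)
    al <- kernelAlign(list(K), pheno)
    spec <- modelSpec(al$pheno, kernels = al$kernels, mcmc = mcmc)
    folds <- makeFolds(nrow(al$pheno), k = k_folds, seed = seed)
    cv <- crossValidate(al$pheno$value, spec, folds)
    cv$meanCor
  }, numeric(1))
  out <- data.frame(h = grid, cv_correlation = scores)
  attr(out, "best") <- grid[which.max(scores)]
  out
}
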