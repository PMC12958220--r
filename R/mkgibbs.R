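## Single- and multi-kernel Bayesian mixed models fitted by Gibbs sampling.
##
## Model: y = X beta + sum_j g_j + e, with g_j ~ N(0, K_j sigma2_j) and
## e ~ N(0, I sigma2_e).  Each g_j is parameterised in the eigenbasis of
## its kernel, g_j = V_j alpha_j with alpha_j ~ N(0, diag(lambda_j)
## sigma2_j); the decomposition is computed once per kernel.  beta has a
## flat prior; variances have scaled-inverse-chi-square priors.

#' Build the fixed-effect design matrix
#'
#' Intercept, herd-year-season (HYS) one-hot columns with the first sorted
#' level as reference, age in months and its square (age centered at
#' `age_center` for conditioning).
#'
#' @param pheno data.frame with columns `hys` and `age_months`.
#' @param hys_levels level set to code against (defaults to the levels in
#'   `pheno`); records with a level outside this set are flagged.
#' @param age_center centering constant (defaults to the mean age).
#' @return list with `X`, `hys_levels`, `age_center`, and `unseen`
#'   (logical; rows whose HYS level is not in `hys_levels`).
#' @export
fixedDesign <- function(pheno, hys_levels = NULL, age_center = NULL) {
  hys <- as.character(pheno$hys)
  if (is.null(hys_levels)) hys_levels <- sort(unique(hys))
  if (is.null(age_center)) age_center <- mean(pheno$age_months)
  unseen <- !(hys %in% hys_levels)
  n <- nrow(pheno)
  agec <- pheno$age_months - age_center
  X <- cbind(intercept = rep(1, n), age = agec, age2 = agec^2)
  if (length(hys_levels) > 1) {
    H <- matrix(0, n, length(hys_levels) - 1,
                dimnames = list(NULL, paste0("hys", hys_levels[-1])))
    for (l in seq_along(hys_levels[-1]))
      H[hys == hys_levels[-1][l], l] <- 1
    X <- cbind(X, H)
  }
  list(X = X, hys_levels = hys_levels, age_center = age_center,
       unseen = unseen)
}

#' Specify a (multi-)kernel model
#'
#' @param pheno phenotype data.frame (`value`, `hys`, `age_months`,
#'   `animal_id`), already aligned to the kernels (see [kernelAlign()]).
#' @param kernels list of 0 to 3+ [GenomicKernel-class] objects; an empty
#'   list gives the fixed-effects-only model.
#' @param mcmc list: `n_iter` (default 100000), `burn_in` (30000), `thin`
#'   (5), `seed`.
#' @param priors optional list with `df` (default 5) and `scale` per
#'   variance; by default scales are set so each prior mode corresponds to
#'   an equal split of half the phenotypic variance across the kernels
#'   (and half to the residual).
#' @param fix_variances optional numeric vector `c(varG..., varE)` to hold
#'   all variances fixed (degenerate priors), used for closed-form checks.
#' @return list of class `model_spec`.
#' @export
modelSpec <- function(pheno, kernels = list(),
                      mcmc = list(), priors = NULL, fix_variances = NULL) {
  mc <- utils::modifyList(list(n_iter = 100000, burn_in = 30000, thin = 5,
                               seed = 1), mcmc)
  stopifnot(mc$n_iter > mc$burn_in, mc$thin >= 1)
  fd <- fixedDesign(pheno)
  for (K in kernels)
    if (!identical(animalIds(K), pheno$animal_id))
      stop("kernel animal ids are not aligned to the phenotype table; ",
           "run kernelAlign() first")
  structure(list(pheno = pheno, X = fd$X, design = fd, kernels = kernels,
                 mcmc = mc, priors = priors,
                 fix_variances = fix_variances),
            class = "model_spec")
}

#' Number of retained MCMC draws
#'
#' @param n_iter,burn_in,thin chain settings.
#' @return `floor((n_iter - burn_in) / thin)`.
#' @export
retainedDraws <- function(n_iter, burn_in, thin) {
  as.integer(floor((n_iter - burn_in) / thin))
}

## eigendecomposition of a kernel, truncated below tol * max eigenvalue
.kernelEigen <- function(K, tol = 1e-10) {
  e <- eigen(K, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 1)
  list(V = e$vectors[, keep, drop = FALSE], lambda = e$values[keep])
}

#' Fit a (multi-)kernel Bayesian mixed model by Gibbs sampling
#'
#' @param y numeric response vector aligned to `spec$pheno`.
#' @param spec a [modelSpec()] object.
#' @param keep_g also store the retained draws of each kernel's genetic
#'   values (`chains$g`, one draws x n matrix per kernel); off by default
#'   to save memory.
#' @return list with:
#'   \describe{
#'     \item{summary}{a [PosteriorSummary-class].}
#'     \item{chains}{list of retained draws: `var` (columns: one per
#'       kernel, `varE`, `h2`) and `beta`.}
#'     \item{postMean}{posterior means: `beta`, `g` (per-kernel genetic
#'       values), `w` (per-kernel weights `K^-1 g` for out-of-sample
#'       projection), `fitted` (X beta + sum g).}
#'     \item{eigen}{the cached kernel eigendecompositions.}
#'   }
#' @export
fitMKModel <- function(y, spec, keep_g = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  X <- spec$X
  n <- length(y)
  stopifnot(nrow(X) == n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("fixed-effect design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  mc <- spec$mcmc
  set.seed(mc$seed)
  nk <- length(spec$kernels)
  eig <- lapply(spec$kernels, function(K) {
    M <- kernelMatrix(K)
    e <- tryCatch(.kernelEigen(M), error = function(err) NULL)
    if (is.null(e)) e <- .kernelEigen(M + diag(1e-8, nrow(M)))
    if (min(e$lambda) <= 0)
      stop("kernel '", kernelSource(K), "' is not positive semidefinite")
    e
  })
  srcs <- make.unique(vapply(spec$kernels, kernelSource, character(1)))
  p <- ncol(X)
  XtXi <- chol2inv(chol(crossprod(X)))
  U <- chol(XtXi)                       # XtXi = t(U) %*% U
  vy <- var(y)
  df0 <- if (!is.null(spec$priors$df)) spec$priors$df else 5
  Sg <- if (!is.null(spec$priors$scale)) rep_len(spec$priors$scale, max(nk, 1))
        else rep(0.5 * vy / max(nk, 1) * (df0 + 2) / df0, max(nk, 1))
  Se <- if (!is.null(spec$priors$scale_e)) spec$priors$scale_e
        else 0.5 * vy * (df0 + 2) / df0
  fixed <- spec$fix_variances
  varG <- if (!is.null(fixed) && nk) fixed[seq_len(nk)] else rep(vy / 2 / max(nk, 1), nk)
  varE <- if (!is.null(fixed)) fixed[length(fixed)] else vy / 2
  alpha <- lapply(eig, function(e) numeric(length(e$lambda)))
  g <- lapply(eig, function(e) numeric(n))
  gtot <- numeric(n)
  beta <- numeric(p)
  nret <- retainedDraws(mc$n_iter, mc$burn_in, mc$thin)
  varChain <- matrix(NA_real_, nret, nk + 2,
                     dimnames = list(NULL, c(srcs, "varE", "h2")))
  betaChain <- matrix(NA_real_, nret, p, dimnames = list(NULL, colnames(X)))
  betaSum <- numeric(p); gSum <- lapply(seq_len(nk), function(j) numeric(n))
  wSum <- lapply(eig, function(e) numeric(n))
  gChain <- if (keep_g) lapply(seq_len(nk), function(j)
    matrix(NA_real_, nret, n)) else NULL
  r <- 0L
  for (it in seq_len(mc$n_iter)) {
    ## beta | rest
    bhat <- XtXi %*% crossprod(X, y - gtot)
    beta <- drop(bhat + sqrt(varE) * crossprod(U, rnorm(p)))
    xb <- drop(X %*% beta)
    ## alpha_j | rest, in the kernel eigenbasis
    for (j in seq_len(nk)) {
      rj <- y - xb - gtot + g[[j]]
      s <- crossprod(eig[[j]]$V, rj)
      cvar <- 1 / (1 / varE + 1 / (eig[[j]]$lambda * varG[j]))
      alpha[[j]] <- drop(cvar * s / varE) +
        sqrt(cvar) * rnorm(length(cvar))
      gnew <- drop(eig[[j]]$V %*% alpha[[j]])
      gtot <- gtot - g[[j]] + gnew
      g[[j]] <- gnew
      if (is.null(fixed)) {
        ss <- sum(alpha[[j]]^2 / eig[[j]]$lambda)
        m <- length(alpha[[j]])
        varG[j] <- (ss + df0 * Sg[j]) / rchisq(1, df0 + m)
      }
    }
    ## residual variance
    if (is.null(fixed)) {
      res <- y - xb - gtot
      varE <- (sum(res^2) + df0 * Se) / rchisq(1, df0 + n)
    }
    if (it > mc$burn_in && (it - mc$burn_in) %% mc$thin == 0) {
      r <- r + 1L
      tg <- if (nk) sum(varG) else 0
      varChain[r, ] <- c(varG, varE, tg / (tg + varE))
      betaChain[r, ] <- beta
      betaSum <- betaSum + beta
      for (j in seq_len(nk)) {
        gSum[[j]] <- gSum[[j]] + g[[j]]
        wSum[[j]] <- wSum[[j]] +
          drop(eig[[j]]$V %*% (alpha[[j]] / eig[[j]]$lambda))
        if (keep_g) gChain[[j]][r, ] <- g[[j]]
      }
    }
  }
  stopifnot(r == nret)
  postBeta <- betaSum / nret
  postG <- lapply(gSum, function(x) x / nret)
  postW <- lapply(wSum, function(x) x / nret)
  fitted <- drop(X %*% postBeta) + if (nk) Reduce(`+`, postG) else 0
  summary <- .posteriorSummary(varChain, postBeta, srcs, nret, nk)
  list(summary = summary,
       chains = list(var = varChain, beta = betaChain, g = gChain),
       postMean = list(beta = postBeta, g = postG, w = postW,
                       fitted = fitted),
       eigen = eig, spec = spec)
}

.posteriorSummary <- function(varChain, postBeta, srcs, nret, nk) {
  varE <- varChain[, "varE"]
  h2 <- varChain[, "h2"]
  if (nk) {
    G <- varChain[, seq_len(nk), drop = FALSE]
    tot <- rowSums(G)
    pct <- 100 * G / tot
    vc <- data.frame(source = srcs,
                     mean = colMeans(G),
                     sd = apply(G, 2, sd),
                     pctMean = colMeans(pct),
                     pctSd = apply(pct, 2, sd),
                     stringsAsFactors = FALSE)
    totg <- c(mean = mean(tot), sd = sd(tot))
  } else {
    vc <- data.frame(source = character(0), mean = numeric(0),
                     sd = numeric(0), pctMean = numeric(0),
                     pctSd = numeric(0))
    totg <- c(mean = 0, sd = 0)
  }
  new("PosteriorSummary", varComponents = vc,
      residual = c(mean = mean(varE), sd = sd(varE)),
      totalGenetic = totg,
      heritability = c(mean = mean(h2), sd = sd(h2)),
      fixedEffects = postBeta, nRetained = as.integer(nret))
}

#' Heritability per draw
#'
#' h2 = sum of genetic variances / (that sum + residual variance),
#' computed draw-wise, never from plugged-in posterior means.
#'
#' @param varG matrix (draws x kernels) or vector of genetic-variance
#'   draws.
#' @param varE vector of residual-variance draws.
#' @return list with `draws` and summary `mean`, `sd`.
#' @export
heritabilityDraws <- function(varG, varE) {
  varG <- as.matrix(varG)
  tot <- rowSums(varG)
  h2 <- tot / (tot + varE)
  list(draws = h2, mean = mean(h2), sd = sd(h2))
}

#' Variance partition across kernels
#'
#' Percentage of the total genetic variance attributed to each kernel,
#' computed per retained draw and then summarized.
#'
#' @param x a [PosteriorSummary-class], a fit from [fitMKModel()], or a
#'   draws x kernels matrix of genetic-variance draws.
#' @return data.frame with `source`, `pctMean`, `pctSd`.
#' @export
variancePartition <- function(x) {
  if (is(x, "PosteriorSummary"))
    return(varComponents(x)[, c("source", "pctMean", "pctSd")])
  if (is.list(x) && !is.null(x$summary))
    return(variancePartition(x$summary))
  G <- as.matrix(x)
  pct <- 100 * G / rowSums(G)
  data.frame(source = colnames(G) %||% paste0("K", seq_len(ncol(G))),
             pctMean = colMeans(pct), pctSd = apply(pct, 2, sd),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' In-sample goodness of fit
#'
#' Squared Pearson correlation between observed values and in-sample
#' fitted values (fixed-effect plus genetic posterior means); a constant
#' fit returns 0.
#'
#' @param y observed values.
#' @param fitted fitted values.
#' @return R-squared in [0, 1].
#' @export
goodnessOfFit <- function(y, fitted) {
  if (sd(fitted) < 1e-300 || sd(y) < 1e-300) return(0)
  cor(y, fitted)^2
}
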