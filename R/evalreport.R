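## Cross-validated prediction, model comparison, and the end-to-end
## pipeline from (simulated or read) genotypes to the report tables.

#' Random k-fold assignment
#'
#' A random permutation split into k nonoverlapping parts whose sizes
#' differ by at most 1.
#'
#' @param n number of records.
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return integer vector of fold labels in 1..k, length n.
#' @export
makeFolds <- function(n, k = 10, seed = 1) {
  stopifnot(n >= k, k >= 2)
  set.seed(seed)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  folds <- integer(n)
  folds[sample.int(n)] <- rep(seq_len(k), times = sizes)
  folds
}

## out-of-sample prediction for one fitted fold
.predictFold <- function(fit, spec, testPheno, kernelsFull, testIds) {
  fd <- fit$spec$design
  td <- fixedDesign(testPheno, hys_levels = fd$hys_levels,
                    age_center = fd$age_center)
  pred <- drop(td$X %*% fit$postMean$beta)
  if (any(td$unseen)) {
    grand <- mean(drop(fit$spec$X %*% fit$postMean$beta))
    pred[td$unseen] <- grand
  }
  trainIds <- fit$spec$pheno$animal_id
  for (j in seq_along(kernelsFull)) {
    Ktt <- kernelMatrix(kernelsFull[[j]])[testIds, trainIds, drop = FALSE]
    pred <- pred + drop(Ktt %*% fit$postMean$w[[j]])
  }
  list(pred = pred, nUnseen = sum(td$unseen))
}

#' Cross-validated prediction
#'
#' Per fold, the model is fitted on the training records only; test
#' phenotypes are predicted as the fixed-effect prediction plus the
#' kernel-projected genetic values (the train-test kernel block applied to
#' the training solutions).  Test records whose HYS level is unseen in
#' training receive the grand fixed-effect mean.
#'
#' @param y response vector aligned to `spec$pheno`.
#' @param spec a [modelSpec()] over all records; kernels must cover all
#'   records.
#' @param folds fold labels from [makeFolds()].
#' @param label model label stored in the result.
#' @return list of class `cv_result`: `foldCor`, `meanCor`, `ci` (normal
#'   approximation across folds, the reporting convention), `ciPercentile`
#'   (percentile interval of the fold correlations; wider, and preferable
#'   when the folds are strongly dependent), `foldSizes`, `label`,
#'   `predictions` (out-of-fold prediction per record), `nUnseen`.
#' @export
crossValidate <- function(y, spec, folds, label = "model") {
  stopifnot(inherits(spec, "model_spec"), length(folds) == length(y))
  k <- max(folds)
  foldCor <- numeric(k)
  predictions <- numeric(length(y))
  nUnseen <- 0L
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    phTr <- spec$pheno[train, , drop = FALSE]
    kTr <- lapply(spec$kernels, function(K) {
      M <- kernelMatrix(K)[train, train, drop = FALSE]
      new("GenomicKernel", matrix = M, kind = kernelKind(K),
          source = kernelSource(K), param = K@param)
    })
    mcf <- spec$mcmc
    mcf$seed <- spec$mcmc$seed + f
    sp <- modelSpec(phTr, kernels = kTr, mcmc = mcf,
                    priors = spec$priors,
                    fix_variances = spec$fix_variances)
    fit <- fitMKModel(y[train], sp)
    pr <- .predictFold(fit, sp, spec$pheno[test, , drop = FALSE],
                       spec$kernels, spec$pheno$animal_id[test])
    nUnseen <- nUnseen + pr$nUnseen
    predictions[test] <- pr$pred
    cc <- suppressWarnings(cor(pr$pred, y[test]))
    foldCor[f] <- if (is.na(cc)) 0 else cc
  }
  m <- mean(foldCor)
  se <- sd(foldCor) / sqrt(k)
  qs <- stats::quantile(foldCor, c(0.025, 0.975), names = FALSE)
  structure(list(foldCor = foldCor, meanCor = m,
                 ci = c(lower = m - 1.96 * se, upper = m + 1.96 * se),
                 ciPercentile = c(lower = qs[1], upper = qs[2]),
                 foldSizes = tabulate(folds, k), label = label,
                 predictions = predictions, nUnseen = nUnseen),
            class = "cv_result")
}

#' Compare cross-validation results
#'
#' @param results list of `cv_result` objects.
#' @param sort rank rows by mean correlation (stable sort, ties preserved);
#'   `FALSE` keeps the input order.
#' @return data.frame: `label`, `meanCor`, `ciLower`, `ciUpper`, plus the
#'   per-fold correlations as attribute `"folds"` (for box plots).
#' @export
compareModels <- function(results, sort = TRUE) {
  tab <- data.frame(
    label = vapply(results, `[[`, character(1), "label"),
    meanCor = vapply(results, `[[`, numeric(1), "meanCor"),
    ciLower = vapply(results, function(r) r$ci[["lower"]], numeric(1)),
    ciUpper = vapply(results, function(r) r$ci[["upper"]], numeric(1)),
    stringsAsFactors = FALSE)
  folds <- lapply(results, `[[`, "foldCor")
  names(folds) <- tab$label
  if (sort) {
    o <- order(-tab$meanCor)
    tab <- tab[o, , drop = FALSE]
    folds <- folds[o]
    rownames(tab) <- NULL
  }
  attr(tab, "folds") <- folds
  tab
}

#' Pipeline configuration
#'
#' Desk-scale defaults; every stage's parameters are exposed.
#'
#' @param sim a [simConfig()]; ignored when `plink_prefix` is given.
#' @param plink_prefix optional path prefix of an existing bed/bim/fam set
#'   (with `<prefix>_pheno.csv` alongside) to analyse instead of
#'   simulating.
#' @param trait trait type for the record filters (see
#'   [filterPhenotypes()]).
#' @param thresholds a [qcThresholds()].
#' @param roh a [rohParams()].
#' @param r2_min,min_block_snps,min_hap_freq haplotype-block settings.
#' @param bandwidth Gaussian ROH kernel bandwidth.
#' @param mcmc MCMC settings for every fit.
#' @param k_folds cross-validation folds.
#' @param models model labels to evaluate; the default is the full set of
#'   kernel combinations (XB = fixed effects only; K1 = SNP, K2 = HAP,
#'   K3 = ROH).
#' @param seed master seed for folds and chains.
#' @return list of class `pipeline_config`.
#' @export
pipelineConfig <- function(sim = simConfig(), plink_prefix = NULL,
                           trait = "milk",
                           thresholds = qcThresholds(),
                           roh = rohParams(),
                           r2_min = 0.80, min_block_snps = 2,
                           min_hap_freq = 0.01, bandwidth = 1.5,
                           mcmc = list(n_iter = 2000, burn_in = 500,
                                       thin = 5),
                           k_folds = 10,
                           models = c("XB", "K1", "K2", "K3", "K1+K2",
                                      "K1+K3", "K2+K3", "K1+K2+K3"),
                           seed = 1) {
  structure(list(sim = sim, plink_prefix = plink_prefix, trait = trait,
                 thresholds = thresholds, roh = roh, r2_min = r2_min,
                 min_block_snps = min_block_snps,
                 min_hap_freq = min_hap_freq, bandwidth = bandwidth,
                 mcmc = mcmc, k_folds = k_folds, models = models,
                 seed = seed),
            class = "pipeline_config")
}

.modelKernels <- function(label, K1, K2, K3) {
  if (label == "XB") return(list())
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  lapply(parts, function(p) switch(p, K1 = K1, K2 = K2, K3 = K3,
                                   stop("unknown kernel label: ", p)))
}

#' Run the whole pipeline
#'
#' Simulate (or read) genotypes, apply marker and record QC, build
#' haplotype blocks and the ROH incidence, construct the three kernels,
#' fit every requested model variant, cross-validate, and assemble the
#' report tables (CV correlations; variance partition and heritability per
#' model).
#'
#' @param config a [pipelineConfig()].
#' @param out_dir optional directory; when given, the report is written as
#'   JSON and markdown and intermediates as text files.
#' @return list with `cv` (comparison table), `variance` (per-model total
#'   genetic variance and percentage per kernel), `heritability`
#'   (per-model h2 mean and sd), `qcReport`, `rohOverall`, `nRecords`,
#'   `config`.
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ## ---- data ----
  if (!is.null(config$plink_prefix)) {
    if (!file.exists(paste0(config$plink_prefix, ".bed")))
      stop("genotype file not found: ", config$plink_prefix, ".bed")
    geno <- readPlink(config$plink_prefix)
    phenoAll <- readPhenotypes(paste0(config$plink_prefix, "_pheno.csv"))
    truth <- NULL
  } else {
    sim <- simulateGenotypes(config$sim)
    geno <- sim$geno
  }
  ## ---- marker QC (SNPs) ----
  mq <- markerQC(geno, config$thresholds)
  genoQC <- mq$geno
  ## ---- haplotype blocks on QC'd SNPs ----
  blocks <- findBlocks(genoQC, r2_min = config$r2_min,
                       min_snps = config$min_block_snps)
  pseudo <- NULL
  if (length(blocks)) {
    bh <- lapply(blocks, function(b) inferBlockHaplotypes(genoQC, b$idx))
    pseudo <- recodePseudoSNP(bh, min_freq = config$min_hap_freq)
    pq <- markerQC(pseudo, config$thresholds)
    pseudo <- pq$geno
  }
  if (is.null(pseudo) || ncol(genotypes(pseudo)) == 0)
    stop("no haplotype blocks survived QC; cannot build the HAP kernel")
  ## ---- ROH on the full marker set (scanner does its own missingness prep)
  segments <- scanRoh(geno, config$roh)
  rohAll <- poolRoh(segments)
  ## ---- phenotypes ----
  if (is.null(config$plink_prefix)) {
    phe <- simulatePhenotypes(geno, pseudo, rohAll, config$sim)
    phenoAll <- phe$pheno
    truth <- phe$truth
  }
  pheno <- filterPhenotypes(phenoAll, trait = config$trait,
                            thresholds = config$thresholds,
                            genotyped_ids = animalIds(geno))
  ## per-trait ROH incidence: rebuilt on the retained records
  segTrait <- segments[segments$animal_id %in% pheno$animal_id, ,
                       drop = FALSE]
  rohInc <- poolRoh(segTrait)
  ## ---- kernels on the trait's record set ----
  ids <- pheno$animal_id
  K1 <- linearKernel(genotypes(genoQC)[ids, , drop = FALSE], source = "SNP")
  K2 <- linearKernel(genotypes(pseudo)[ids, , drop = FALSE], source = "HAP")
  K3 <- gaussianRohKernel(rohInc, h = config$bandwidth)
  al <- kernelAlign(list(K1, K2, K3), pheno)
  pheno <- al$pheno
  K1 <- al$kernels[[1]]; K2 <- al$kernels[[2]]; K3 <- al$kernels[[3]]
  y <- pheno$value
  n <- nrow(pheno)
  folds <- makeFolds(n, k = config$k_folds, seed = config$seed)
  ## ---- fit and cross-validate each model ----
  cvResults <- list()
  varianceTab <- list()
  h2Tab <- list()
  for (i in seq_along(config$models)) {
    lab <- config$models[[i]]
    kern <- .modelKernels(lab, K1, K2, K3)
    mcmc <- config$mcmc
    mcmc$seed <- config$seed + 1000 * i
    sp <- modelSpec(pheno, kernels = kern, mcmc = mcmc)
    cvResults[[i]] <- crossValidate(y, sp, folds, label = lab)
    fit <- fitMKModel(y, sp)
    s <- fit$summary
    vc <- varComponents(s)
    row <- data.frame(model = lab,
                      totalGenetic = s@totalGenetic[["mean"]],
                      totalGeneticSd = s@totalGenetic[["sd"]],
                      pctSNP = NA_real_, pctHAP = NA_real_,
                      pctROH = NA_real_,
                      R2 = goodnessOfFit(y, fit$postMean$fitted),
                      stringsAsFactors = FALSE)
    if (nrow(vc)) {
      for (j in seq_len(nrow(vc)))
        row[[paste0("pct", vc$source[j])]] <- vc$pctMean[j]
    }
    varianceTab[[i]] <- row
    h2Tab[[i]] <- data.frame(model = lab,
                             h2 = s@heritability[["mean"]],
                             h2Sd = s@heritability[["sd"]],
                             stringsAsFactors = FALSE)
  }
  report <- list(cv = compareModels(cvResults, sort = FALSE),
                 cvResults = cvResults,
                 variance = do.call(rbind, varianceTab),
                 heritability = do.call(rbind, h2Tab),
                 qcReport = mq$report,
                 rohOverall = rohSummary(segTrait)$overall,
                 nRecords = n, truth = truth,
                 config = config)
  if (!is.null(out_dir)) writeReport(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' @param report result of [runPipeline()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeReport <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonPath <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(cv = report$cv, variance = report$variance,
         heritability = report$heritability, qc = report$qcReport,
         n_records = report$nRecords),
    jsonPath, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  mdPath <- file.path(out_dir, "report.md")
  con <- file(mdPath, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# Multi-kernel genomic prediction report")
  w("")
  w("## Cross-validated prediction (", length(report$cvResults[[1]]$foldCor),
    "-fold)")
  w("")
  w("| model | mean r | 95% CI |")
  w("|---|---|---|")
  cv <- report$cv
  for (i in seq_len(nrow(cv)))
    w(sprintf("| %s | %.3f | (%.3f, %.3f) |", cv$label[i], cv$meanCor[i],
              cv$ciLower[i], cv$ciUpper[i]))
  w("")
  w("## Genetic variance and partition")
  w("")
  w("| model | total var | %SNP | %HAP | %ROH | R2 |")
  w("|---|---|---|---|---|---|")
  v <- report$variance
  pf <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))
  for (i in seq_len(nrow(v)))
    w(sprintf("| %s | %.3f | %s | %s | %s | %.2f |", v$model[i],
              v$totalGenetic[i], pf(v$pctSNP[i]), pf(v$pctHAP[i]),
              pf(v$pctROH[i]), v$R2[i]))
  w("")
  w("## Heritability")
  w("")
  w("| model | h2 | sd |")
  w("|---|---|---|")
  h <- report$heritability
  for (i in seq_len(nrow(h)))
    w(sprintf("| %s | %.3f | %.3f |", h$model[i], h$h2[i], h$h2Sd[i]))
  invisible(c(jsonPath, mdPath))
}
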