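## Phenotype filters and marker quality control.

#' Quality-control thresholds
#'
#' @param min_call_rate markers with call rate below this are removed.
#' @param min_maf minimum minor allele frequency.
#' @param hwe_threshold markers whose Hardy-Weinberg exact-test p-value is
#'   below this are removed.
#' @param age_window_months closed interval of admissible age at first
#'   calving, in months.
#' @param milk_sd_window half-width, in standard deviations, of the milk
#'   yield window around the mean.
#' @param days_open_range closed interval of admissible days open.
#' @return list of class `qc_thresholds`.
#' @export
qcThresholds <- function(min_call_rate = 0.95, min_maf = 0.05,
                         hwe_threshold = 0.15,
                         age_window_months = c(16, 60),
                         milk_sd_window = 3,
                         days_open_range = c(30, 400)) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1,
            hwe_threshold >= 0, hwe_threshold <= 1,
            age_window_months[1] < age_window_months[2],
            days_open_range[1] < days_open_range[2],
            milk_sd_window > 0)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_threshold = hwe_threshold,
                 age_window_months = age_window_months,
                 milk_sd_window = milk_sd_window,
                 days_open_range = days_open_range),
            class = "qc_thresholds")
}

#' Somatic cell score transform
#'
#' SCS = log2(SCC / 1,000,000) + 3, with SCC in cells/mL.
#'
#' @param scc somatic cell count(s), cells/mL; must be positive.
#' @return numeric SCS on the log2 scale.
#' @export
scsTransform <- function(scc) {
  if (any(!is.finite(scc)) || any(scc <= 0))
    stop("somatic cell counts must be positive and finite")
  log2(scc / 1e6) + 3
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact p-value: conditional on the observed allele counts, sums
#' the probabilities of all heterozygote counts no more likely than the
#' observed one.
#'
#' @param nAA,nAB,nBB genotype counts.
#' @return p-value in (0, 1].
#' @export
hweExactTest <- function(nAA, nAB, nBB) {
  if (any(c(nAA, nAB, nBB) < 0)) stop("genotype counts must be non-negative")
  n <- nAA + nAB + nBB
  if (n == 0) stop("no genotypes observed")
  nA <- 2 * nAA + nAB
  nB <- 2 * nBB + nAB
  ## all heterozygote counts with the parity of nA, in [parity, min(nA, nB)]
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  ## log P(nAB = h | nA, n) up to a common constant:
  ##   n! / (nAA! nAB! nBB!) * 2^nAB  with nAA = (nA - h)/2, nBB = (nB - h)/2
  lp <- vapply(hets, function(h) {
    a <- (nA - h) / 2; b <- (nB - h) / 2
    h * log(2) - lfactorial(a) - lfactorial(h) - lfactorial(b)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(nAB, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Marker quality control
#'
#' Removes markers failing call rate, minor allele frequency, or the
#' Hardy-Weinberg exact test. Retained genotype values are never altered;
#' only columns are dropped. The same filter applies to pseudo-SNP
#' (haplotype allele) columns.
#'
#' @param geno a [GenotypeData-class], [PseudoSNPData-class], or plain
#'   animals x markers matrix of 0/1/2/NA codes.
#' @param thresholds a [qcThresholds()] list.
#' @return list with `geno` (same class, filtered) and `report` (counts of
#'   markers failing each criterion and totals).
#' @export
markerQC <- function(geno, thresholds = qcThresholds()) {
  cd <- if (is(geno, "GenotypeData") || is(geno, "PseudoSNPData"))
    genotypes(geno) else as.matrix(geno)
  n <- nrow(cd)
  callRate <- 1 - colSums(is.na(cd)) / n
  pA <- colMeans(cd, na.rm = TRUE) / 2
  maf <- pmin(pA, 1 - pA)
  maf[is.nan(maf)] <- 0
  hwe <- vapply(seq_len(ncol(cd)), function(j) {
    x <- cd[, j]
    cnt <- c(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
             sum(x == 0, na.rm = TRUE))
    if (sum(cnt) == 0) return(0)
    hweExactTest(cnt[1], cnt[2], cnt[3])
  }, numeric(1))
  failCall <- callRate < thresholds$min_call_rate
  failMaf <- maf < thresholds$min_maf
  failHwe <- hwe < thresholds$hwe_threshold
  keep <- !(failCall | failMaf | failHwe)
  report <- list(n_markers = ncol(cd),
                 fail_call_rate = sum(failCall),
                 fail_maf = sum(failMaf),
                 fail_hwe = sum(failHwe),
                 removed = sum(!keep),
                 retained = sum(keep))
  out <-
    if (is(geno, "GenotypeData")) {
      GenotypeData(genotypes(geno)[, keep, drop = FALSE],
                   markers(geno)[keep, , drop = FALSE])
    } else if (is(geno, "PseudoSNPData")) {
      new("PseudoSNPData", codes = geno@codes[, keep, drop = FALSE],
          columns = geno@columns[keep, , drop = FALSE])
    } else cd[, keep, drop = FALSE]
  list(geno = out, report = report)
}

#' Filter phenotype records
#'
#' Applies the trait-specific record filters: age at first calving inside
#' the age window (all traits); milk yield inside mean +- 3 SD, with the SD
#' computed once on the age-filtered set; days open inside its closed
#' range.  Optionally drops records without genotypes.
#'
#' @param pheno data.frame with columns `animal_id`, `value`, `hys`,
#'   `age_months`.
#' @param trait one of `"milk"`, `"scs"`, `"days_open"`.
#' @param thresholds a [qcThresholds()] list.
#' @param genotyped_ids optional character vector; records whose
#'   `animal_id` is absent are dropped (only animals with both genomic and
#'   phenotypic information are kept).
#' @return filtered data.frame.
#' @export
filterPhenotypes <- function(pheno, trait = c("milk", "scs", "days_open"),
                             thresholds = qcThresholds(),
                             genotyped_ids = NULL) {
  trait <- match.arg(trait)
  stopifnot(all(c("animal_id", "value", "hys", "age_months") %in%
                names(pheno)))
  if (nrow(pheno) == 0) return(pheno)
  aw <- thresholds$age_window_months
  keep <- pheno$age_months >= aw[1] & pheno$age_months <= aw[2]
  out <- pheno[keep, , drop = FALSE]
  if (trait == "milk" && nrow(out)) {
    m <- mean(out$value); s <- sd(out$value)
    w <- thresholds$milk_sd_window
    if (is.finite(s) && s > 0)
      out <- out[out$value >= m - w * s & out$value <= m + w * s, ,
                 drop = FALSE]
  } else if (trait == "days_open") {
    dr <- thresholds$days_open_range
    out <- out[out$value >= dr[1] & out$value <= dr[2], , drop = FALSE]
  }
  if (!is.null(genotyped_ids))
    out <- out[out$animal_id %in% genotyped_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}
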