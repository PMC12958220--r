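## Runs-of-homozygosity detection with the sliding-window scanner, pooling
## of overlapping runs into population-level loci, and summaries.

#' ROH scanning parameters
#'
#' Mirrors the flag set of the standard window scanner: 50-SNP windows
#' allowing 1 heterozygote and 1 missing call, runs split at gaps over
#' 500 kb, X excluded, marker/animal missingness capped at 10%.  Fields the
#' flag set leaves at scanner defaults (minimum SNPs per run, minimum
#' length, density, window hit threshold) use those published defaults.
#'
#' @param window_snp SNPs per sliding window.
#' @param window_het maximum heterozygous calls for a homozygous window.
#' @param window_missing maximum missing calls for a homozygous window.
#' @param max_gap_kb split a run where adjacent member SNPs are further
#'   apart than this.
#' @param exclude_chromosomes chromosome labels dropped before scanning
#'   (case-insensitive).
#' @param geno_miss_max markers with a higher missing fraction are dropped.
#' @param mind_miss_max animals with a higher missing fraction are dropped.
#' @param min_snp_in_run minimum member SNPs for a reported segment.
#' @param min_length_kb minimum segment length in kb.
#' @param min_density_kb_per_snp maximum kb per SNP inside a segment.
#' @param window_hit_threshold minimum fraction of homozygous windows
#'   covering a SNP for it to join a run candidate.
#' @return list of class `roh_params`.
#' @export
rohParams <- function(window_snp = 50, window_het = 1, window_missing = 1,
                      max_gap_kb = 500, exclude_chromosomes = "X",
                      geno_miss_max = 0.10, mind_miss_max = 0.10,
                      min_snp_in_run = 100, min_length_kb = 1000,
                      min_density_kb_per_snp = 50,
                      window_hit_threshold = 0.05) {
  stopifnot(window_snp >= 1, window_het >= 0, window_missing >= 0,
            max_gap_kb > 0, min_snp_in_run >= 1, min_length_kb > 0,
            window_hit_threshold > 0, window_hit_threshold <= 1)
  structure(list(window_snp = as.integer(window_snp),
                 window_het = window_het, window_missing = window_missing,
                 max_gap_kb = max_gap_kb,
                 exclude_chromosomes = exclude_chromosomes,
                 geno_miss_max = geno_miss_max,
                 mind_miss_max = mind_miss_max,
                 min_snp_in_run = min_snp_in_run,
                 min_length_kb = min_length_kb,
                 min_density_kb_per_snp = min_density_kb_per_snp,
                 window_hit_threshold = window_hit_threshold),
            class = "roh_params")
}

## candidate SNP flags for one animal on one chromosome
.rohCandidates <- function(het, mis, p) {
  m <- length(het)
  W <- p$window_snp
  if (m < W) return(logical(m))      # no full window fits
  nw <- m - W + 1L
  csH <- cumsum(c(0L, het)); csM <- cumsum(c(0L, mis))
  winHom <- (csH[(W + 1):(m + 1)] - csH[1:nw]) <= p$window_het &
            (csM[(W + 1):(m + 1)] - csM[1:nw]) <= p$window_missing
  ## SNP t covered by windows max(1, t-W+1) .. min(t, nw)
  csW <- cumsum(c(0L, as.integer(winHom)))
  t <- seq_len(m)
  lo <- pmax(1L, t - W + 1L)
  hi <- pmin(t, nw)
  nHom <- csW[hi + 1L] - csW[lo]
  nCov <- hi - lo + 1L
  nHom / nCov >= p$window_hit_threshold
}

## split a run of candidate indices at large bp gaps, then apply the
## segment-level count / length / density filters
.rohSegments <- function(cand, bp, p) {
  segs <- list()
  runs <- rle(cand)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values)) {
    idx <- starts[r]:ends[r]
    gaps <- diff(bp[idx])
    cut <- which(gaps > p$max_gap_kb * 1000)
    bounds <- c(0L, cut, length(idx))
    for (s in seq_len(length(bounds) - 1L)) {
      part <- idx[(bounds[s] + 1L):bounds[s + 1L]]
      lenKb <- (bp[part[length(part)]] - bp[part[1]] + 1) / 1000
      if (length(part) >= p$min_snp_in_run &&
          lenKb >= p$min_length_kb &&
          lenKb / length(part) <= p$min_density_kb_per_snp)
        segs[[length(segs) + 1L]] <- c(part[1], part[length(part)],
                                       length(part))
    }
  }
  segs
}

#' Scan runs of homozygosity
#'
#' Sliding fixed-size windows per animal and chromosome; a window is
#' homozygous when it holds at most `window_het` heterozygous and
#' `window_missing` missing calls; a SNP joins a run candidate when the
#' fraction of covering windows that are homozygous reaches
#' `window_hit_threshold`; maximal candidate stretches are split at gaps
#' over `max_gap_kb` and must satisfy the count, length and density
#' minima.  Excluded chromosomes and high-missingness markers/animals are
#' dropped first.
#'
#' @param geno a [GenotypeData-class]; markers must be map-sorted.
#' @param params a [rohParams()] list.
#' @return data.frame of segments: `animal_id`, `chrom`, `start`, `end`
#'   (bp at member SNPs, 1-based inclusive), `n_snps`, `length_kb`.
#' @export
scanRoh <- function(geno, params = rohParams()) {
  cd <- genotypes(geno)
  mk <- markers(geno)
  if (any(vapply(split(mk$bp, mk$chrom), function(x) any(diff(x) <= 0),
                 logical(1))))
    stop("marker map must be sorted by position within chromosome")
  keepChr <- !(toupper(mk$chrom) %in% toupper(params$exclude_chromosomes))
  cd <- cd[, keepChr, drop = FALSE]
  mk <- mk[keepChr, , drop = FALSE]
  if (ncol(cd)) {
    keepSnp <- colMeans(is.na(cd)) <= params$geno_miss_max
    cd <- cd[, keepSnp, drop = FALSE]
    mk <- mk[keepSnp, , drop = FALSE]
  }
  keepAni <- if (ncol(cd)) rowMeans(is.na(cd)) <= params$mind_miss_max
             else rep(TRUE, nrow(cd))
  cd <- cd[keepAni, , drop = FALSE]
  out <- list()
  chroms <- unique(mk$chrom)
  for (ch in chroms) {
    cols <- which(mk$chrom == ch)
    bp <- mk$bp[cols]
    sub <- cd[, cols, drop = FALSE]
    for (a in seq_len(nrow(sub))) {
      g <- sub[a, ]
      cand <- .rohCandidates(!is.na(g) & g == 1L, is.na(g), params)
      for (sg in .rohSegments(cand, bp, params))
        out[[length(out) + 1L]] <-
          data.frame(animal_id = rownames(sub)[a], chrom = ch,
                     start = bp[sg[1]], end = bp[sg[2]],
                     n_snps = sg[3],
                     length_kb = (bp[sg[2]] - bp[sg[1]] + 1) / 1000,
                     stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(animal_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), n_snps = integer(0),
               length_kb = numeric(0))
}

#' Pool ROH segments into population loci
#'
#' Single-linkage clustering per chromosome: two segments link when their
#' reciprocal overlap (intersection over each length) is at least
#' `overlap_min`.  Each cluster becomes one locus with consensus region
#' equal to the intersection of member spans; the incidence cell is 1 when
#' the animal contributed a member segment.  Animals with no segment at
#' all are absent from the matrix.
#'
#' @param segments data.frame from [scanRoh()].
#' @param overlap_min reciprocal overlap threshold (default 0.95).
#' @return A [ROHIncidence-class]; zero segments give a 0 x 0 matrix with
#'   a warning.
#' @export
poolRoh <- function(segments, overlap_min = 0.95) {
  if (nrow(segments) == 0) {
    warning("no ROH segments to pool; returning an empty incidence matrix")
    return(new("ROHIncidence",
               incidence = matrix(0, 0, 0,
                                  dimnames = list(character(0), NULL)),
               loci = data.frame(chrom = character(0), start = integer(0),
                                 end = integer(0), nCarriers = integer(0))))
  }
  segments$cluster <- NA_integer_
  nextId <- 1L
  for (ch in unique(segments$chrom)) {
    rows <- which(segments$chrom == ch)
    s <- segments$start[rows]; e <- segments$end[rows]
    len <- e - s + 1
    parent <- seq_along(rows)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_along(rows)) for (j in seq_len(i - 1L)) {
      ov <- min(e[i], e[j]) - max(s[i], s[j]) + 1
      if (ov > 0 && ov / len[i] >= overlap_min && ov / len[j] >= overlap_min) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
    roots <- vapply(seq_along(rows), find, integer(1))
    segments$cluster[rows] <- nextId + match(roots, unique(roots)) - 1L
    nextId <- nextId + length(unique(roots))
  }
  animals <- sort(unique(segments$animal_id))
  nLoci <- max(segments$cluster)
  inc <- matrix(0L, length(animals), nLoci,
                dimnames = list(animals, paste0("locus", seq_len(nLoci))))
  loci <- data.frame(chrom = character(nLoci), start = integer(nLoci),
                     end = integer(nLoci), nCarriers = integer(nLoci),
                     stringsAsFactors = FALSE)
  for (cl in seq_len(nLoci)) {
    mem <- segments[segments$cluster == cl, ]
    inc[unique(mem$animal_id), cl] <- 1L
    loci$chrom[cl] <- mem$chrom[1]
    loci$start[cl] <- max(mem$start)   # intersection of member spans
    loci$end[cl] <- min(mem$end)
    loci$nCarriers[cl] <- length(unique(mem$animal_id))
  }
  new("ROHIncidence", incidence = inc, loci = loci)
}

#' Per-animal ROH summary
#'
#' @param segments data.frame from [scanRoh()].
#' @return list with `perAnimal` (animal_id, n_roh, mean_length_mb,
#'   coverage_mb) and `overall` (mean and SD of count, mean length, and
#'   genome coverage across animals); both empty when no segments exist.
#' @export
rohSummary <- function(segments) {
  if (nrow(segments) == 0)
    return(list(perAnimal = data.frame(animal_id = character(0),
                                       n_roh = integer(0),
                                       mean_length_mb = numeric(0),
                                       coverage_mb = numeric(0)),
                overall = NULL))
  sp <- split(segments, segments$animal_id)
  per <- do.call(rbind, lapply(sp, function(d)
    data.frame(animal_id = d$animal_id[1], n_roh = nrow(d),
               mean_length_mb = mean(d$length_kb) / 1000,
               coverage_mb = sum(d$length_kb) / 1000,
               stringsAsFactors = FALSE)))
  rownames(per) <- NULL
  overall <- data.frame(
    metric = c("n_roh", "mean_length_mb", "coverage_mb"),
    mean = c(mean(per$n_roh), mean(per$mean_length_mb),
             mean(per$coverage_mb)),
    sd = c(sd(per$n_roh), sd(per$mean_length_mb), sd(per$coverage_mb)))
  list(perAnimal = per, overall = overall)
}
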