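## LD-based haplotype blocks: pairwise r2 by two-locus EM, greedy block
## construction, within-block haplotype inference by multinomial EM, and
## recoding of haplotype alleles as pseudo-SNP copy counts.

## fast 3 x 3 genotype cross-table for codes in {0,1,2}
.crossTab3 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  tab <- tabulate(x[ok] * 3L + y[ok] + 1L, nbins = 9L)
  matrix(tab, 3, 3, byrow = TRUE)  # tab[x+1, y+1]
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Estimates the two-locus haplotype frequency by EM on the 3 x 3 genotype
#' table (only the double heterozygote is phase-ambiguous) and returns
#' r2 = D^2 / (pA (1-pA) pB (1-pB)).  The composite (genotypic
#' correlation) estimator is available as an option.
#'
#' @param geno a [GenotypeData-class] or a plain codes matrix.
#' @param i,j marker (column) indices.
#' @param method `"em"` (haplotype-frequency EM, default) or `"composite"`
#'   (squared genotypic correlation).
#' @return list with `i`, `j` and `r2`; `r2` is `NA` when either marker is
#'   monomorphic among complete pairs.
#' @export
pairwiseR2 <- function(geno, i, j, method = c("em", "composite")) {
  method <- match.arg(method)
  cd <- if (is(geno, "GenotypeData")) genotypes(geno) else geno
  x <- cd[, i]; y <- cd[, j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  out <- list(i = i, j = j, r2 = NA_real_)
  if (n == 0) return(out)
  pA <- mean(x) / 2; pB <- mean(y) / 2
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(out)
  if (method == "composite") {
    out$r2 <- suppressWarnings(cor(x, y))^2
    return(out)
  }
  tab <- .crossTab3(x, y)                     # tab[x+1, y+1]
  ## phase-known haplotype counts (AB, Ab, aB, ab)
  cAB <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]
  cAb <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1]
  caB <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3]
  cab <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  ndh <- tab[2, 2]
  pAB <- pA * pB                              # linkage-equilibrium start
  for (it in seq_len(1000)) {
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
    num <- pAB * pab
    den <- num + pAb * paB
    w <- if (den > 0) num / den else 0.5
    new <- (cAB + ndh * w) / (2 * n)
    new <- min(max(new, 0), min(pA, pB))
    if (abs(new - pAB) < 1e-12) { pAB <- new; break }
    pAB <- new
  }
  D <- pAB - pA * pB
  out$r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  out
}

#' Find LD-based haplotype blocks
#'
#' Greedy left-to-right extension within each chromosome: a block grows
#' while the next SNP in map order has r2 at or above `r2_min` with every
#' SNP already in the block.  Blocks never span chromosomes and need at
#' least `min_snps` members; singleton SNPs are not blocks.
#'
#' @param geno a [GenotypeData-class]; markers must be map-sorted.
#' @param r2_min minimum pairwise r2 (default 0.80).
#' @param min_snps minimum SNPs per block (default 2).
#' @return list of blocks; each a list with `chrom`, `idx` (global marker
#'   column indices, contiguous), `startBp`, `endBp`.
#' @export
findBlocks <- function(geno, r2_min = 0.80, min_snps = 2) {
  cd <- genotypes(geno)
  mk <- markers(geno)
  blocks <- list()
  for (ch in unique(mk$chrom)) {
    cols <- which(mk$chrom == ch)
    i <- 1L
    while (i <= length(cols)) {
      member <- cols[i]
      j <- i + 1L
      while (j <= length(cols)) {
        cand <- cols[j]
        r2s <- vapply(member, function(m)
          pairwiseR2(cd, m, cand)$r2, numeric(1))
        if (any(is.na(r2s)) || any(r2s < r2_min)) break
        member <- c(member, cand)
        j <- j + 1L
      }
      if (length(member) >= min_snps) {
        blocks[[length(blocks) + 1L]] <-
          list(chrom = ch, idx = member,
               startBp = mk$bp[member[1]],
               endBp = mk$bp[member[length(member)]])
        i <- j
      } else i <- i + 1L
    }
  }
  blocks
}

## enumerate compatible (hap1, hap2) pairs for one genotype vector over a
## block; haplotypes encoded as strings over {A, B}; returns a 2-column
## character matrix, or NULL when the animal has missing calls in the block
.compatiblePairs <- function(g, max_het = 14L) {
  if (anyNA(g)) return(NULL)
  L <- length(g)
  h1 <- ifelse(g == 2, "A", "B")   # code 2 -> A/A, 0 -> B/B
  h2 <- h1
  hets <- which(g == 1L)
  if (length(hets) == 0L)
    return(matrix(c(paste(h1, collapse = ""), paste(h2, collapse = "")), 1))
  if (length(hets) > max_het) return(NULL)  # too ambiguous to enumerate
  ## first het fixed as A on hap1 (unordered pairs); rest free
  free <- hets[-1]
  nfree <- length(free)
  combos <- if (nfree == 0) matrix(0L, 1, 0) else
    as.matrix(expand.grid(rep(list(0:1), nfree)))
  pairs <- matrix("", nrow(combos), 2)
  for (r in seq_len(nrow(combos))) {
    a <- h1; b <- h2
    a[hets[1]] <- "A"; b[hets[1]] <- "B"
    if (nfree) {
      aa <- ifelse(combos[r, ] == 1, "A", "B")
      a[free] <- aa
      b[free] <- ifelse(aa == "A", "B", "A")
    }
    pairs[r, ] <- sort(c(paste(a, collapse = ""), paste(b, collapse = "")))
  }
  pairs
}

#' Infer within-block haplotypes by EM
#'
#' Maximises the multinomial likelihood of per-animal diplotypes over the
#' block's haplotypes, enumerating the phase configurations of each
#' animal's heterozygous sites.  Animals with missing calls in the block
#' receive a missing diplotype.
#'
#' @param geno a [GenotypeData-class] or codes matrix.
#' @param block integer vector of member marker indices (map-contiguous).
#' @param tol convergence tolerance on the largest frequency change
#'   (default 1e-8); at most 500 iterations.
#' @return list with `haplotypes` (strings over A/B), `freq` (summing to
#'   1), `diplotypes` (n x 2 character matrix, most probable pair, ties
#'   broken toward the lexicographically smaller pair; NA rows for animals
#'   with missing data), plus `chrom`, `idx`, `startBp`, `endBp` when
#'   `geno` is a GenotypeData.
#' @export
inferBlockHaplotypes <- function(geno, block, tol = 1e-8) {
  cd <- if (is(geno, "GenotypeData")) genotypes(geno) else geno
  sub <- cd[, block, drop = FALSE]
  n <- nrow(sub)
  pairsList <- lapply(seq_len(n), function(a) .compatiblePairs(sub[a, ]))
  haps <- sort(unique(unlist(pairsList)))
  if (length(haps) == 0)
    stop("no animal in the block has complete genotypes")
  ## linkage-equilibrium initialisation from per-locus allele frequencies
  pA <- colMeans(sub, na.rm = TRUE) / 2
  pA <- pmin(pmax(pA, 1e-6), 1 - 1e-6)
  hapBits <- do.call(rbind, strsplit(haps, ""))
  f <- apply(hapBits, 1, function(h) prod(ifelse(h == "A", pA, 1 - pA)))
  f <- f / sum(f)
  names(f) <- haps
  used <- which(!vapply(pairsList, is.null, logical(1)))
  idxPairs <- lapply(pairsList[used], function(p)
    cbind(match(p[, 1], haps), match(p[, 2], haps)))
  for (it in seq_len(500)) {
    counts <- numeric(length(haps))
    for (p in idxPairs) {
      w <- f[p[, 1]] * f[p[, 2]] * ifelse(p[, 1] == p[, 2], 1, 2)
      s <- sum(w)
      w <- if (s > 0) w / s else rep(1 / nrow(p), nrow(p))
      for (r in seq_len(nrow(p))) {
        counts[p[r, 1]] <- counts[p[r, 1]] + w[r]
        counts[p[r, 2]] <- counts[p[r, 2]] + w[r]
      }
    }
    fNew <- counts / (2 * length(used))
    delta <- max(abs(fNew - f))
    f <- fNew
    if (delta < tol) break
  }
  names(f) <- haps
  ## most probable diplotype per animal; ties -> lexicographically smaller
  diplo <- matrix(NA_character_, n, 2)
  for (a in seq_along(pairsList)) {
    p <- pairsList[[a]]
    if (is.null(p)) next
    pi1 <- match(p[, 1], haps); pi2 <- match(p[, 2], haps)
    pr <- f[pi1] * f[pi2] * ifelse(pi1 == pi2, 1, 2)
    best <- which(pr >= max(pr) - 1e-15)
    if (length(best) > 1)
      best <- best[order(p[best, 1], p[best, 2])][1]
    diplo[a, ] <- p[best, ]
  }
  rownames(diplo) <- rownames(sub)
  out <- list(haplotypes = haps, freq = f, diplotypes = diplo)
  if (is(geno, "GenotypeData")) {
    mk <- markers(geno)
    out$chrom <- mk$chrom[block[1]]
    out$idx <- block
    out$startBp <- mk$bp[block[1]]
    out$endBp <- mk$bp[block[length(block)]]
  }
  out
}

#' Recode inferred haplotypes as pseudo-SNP copy counts
#'
#' One column per haplotype allele whose population frequency is at least
#' `min_freq`; each cell counts the copies carried by the animal's most
#' probable diplotype.  Animals with a missing diplotype get missing cells
#' for that block (mean-imputed downstream by the kernel builder).
#'
#' @param blockHaps list of results from [inferBlockHaplotypes()].
#' @param min_freq minimum haplotype frequency for a column (default 0.01).
#' @return A [PseudoSNPData-class] object.
#' @export
recodePseudoSNP <- function(blockHaps, min_freq = 0.01) {
  if (length(blockHaps) == 0) stop("no blocks supplied")
  ids <- rownames(blockHaps[[1]]$diplotypes)
  n <- length(ids)
  cols <- list(); meta <- list()
  for (b in seq_along(blockHaps)) {
    bh <- blockHaps[[b]]
    keep <- which(bh$freq >= min_freq)
    for (k in keep) {
      hap <- bh$haplotypes[k]
      cnt <- (bh$diplotypes[, 1] == hap) + (bh$diplotypes[, 2] == hap)
      cols[[length(cols) + 1L]] <- as.integer(cnt)
      meta[[length(meta) + 1L]] <-
        data.frame(block = b,
                   chrom = if (!is.null(bh$chrom)) bh$chrom else NA,
                   startBp = if (!is.null(bh$startBp)) bh$startBp else NA,
                   endBp = if (!is.null(bh$endBp)) bh$endBp else NA,
                   haplotype = hap, freq = unname(bh$freq[k]),
                   stringsAsFactors = FALSE)
    }
  }
  codes <- if (length(cols)) do.call(cbind, cols) else
    matrix(integer(0), n, 0)
  rownames(codes) <- ids
  columns <- if (length(meta)) do.call(rbind, meta) else
    data.frame(block = integer(0), chrom = character(0),
               startBp = integer(0), endBp = integer(0),
               haplotype = character(0), freq = numeric(0))
  if (ncol(codes))
    colnames(codes) <- paste0("blk", columns$block, "_", columns$haplotype)
  new("PseudoSNPData", codes = codes, columns = columns)
}
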