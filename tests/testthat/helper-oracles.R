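## Independent reference implementations used as oracles.  These are kept
## deliberately literal (plain loops, closed forms) and share no code with
## the package internals they check.

## -- brute-force ROH window scanner ------------------------------------------
## Enumerates every window and applies the rules verbatim, one step at a
## time, per animal and chromosome.
refScanRoh <- function(geno, p) {
  cd <- genotypes(geno)
  mk <- markers(geno)
  keep <- !(toupper(mk$chrom) %in% toupper(p$exclude_chromosomes))
  cd <- cd[, keep, drop = FALSE]; mk <- mk[keep, , drop = FALSE]
  if (ncol(cd)) {
    ks <- logical(ncol(cd))
    for (j in seq_len(ncol(cd)))
      ks[j] <- mean(is.na(cd[, j])) <= p$geno_miss_max
    cd <- cd[, ks, drop = FALSE]; mk <- mk[ks, , drop = FALSE]
  }
  ka <- logical(nrow(cd))
  for (a in seq_len(nrow(cd)))
    ka[a] <- if (ncol(cd)) mean(is.na(cd[a, ])) <= p$mind_miss_max else TRUE
  cd <- cd[ka, , drop = FALSE]
  res <- list()
  for (ch in unique(mk$chrom)) {
    cols <- which(mk$chrom == ch)
    bp <- mk$bp[cols]
    m <- length(cols)
    for (a in seq_len(nrow(cd))) {
      g <- cd[a, cols]
      W <- p$window_snp
      cand <- logical(m)
      if (m >= W) {
        winHom <- logical(m - W + 1)
        for (s in seq_len(m - W + 1)) {
          win <- g[s:(s + W - 1)]
          winHom[s] <- sum(win == 1, na.rm = TRUE) <= p$window_het &&
            sum(is.na(win)) <= p$window_missing
        }
        for (t in seq_len(m)) {
          hit <- 0; tot <- 0
          for (s in seq_len(m - W + 1)) {
            if (s <= t && t <= s + W - 1) {
              tot <- tot + 1
              if (winHom[s]) hit <- hit + 1
            }
          }
          cand[t] <- tot > 0 && hit / tot >= p$window_hit_threshold
        }
      }
      ## maximal candidate stretches, split at big gaps, then filtered
      t <- 1
      while (t <= m) {
        if (!cand[t]) { t <- t + 1; next }
        u <- t
        while (u + 1 <= m && cand[u + 1]) u <- u + 1
        run <- t:u
        piece <- run[1]
        pieces <- list()
        for (q in run[-1]) {
          if (bp[q] - bp[piece[length(piece)]] > p$max_gap_kb * 1000) {
            pieces[[length(pieces) + 1]] <- piece
            piece <- q
          } else piece <- c(piece, q)
        }
        pieces[[length(pieces) + 1]] <- piece
        for (pc in pieces) {
          lenKb <- (bp[pc[length(pc)]] - bp[pc[1]] + 1) / 1000
          if (length(pc) >= p$min_snp_in_run && lenKb >= p$min_length_kb &&
              lenKb / length(pc) <= p$min_density_kb_per_snp)
            res[[length(res) + 1]] <-
              data.frame(animal_id = rownames(cd)[a], chrom = ch,
                         start = bp[pc[1]], end = bp[pc[length(pc)]],
                         n_snps = length(pc), length_kb = lenKb,
                         stringsAsFactors = FALSE)
        }
        t <- u + 1
      }
    }
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(animal_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), n_snps = integer(0),
               length_kb = numeric(0))
}

## -- two-locus r2 oracle -----------------------------------------------------
## Maximises the multinomial genotype likelihood over the single free
## haplotype frequency pAB (coarse grid + optimize refinement), then
## returns r2 = D^2 / (pA qA pB qB).
refR2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  pA <- mean(x) / 2; pB <- mean(y) / 2
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NA_real_)
  tab <- matrix(0, 3, 3)
  for (i in seq_along(x)) tab[x[i] + 1, y[i] + 1] <- tab[x[i] + 1, y[i] + 1] + 1
  loglik <- function(pAB) {
    pAb <- pA - pAB; paB <- pB - pAB; pab <- 1 - pA - pB + pAB
    P <- matrix(0, 3, 3)
    P[3, 3] <- pAB^2;           P[3, 2] <- 2 * pAB * pAb; P[3, 1] <- pAb^2
    P[2, 3] <- 2 * pAB * paB;   P[2, 2] <- 2 * pAB * pab + 2 * pAb * paB
    P[2, 1] <- 2 * pAb * pab;   P[1, 3] <- paB^2
    P[1, 2] <- 2 * paB * pab;   P[1, 1] <- pab^2
    sum(tab[tab > 0] * log(pmax(P[tab > 0], 1e-300)))
  }
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, length.out = 2001)
  ll <- vapply(grid, loglik, numeric(1))
  best <- grid[which.max(ll)]
  span <- (hi - lo) / 2000
  opt <- optimize(loglik, c(max(lo, best - span), min(hi, best + span)),
                  maximum = TRUE, tol = 1e-12)
  pAB <- opt$maximum
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

## -- HWE exact-test oracle ---------------------------------------------------
## Full enumeration with plain factorials (valid for allele counts <= 80):
## P(nAB | nA, n) = n! 2^nAB nA! nB! / (nAA! nAB! nBB! (2n)!)
refHWE <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB; nB <- 2 * nBB + nAB
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  prob <- sapply(hets, function(h) {
    a <- (nA - h) / 2; b <- (nB - h) / 2
    factorial(n) * 2^h * factorial(nA) * factorial(nB) /
      (factorial(a) * factorial(h) * factorial(b) * factorial(2 * n))
  })
  pobs <- prob[hets == nAB]
  min(1, sum(prob[prob <= pobs * (1 + 1e-12)]))
}

## -- small fixture builders --------------------------------------------------
makeGeno <- function(codes, bp = NULL, chrom = "1") {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes)) && nrow(codes) > 0)
    rownames(codes) <- paste0("an", seq_len(nrow(codes)))
  m <- ncol(codes)
  if (is.null(bp)) bp <- seq_len(m) * 10000
  GenotypeData(codes,
               data.frame(snp = paste0("s", seq_len(m)),
                          chrom = rep_len(chrom, m), bp = bp,
                          alleleA = "A", alleleB = "B",
                          stringsAsFactors = FALSE))
}

## random genotype fixture with homozygous stretches, for scanner fuzzing
randomRohFixture <- function(seed) {
  set.seed(seed)
  n <- sample(4:20, 1)
  m <- sample(80:400, 1)
  nchr <- sample(1:3, 1)
  perchr <- ceiling(m / nchr)
  chrom <- rep(as.character(seq_len(nchr)), each = perchr)[seq_len(m)]
  ## chrom labels are already in sorted blocks, so per-chrom cumsums
  ## concatenate back in the original marker order
  bp <- as.integer(unlist(lapply(split(seq_len(m), chrom), function(ix)
    cumsum(sample(c(5000, 20000, 60000, 600000), length(ix), TRUE,
                  prob = c(0.4, 0.4, 0.15, 0.05))))))
  codes <- matrix(0L, n, m)
  for (a in seq_len(n)) {
    x <- sample(0:2, m, TRUE, prob = c(0.3, 0.3, 0.4))
    nruns <- sample(0:3, 1)
    for (r in seq_len(nruns)) {
      s <- sample(m, 1); len <- sample(10:120, 1)
      e <- min(m, s + len)
      x[s:e] <- sample(c(0L, 2L), 1)
      if (runif(1) < 0.5) x[sample(s:e, 1)] <- 1L       # isolated het
    }
    x[runif(m) < 0.01] <- NA
    codes[a, ] <- x
  }
  rownames(codes) <- paste0("an", seq_len(n))
  geno <- GenotypeData(codes, data.frame(snp = paste0("s", seq_len(m)),
                                         chrom = chrom, bp = bp,
                                         alleleA = "A", alleleB = "B",
                                         stringsAsFactors = FALSE))
  params <- rohParams(window_snp = sample(8:20, 1),
                      window_het = sample(0:1, 1),
                      window_missing = 1,
                      max_gap_kb = sample(c(100, 500), 1),
                      min_snp_in_run = sample(10:25, 1),
                      min_length_kb = sample(c(50, 200), 1),
                      min_density_kb_per_snp = 50,
                      window_hit_threshold = 0.05)
  list(geno = geno, params = params)
}

## deterministic two-column genotype matrix from 3x3 counts
genoFromTable <- function(tab) {
  x <- integer(0); y <- integer(0)
  for (i in 0:2) for (j in 0:2) {
    k <- tab[i + 1, j + 1]
    x <- c(x, rep(i, k)); y <- c(y, rep(j, k))
  }
  cbind(x, y)
}
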