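test_that("pairwise r2 handles the canonical LD configurations", {
  ## identical columns
  x <- c(0, 1, 2, 1, 0, 2, 2, 0)
  expect_equal(pairwiseR2(cbind(x, x), 1, 2)$r2, 1)
  ## phase-unambiguous perfect LD: no double heterozygote
  g <- rbind(c(2, 2), c(2, 2), c(0, 0), c(0, 0))
  expect_equal(pairwiseR2(g, 1, 2)$r2, 1)
  ## exact linkage equilibrium: balanced 3x3 table -> D = 0
  tab <- outer(c(1, 2, 1), c(1, 2, 1))
  g0 <- genoFromTable(tab)
  expect_equal(pairwiseR2(g0, 1, 2)$r2, 0, tolerance = 1e-12)
  ## monomorphic marker is flagged, not guessed
  expect_true(is.na(pairwiseR2(cbind(rep(2, 6), c(0, 1, 2, 0, 1, 2)),
                               1, 2)$r2))
})

test_that("EM r2 agrees with the likelihood-maximisation oracle", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    ## correlated pair via shared haplotype structure
    h1 <- rbinom(2 * n, 1, 0.5)
    h2 <- ifelse(runif(2 * n) < runif(1, 0.5, 1), h1, rbinom(2 * n, 1, 0.5))
    x <- h1[1:n] + h1[(n + 1):(2 * n)]
    y <- h2[1:n] + h2[(n + 1):(2 * n)]
    r2em <- pairwiseR2(cbind(x, y), 1, 2)$r2
    r2ref <- refR2(x, y)
    if (is.na(r2ref)) {
      expect_true(is.na(r2em))
    } else {
      expect_equal(r2em, r2ref, tolerance = 1e-6, info = paste("rep", rep))
    }
  }
})

test_that("greedy block finding follows the all-pairs rule within chromosomes", {
  set.seed(5)
  base <- rbinom(60, 2, 0.5)
  indep <- rbinom(60, 2, 0.5)
  codes <- cbind(base, base, base, indep)
  rownames(codes) <- paste0("a", 1:60)
  geno <- makeGeno(codes)
  blocks <- findBlocks(geno)
  expect_length(blocks, 1)
  expect_identical(blocks[[1]]$idx, 1:3)

  ## mutually independent SNPs -> no blocks
  set.seed(6)
  ind <- matrix(rbinom(240, 2, 0.5), 60, 4,
                dimnames = list(paste0("a", 1:60), NULL))
  expect_length(findBlocks(makeGeno(ind)), 0)

  ## perfect pairs on two chromosomes never merge across the boundary
  codes2 <- cbind(base, base, indep, indep)
  rownames(codes2) <- paste0("a", 1:60)
  geno2 <- GenotypeData(codes2,
    data.frame(snp = paste0("s", 1:4), chrom = c("1", "1", "2", "2"),
               bp = c(100, 200, 100, 200), alleleA = "A", alleleB = "B"))
  blocks2 <- findBlocks(geno2)
  expect_length(blocks2, 2)
  expect_identical(lapply(blocks2, `[[`, "chrom"), list("1", "2"))
})

test_that("block haplotype EM resolves phase and is order invariant", {
  ## all-homozygous block: frequencies are direct counts
  g <- rbind(c(2, 2), c(2, 2), c(0, 0), c(2, 2))
  rownames(g) <- paste0("a", 1:4)
  bh <- inferBlockHaplotypes(g, 1:2)
  expect_equal(unname(bh$freq[c("AA", "BB")]), c(0.75, 0.25))
  expect_identical(unname(bh$diplotypes[3, ]), c("BB", "BB"))

  ## a single double heterozygote among unambiguous animals takes the
  ## phase of the dominant haplotypes (closed-form 2-locus EM fixed point)
  g2 <- rbind(matrix(rep(c(2, 2), 6), 6, 2, byrow = TRUE),
              matrix(rep(c(0, 0), 6), 6, 2, byrow = TRUE),
              c(1, 1))
  rownames(g2) <- paste0("a", 1:13)
  bh2 <- inferBlockHaplotypes(g2, 1:2)
  expect_identical(sort(unname(bh2$diplotypes[13, ])), c("AA", "BB"))
  expect_gt(bh2$freq[["AA"]], 0.4)

  ## shuffling animals leaves the frequencies untouched
  perm <- c(7, 1, 13, 3, 2, 12, 5, 9, 4, 11, 8, 10, 6)
  bh3 <- inferBlockHaplotypes(g2[perm, ], 1:2)
  expect_equal(bh3$freq, bh2$freq, tolerance = 1e-12)

  ## animals with missing data get missing diplotypes
  g4 <- g2; g4[2, 1] <- NA
  bh4 <- inferBlockHaplotypes(g4, 1:2)
  expect_true(all(is.na(bh4$diplotypes[2, ])))
})

test_that("pseudo-SNP recoding keeps frequent haplotypes and sums to 2", {
  set.seed(8)
  hapPool <- c("AA", "AB")
  picks <- matrix(sample(hapPool, 120, TRUE, prob = c(0.6, 0.4)), 60, 2)
  g <- t(apply(picks, 1, function(p) {
    a <- as.integer(strsplit(p[1], "")[[1]] == "A")
    b <- as.integer(strsplit(p[2], "")[[1]] == "A")
    a + b
  }))
  rownames(g) <- paste0("a", 1:60)
  bh <- inferBlockHaplotypes(g, 1:2)
  ps <- recodePseudoSNP(list(bh), min_freq = 0.01)
  expect_equal(ncol(genotypes(ps)), 2)
  expect_true(all(rowSums(genotypes(ps)) == 2))
  ## rare haplotype below 1% gets no column
  bhRare <- bh
  bhRare$freq <- c(AA = 0.6, AB = 0.395, BB = 0.005)
  bhRare$haplotypes <- c("AA", "AB", "BB")
  ps2 <- recodePseudoSNP(list(bhRare), min_freq = 0.01)
  expect_false("BB" %in% markers(ps2)$haplotype)
})

test_that("pseudo-SNP codes recover true copy counts on simulated phase", {
  cfg <- simConfig(n_animals = 200, n_founders = 60, n_chromosomes = 2,
                   snps_per_chromosome = 300, seed = 21)
  sim <- simulateGenotypes(cfg)
  blocks <- findBlocks(sim$geno)
  expect_gt(length(blocks), 0)
  mk <- markers(sim$geno)
  m <- cfg$snps_per_chromosome
  hits <- 0; total <- 0
  for (b in blocks[seq_len(min(5, length(blocks)))]) {
    bh <- inferBlockHaplotypes(sim$geno, b$idx)
    ch <- as.integer(b$chrom)
    within <- b$idx - (ch - 1) * m
    H <- sim$haplotypes[[ch]]
    n <- nrow(genotypes(sim$geno))
    trueHaps <- vapply(seq_len(n), function(a) {
      h1 <- paste(ifelse(H[2 * a - 1, within] == 1, "A", "B"), collapse = "")
      h2 <- paste(ifelse(H[2 * a, within] == 1, "A", "B"), collapse = "")
      paste(sort(c(h1, h2)), collapse = "|")
    }, character(1))
    called <- vapply(seq_len(n), function(a)
      paste(sort(bh$diplotypes[a, ]), collapse = "|"), character(1))
    ## unambiguous animals: at most one heterozygous site in the block
    nhet <- rowSums(genotypes(sim$geno)[, b$idx, drop = FALSE] == 1)
    unamb <- which(nhet <= 1)
    hits <- hits + sum(called[unamb] == trueHaps[unamb])
    total <- total + length(unamb)
  }
  expect_gte(hits / total, 0.99)
})
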