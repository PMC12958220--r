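test_that("constructed homozygous stretches are found exactly once", {
  p <- rohParams(window_snp = 50, min_snp_in_run = 100,
                 min_length_kb = 500, min_density_kb_per_snp = 50)
  ## 300 SNPs at 10 kb spacing: homozygous at 1-150, heterozygous after
  g <- c(rep(2L, 150), rep(1L, 150))
  geno <- makeGeno(matrix(g, 1, 300, dimnames = list("an1", NULL)),
                   bp = seq_len(300) * 10000)
  seg <- scanRoh(geno, p)
  expect_equal(nrow(seg), 1)
  expect_lte(seg$start, 10000 * 10)      # starts near the chromosome start
  expect_gte(seg$end, 150 * 10000 - 10 * 10000)
  expect_identical(seg, refScanRoh(geno, p))

  ## an isolated heterozygote inside the run is absorbed (window_het = 1)
  g2 <- g; g2[75] <- 1L
  geno2 <- makeGeno(matrix(g2, 1, 300, dimnames = list("an1", NULL)),
                    bp = seq_len(300) * 10000)
  seg2 <- scanRoh(geno2, p)
  expect_equal(nrow(seg2), 1)
  expect_identical(seg2, refScanRoh(geno2, p))

  ## an animal heterozygous everywhere has no runs
  allhet <- makeGeno(matrix(1L, 1, 300, dimnames = list("an1", NULL)),
                     bp = seq_len(300) * 10000)
  expect_equal(nrow(scanRoh(allhet, p)), 0)
})

test_that("scanner equals the literal window-by-window reference on random fixtures", {
  for (seed in 1:50) {
    fx <- randomRohFixture(seed)
    got <- scanRoh(fx$geno, fx$params)
    ref <- refScanRoh(fx$geno, fx$params)
    o <- function(d) d[order(d$animal_id, d$chrom, d$start), , drop = FALSE]
    got <- o(got); ref <- o(ref)
    rownames(got) <- rownames(ref) <- NULL
    expect_equal(got, ref, info = paste("fixture", seed))
  }
})

test_that("segments respect the gap rule and X is excluded", {
  set.seed(77)
  fx <- randomRohFixture(99)
  seg <- scanRoh(fx$geno, fx$params)
  mk <- markers(fx$geno)
  for (i in seq_len(nrow(seg))) {
    memb <- mk$bp[mk$chrom == seg$chrom[i] &
                  mk$bp >= seg$start[i] & mk$bp <= seg$end[i]]
    if (length(memb) > 1)
      expect_true(all(diff(memb) <= fx$params$max_gap_kb * 1000))
  }
  ## X chromosome dropped case-insensitively
  g <- matrix(2L, 2, 100, dimnames = list(c("a1", "a2"), NULL))
  genoX <- GenotypeData(g, data.frame(snp = paste0("s", 1:100),
                                      chrom = "x", bp = (1:100) * 10000,
                                      alleleA = "A", alleleB = "B"))
  p <- rohParams(window_snp = 10, min_snp_in_run = 10, min_length_kb = 50)
  expect_equal(nrow(scanRoh(genoX, p)), 0)
})

test_that("pooling clusters by single linkage with reciprocal overlap", {
  seg <- function(id, s, e) data.frame(animal_id = id, chrom = "1",
                                       start = s, end = e,
                                       n_snps = 100,
                                       length_kb = (e - s + 1) / 1000,
                                       stringsAsFactors = FALSE)
  ## identical segments in two animals -> one locus, two carriers
  inc <- poolRoh(rbind(seg("a", 1e6, 2e6), seg("b", 1e6, 2e6)))
  expect_equal(ncol(genotypes(inc)), 1)
  expect_equal(rohLoci(inc)$nCarriers, 2)
  ## disjoint segments -> two loci, one carrier each
  inc2 <- poolRoh(rbind(seg("a", 1e6, 2e6), seg("b", 5e6, 6e6)))
  expect_equal(ncol(genotypes(inc2)), 2)
  expect_equal(rohLoci(inc2)$nCarriers, c(1, 1))
  ## chain A-B-C: A and C below threshold but linked through B
  chain <- rbind(seg("a", 1.00e6, 2.00e6),
                 seg("b", 1.02e6, 2.02e6),
                 seg("c", 1.04e6, 2.04e6))
  inc3 <- poolRoh(chain, overlap_min = 0.97)
  expect_equal(ncol(genotypes(inc3)), 1)
  expect_equal(rohLoci(inc3)$nCarriers, 3)
  ## incidence invariants: no all-zero column, all animals carry >= 1
  expect_true(all(colSums(genotypes(inc3)) >= 1))
  expect_true(all(rowSums(genotypes(inc3)) >= 1))
  ## empty input warns and returns an empty matrix
  expect_warning(empty <- poolRoh(seg("a", 1, 2)[0, ]), "no ROH")
  expect_equal(dim(genotypes(empty)), c(0, 0))
})

test_that("ROH summary reports count, length and coverage per animal", {
  seg <- data.frame(animal_id = "a1", chrom = "1", start = 1,
                    end = 2e6, n_snps = 120, length_kb = 2000,
                    stringsAsFactors = FALSE)
  s <- rohSummary(seg)
  expect_equal(s$perAnimal$n_roh, 1)
  expect_equal(s$perAnimal$mean_length_mb, 2)
  expect_equal(s$perAnimal$coverage_mb, 2)
  expect_equal(nrow(rohSummary(seg[0, ])$perAnimal), 0)
})

test_that("inbreeding raises ROH burden (matched seeds)", {
  p <- rohParams(min_snp_in_run = 50, min_length_kb = 500)
  covFor <- function(inbred, gens = 4) {
    cfg <- simConfig(n_animals = 120, n_founders = 40, n_chromosomes = 3,
                     snps_per_chromosome = 300, chromosome_length_bp = 1.2e7,
                     inbred_fraction = inbred, n_generations = gens,
                     n_hys_levels = 4, seed = 33)
    seg <- scanRoh(simulateGenotypes(cfg)$geno, p)
    if (nrow(seg) == 0) return(c(n = 0, cov = 0))
    s <- rohSummary(seg)$perAnimal
    c(n = sum(s$n_roh) / 120, cov = sum(s$coverage_mb) / 120)
  }
  low <- covFor(0); mid <- covFor(0.4); high <- covFor(0.8)
  expect_lt(low[["cov"]], mid[["cov"]])
  expect_lt(mid[["cov"]], high[["cov"]])
  ## founders from a large pool, one generation, no inbred matings
  cfgU <- simConfig(n_animals = 120, n_founders = 120, n_chromosomes = 3,
                    snps_per_chromosome = 300, chromosome_length_bp = 1.2e7,
                    haplotype_pool_size = 60,
                    inbred_fraction = 0, n_generations = 1,
                    n_hys_levels = 4, seed = 33)
  segU <- scanRoh(simulateGenotypes(cfgU)$geno, p)
  nU <- if (nrow(segU)) sum(rohSummary(segU)$perAnimal$n_roh) / 120 else 0
  expect_lt(nU, mid[["n"]])
})
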