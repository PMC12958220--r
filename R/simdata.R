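## Forward simulator of a half-sib/inbred cattle-like population: founders
## draw chromosome haplotypes from a small pool (creating block-wise LD),
## descendants are produced by gene dropping with recombination, and a
## configurable fraction of matings is between half/full sibs so that long
## autozygous tracts (ROH) arise.  Phenotypes follow the decomposition
## herd-year-season + age + age^2 + SNP effects + haplotype-block effects
## + directional ROH effects + residual.

#' Simulation configuration
#'
#' @param n_founders founder animals in generation 0.
#' @param n_generations gene-dropping generations after the founders; 0
#'   returns the founders themselves.
#' @param n_animals animals in the final (genotyped, phenotyped)
#'   generation.
#' @param n_chromosomes,snps_per_chromosome,chromosome_length_bp genome
#'   layout; markers are evenly spaced.
#' @param recombination_rate_per_bp probability of crossover per bp per
#'   meiosis (expected crossovers = rate x length).
#' @param inbred_fraction fraction of matings between half/full sibs.
#' @param haplotype_pool_size distinct founder haplotypes per chromosome;
#'   a small pool creates block-wise LD.
#' @param n_hys_levels,min_per_hys herd-year-season levels; levels are
#'   assigned round-robin then shuffled so each has at least `min_per_hys`
#'   animals.
#' @param age_range_months uniform range of age at first calving.
#' @param beta_age,beta_age2 linear and quadratic age effects.
#' @param var_snp,var_hap,var_roh,var_resid realized variances of the
#'   additive SNP, haplotype-block, ROH-linked, and residual components.
#' @param var_hys variance of the herd-year-season level effects.
#' @param missing_rate fraction of genotype calls set to missing.
#' @param seed global seed; every operation derives a named substream.
#' @return list of class `sim_config`.
#' @export
simConfig <- function(n_founders = 80, n_generations = 4, n_animals = 400,
                      n_chromosomes = 10, snps_per_chromosome = 500,
                      chromosome_length_bp = 2.5e7,
                      recombination_rate_per_bp = 1e-8,
                      inbred_fraction = 0.3, haplotype_pool_size = 8,
                      n_hys_levels = 10, min_per_hys = 20,
                      age_range_months = c(20, 36),
                      beta_age = 0.5, beta_age2 = -0.01,
                      var_snp = 1, var_hap = 0.5, var_roh = 0.5,
                      var_resid = 1, var_hys = 1, missing_rate = 0,
                      seed = 1) {
  cfg <- list(n_founders = n_founders, n_generations = n_generations,
              n_animals = n_animals, n_chromosomes = n_chromosomes,
              snps_per_chromosome = snps_per_chromosome,
              chromosome_length_bp = chromosome_length_bp,
              recombination_rate_per_bp = recombination_rate_per_bp,
              inbred_fraction = inbred_fraction,
              haplotype_pool_size = haplotype_pool_size,
              n_hys_levels = n_hys_levels, min_per_hys = min_per_hys,
              age_range_months = age_range_months,
              beta_age = beta_age, beta_age2 = beta_age2,
              var_snp = var_snp, var_hap = var_hap, var_roh = var_roh,
              var_resid = var_resid, var_hys = var_hys,
              missing_rate = missing_rate, seed = seed)
  if (cfg$n_animals < cfg$n_hys_levels * cfg$min_per_hys)
    stop("n_animals must be at least n_hys_levels x min_per_hys")
  if (any(c(cfg$var_snp, cfg$var_hap, cfg$var_roh) < 0) ||
      cfg$var_resid <= 0)
    stop("variances must be non-negative and var_resid positive")
  if (cfg$recombination_rate_per_bp < 0 || cfg$inbred_fraction < 0 ||
      cfg$inbred_fraction > 1)
    stop("recombination rate and inbred_fraction must be valid")
  structure(cfg, class = "sim_config")
}

## named substream: derive a 31-bit seed from the global seed and a label
.substreamSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  (as.integer(seed) %% 1000003L) * 2011L + h %% 1000003L
}

## one gamete from a parent's two haplotypes over one chromosome
.gamete <- function(h1, h2, bp, expCross) {
  ncross <- rpois(1, expCross)
  phase <- sample(1:2, 1)
  if (ncross == 0) return(if (phase == 1) h1 else h2)
  cuts <- sort(runif(ncross, min(bp), max(bp)))
  seg <- findInterval(bp, cuts)           # 0..ncross
  use1 <- (seg + phase) %% 2 == 0
  out <- h2
  out[use1] <- h1[use1]
  out
}

#' Simulate genotypes by gene dropping
#'
#' Founders draw chromosome haplotypes from a finite pool (block-wise LD);
#' each later generation is bred from the previous one with crossovers at
#' `recombination_rate_per_bp`, and an `inbred_fraction` of matings pairs
#' half or full sibs, creating long homozygous tracts.  The final
#' generation is returned as the study population.
#'
#' @param config a [simConfig()] list.
#' @return list with `geno` (a [GenotypeData-class]), `pedigree`
#'   (data.frame id, sire, dam, generation), and `haplotypes` (list per
#'   chromosome of 2n x SNPs 0/1 matrices for the final generation; 1 =
#'   allele A).
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substreamSeed(config$seed, "genotypes"))
  nc <- config$n_chromosomes
  m <- config$snps_per_chromosome
  spacing <- floor(config$chromosome_length_bp / m)
  bp <- spacing * seq_len(m)
  expCross <- config$recombination_rate_per_bp * config$chromosome_length_bp
  ## founder haplotype pool: per chromosome, pool_size binary haplotypes
  pools <- lapply(seq_len(nc), function(ch) {
    p <- runif(m, 0.1, 0.9)
    pool <- matrix(rbinom(config$haplotype_pool_size * m, 1,
                          rep(p, each = config$haplotype_pool_size)),
                   nrow = config$haplotype_pool_size, byrow = FALSE)
    pool
  })
  nF <- if (config$n_generations == 0) config$n_animals else
    config$n_founders
  sizes <- c(nF,
             rep(config$n_founders, max(config$n_generations - 1, 0)),
             if (config$n_generations >= 1) config$n_animals)
  gens <- length(sizes) - 1L
  haps <- lapply(seq_len(nc), function(ch) {
    idx <- sample(config$haplotype_pool_size, 2 * nF, replace = TRUE)
    pools[[ch]][idx, , drop = FALSE]
  })
  ped <- data.frame(id = paste0("G0_", seq_len(nF)),
                    sire = NA_character_, dam = NA_character_,
                    generation = 0L, stringsAsFactors = FALSE)
  curIds <- ped$id
  curSire <- ped$sire; curDam <- ped$dam
  for (g in seq_len(gens)) {
    nOff <- sizes[g + 1L]
    nPar <- length(curIds)
    offSire <- integer(nOff); offDam <- integer(nOff)
    for (o in seq_len(nOff)) {
      s <- sample(nPar, 1)
      d <- NA_integer_
      if (runif(1) < config$inbred_fraction && g > 1) {
        share <- which((curSire == curSire[s] | curDam == curDam[s]) &
                       seq_len(nPar) != s &
                       !is.na(curSire) & !is.na(curDam))
        if (length(share)) d <- share[sample.int(length(share), 1)]
      }
      if (is.na(d)) {
        repeat { d <- sample(nPar, 1); if (d != s) break }
      }
      offSire[o] <- s; offDam[o] <- d
    }
    newHaps <- lapply(seq_len(nc), function(ch) {
      H <- haps[[ch]]
      out <- matrix(0L, 2 * nOff, m)
      for (o in seq_len(nOff)) {
        s <- offSire[o]; d <- offDam[o]
        out[2 * o - 1L, ] <- .gamete(H[2 * s - 1L, ], H[2 * s, ], bp, expCross)
        out[2 * o, ] <- .gamete(H[2 * d - 1L, ], H[2 * d, ], bp, expCross)
      }
      out
    })
    ids <- paste0("G", g, "_", seq_len(nOff))
    ped <- rbind(ped, data.frame(id = ids, sire = curIds[offSire],
                                 dam = curIds[offDam], generation = g,
                                 stringsAsFactors = FALSE))
    haps <- newHaps
    curSire <- curIds[offSire]; curDam <- curIds[offDam]
    curIds <- ids
  }
  n <- length(curIds)
  codes <- matrix(0L, n, nc * m)
  for (ch in seq_len(nc)) {
    H <- haps[[ch]]
    codes[, (ch - 1) * m + seq_len(m)] <-
      H[2 * seq_len(n) - 1L, , drop = FALSE] +
      H[2 * seq_len(n), , drop = FALSE]
  }
  if (config$missing_rate > 0) {
    miss <- runif(length(codes)) < config$missing_rate
    codes[miss] <- NA_integer_
  }
  rownames(codes) <- curIds
  mk <- data.frame(snp = paste0("snp", seq_len(nc * m)),
                   chrom = as.character(rep(seq_len(nc), each = m)),
                   bp = rep(bp, nc),
                   alleleA = "A", alleleB = "B", stringsAsFactors = FALSE)
  list(geno = GenotypeData(codes, mk), pedigree = ped, haplotypes = haps)
}

## rescale a component so its population variance is exactly target
.rescaleVar <- function(x, target) {
  if (target == 0) return(numeric(length(x)))
  v <- mean((x - mean(x))^2)
  if (v < 1e-300) stop("component has zero variance; cannot scale")
  x * sqrt(target / v)
}

#' Simulate phenotypes over the genomic features
#'
#' y = HYS + beta_age AGE + beta_age2 AGE^2 + Z_snp a + Z_hap b + R c + e.
#' SNP and haplotype effects act on centered/standardized feature columns;
#' ROH effects are directional (all negative, mimicking an
#' inbreeding-depression-like signal).  Each genetic component is rescaled
#' so its realized population variance equals the configured target; the
#' truth record stores the realized variances and effect vectors.
#'
#' @param geno a [GenotypeData-class].
#' @param pseudo a [PseudoSNPData-class] (haplotype-block copy counts) or
#'   NULL when `var_hap` is 0.
#' @param roh a [ROHIncidence-class] or NULL when `var_roh` is 0; animals
#'   missing from the incidence get a 0 ROH component.
#' @param config a [simConfig()] list.
#' @return list with `pheno` (data.frame: animal_id, value, hys,
#'   age_months) and `truth` (realized variances, effect vectors, and the
#'   genetic component vectors).
#' @export
simulatePhenotypes <- function(geno, pseudo = NULL, roh = NULL, config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- animalIds(geno)
  n <- length(ids)
  if (!is.null(pseudo) && !identical(animalIds(pseudo), ids))
    stop("pseudo-SNP matrix is not aligned to the genotype animals")
  if (!is.null(roh) && !all(animalIds(roh) %in% ids))
    stop("ROH incidence contains animals absent from the genotypes")
  set.seed(.substreamSeed(config$seed, "phenotypes"))
  ## herd-year-season: round-robin then shuffled
  lev <- paste0("hys", seq_len(config$n_hys_levels))
  hys <- sample(rep_len(lev, n))
  hysEff <- rnorm(config$n_hys_levels, 0, sqrt(config$var_hys))
  names(hysEff) <- lev
  age <- runif(n, config$age_range_months[1], config$age_range_months[2])
  std <- function(M) {
    M <- .meanImpute(M)
    M <- sweep(M, 2, colMeans(M))
    s <- sqrt(colMeans(M^2))
    keep <- s > 1e-12
    sweep(M[, keep, drop = FALSE], 2, s[keep], "/")
  }
  gSnp <- gHap <- gRoh <- numeric(n)
  aEff <- bEff <- cEff <- numeric(0)
  if (config$var_snp > 0) {
    Z <- std(apply(genotypes(geno), 2, as.numeric))
    aEff <- rnorm(ncol(Z)) / sqrt(ncol(Z))
    gSnp <- .rescaleVar(drop(Z %*% aEff), config$var_snp)
  }
  if (config$var_hap > 0) {
    if (is.null(pseudo)) stop("var_hap > 0 requires a pseudo-SNP matrix")
    Zh <- std(apply(genotypes(pseudo), 2, as.numeric))
    bEff <- rnorm(ncol(Zh)) / sqrt(ncol(Zh))
    gHap <- .rescaleVar(drop(Zh %*% bEff), config$var_hap)
  }
  if (config$var_roh > 0) {
    if (is.null(roh)) stop("var_roh > 0 requires a ROH incidence matrix")
    R <- matrix(0, n, ncol(genotypes(roh)), dimnames = list(ids, NULL))
    R[animalIds(roh), ] <- genotypes(roh)
    cEff <- -abs(rnorm(ncol(R))) / sqrt(max(ncol(R), 1))  # directional
    gRoh <- .rescaleVar(drop(R %*% cEff), config$var_roh)
  }
  e <- rnorm(n, 0, sqrt(config$var_resid))
  y <- hysEff[hys] + config$beta_age * age + config$beta_age2 * age^2 +
    gSnp + gHap + gRoh + e
  pvar <- function(x) mean((x - mean(x))^2)
  truth <- list(var_snp = pvar(gSnp), var_hap = pvar(gHap),
                var_roh = pvar(gRoh), var_resid_realized = pvar(e),
                var_resid = config$var_resid,
                effects = list(snp = aEff, hap = bEff, roh = cEff,
                               hys = hysEff),
                components = list(g_snp = gSnp, g_hap = gHap, g_roh = gRoh,
                                  e = e))
  pheno <- data.frame(animal_id = ids, value = unname(y), hys = hys,
                      age_months = age, stringsAsFactors = FALSE)
  list(pheno = pheno, truth = truth)
}

#' Write a simulated data set to disk
#'
#' PLINK bed/bim/fam for the genotypes, a phenotype CSV, and a truth JSON.
#'
#' @param sim result of [simulateGenotypes()].
#' @param phe result of [simulatePhenotypes()].
#' @param prefix output path prefix.
#' @export
writeSimulation <- function(sim, phe, prefix) {
  writePlink(sim$geno, prefix)
  writePhenotypes(phe$pheno, paste0(prefix, "_pheno.csv"))
  tr <- phe$truth
  jsonlite::write_json(
    list(var_snp = tr$var_snp, var_hap = tr$var_hap, var_roh = tr$var_roh,
         var_resid = tr$var_resid),
    paste0(prefix, "_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
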