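## small simulated data set shared across sampler tests
.sampGeno <- function(n = 200, seed = 19) {
  cfg <- simConfig(n_animals = n, n_founders = 60, n_chromosomes = 2,
                   snps_per_chromosome = 250, n_hys_levels = 5,
                   min_per_hys = 10, seed = seed)
  simulateGenotypes(cfg)
}

.sampPheno <- function(geno, seed = 19) {
  set.seed(seed)
  ids <- animalIds(geno)
  data.frame(animal_id = ids,
             hys = sample(paste0("h", 1:5), length(ids), TRUE),
             age_months = runif(length(ids), 20, 36),
             stringsAsFactors = FALSE)
}

test_that("chain bookkeeping and determinism", {
  expect_identical(retainedDraws(100000, 30000, 5), 14000L)
  sim <- .sampGeno(60)
  ph <- .sampPheno(sim$geno)
  ph$value <- rnorm(60)
  sp <- modelSpec(ph, mcmc = list(n_iter = 700, burn_in = 200, thin = 5,
                                  seed = 2))
  fit <- fitMKModel(ph$value, sp)
  expect_identical(fit$summary@nRetained, retainedDraws(700, 200, 5))
  ## fixed seed reproduces chains bit-identically
  fit2 <- fitMKModel(ph$value, sp)
  expect_identical(fit$chains$var, fit2$chains$var)
  expect_identical(fit$chains$beta, fit2$chains$beta)
  expect_error(modelSpec(ph, mcmc = list(n_iter = 100, burn_in = 200)))
})

test_that("zero-kernel model recovers the least-squares fixed effects", {
  sim <- .sampGeno(200)
  ph <- .sampPheno(sim$geno)
  set.seed(23)
  ph$value <- 3 + 0.4 * ph$age_months +
    c(h1 = 0, h2 = 1, h3 = -1, h4 = 2, h5 = 0.5)[ph$hys] + rnorm(200)
  sp <- modelSpec(ph, mcmc = list(n_iter = 4000, burn_in = 1000, thin = 2,
                                  seed = 3))
  fit <- fitMKModel(ph$value, sp)
  ## closed-form least squares on the same design
  bls <- drop(solve(crossprod(sp$X), crossprod(sp$X, ph$value)))
  se <- apply(fit$chains$beta, 2, sd) / sqrt(nrow(fit$chains$beta) / 5)
  expect_true(all(abs(fit$postMean$beta - bls) < 4 * se + 1e-8))
  expect_gt(cor(fit$postMean$beta, bls), 0.999)
})

test_that("with variances fixed the posterior mean of u equals BLUP", {
  sim <- .sampGeno(200)
  K <- linearKernel(sim$geno)
  ph <- .sampPheno(sim$geno)
  set.seed(29)
  L <- t(chol(kernelMatrix(K) + diag(1e-6, 200)))
  u <- drop(L %*% rnorm(200))
  ph$value <- 1 + u + rnorm(200)
  sp <- modelSpec(ph, kernels = list(K),
                  mcmc = list(n_iter = 6000, burn_in = 1000, thin = 5,
                              seed = 5),
                  fix_variances = c(1, 1))
  fit <- fitMKModel(ph$value, sp, keep_g = TRUE)
  ## closed form: joint (beta, u) mixed-model solve at varU = varE = 1
  X <- sp$X
  Kj <- kernelMatrix(K) + diag(1e-8, 200)
  Kinv <- solve(Kj)
  C <- rbind(cbind(crossprod(X), t(X)),
             cbind(X, diag(200) + Kinv))
  sol <- solve(C, c(crossprod(X, ph$value), ph$value))
  blup <- sol[-(1:ncol(X))]
  ## batch-means Monte Carlo SE per coordinate
  gch <- fit$chains$g[[1]]
  nb <- 20; bs <- nrow(gch) / nb
  bm <- sapply(seq_len(nb), function(b)
    colMeans(gch[((b - 1) * bs + 1):(b * bs), , drop = FALSE]))
  mcse <- apply(bm, 1, sd) / sqrt(nb)
  within <- abs(fit$postMean$g[[1]] - blup) <= 3 * mcse + 1e-6
  expect_gte(mean(within), 0.95)
  expect_gt(cor(fit$postMean$g[[1]], blup), 0.995)
})

test_that("identity kernel reduces to the ridge closed form", {
  n <- 150
  set.seed(31)
  ph <- data.frame(animal_id = paste0("r", 1:n),
                   hys = sample(paste0("h", 1:3), n, TRUE),
                   age_months = runif(n, 20, 36), stringsAsFactors = FALSE)
  K <- diag(n); dimnames(K) <- list(ph$animal_id, ph$animal_id)
  KI <- new("GenomicKernel", matrix = K, kind = "linear", source = "SNP",
            param = list(k = n))
  ph$value <- 2 + rnorm(n) + rnorm(n)
  sp <- modelSpec(ph, kernels = list(KI),
                  mcmc = list(n_iter = 6000, burn_in = 1000, thin = 5,
                              seed = 7),
                  fix_variances = c(1.5, 1))
  fit <- fitMKModel(ph$value, sp)
  X <- sp$X
  C <- rbind(cbind(crossprod(X) / 1, t(X) / 1),
             cbind(X / 1, diag(n) / 1 + diag(n) / 1.5))
  sol <- solve(C, c(crossprod(X, ph$value), ph$value))
  ridge <- sol[-(1:ncol(X))]
  expect_gt(cor(fit$postMean$g[[1]], ridge), 0.995)
  expect_lt(mean(abs(fit$postMean$g[[1]] - ridge)), 0.05)
})

test_that("destroying the phenotype-kernel link empties the genetic variance", {
  sim <- .sampGeno(150, seed = 37)
  K <- linearKernel(sim$geno)
  ph <- .sampPheno(sim$geno, seed = 37)
  set.seed(41)
  L <- t(chol(kernelMatrix(K) + diag(1e-6, 150)))
  ph$value <- drop(L %*% rnorm(150)) * 2 + rnorm(150, sd = 0.5)
  mc <- list(n_iter = 3000, burn_in = 1000, thin = 2, seed = 9)
  fit <- fitMKModel(ph$value, modelSpec(ph, list(K), mcmc = mc))
  phP <- ph
  set.seed(43); phP$value <- sample(ph$value)
  fitP <- fitMKModel(phP$value, modelSpec(phP, list(K), mcmc = mc))
  vG <- varComponents(fit$summary)$mean
  vGP <- varComponents(fitP$summary)$mean
  expect_lt(vGP, 0.35 * vG)
})

test_that("heritability and variance partition are draw-wise arithmetic", {
  h <- heritabilityDraws(rep(1, 100), rep(1, 100))
  expect_equal(h$mean, 0.5); expect_equal(h$sd, 0)
  expect_equal(heritabilityDraws(rep(0, 10), rep(2, 10))$mean, 0)
  G <- matrix(rep(c(1, 1, 2), each = 50), 50, 3,
              dimnames = list(NULL, c("SNP", "HAP", "ROH")))
  h3 <- heritabilityDraws(G, rep(4, 50))
  expect_equal(h3$mean, 0.5)
  vp <- variancePartition(G)
  expect_equal(vp$pctMean, c(25, 25, 50))
  expect_equal(variancePartition(matrix(c(3, 1), 50, 2, byrow = TRUE,
                                        dimnames = list(NULL, c("a", "b"))))$pctMean,
               c(75, 25))
  ## single kernel always explains 100%
  expect_equal(variancePartition(matrix(rchisq(20, 3), 20, 1,
                                        dimnames = list(NULL, "SNP")))$pctMean,
               100)
})

test_that("goodness of fit is the squared correlation with sane edges", {
  y <- rnorm(50)
  expect_equal(goodnessOfFit(y, y), 1)
  expect_equal(goodnessOfFit(y, rep(2, 50)), 0)
  set.seed(51)
  y2 <- rnorm(20000)
  expect_equal(goodnessOfFit(y2, y2 + rnorm(20000)), 0.5, tolerance = 0.03)
})

test_that("rank-deficient designs are refused with the offending column named", {
  ph <- data.frame(animal_id = paste0("a", 1:30), value = rnorm(30),
                   hys = "h1", age_months = 24, stringsAsFactors = FALSE)
  ## constant age makes age2 collinear with the intercept
  sp <- modelSpec(ph, mcmc = list(n_iter = 50, burn_in = 10, thin = 1))
  expect_error(fitMKModel(ph$value, sp), "rank deficient")
})
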