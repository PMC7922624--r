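test_that("identity-V scan reduces to ordinary least squares", {
  set.seed(51)
  n <- 80
  y <- rnorm(n)
  M <- matrix(rbinom(n * 20, 2, 0.4), n, 20)
  G <- diag(1, n)
  sc <- mlmaScan(y, M, list(g = G), c(g = 0, residual = 1))
  ## oracle: explicit projection with X0 = intercept, V = I
  X0 <- matrix(1, n, 1)
  P0 <- diag(n) - X0 %*% solve(crossprod(X0), t(X0))
  for (j in c(1, 7, 20)) {
    m <- M[, j]
    bO <- sum(m * (P0 %*% y)) / sum(m * (P0 %*% m))
    expect_equal(sc$effect[j], bO, tolerance = 1e-8)
    expect_equal(sc$t[j], bO * sqrt(sum(m * (P0 %*% m))), tolerance = 1e-8)
    ## effect estimate agrees with lm() to numerical precision
    expect_equal(bO, unname(coef(lm(y ~ m))["m"]), tolerance = 1e-8)
  }
})

test_that("monomorphic and covariate-aliased markers return NA with a reason", {
  set.seed(52)
  n <- 60
  y <- rnorm(n)
  breed <- rbinom(n, 4, 0.5) / 4
  M <- cbind(mono = rep(2, n), dup = breed, ok = rbinom(n, 2, 0.5))
  sc <- mlmaScan(y, M, list(g = diag(1, n)), c(g = 0, residual = 1),
                 X0 = cbind(1, breed))
  expect_identical(sc$reason, c("monomorphic", "aliased", NA))
  expect_true(is.na(sc$p[1]) && is.na(sc$p[2]) && !is.na(sc$p[3]))
})

test_that("conditioning on a perfect tag wipes out the causal signal", {
  set.seed(53)
  d <- grmModelData(n = 500, m = 300, h2 = 0.3, seed = 53)
  causal <- d$W[, 5]
  y <- d$y + causal * sqrt(0.3 / var(causal))   # strong marker effect
  vc <- remlFit(y, list(g = d$G))
  M <- cbind(causal = causal, other = d$W[, 200])
  un <- mlmaScan(y, M, list(g = d$G), vc)
  expect_lt(un$p[1], 1e-8)
  cond <- conditionalScan(y, M, list(g = d$G), vc,
                          conditioningMarker = causal)
  expect_true(is.na(cond$p[1]))       # self-conditioning -> aliased
  tag <- causal                        # r2 = 1 tag
  cond2 <- conditionalScan(y, M, list(g = d$G), vc, conditioningMarker = tag)
  expect_true(is.na(cond2$p[1]) || cond2$p[1] > 1e-3)
})

test_that("conditioning on an independent marker barely moves null p-values", {
  set.seed(54)
  d <- grmModelData(n = 400, m = 300, h2 = 0.4, seed = 54)
  vc <- remlFit(d$y, list(g = d$G))
  Mnull <- matrix(rbinom(400 * 200, 2, 0.3), 400, 200)
  indep <- rbinom(400, 2, 0.5)
  a <- mlmaScan(d$y, Mnull, list(g = d$G), vc)
  b <- conditionalScan(d$y, Mnull, list(g = d$G), vc,
                       conditioningMarker = indep)
  dlp <- abs(log10(a$p) - log10(b$p))
  expect_lt(median(dlp, na.rm = TRUE), 0.1)
})

test_that("t-correlation matrix behaves like a correlation matrix", {
  set.seed(55)
  tm <- matrix(rnorm(3000), 1000, 3)
  V <- tCorrelation(cbind(tm, tm[, 1]))
  expect_equal(V[1, 4], 1, tolerance = 1e-12)
  expect_equal(diag(V), rep(1, 4), ignore_attr = TRUE)
  ## independent columns: off-diagonals within +-3/sqrt(m)
  V0 <- tCorrelation(tm)
  expect_true(all(abs(V0[upper.tri(V0)]) < 3 / sqrt(1000)))
  ## permuting the cohort-trait columns permutes V accordingly
  perm <- c(2, 3, 1)
  expect_equal(tCorrelation(tm[, perm]), V0[perm, perm],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(tCorrelation(tm[1:5, ]), "fewer than 10")
})

test_that("multi-trait chi-square reduces correctly under identity V", {
  tm <- matrix(c(1, 2, 3, 0, 0, 0), nrow = 1)
  r <- multiTraitChi2(tm, diag(1, 6))
  expect_equal(r$chi2, 14)
  expect_equal(r$df, 6)
  ## k = 1 equals the squared t with matching normal p
  t1 <- matrix(rnorm(50), ncol = 1)
  r1 <- multiTraitChi2(t1, matrix(1, 1, 1))
  expect_equal(r1$chi2, drop(t1)^2, tolerance = 1e-12)
  expect_equal(r1$p, 2 * pnorm(-abs(drop(t1))), tolerance = 1e-12)
  ## missing t propagates to NA
  t1[3] <- NA
  expect_true(is.na(multiTraitChi2(t1, matrix(1, 1, 1))$chi2[3]))
})

test_that("chi-square is invariant to joint column permutation", {
  set.seed(56)
  V <- cov2cor(crossprod(matrix(rnorm(36), 6, 6)) + diag(1, 6))
  tm <- matrix(rnorm(600), 100, 6) %*% chol(V)
  perm <- sample(6)
  a <- multiTraitChi2(tm, V)$chi2
  b <- multiTraitChi2(tm[, perm], V[perm, perm])$chi2
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("single-trait bull/cow meta-analysis is the k = 2 special case", {
  set.seed(57)
  bt <- data.frame(id = paste0("m", 1:500), t = rnorm(500))
  ct <- data.frame(id = bt$id, t = 0.5 * bt$t + rnorm(500, sd = sqrt(0.75)))
  r <- metaSingleTrait(bt, ct)
  expect_equal(unique(r$df), 2)
  V <- tCorrelation(cbind(bt$t, ct$t))
  manual <- multiTraitChi2(cbind(bt$t, ct$t), V)
  expect_equal(r$chi2, manual$chi2, tolerance = 1e-12)
})

test_that("FDR estimator reproduces published table arithmetic", {
  expect_equal(round(100 * fdrEstimate(1e-7, 1, 4489), 2), 0.04)
  expect_equal(round(100 * fdrEstimate(1e-5, 1, 4489), 2), 4.49)
  expect_equal(fdrEstimate(1e-7, 4489, 4489), 0)
  expect_true(is.na(fdrEstimate(1e-5, 0, 4489)))
  expect_error(fdrEstimate(0, 1, 10))
})

test_that("FDR is monotone in P and in S on a grid", {
  Ps <- c(1e-7, 1e-6, 1e-5, 1e-4)
  for (S in 1:4) {
    f <- fdrEstimate(Ps, S, 4489)
    expect_true(all(diff(f) > 0))
  }
  for (P in Ps) {
    f <- vapply(1:10, function(S) fdrEstimate(P, S, 4489), numeric(1))
    expect_true(all(diff(f) < 0))
  }
})

test_that("significance thresholds include Bonferroni and the fixed ladder", {
  th <- significanceThresholds(583488)
  expect_equal(th$bonferroni, 0.05 / 583488)
  expect_lt(th$bonferroni, 1e-7)
  expect_equal(th$ladder, c(1e-7, 1e-5, 1e-4))
  expect_equal(significanceThresholds(5)$bonferroni, 0.01)
})

test_that("LD window r2 matches the covariance-formula oracle", {
  set.seed(58)
  n <- 300
  snp <- matrix(rbinom(n * 10, 2, 0.4), n, 10,
                dimnames = list(NULL, paste0("s", 1:10)))
  pos <- seq(1000, 10000, by = 1000)
  snpR <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos),
                                 type = "SNP")
  svR <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4500, 5600),
                                type = "DEL")
  sv <- snp[, 5]                      # identical to one SNP
  ld <- ldWindow(sv, svR, snp, snpR, windowBp = 2000)
  expect_equal(ld$r2[ld$snp == "s5"], 1, tolerance = 1e-12)
  ## only SNPs within the window around the midpoint (5050) are present
  expect_setequal(ld$snp, paste0("s", 4:7))
  ## oracle: explicit covariance formula
  for (j in seq_len(nrow(ld))) {
    s <- snp[, ld$snp[j]]
    num <- mean(sv * s) - mean(sv) * mean(s)
    oracle <- num^2 / (mean(sv^2) - mean(sv)^2) / (mean(s^2) - mean(s)^2)
    expect_equal(ld$r2[j], oracle, tolerance = 1e-12)
  }
  ## independent markers have tiny r2 almost always
  set.seed(59)
  hits <- replicate(100, {
    a <- rbinom(1000, 2, 0.5); b <- rbinom(1000, 2, 0.5)
    cor(a, b)^2 < 0.01
  })
  expect_gte(mean(hits), 0.95)
  ## monomorphic SNP gives NA
  snp[, 4] <- 2
  ld2 <- ldWindow(sv, svR, snp, snpR, windowBp = 2000)
  expect_true(is.na(ld2$r2[ld2$snp == "s4"]))
})
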