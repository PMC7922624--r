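## helper: build GenotypeData pair where SV dosages have a controlled
## relationship to one SNP column
ldFixture <- function(n = 200, nSnp = 30, seed = 61, svFrom = 15,
                      independentSv = FALSE) {
  set.seed(seed)
  snp <- matrix(rbinom(nSnp * n, 2, 0.4), nSnp, n,
                dimnames = list(paste0("s", seq_len(nSnp)),
                                paste0("i", seq_len(n))))
  pos <- seq(1000, by = 1000, length.out = nSnp)
  snpR <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, pos),
                                 type = "SNP")
  names(snpR) <- rownames(snp)
  sv <- if (independentSv) matrix(rbinom(n, 2, 0.4), 1, n)
        else snp[svFrom, , drop = FALSE]
  rownames(sv) <- "sv1"; colnames(sv) <- colnames(snp)
  svR <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(pos[svFrom] + 300,
                                                 pos[svFrom] + 650),
                                type = "DEL")
  names(svR) <- "sv1"
  storage.mode(sv) <- "integer"
  list(snp = genotypeData(snp, snpR), sv = genotypeData(sv, svR))
}

test_that("fold plans are balanced, seeded and disjoint", {
  p <- makeFolds(paste0("i", 1:10), k = 5, seed = 1)
  expect_true(all(table(p$assignment) == 2))
  p2 <- makeFolds(paste0("i", 1:10), k = 5, seed = 1)
  expect_identical(p$assignment, p2$assignment)
  p3 <- makeFolds(paste0("i", 1:23), k = 5, seed = 2)
  expect_lte(diff(range(table(p3$assignment))), 1)
  expect_setequal(names(p3$assignment), paste0("i", 1:23))
  expect_error(makeFolds(paste0("i", 1:3), k = 5), "more folds")
})

test_that("an SV in perfect LD with a flanking SNP is imputed exactly", {
  fx <- ldFixture()
  res <- runImputationCV(snpGeno = fx$snp, svGeno = fx$sv, k = 5, seed = 7)
  expect_equal(res$accuracy$r2, 1, tolerance = 1e-9)
})

test_that("an SV independent of all SNPs has near-zero accuracy", {
  r2 <- vapply(1:20, function(s) {
    fx <- ldFixture(n = 500, seed = 600 + s, independentSv = TRUE)
    runImputationCV(snpGeno = fx$snp, svGeno = fx$sv, k = 5,
                    seed = s)$accuracy$r2
  }, numeric(1))
  expect_gte(mean(r2 < 0.1, na.rm = TRUE), 0.9)
})

test_that("SNP-in-SV exclusion matches a brute-force position scan", {
  fx <- ldFixture(n = 150, nSnp = 40, seed = 62)
  svR <- markerRanges(fx$sv)
  snpR <- markerRanges(fx$snp)
  ## widen the SV to cover several SNPs
  wide <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10500, 20500),
                                 type = "DEL")
  fl <- svgblup:::.flankingSnps(
    anchorPos = 10500, svChrom = "chr1", svStart = 10500, svEnd = 20500,
    snpPos = GenomicRanges::start(snpR),
    snpChrom = as.character(GenomicRanges::seqnames(snpR)),
    excludeSnpsInSv = TRUE, w = 40)
  inside <- which(GenomicRanges::start(snpR) >= 10500 &
                    GenomicRanges::start(snpR) <= 20500)
  expect_length(intersect(fl, inside), 0)
  expect_setequal(fl, setdiff(seq_along(snpR), inside))
  ## behavioral check: excluding a perfectly informative in-SV SNP
  ## destroys the perfect prediction
  snpM <- genoCodes(fx$snp)
  sv <- snpM[20, , drop = FALSE]       # identical to SNP 20 (pos 20000)
  rownames(sv) <- "svW"
  svWide <- genotypeData(sv, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(19500, 20400), type = "DEL"))
  with20 <- runImputationCV(snpGeno = fx$snp, svGeno = svWide, k = 5,
                            seed = 3, excludeSnpsInSv = FALSE)
  without20 <- runImputationCV(snpGeno = fx$snp, svGeno = svWide, k = 5,
                               seed = 3, excludeSnpsInSv = TRUE)
  expect_equal(with20$accuracy$r2, 1, tolerance = 1e-9)
  expect_lt(without20$accuracy$r2, 0.5)
})

test_that("anchor modes shift the flanking-SNP neighbourhood", {
  fx <- ldFixture(n = 100, nSnp = 40, seed = 63)
  snpR <- markerRanges(fx$snp)
  pos <- GenomicRanges::start(snpR)
  ch <- as.character(GenomicRanges::seqnames(snpR))
  s <- svgblup:::.flankingSnps(5000, "chr1", 5000, 30000, pos, ch, FALSE, 4)
  e <- svgblup:::.flankingSnps(30000, "chr1", 5000, 30000, pos, ch, FALSE, 4)
  expect_setequal(s, c(3, 4, 5, 6))
  expect_setequal(e, c(28, 29, 30, 31))
})

test_that("accuracy table matches the correlation oracle and is sign-blind", {
  set.seed(64)
  truth <- matrix(rbinom(300, 2, 0.5), 100, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  imputed <- truth + matrix(rnorm(300, sd = 0.3), 100, 3)
  acc <- accuracyTable(truth, imputed)
  for (j in 1:3)
    expect_equal(acc$r2[j], cor(truth[, j], imputed[, j])^2,
                 tolerance = 1e-12)
  expect_equal(accuracyTable(truth, truth)$r2, rep(1, 3))
  expect_equal(accuracyTable(truth, 2 - truth)$r2, rep(1, 3))
  expect_error(accuracyTable(truth, imputed[1:50, ]), "dimensions differ")
  const <- matrix(1, 100, 1)
  expect_true(is.na(accuracyTable(const, const + rnorm(100))$r2))
})

test_that("threshold summary applies the strictly-above rule", {
  acc <- data.frame(sv = c("a", "b", "c"), r2 = c(0.4, 0.6, 0.9),
                    maf = c(0.1, 0.2, 0.3))
  s <- thresholdSummary(acc)
  expect_equal(s$pctAbove, c(2 / 3, 1 / 3) * 100, tolerance = 1e-9)
  accAll1 <- data.frame(sv = "x", r2 = 1, maf = 0.5)
  expect_equal(thresholdSummary(accAll1)$pctAbove, c(100, 100))
  boundary <- data.frame(sv = "y", r2 = 0.5, maf = 0.5)
  expect_equal(thresholdSummary(boundary)$pctAbove[1], 0)
})

test_that("MAF-binned accuracy matches a group-by oracle", {
  set.seed(65)
  acc <- data.frame(sv = paste0("s", 1:200), r2 = runif(200),
                    maf = runif(200, 0, 0.5))
  b <- accuracyByMaf(acc)
  oracle <- tapply(acc$r2,
                   cut(acc$maf, seq(0, 0.5, 0.05), include.lowest = TRUE,
                       right = FALSE),
                   mean)
  expect_equal(b$meanR2, as.numeric(oracle), tolerance = 1e-12)
  one <- accuracyByMaf(acc, binWidth = 0.5)
  expect_equal(one$meanR2, mean(acc$r2), tolerance = 1e-12)
})

test_that("SV selection is strict and merges across sets like the overlap oracle", {
  gr1 <- randomSVSet(30, seed = 66)
  names(gr1) <- paste0("a", 1:30)
  gr2 <- randomSVSet(30, seed = 67)
  names(gr2) <- paste0("b", 1:30)
  set.seed(68)
  acc1 <- data.frame(sv = names(gr1), r2 = runif(30), maf = 0.2)
  attr(acc1, "ranges") <- gr1
  acc2 <- data.frame(sv = names(gr2), r2 = runif(30), maf = 0.2)
  attr(acc2, "ranges") <- gr2
  sel <- selectSVs(list(acc1, acc2), minR2 = 0.5)
  keep <- c(gr1[acc1$r2 > 0.5], gr2[acc2$r2 > 0.5])
  expected <- overlapClustersOracle(
    as.character(GenomicRanges::seqnames(keep)),
    GenomicRanges::start(keep), GenomicRanges::end(keep),
    S4Vectors::mcols(keep)$type)
  expect_length(sel, expected)
  ## boundary: r2 exactly 0.5 is excluded; all-below gives empty
  accB <- data.frame(sv = names(gr1)[1], r2 = 0.5, maf = 0.2)
  attr(accB, "ranges") <- gr1[1]
  expect_length(selectSVs(accB), 0)
})

test_that("masked individuals never leak into the reference", {
  fx <- ldFixture(n = 120, seed = 69)
  testIds <- paste0("i", 1:24)
  pred1 <- maskAndImpute(fx$snp, fx$sv, testIds)
  ## poison the test individuals' SV genotypes; predictions must not move
  codes <- genoCodes(fx$sv)
  codes[, testIds] <- 2L - codes[, testIds]
  svPoisoned <- genotypeData(codes, markerRanges(fx$sv))
  pred2 <- maskAndImpute(fx$snp, svPoisoned, testIds)
  expect_identical(pred1, pred2)
})

test_that("fold accuracy is invariant to fold order and pools every individual once", {
  fx <- ldFixture(n = 100, seed = 70)
  res <- runImputationCV(snpGeno = fx$snp, svGeno = fx$sv, k = 5, seed = 11,
                         perFold = TRUE)
  expect_false(anyNA(res$imputed))
  counts <- table(res$folds$assignment)
  expect_lte(diff(range(counts)), 1)
})

test_that("near-complete LD populations impute common SVs accurately", {
  cfg <- simConfig(nIndividuals = 200, nSnp = 1200, nSv = 60, nChrom = 2,
                   ldRho = 1e-7, breedFractions = c(`1` = 1),
                   nSireSonPairs = 0, nDuplicates = 0, depthMean = 50,
                   seed = 71)
  pop <- simulatePopulation(cfg)
  acc <- runImputationCV(pop, k = 5, seed = 3)$accuracy
  common <- acc[!is.na(acc$r2) & !is.na(acc$maf) & acc$maf >= 0.1, ]
  expect_gte(mean(common$r2 > 0.8), 0.9)
  ## and a weak-LD population does worse above the 0.5 threshold
  cfgLow <- simConfig(nIndividuals = 200, nSnp = 1200, nSv = 60, nChrom = 2,
                      ldRho = 1, breedFractions = c(`1` = 1),
                      nSireSonPairs = 0, nDuplicates = 0, depthMean = 50,
                      seed = 71)
  accLow <- runImputationCV(simulatePopulation(cfgLow), k = 5,
                            seed = 3)$accuracy
  expect_gt(thresholdSummary(acc)$pctAbove[1],
            thresholdSummary(accLow)$pctAbove[1])
})
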