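gr <- function(chrom, start, end, type = "DEL", source = NULL) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), type = type)
  if (!is.null(source)) S4Vectors::mcols(g)$source <- source
  g
}

test_that("merge honours the >= 1 bp overlap boundary", {
  ## [100,200) and [199,300) half-open share 1 bp: as 1-based inclusive
  ## ranges these are 101-200 and 200-300
  a <- gr("chr1", 101, 200)
  b <- gr("chr1", 200, 300)
  m <- mergeSVCalls(a, b)
  expect_length(m, 1)
  expect_equal(GenomicRanges::start(m), 101)
  expect_equal(GenomicRanges::end(m), 300)
  expect_equal(S4Vectors::mcols(m)$source, "setA+setB")
  ## [100,200) and [200,300) half-open do not overlap: 101-200 vs 201-300
  m2 <- mergeSVCalls(gr("chr1", 101, 200), gr("chr1", 201, 300))
  expect_length(m2, 2)
})

test_that("same positions but different SV types never merge", {
  m <- mergeSVCalls(gr("chr1", 101, 200, "DEL"), gr("chr1", 150, 250, "INV"))
  expect_length(m, 2)
  expect_setequal(S4Vectors::mcols(m)$type, c("DEL", "INV"))
})

test_that("merge is commutative and idempotent on random sets", {
  a <- randomSVSet(60, seed = 1)
  b <- randomSVSet(60, seed = 2)
  ab <- mergeSVCalls(a, b)
  ba <- mergeSVCalls(b, a)
  expect_equal(GenomicRanges::granges(ab), GenomicRanges::granges(ba))
  expect_identical(S4Vectors::mcols(ab)$type, S4Vectors::mcols(ba)$type)
  aa <- mergeSVCalls(a, a)
  ## merge(S, S) has the same interval set as the self-collapsed S
  self <- mergeSVCalls(a[0], a)
  expect_equal(GenomicRanges::granges(aa), GenomicRanges::granges(self))
})

test_that("merged record count matches the all-pairs overlap oracle", {
  for (seed in c(3, 4, 5)) {
    a <- randomSVSet(50, seed = seed)
    b <- randomSVSet(50, seed = seed + 100)
    m <- mergeSVCalls(a, b)
    comb <- c(a, b)
    expected <- overlapClustersOracle(
      as.character(GenomicRanges::seqnames(comb)),
      GenomicRanges::start(comb), GenomicRanges::end(comb),
      S4Vectors::mcols(comb)$type)
    expect_length(m, expected)
  }
  ## larger minimum overlap is respected
  a <- gr("chr1", 101, 200); b <- gr("chr1", 191, 300)
  expect_length(mergeSVCalls(a, b, minOverlapBp = 10), 1)
  expect_length(mergeSVCalls(a, b, minOverlapBp = 11), 2)
})

test_that("target intersection keeps exactly the overlapping calls", {
  target <- randomSVSet(40, seed = 9)
  calls <- target[seq(1, 39, by = 2)]
  expect_equal(
    GenomicRanges::granges(suppressMessages(intersectWithTarget(calls, target))),
    GenomicRanges::granges(calls))
  far <- gr("chr9", c(10, 500), c(100, 900), type = c("DEL", "DEL"))
  ## suppressWarnings: the disjoint chromosome sets trigger a Seqinfo
  ## merge notice from the overlap machinery
  expect_length(suppressWarnings(suppressMessages(
    intersectWithTarget(far, target))), 0)
  expect_warning(intersectWithTarget(calls, target[0]), "empty target")
  ## random fixture against a brute-force all-pairs oracle
  calls2 <- randomSVSet(70, seed = 10)
  kept <- suppressMessages(intersectWithTarget(calls2, target))
  oracle <- vapply(seq_along(calls2), function(i) {
    any(as.character(GenomicRanges::seqnames(target)) ==
          as.character(GenomicRanges::seqnames(calls2))[i] &
        S4Vectors::mcols(target)$type == S4Vectors::mcols(calls2)$type[i] &
        pmin(GenomicRanges::end(target), GenomicRanges::end(calls2)[i]) -
          pmax(GenomicRanges::start(target), GenomicRanges::start(calls2)[i]) + 1 >= 1)
  }, logical(1))
  expect_length(kept, sum(oracle))
})

test_that("validation sets require the SV in both members of a pair", {
  samples <- data.frame(id = c("s1", "s1b", "sire", "son", "lone"),
                        duplicateOf = c(NA, "s1", NA, NA, NA),
                        sireId = c(NA, NA, NA, "sire", NA),
                        stringsAsFactors = FALSE)
  calls <- GenomicRanges::GRangesList(
    s1 = gr("chr1", c(100, 5000), c(400, 5400)),
    s1b = gr("chr1", 350, 700),              # overlaps first s1 call only
    sire = gr("chr2", 100, 300),
    son = c(gr("chr2", 250, 600), gr("chr2", 9000, 9400)),
    lone = gr("chr3", 1, 100))
  vs <- buildValidationSets(calls, samples)
  expect_length(vs$TWICE_SEQ, 1)
  expect_equal(GenomicRanges::start(vs$TWICE_SEQ), 100)
  expect_equal(GenomicRanges::end(vs$TWICE_SEQ), 700)
  ## son-only SV (chr2:9000) excluded; shared SV kept as union span
  expect_length(vs$FAM, 1)
  expect_equal(GenomicRanges::start(vs$FAM), 100)
  expect_equal(GenomicRanges::end(vs$FAM), 600)
})

test_that("simulated transmission fixture matches pair-enumeration oracle", {
  pop <- tinyPop()
  sv <- pop@sv
  codes <- genoCodes(sv)
  rng <- markerRanges(sv)
  samples <- sampleData(sv)
  called <- function(id) {
    idx <- which(codes[, id] %in% c(1L, 2L))
    rng[idx]
  }
  calls <- GenomicRanges::GRangesList(lapply(setNames(samples$id, samples$id),
                                             called))
  vs <- suppressWarnings(buildValidationSets(calls, samples))
  ## oracle: enumerate sire-son pairs, collect SV loci called in both
  pairs <- samples[!is.na(samples$sireId), c("id", "sireId")]
  oracle <- unique(unlist(lapply(seq_len(nrow(pairs)), function(r) {
    both <- codes[, pairs$id[r]] %in% c(1L, 2L) &
      codes[, pairs$sireId[r]] %in% c(1L, 2L)
    rownames(codes)[both]
  })))
  ## every oracle locus is covered by the FAM set
  if (length(oracle)) {
    expect_true(all(IRanges::overlapsAny(rng[oracle], vs$FAM)))
  }
  ## and FAM loci exist only where some pair shares the call
  expect_equal(length(vs$FAM) > 0, length(oracle) > 0)
})

test_that("genotype encoding maps symbols and applies the depth filter", {
  gt <- matrix(c("0/1", "1/1", "0/0",
                 "0/0", "0/0", "0/0"), nrow = 2, byrow = TRUE,
               dimnames = list(c("sv1", "sv2"), c("a", "b", "c")))
  dp <- matrix(c(10L, 4L, 9L, 8L, 7L, 6L), nrow = 2, byrow = TRUE,
               dimnames = dimnames(gt))
  rng <- gr("chr1", c(100, 900), c(300, 1200), type = c("DEL", "DUP"))
  gd <- encodeGenotypes(gt, dp, rng)
  expect_identical(genoCodes(gd)["sv1", ], c(a = 1L, b = 5L, c = 0L))
  expect_identical(genoCodes(gd)["sv2", ], c(a = 0L, b = 0L, c = 0L))
  gt[1, 2] <- "2/2"
  expect_error(encodeGenotypes(gt, dp, rng), "unknown genotype symbol.*sv1")
})
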