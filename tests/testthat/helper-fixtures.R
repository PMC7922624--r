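## Shared fixtures, generated in code and cached per test run.

.fixtureEnv <- new.env(parent = emptyenv())

## small population reused by several module tests
tinyPop <- function() {
  if (is.null(.fixtureEnv$pop)) {
    cfg <- simConfig(nIndividuals = 120, nSnp = 600, nSv = 30,
                     nChrom = 3, nSireSonPairs = 12, nDuplicates = 6,
                     seed = 42)
    .fixtureEnv$pop <- simulatePopulation(cfg)
  }
  .fixtureEnv$pop
}

## random SV GRanges for interval-arithmetic oracles
randomSVSet <- function(n, seed, chroms = c("chr1", "chr2"),
                        maxPos = 1e5, types = c("DEL", "INV", "DUP")) {
  set.seed(seed)
  st <- sample.int(maxPos, n, replace = TRUE)
  gr <- GenomicRanges::GRanges(sample(chroms, n, replace = TRUE),
                               IRanges::IRanges(st, st + sample.int(500, n, replace = TRUE)),
                               type = sample(types, n, replace = TRUE))
  GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  gr[order(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr))]
}

## O(n^2) union-find-free oracle: number of transitively merged clusters of
## same-type records overlapping by >= minOv bp (1-based inclusive ranges)
overlapClustersOracle <- function(chrom, start, end, type, minOv = 1) {
  n <- length(start)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ov <- min(end[i], end[j]) - max(start[i], start[j]) + 1
    adj[i, j] <- chrom[i] == chrom[j] && type[i] == type[j] && ov >= minOv
  }
  ## connected components by repeated expansion
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] > comp[i]) { comp[j] <- comp[i]; changed <- TRUE }
      if (adj[i, j] && comp[i] > comp[j]) { comp[i] <- comp[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  length(unique(comp))
}

## marker-based polygenic data simulated straight from the GBLUP model
grmModelData <- function(n, m, h2, seed, freq = NULL) {
  set.seed(seed)
  p <- if (is.null(freq)) runif(m, 0.1, 0.9) else rep(freq, m)
  W <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  pHat <- colMeans(W) / 2
  keep <- pHat > 0 & pHat < 1
  W <- W[, keep, drop = FALSE]; pHat <- pHat[keep]
  Ws <- sweep(sweep(W, 2, 2 * pHat), 2, sqrt(2 * pHat * (1 - pHat)), "/")
  G <- tcrossprod(Ws) / ncol(Ws)
  ids <- sprintf("i%04d", seq_len(n))
  dimnames(G) <- list(ids, ids)
  g <- drop(Ws %*% rnorm(ncol(Ws)))
  g <- (g - mean(g)) / sd(g) * sqrt(h2)
  e <- rnorm(n); e <- (e - mean(e)) / sd(e) * sqrt(1 - h2)
  y <- g + e
  names(y) <- ids
  list(W = W, Ws = Ws, G = G, g = g, y = y, ids = ids)
}
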