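## Masking-based evaluation of SV imputation accuracy.
##
## Fivefold cross-validation over individuals: each fold's SV genotypes are
## masked (coded 5) and re-predicted from SNP haplotype context using the
## remaining individuals as reference. The stand-in imputer is a
## least-squares regression of the SV dosage on the w nearest flanking SNP
## dosages, fitted in the reference and clipped to [0, 2]; it is a pluggable
## stand-in for an external phasing/imputation engine, sharing its key
## property that accuracy is driven by SV-SNP LD. Accuracy is the squared
## Pearson correlation between imputed dosage and true code over all masked
## individuals pooled across folds.

#' Random fold assignment for cross-validation
#'
#' Seeded uniform partition of individuals into k folds of sizes differing
#' by at most one; each fold serves once as the masked test set.
#'
#' @param ids character vector of individual ids.
#' @param k number of folds (default 5).
#' @param seed integer seed, or NA to continue the RNG stream.
#' @return list: \code{k}, \code{assignment} (named integer fold per id),
#'   \code{seed}.
#' @export
makeFolds <- function(ids, k = 5, seed = NULL) {
  n <- length(ids)
  if (k > n) stop("more folds than individuals")
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  names(fold) <- ids
  list(k = k, assignment = fold, seed = if (is.null(seed)) NA_integer_ else seed)
}

## nearest flanking SNPs for one SV anchor; ties broken by lower position
.flankingSnps <- function(anchorPos, svChrom, svStart, svEnd, snpPos,
                          snpChrom, excludeSnpsInSv, w) {
  cand <- which(snpChrom == svChrom)
  if (excludeSnpsInSv)
    cand <- cand[!(snpPos[cand] >= svStart & snpPos[cand] <= svEnd)]
  if (length(cand) < 2) return(integer(0))
  d <- abs(snpPos[cand] - anchorPos)
  cand[order(d, snpPos[cand])][seq_len(min(w, length(cand)))]
}

#' Mask and impute SV genotypes for a test set
#'
#' For each SV (represented on the marker scaffold by a single anchor
#' position: its start, middle or end), the imputer regresses the reference
#' individuals' SV dosage on their \code{w} nearest flanking SNP dosages
#' and predicts the masked test individuals, clipping to [0, 2]. SNPs whose
#' position falls inside the SV interval can be excluded from the scaffold.
#' Reference SV calls that are themselves missing (code 5) are dropped from
#' the fit.
#'
#' @param snpGeno \linkS4class{GenotypeData} of SNPs (all individuals).
#' @param svGeno \linkS4class{GenotypeData} of SVs; the assay named by
#'   \code{svAssay} provides the reference genotypes.
#' @param testIds ids of the masked individuals.
#' @param anchor one of \code{"start"}, \code{"middle"}, \code{"end"}.
#' @param excludeSnpsInSv drop SNPs inside the SV interval from the
#'   scaffold.
#' @param w number of flanking SNPs used by the regression (default 20).
#' @param mafMin optional MAF filter applied to the SNP scaffold (emulates
#'   a sequence-panel MAF > 0.05 filter); default 0.
#' @param svAssay assay of \code{svGeno} used as reference genotypes.
#' @return numeric matrix (test individuals x SVs) of imputed dosages; NA
#'   where an SV had fewer than 2 usable flanking SNPs.
#' @export
maskAndImpute <- function(snpGeno, svGeno, testIds,
                          anchor = c("start", "middle", "end"),
                          excludeSnpsInSv = FALSE, w = 20, mafMin = 0,
                          svAssay = "geno") {
  anchor <- match.arg(anchor)
  allIds <- colnames(snpGeno)
  stopifnot(all(testIds %in% allIds))
  refIds <- setdiff(allIds, testIds)

  snpD <- dosageMatrix(snpGeno, missing = "mean")   # individuals x SNPs
  if (mafMin > 0) {
    af <- alleleFrequencies(snpGeno)
    snpD <- snpD[, !is.na(af$maf) & af$maf > mafMin, drop = FALSE]
    snpR <- markerRanges(snpGeno)[!is.na(af$maf) & af$maf > mafMin]
  } else snpR <- markerRanges(snpGeno)
  snpPos <- start(snpR)
  snpChrom <- as.character(seqnames(snpR))

  svR <- markerRanges(svGeno)
  svCodes <- t(assay(svGeno, svAssay))              # individuals x SVs
  svCodes[svCodes == MISSING_CODE] <- NA_real_

  anchorPos <- switch(anchor,
                      start = start(svR),
                      middle = floor((start(svR) + end(svR)) / 2),
                      end = end(svR))
  nSv <- length(svR)
  pred <- matrix(NA_real_, length(testIds), nSv,
                 dimnames = list(testIds, rownames(svGeno)))
  for (j in seq_len(nSv)) {
    fl <- .flankingSnps(anchorPos[j], as.character(seqnames(svR))[j],
                        start(svR)[j], end(svR)[j], snpPos, snpChrom,
                        excludeSnpsInSv, w)
    if (length(fl) < 2) next
    yRef <- svCodes[refIds, j]
    use <- !is.na(yRef)
    if (sum(use) < 3) next
    Xref <- cbind(1, snpD[refIds[use], fl, drop = FALSE])
    fit <- lm.fit(Xref, yRef[use])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    Xtest <- cbind(1, snpD[testIds, fl, drop = FALSE])
    pred[, j] <- pmin(pmax(drop(Xtest %*% beta), 0), 2)
  }
  pred
}

#' Pooled imputation accuracy per SV
#'
#' Squared Pearson correlation between the true code and the imputed
#' dosage, pooled over all masked individuals (every individual masked
#' exactly once across folds). NA when either vector is constant or the
#' prediction is missing.
#'
#' @param truth individuals x SVs matrix of true codes \{0,1,2\}.
#' @param imputed individuals x SVs matrix of imputed dosages (same
#'   dimensions and order).
#' @param svRanges optional \code{GRanges} (one per SV) carried into the
#'   output and used by \code{\link{selectSVs}}.
#' @return data.frame: \code{sv}, \code{r2}, \code{maf} (from truth),
#'   \code{type} when ranges are given; ranges attached as attribute
#'   \code{"ranges"}.
#' @export
accuracyTable <- function(truth, imputed, svRanges = NULL) {
  truth <- as.matrix(truth); imputed <- as.matrix(imputed)
  if (!all(dim(truth) == dim(imputed)))
    stop("truth and imputed dimensions differ")
  r2 <- vapply(seq_len(ncol(truth)), function(j) {
    tj <- truth[, j]; ij <- imputed[, j]
    ok <- !is.na(tj) & !is.na(ij)
    if (sum(ok) < 3) return(NA_real_)
    if (var(tj[ok]) < .Machine$double.eps ||
        var(ij[ok]) < .Machine$double.eps) return(NA_real_)
    cor(tj[ok], ij[ok])^2
  }, numeric(1))
  p <- colMeans(truth, na.rm = TRUE) / 2
  ids <- colnames(truth)
  if (is.null(ids)) ids <- paste0("sv", seq_len(ncol(truth)))
  out <- data.frame(sv = ids, r2 = r2, maf = pmin(p, 1 - p),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(svRanges)) {
    out$type <- mcols(svRanges)$type
    attr(out, "ranges") <- svRanges
  }
  out
}

#' Fraction of SVs above accuracy thresholds
#'
#' @param acc accuracy table from \code{\link{accuracyTable}}.
#' @param thresholds accuracy cutoffs; strictly-above rule.
#' @return data.frame: \code{threshold}, \code{pctAbove} (percentage of
#'   non-NA SVs with r2 > threshold), \code{nUsed}, \code{nNA}.
#' @export
thresholdSummary <- function(acc, thresholds = c(0.5, 0.8)) {
  stopifnot(nrow(acc) > 0)
  ok <- !is.na(acc$r2)
  data.frame(threshold = thresholds,
             pctAbove = vapply(thresholds,
                               function(th) 100 * mean(acc$r2[ok] > th),
                               numeric(1)),
             nUsed = sum(ok), nNA = sum(!ok), row.names = NULL)
}

#' Mean imputation accuracy by MAF bin
#'
#' @param acc accuracy table with \code{maf} column.
#' @param binWidth bin width on [0, 0.5]; default 0.05.
#' @return data.frame: \code{binLow}, \code{binHigh}, \code{meanR2}
#'   (NA for empty bins), \code{n}.
#' @export
accuracyByMaf <- function(acc, binWidth = 0.05) {
  breaks <- seq(0, 0.5, by = binWidth)
  if (breaks[length(breaks)] < 0.5) breaks <- c(breaks, 0.5)
  bin <- cut(acc$maf, breaks, include.lowest = TRUE, right = FALSE)
  means <- tapply(acc$r2, bin, function(v) mean(v, na.rm = TRUE))
  counts <- tapply(seq_len(nrow(acc)), bin, length)
  counts[is.na(counts)] <- 0
  data.frame(binLow = breaks[-length(breaks)], binHigh = breaks[-1],
             meanR2 = as.numeric(means), n = as.integer(counts),
             row.names = NULL)
}

#' Select well-imputed SVs and merge across sets
#'
#' Keeps SVs with accuracy strictly above \code{minR2} ("above 0.5" rule)
#' from one or several accuracy tables and collapses the selected records
#' across sets by the >= 1 bp same-type overlap merge.
#'
#' @param acc an accuracy table (with attached ranges) or a list of them.
#' @param minR2 selection threshold; strict inequality.
#' @return \code{GRanges} of selected (merged) SVs.
#' @export
selectSVs <- function(acc, minR2 = 0.5) {
  if (is.data.frame(acc)) acc <- list(acc)
  picked <- lapply(acc, function(a) {
    gr <- attr(a, "ranges")
    if (is.null(gr)) stop("accuracy table lacks attached ranges")
    keep <- !is.na(a$r2) & a$r2 > minR2
    g <- gr[keep]
    if (is.null(mcols(g)$source))
      mcols(g)$source <- rep("selected", length(g))
    g
  })
  sel <- do.call(c, unname(picked))
  if (length(sel) == 0) return(sel)
  .collapseByType(GenomicRanges::sort(sel), 1L)
}

#' Cross-validated SV imputation accuracy
#'
#' Runs the full masking design: partition individuals into k folds, mask
#' each fold's SV genotypes in turn, impute them from the remaining
#' individuals, pool the predictions, and score accuracy per SV against the
#' truth assay. The reference never contains a test individual's SV
#' genotypes, so there is no leakage.
#'
#' @param pop a \linkS4class{SyntheticPopulation}, or NULL when
#'   \code{snpGeno}/\code{svGeno} are given directly.
#' @param k folds (default 5).
#' @param seed fold-assignment seed.
#' @param anchor,excludeSnpsInSv,w,mafMin passed to
#'   \code{\link{maskAndImpute}}.
#' @param perFold also return per-fold accuracy tables (pooling remains
#'   the headline estimate).
#' @param snpGeno,svGeno alternative direct inputs; \code{svGeno} must
#'   carry a \code{truth} assay (or its \code{geno} assay is taken as
#'   truth).
#' @return list: \code{accuracy} (pooled \code{\link{accuracyTable}}),
#'   \code{imputed} (individuals x SVs), \code{folds}, and \code{byFold}
#'   when requested.
#' @export
runImputationCV <- function(pop = NULL, k = 5, seed = 1,
                            anchor = "start", excludeSnpsInSv = FALSE,
                            w = 20, mafMin = 0, perFold = FALSE,
                            snpGeno = NULL, svGeno = NULL) {
  if (!is.null(pop)) {
    snpGeno <- pop@snp
    svGeno <- pop@sv
  }
  truthAssay <- if ("truth" %in% assayNames(svGeno)) "truth" else "geno"
  truth <- t(assay(svGeno, truthAssay)) * 1.0
  truth[truth == MISSING_CODE] <- NA_real_
  ids <- colnames(snpGeno)
  plan <- makeFolds(ids, k = k, seed = seed)
  imputed <- matrix(NA_real_, length(ids), nrow(svGeno),
                    dimnames = list(ids, rownames(svGeno)))
  byFold <- if (perFold) vector("list", k) else NULL
  for (f in seq_len(k)) {
    testIds <- ids[plan$assignment == f]
    pred <- maskAndImpute(snpGeno, svGeno, testIds, anchor = anchor,
                          excludeSnpsInSv = excludeSnpsInSv, w = w,
                          mafMin = mafMin)
    imputed[testIds, ] <- pred
    if (perFold)
      byFold[[f]] <- accuracyTable(truth[testIds, , drop = FALSE], pred,
                                   markerRanges(svGeno))
  }
  acc <- accuracyTable(truth, imputed, markerRanges(svGeno))
  out <- list(accuracy = acc, imputed = imputed, folds = plan)
  if (perFold) out$byFold <- byFold
  out
}
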