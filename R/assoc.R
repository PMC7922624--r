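## Mixed-linear-model association and meta-analysis.
##
## Markers are tested one at a time by generalized least squares with the
## covariance V = sum_k s2_k G_k + s2_e I held fixed at the null-model REML
## estimates (the EMMAX / MLMA scheme). With P0 the projection matrix for
## the null fixed design X0, the marker effect is
##   b = (m' P0 y) / (m' P0 m),  Var(b) = 1 / (m' P0 m),
## and the whole scan reduces to one n x n x m matrix product.

.nullProjection <- function(y, grms, vc, X0) {
  comp <- if (is(vc, "VarianceComponents")) vc@components else vc
  if (!is.list(grms)) grms <- list(g1 = grms)
  if (is.null(names(grms)) || any(names(grms) == ""))
    names(grms) <- paste0("g", seq_along(grms))
  n <- length(y)
  V <- diag(comp[["residual"]], n)
  for (k in names(grms)) V <- V + comp[[k]] * .asGrmMatrix(grms[[k]])
  Vinv <- chol2inv(.cholSafe(V, "V"))
  VinvX <- Vinv %*% X0
  P0 <- Vinv - VinvX %*% solve(crossprod(X0, VinvX), t(VinvX))
  list(P0 = P0, P0y = drop(P0 %*% y))
}

#' Mixed-linear-model GWAS scan
#'
#' Tests each marker for association with the phenotype under the GBLUP
#' covariance structure, with variance components estimated once under the
#' null model and held fixed across markers. Missing dosages are
#' mean-imputed per marker; monomorphic markers and markers aliased with
#' the null covariates return NA with a reason. Two-sided p-values come
#' from the standard normal applied to t = b / SE(b).
#'
#' @param y phenotype vector (no NAs; subset beforehand).
#' @param markers individuals x markers numeric dosage matrix (codes
#'   \{0,1,2\}, 5/NA treated as missing).
#' @param grms named list of \linkS4class{GRM} or matrices aligned to
#'   \code{y}.
#' @param vc null-model \linkS4class{VarianceComponents} (or named vector).
#' @param X0 null fixed design (default intercept; add the breed-fraction
#'   covariate for mixed-breed cohorts).
#' @param markerInfo optional \code{GRanges} (one per marker) supplying
#'   chrom, pos and marker class for the output table.
#' @return data.frame with one row per marker: \code{id}, \code{chrom},
#'   \code{pos}, \code{class}, \code{effect}, \code{se}, \code{t},
#'   \code{p}, \code{reason} (NA unless the marker was skipped).
#' @export
mlmaScan <- function(y, markers, grms, vc, X0 = NULL, markerInfo = NULL) {
  stopifnot(!anyNA(y))
  n <- length(y)
  M <- as.matrix(markers) * 1.0
  stopifnot(nrow(M) == n)
  M[M == MISSING_CODE] <- NA_real_
  mu <- colMeans(M, na.rm = TRUE)
  idx <- which(is.na(M), arr.ind = TRUE)
  if (nrow(idx)) M[idx] <- mu[idx[, 2L]]
  mono <- apply(M, 2L, function(col) var(col) < .Machine$double.eps)

  X0 <- if (is.null(X0)) matrix(1, n, 1, dimnames = list(NULL, "intercept"))
        else .fullRankDesign(as.matrix(X0))
  np <- .nullProjection(y, grms, vc, X0)
  PM <- np$P0 %*% M
  den <- colSums(M * PM)
  num <- drop(crossprod(M, np$P0y))
  aliased <- den < 1e-10 * colSums(M * M)
  bad <- mono | aliased | den <= 0
  b <- se <- rep(NA_real_, ncol(M))
  b[!bad] <- num[!bad] / den[!bad]
  se[!bad] <- 1 / sqrt(den[!bad])
  tval <- b / se
  p <- 2 * pnorm(-abs(tval))
  ids <- colnames(M)
  if (is.null(ids)) ids <- paste0("m", seq_len(ncol(M)))
  out <- data.frame(id = ids, chrom = NA_character_, pos = NA_integer_,
                    class = NA_character_, effect = b, se = se, t = tval,
                    p = p,
                    reason = ifelse(mono, "monomorphic",
                                    ifelse(aliased, "aliased", NA_character_)),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(markerInfo)) {
    out$chrom <- as.character(seqnames(markerInfo))
    out$pos <- start(markerInfo)
    tp <- mcols(markerInfo)$type
    out$class <- ifelse(tp == "SNP", "SNP", "SV")
  }
  out
}

#' Conditional GWAS scan with a fixed conditioning marker
#'
#' Identical to \code{\link{mlmaScan}} except that the dosage of a
#' conditioning marker (for example the top SNP of a known gene) is added
#' to the null fixed design, so every test measures association beyond what
#' that marker explains. A test marker in perfect LD with the conditioning
#' marker is reported as aliased.
#'
#' @inheritParams mlmaScan
#' @param conditioningMarker numeric dosage vector of the conditioning
#'   marker (no missing values among tested individuals).
#' @export
conditionalScan <- function(y, markers, grms, vc, conditioningMarker,
                            X0 = NULL, markerInfo = NULL) {
  stopifnot(length(conditioningMarker) == length(y),
            !anyNA(conditioningMarker))
  X0 <- if (is.null(X0)) matrix(1, length(y), 1,
                                dimnames = list(NULL, "intercept"))
        else as.matrix(X0)
  X0 <- cbind(X0, conditioning = as.numeric(conditioningMarker))
  mlmaScan(y, markers, grms, vc, X0 = X0, markerInfo = markerInfo)
}

#' Correlation matrix of signed t-values across cohort-traits
#'
#' Pearson correlations of the per-marker signed t-values between every
#' pair of GWAS tables, computed pairwise-complete over the shared marker
#' universe. This is the V matrix of the multi-trait chi-square statistic;
#' under the null it captures the correlation induced by shared samples and
#' correlated traits.
#'
#' @param tMatrix markers x k numeric matrix of signed t-values (columns =
#'   cohort-traits), or a named list of GWAS tables from
#'   \code{\link{mlmaScan}} sharing the same marker order.
#' @return symmetric k x k correlation matrix with unit diagonal.
#' @export
tCorrelation <- function(tMatrix) {
  if (is.list(tMatrix) && !is.matrix(tMatrix)) {
    stopifnot(length(unique(vapply(tMatrix, nrow, integer(1)))) == 1)
    tMatrix <- vapply(tMatrix, function(d) d$t, numeric(nrow(tMatrix[[1]])))
  }
  tMatrix <- as.matrix(tMatrix)
  if (ncol(tMatrix) < 2) stop("need at least 2 cohort-trait tables")
  shared <- crossprod(!is.na(tMatrix))
  if (any(shared[upper.tri(shared)] < 10))
    stop("fewer than 10 shared markers for at least one pair")
  V <- cor(tMatrix, use = "pairwise.complete.obs")
  diag(V) <- 1
  (V + t(V)) / 2
}

#' Multi-trait chi-square meta-analysis
#'
#' Per marker, the statistic is \eqn{\chi^2 = t' V^{-1} t} where t is the
#' k-vector of signed t-values across cohort-traits and V their correlation
#' matrix; p-values use k degrees of freedom. An ill-conditioned V
#' (condition number > 1e10) is inverted by Moore-Penrose pseudo-inverse
#' with a warning. Markers with any missing t return NA.
#'
#' @param tMatrix markers x k matrix of signed t-values.
#' @param V k x k correlation matrix (from \code{\link{tCorrelation}});
#'   identity when NULL.
#' @return data.frame: \code{chi2}, \code{df}, \code{p}; the V used is
#'   attached as attribute \code{"V"}.
#' @export
multiTraitChi2 <- function(tMatrix, V = NULL) {
  tMatrix <- as.matrix(tMatrix)
  k <- ncol(tMatrix)
  if (is.null(V)) V <- diag(1, k)
  stopifnot(nrow(V) == k, ncol(V) == k)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  Vinv <- if (min(ev) <= 0 || max(ev) / min(ev) > 1e10) {
    warning("V ill-conditioned; using Moore-Penrose pseudo-inverse")
    ginv(V)
  } else solve(V)
  ok <- complete.cases(tMatrix)
  chi2 <- rep(NA_real_, nrow(tMatrix))
  chi2[ok] <- rowSums((tMatrix[ok, , drop = FALSE] %*% Vinv) *
                        tMatrix[ok, , drop = FALSE])
  out <- data.frame(chi2 = chi2, df = k,
                    p = pchisq(chi2, df = k, lower.tail = FALSE))
  rownames(out) <- rownames(tMatrix)
  attr(out, "V") <- V
  out
}

#' Single-trait meta-analysis of bull and cow GWAS
#'
#' The k = 2 case of \code{\link{multiTraitChi2}}: signed t-values of the
#' two cohorts combined with their 2 x 2 t-correlation, 2 degrees of
#' freedom.
#'
#' @param bullTable,cowTable GWAS tables from \code{\link{mlmaScan}} over
#'   the same markers (matched by row order).
#' @return as \code{\link{multiTraitChi2}}, with marker ids from
#'   \code{bullTable}.
#' @export
metaSingleTrait <- function(bullTable, cowTable) {
  stopifnot(nrow(bullTable) == nrow(cowTable))
  tm <- cbind(bull = bullTable$t, cow = cowTable$t)
  V <- tCorrelation(tm)
  out <- multiTraitChi2(tm, V)
  rownames(out) <- bullTable$id
  out
}

#' FDR estimate at a p-value threshold
#'
#' The false discovery rate among markers declared significant at threshold
#' P, given S significant markers out of T tested:
#' \deqn{FDR = \frac{P (1 - S/T)}{(S/T)(1 - P)}.}
#' Returned as a fraction; multiply by 100 for the percentage convention of
#' reported tables. With S = 0 the estimate is undefined and NA is
#' returned.
#'
#' @param P p-value threshold in (0, 1); vectorized.
#' @param S number of significant markers at P (0 <= S <= T).
#' @param T total number of markers of the class under study.
#' @return FDR as a fraction in [0, 1] (values above 1 are possible for
#'   very lax thresholds and are returned as computed).
#' @examples
#' fdrEstimate(1e-7, 1, 4489) * 100   # ~0.045%
#' @export
fdrEstimate <- function(P, S, T) {
  stopifnot(all(P > 0 & P < 1), all(T > 0), all(S >= 0 & S <= T))
  r <- S / T
  out <- P * (1 - r) / (r * (1 - P))
  out[S == 0] <- NA_real_
  out
}

#' Significance thresholds for a GWAS
#'
#' Returns the Bonferroni-corrected 0.05 threshold together with the fixed
#' ladder of descending-stringency thresholds used when no marker clears
#' Bonferroni.
#'
#' @param nTests total number of tests (SNPs + SVs).
#' @return list: \code{bonferroni} = 0.05 / nTests, \code{ladder} =
#'   c(1e-7, 1e-5, 1e-4) sorted ascending.
#' @export
significanceThresholds <- function(nTests) {
  stopifnot(nTests > 0)
  list(bonferroni = 0.05 / nTests, ladder = sort(c(1e-7, 1e-5, 1e-4)))
}

#' LD between an SV and surrounding SNPs
#'
#' Squared Pearson correlation between the SV dosage and each SNP dosage
#' for SNPs whose position lies within \code{windowBp} of the SV midpoint
#' (composite, genotype-level LD; no phasing assumed). SNPs with r2 > 0.5
#' are flagged as high LD.
#'
#' @param svDosage numeric dosage vector of the SV.
#' @param svRange \code{GRanges} of length 1 giving the SV interval.
#' @param snpDosage individuals x SNPs dosage matrix.
#' @param snpRanges \code{GRanges} of SNP positions (one per column).
#' @param windowBp half-window width in bp (e.g. 5e5 or 1e6).
#' @return data.frame: \code{snp}, \code{chrom}, \code{pos}, \code{r2},
#'   \code{highLD}; monomorphic SNPs get NA r2.
#' @export
ldWindow <- function(svDosage, svRange, snpDosage, snpRanges, windowBp) {
  stopifnot(length(svRange) == 1, windowBp > 0,
            ncol(snpDosage) == length(snpRanges))
  mid <- (start(svRange) + end(svRange)) / 2
  sel <- which(as.character(seqnames(snpRanges)) ==
                 as.character(seqnames(svRange)) &
               abs(start(snpRanges) - mid) <= windowBp)
  if (length(sel) == 0)
    return(data.frame(snp = character(0), chrom = character(0),
                      pos = integer(0), r2 = numeric(0),
                      highLD = logical(0)))
  r2 <- vapply(sel, function(j) {
    s <- snpDosage[, j]
    if (var(s) < .Machine$double.eps || var(svDosage) < .Machine$double.eps)
      return(NA_real_)
    cor(svDosage, s)^2
  }, numeric(1))
  ids <- colnames(snpDosage)[sel]
  if (is.null(ids)) ids <- paste0("snp", sel)
  data.frame(snp = ids, chrom = as.character(seqnames(snpRanges))[sel],
             pos = start(snpRanges)[sel], r2 = r2,
             highLD = !is.na(r2) & r2 > 0.5,
             stringsAsFactors = FALSE, row.names = NULL)
}
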