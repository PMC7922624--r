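## Repeated k-fold cross-validation of genomic prediction accuracy.
##
## For each repeat a fresh random partition is drawn; within a repeat every
## model is evaluated on the identical partition so model comparisons are
## paired and free of partition noise. Validation phenotypes are set to NA
## before training, so validation individuals contribute nothing to the
## right-hand side; their GEBV come through the GRM off-diagonals only.
## Accuracy is the Pearson correlation between predicted GEBV and the
## held-out phenotype; the report aggregates fold means within repeats,
## then mean and SE (sd / sqrt(repeats)) over repeats.

#' Repeated k-fold genomic prediction cross-validation
#'
#' @param y phenotype vector (daughter trait deviations or simulated
#'   analogues) over all individuals.
#' @param models named list of models, each a named list of
#'   \linkS4class{GRM} objects (e.g. \code{list(SNP = list(snp = g1),
#'   SNPSV = list(snp = g1, sv = g2))}). All models see identical
#'   partitions.
#' @param X fixed design over all individuals (default intercept; include
#'   the breed-fraction covariate for combined cohorts).
#' @param k folds per repeat (default 10).
#' @param repeats number of re-sampled repeats (default 10).
#' @param seed partition seed.
#' @param refitVc re-estimate variance components on each training fold
#'   (default TRUE, statistically clean); when FALSE the components fitted
#'   once on the full data (or supplied via \code{vc}) are reused for
#'   speed, which is flagged in the report.
#' @param vc optional named list (per model) of
#'   \linkS4class{VarianceComponents} used when \code{refitVc = FALSE}.
#' @return list: \code{report} (data.frame model, meanAccuracy, se,
#'   refitVc), \code{foldAccuracy} (repeats x k x model array),
#'   \code{repeatMeans} (repeats x model).
#' @export
runPredictionCV <- function(y, models, X = NULL, k = 10, repeats = 10,
                            seed = 1, refitVc = TRUE, vc = NULL) {
  stopifnot(is.list(models), length(models) >= 1)
  if (is.null(names(models)) || any(names(models) == ""))
    names(models) <- paste0("model", seq_along(models))
  n <- length(y)
  ids <- names(y)
  if (is.null(ids)) ids <- sprintf("id%04d", seq_len(n))
  X <- if (is.null(X)) matrix(1, n, 1, dimnames = list(NULL, "intercept"))
       else as.matrix(X)

  if (!refitVc && is.null(vc)) {
    vc <- lapply(models, function(g) remlFit(y, g, X = X))
  }

  nm <- length(models)
  foldAcc <- array(NA_real_, dim = c(repeats, k, nm),
                   dimnames = list(NULL, NULL, names(models)))
  set.seed(seed)
  for (r in seq_len(repeats)) {
    plan <- makeFolds(ids, k = k, seed = NA)
    for (f in seq_len(k)) {
      val <- which(plan$assignment == f)
      if (length(val) < 10)
        warning("fold with fewer than 10 validation records")
      if (var(y[val]) < .Machine$double.eps) {
        message("constant phenotype in validation fold; fold skipped")
        next
      }
      yTrain <- y
      yTrain[val] <- NA
      for (m in seq_len(nm)) {
        grms <- models[[m]]
        vcm <- if (refitVc) {
          tr <- which(!is.na(yTrain))
          gTr <- lapply(grms, function(g)
            .asGrmMatrix(g)[tr, tr, drop = FALSE])
          remlFit(yTrain[tr], gTr, X = X[tr, , drop = FALSE])
        } else vc[[m]]
        sol <- solveBLUP(yTrain, grms, vcm, X = X)
        foldAcc[r, f, m] <- cor(sol$gebv[val], y[val])
      }
    }
  }
  repMeans <- apply(foldAcc, c(1, 3), mean, na.rm = TRUE)
  report <- data.frame(model = names(models),
                       meanAccuracy = colMeans(repMeans, na.rm = TRUE),
                       se = apply(repMeans, 2, sd, na.rm = TRUE) /
                         sqrt(repeats),
                       refitVc = refitVc, row.names = NULL)
  list(report = report, foldAccuracy = foldAcc, repeatMeans = repMeans)
}
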