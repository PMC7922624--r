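## REML and GBLUP for the model
##   y = X b + u_1 + ... + u_K + e,  u_k ~ N(0, G_k s2_k),  e ~ N(0, I s2_e)
## with dense genomic relationship matrices G_k (typically one SNP GRM and
## one SV GRM). Variance components are estimated by average-information
## REML with EM-REML fallback steps whenever an AI update leaves the
## parameter space or decreases the restricted likelihood; breeding values
## come from Henderson's mixed-model equations at the estimated components.

.asGrmMatrix <- function(g) {
  m <- if (is(g, "GRM")) as.matrix(g) else as.matrix(g)
  if (nrow(m) != ncol(m)) stop("GRM must be square")
  m
}

## Drop aliased columns of a fixed design (rank-deficient QR), with warning.
.fullRankDesign <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    warning("dropping aliased fixed-effect column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
  }
  X
}

.cholSafe <- function(V, label = "V") {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-6 * mean(diag(V))
    warning(label, " numerically singular; adding ridge ", signif(ridge, 3),
            " to the diagonal")
    ch <- chol(V + diag(ridge, nrow(V)))
  }
  ch
}

## Restricted log-likelihood and the P-matrix machinery for given
## components. Returns everything the AI/EM updates need.
.remlCore <- function(theta, Glist, X, y) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(Glist)) V <- V + theta[k] * Glist[[k]]
  cholV <- .cholSafe(V, "V")
  Vinv <- chol2inv(cholV)
  VinvX <- Vinv %*% X
  XtVX <- crossprod(X, VinvX)
  P <- Vinv - VinvX %*% solve(XtVX, t(VinvX))
  Py <- drop(P %*% y)
  logL <- -0.5 * (2 * sum(log(diag(cholV))) +
                  determinant(XtVX, logarithm = TRUE)$modulus +
                  sum(y * Py))
  list(P = P, Py = Py, logL = as.numeric(logL))
}

#' Average-information REML for GBLUP variance components
#'
#' Estimates one variance component per relationship matrix plus a residual
#' variance. Iterations start with an EM-REML step, then use AI updates;
#' whenever an AI update would leave the parameter space or reduce the
#' restricted log-likelihood, an EM step (which cannot decrease it) is
#' taken instead. Components are constrained to at least
#' \code{1e-8 * var(y)}; convergence is declared when the relative change
#' in restricted log-likelihood falls below \code{tol}. Standard errors
#' come from the inverse of the average-information matrix.
#'
#' @param y numeric phenotype vector (records with NA are dropped together
#'   with the matching rows/columns of X and the GRMs).
#' @param grms named list of \linkS4class{GRM} objects or square matrices,
#'   rows/columns aligned to \code{y}.
#' @param X fixed-effect design matrix (default intercept only). Aliased
#'   columns are dropped with a warning.
#' @param init optional named starting values (components + residual).
#' @param maxit,tol iteration cap (default 200) and relative log-likelihood
#'   tolerance (default 1e-8).
#' @param verbose print the iteration trace.
#' @return a \linkS4class{VarianceComponents}; component names are the GRM
#'   names plus \code{"residual"}.
#' @export
remlFit <- function(y, grms, X = NULL, init = NULL, maxit = 200,
                    tol = 1e-8, verbose = FALSE) {
  if (!is.list(grms)) grms <- list(g1 = grms)
  if (is.null(names(grms)) || any(names(grms) == ""))
    names(grms) <- paste0("g", seq_along(grms))
  Glist <- lapply(grms, .asGrmMatrix)
  keep <- which(!is.na(y))
  y0 <- y[keep]
  n <- length(y0)
  if (n < 30) stop("need at least 30 phenotyped records")
  X <- if (is.null(X)) matrix(1, n, 1, dimnames = list(NULL, "intercept"))
       else as.matrix(X)[keep, , drop = FALSE]
  X <- .fullRankDesign(X)
  Glist <- lapply(Glist, function(g) g[keep, keep, drop = FALSE])

  K <- length(Glist)
  vy <- var(y0)
  lb <- 1e-8 * vy
  theta <- if (!is.null(init)) pmax(as.numeric(init), lb) else
    c(rep(0.5 * vy / K, K), 0.5 * vy)
  names(theta) <- c(names(Glist), "residual")

  Gall <- c(Glist, list(diag(1, n)))
  trace <- numeric(0)
  logLprev <- -Inf
  converged <- FALSE
  AI <- diag(1, K + 1)
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    core <- .remlCore(theta, Glist, X, y0)
    trace <- c(trace, core$logL)
    if (verbose)
      message(sprintf("it %d  logL %.6f  [%s]", it, core$logL,
                      paste(signif(theta, 4), collapse = ", ")))
    ## quadratic forms and traces per component
    v <- lapply(Gall, function(G) drop(G %*% core$Py))
    yPGPy <- vapply(v, function(vk) sum(core$Py * vk), numeric(1))
    trPG <- vapply(Gall, function(G) sum(core$P * G), numeric(1))
    score <- -0.5 * (trPG - yPGPy)
    Pv <- lapply(v, function(vk) drop(core$P %*% vk))
    AI <- 0.5 * outer(seq_len(K + 1), seq_len(K + 1),
                      Vectorize(function(k, l) sum(v[[k]] * Pv[[l]])))
    AI <- (AI + t(AI)) / 2

    if (abs(core$logL - logLprev) < tol * (abs(logLprev) + 1) && it > 1L) {
      converged <- TRUE
      break
    }
    logLprev <- core$logL

    emStep <- function(th) pmax(th + th^2 / n * (yPGPy - trPG), lb)
    if (it == 1L) {
      theta <- setNames(emStep(theta), names(theta))
      next
    }
    delta <- tryCatch(solve(AI, score), error = function(e) NULL)
    proposal <- if (is.null(delta)) NULL else theta + delta
    useEM <- is.null(proposal) || any(proposal < lb)
    if (!useEM) {
      newLogL <- .remlCore(setNames(proposal, names(theta)), Glist, X, y0)$logL
      if (!is.finite(newLogL) || newLogL < core$logL - 1e-6) useEM <- TRUE
    }
    theta <- if (useEM) setNames(emStep(theta), names(theta))
             else setNames(proposal, names(theta))
  }
  if (!converged)
    warning("REML did not converge in ", maxit, " iterations")
  AIinv <- tryCatch(solve(AI), error = function(e) ginv(AI))
  se <- sqrt(pmax(diag(AIinv), 0))
  new("VarianceComponents",
      components = theta, se = setNames(se, names(theta)),
      logLik = trace[length(trace)], converged = converged,
      iterations = it, ai = AI, trace = trace)
}

#' Variance ratios from fitted components
#'
#' Returns the shares used to report GBLUP results: each genetic component
#' over phenotypic variance, total genetic over phenotypic (genomic
#' heritability), and the SV share of total genetic variance, with
#' \eqn{\sigma^2_p} the sum of all components. Values are not rounded;
#' rounding belongs to presentation.
#'
#' @param vc a \linkS4class{VarianceComponents}, or a named numeric vector
#'   of components including \code{"residual"} (the other entries are taken
#'   as genetic, in order SNP then SV).
#' @return one-row data.frame: \code{snpOverP}, \code{svOverP},
#'   \code{geneticOverP}, \code{svShareOfGenetic}, \code{sigmaP},
#'   \code{zeroGenetic} flag.
#' @examples
#' varianceRatios(c(snp = 0.766, sv = 0.038, residual = 0.196))
#' @export
varianceRatios <- function(vc) {
  comp <- if (is(vc, "VarianceComponents")) vc@components else vc
  if (is.null(names(comp)) || !"residual" %in% names(comp))
    stop("components must be named and include 'residual'")
  gen <- comp[setdiff(names(comp), "residual")]
  snp <- if (length(gen) >= 1) gen[[1]] else 0
  sv <- if (length(gen) >= 2) gen[[2]] else 0
  sigmaP <- sum(comp)
  totG <- snp + sv
  zero <- totG <= 0
  data.frame(snpOverP = snp / sigmaP, svOverP = sv / sigmaP,
             geneticOverP = totG / sigmaP,
             svShareOfGenetic = if (zero) 0 else sv / totG,
             sigmaP = sigmaP, zeroGenetic = zero)
}

#' Solve the GBLUP mixed model for fixed effects and breeding values
#'
#' Computes fixed-effect estimates and breeding values at given variance
#' components through the phenotypic-covariance form: b is the GLS estimate
#' under \eqn{V = \sum_k \sigma^2_k G_k + \sigma^2_e I} over the phenotyped
#' records and \eqn{\hat u_k = \sigma^2_k G_k[, obs] V^{-1}(y - X\hat b)}.
#' This is algebraically identical to Henderson's mixed-model equations but
#' remains exact when a GRM is singular (as sample-frequency GRMs always
#' are, since the standardized markers are centred). All individuals
#' carried by the GRMs receive predictions; individuals whose phenotype is
#' \code{NA} contribute no data and are predicted purely through the
#' off-diagonal relationships. The returned \code{residualNorm} is the
#' relative residual of the mixed-model equations in their G-multiplied
#' form (which avoids \eqn{G^{-1}}), a direct solver-contract check.
#'
#' @param y phenotype vector over all individuals (NA = no record), aligned
#'   with the GRM order.
#' @param grms named list of \linkS4class{GRM} or matrices (all
#'   individuals).
#' @param vc \linkS4class{VarianceComponents} or named numeric vector with
#'   entries matching \code{names(grms)} plus \code{"residual"}.
#' @param X fixed design over all individuals (default intercept).
#' @return list: \code{b} (fixed effects), \code{u} (list of per-component
#'   breeding-value vectors over all individuals), \code{gebv} (their sum),
#'   \code{residualNorm}.
#' @export
solveBLUP <- function(y, grms, vc, X = NULL) {
  if (!is.list(grms)) grms <- list(g1 = grms)
  if (is.null(names(grms)) || any(names(grms) == ""))
    names(grms) <- paste0("g", seq_along(grms))
  comp <- if (is(vc, "VarianceComponents")) vc@components else vc
  Glist <- lapply(grms, .asGrmMatrix)
  nInd <- nrow(Glist[[1]])
  obs <- which(!is.na(y))
  nObs <- length(obs)
  if (nObs == 0) stop("no phenotyped individuals")
  X <- if (is.null(X)) matrix(1, nInd, 1, dimnames = list(NULL, "intercept"))
       else as.matrix(X)
  Xo <- .fullRankDesign(X[obs, , drop = FALSE])
  yo <- y[obs]
  s2e <- comp[["residual"]]

  V <- diag(s2e, nObs)
  for (k in names(Glist)) V <- V + comp[[k]] * Glist[[k]][obs, obs]
  Vinv <- chol2inv(.cholSafe(V, "V"))
  VinvX <- Vinv %*% Xo
  b <- drop(solve(crossprod(Xo, VinvX), crossprod(VinvX, yo)))
  names(b) <- colnames(Xo)
  alpha <- drop(Vinv %*% (yo - Xo %*% b))
  u <- lapply(names(Glist), function(k)
    setNames(drop(comp[[k]] * Glist[[k]][, obs] %*% alpha),
             rownames(Glist[[k]])))
  names(u) <- names(Glist)
  gebv <- Reduce(`+`, u)

  ## G-multiplied Henderson residual: X'e* = 0 and
  ## G_k Z'e* = (s2e/s2k) u_k, with e* the record-level residual
  eStar <- yo - drop(Xo %*% b) - Reduce(`+`, lapply(u, `[`, obs))
  res <- c(drop(crossprod(Xo, eStar)),
           unlist(lapply(names(Glist), function(k)
             drop(Glist[[k]][, obs] %*% (eStar - s2e * alpha)))))
  rhsNorm <- sqrt(sum(crossprod(Xo, yo)^2) +
                  sum(unlist(lapply(Glist, function(G)
                    drop(G[, obs] %*% yo)))^2))
  list(b = b, u = u, gebv = gebv,
       residualNorm = sqrt(sum(res^2)) / max(rhsNorm, .Machine$double.eps))
}
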