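## Genomic relationship matrices.
##
## G_jk = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i)),
## the standard marker-standardization GRM of Yang et al. / GCTA, computed
## from 0/1/2 dosages. Missing calls (code 5) are mean-imputed to 2 p_i
## before standardization, which leaves p_i itself unchanged.

#' Alternative-allele frequencies from genotype codes
#'
#' \eqn{p_i} is the mean dosage over non-missing calls divided by 2.
#' Markers that are monomorphic, or have no non-missing call at all, are
#' flagged so downstream steps can exclude them.
#'
#' @param x a \linkS4class{GenotypeData} or a code matrix
#'   (markers x samples, codes in \{0,1,2,5\}).
#' @return data.frame: \code{id}, \code{p}, \code{maf}, \code{nCalls},
#'   \code{monomorphic}, \code{allMissing}.
#' @export
alleleFrequencies <- function(x) {
  d <- dosageMatrix(x)                       # individuals x markers, NA = missing
  nCalls <- colSums(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  p[nCalls == 0] <- NA_real_
  ids <- colnames(d)
  if (is.null(ids)) ids <- paste0("m", seq_len(ncol(d)))
  data.frame(id = ids, p = unname(p),
             maf = unname(pmin(p, 1 - p)), nCalls = unname(nCalls),
             monomorphic = unname(!is.na(p) & (p == 0 | p == 1)),
             allMissing = unname(nCalls == 0),
             stringsAsFactors = FALSE)
}

#' Build a genomic relationship matrix
#'
#' Markers are filtered to polymorphic loci with MAF >= \code{mafMin},
#' missing codes are mean-imputed to \eqn{2p_i}, columns are centred by
#' \eqn{2p_i} and scaled by \eqn{\sqrt{2p_i(1-p_i)}}, and the relationship
#' matrix is the average over markers of the outer products. The
#' alternative diagonal estimator of Yang et al. (based on
#' \eqn{x^2-(1+2p)x+2p^2}) is available via \code{yangDiagonal}.
#'
#' @param x \linkS4class{GenotypeData} or code matrix (markers x samples).
#' @param freqs optional data.frame from \code{\link{alleleFrequencies}}
#'   (recomputed when NULL).
#' @param mafMin minimum MAF; default 0 keeps every polymorphic marker.
#' @param yangDiagonal use the Yang et al. self-relationship estimator on
#'   the diagonal instead of the cross formula at j = k.
#' @return a \linkS4class{GRM}.
#' @examples
#' g <- matrix(c(0L, 2L, 1L, 1L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("m1", "m2"), c("a", "b")))
#' buildGRM(g)
#' @export
buildGRM <- function(x, freqs = NULL, mafMin = 0, yangDiagonal = FALSE) {
  d <- dosageMatrix(x)                       # individuals x markers
  if (is.null(freqs)) freqs <- alleleFrequencies(x)
  keep <- !freqs$monomorphic & !freqs$allMissing & !is.na(freqs$p) &
    freqs$maf >= mafMin
  if (!any(keep)) stop("no polymorphic markers survive the MAF filter")
  d <- d[, keep, drop = FALSE]
  p <- freqs$p[keep]
  ## mean-impute missing to 2p
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- 2 * p[idx[, 2L]]
  m <- ncol(d)
  w <- sweep(d, 2L, 2 * p, "-")
  w <- sweep(w, 2L, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(w) / m
  if (yangDiagonal) {
    ## 1 + (1/m) sum_i (x^2 - (1+2p)x + 2p^2) / (2p(1-p))
    sc <- 2 * p * (1 - p)
    term <- sweep(d * d - sweep(d, 2L, 1 + 2 * p, "*"), 2L, 2 * p * p, "+")
    diag(G) <- 1 + rowSums(sweep(term, 2L, sc, "/")) / m
  }
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(d), rownames(d))
  new("GRM", mat = G, freq = p, nMarkers = as.integer(m))
}
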