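## Central S4 containers.
##
## GenotypeData holds a markers x samples matrix of dosage codes in the
## alphabet {0, 1, 2, 5} (5 = missing, the convention used for
## depth-filtered and masked SV calls) as a RangedSummarizedExperiment:
## rowRanges carry the marker map (chrom/start/end plus a `type` column,
## "SNP" or an SV type), colData carries sample metadata (sex, breed
## fraction, sire and duplicate links).

GENO_CODES <- c(0L, 1L, 2L, 5L)
MISSING_CODE <- 5L
SV_TYPES <- c("DEL", "INS", "INV", "DUP")
BREED_FRACTIONS <- c(0, 0.25, 0.5, 0.75, 1)

#' GenotypeData: dosage codes with marker map and sample metadata
#'
#' A \linkS4class{RangedSummarizedExperiment} whose \code{"geno"} assay is an
#' integer matrix of genotype codes in \{0, 1, 2, 5\} (markers in rows,
#' individuals in columns; 5 codes a missing call). An optional
#' \code{"depth"} assay carries per-call sequencing read depth, and SV
#' objects produced by the simulator keep the pre-masking truth in a
#' \code{"truth"} assay. Row ranges hold marker coordinates (1-based,
#' inclusive) with a \code{type} metadata column (\code{"SNP"},
#' \code{"DEL"}, \code{"INS"}, \code{"INV"} or \code{"DUP"}).
#'
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  if (!"geno" %in% assayNames(object))
    return("assay 'geno' is required")
  g <- assay(object, "geno")
  ok <- is.na(g) | g %in% GENO_CODES
  if (!all(ok))
    return("genotype codes must be in {0, 1, 2, 5} or NA")
  if (is.null(mcols(rowRanges(object))$type))
    return("rowRanges must carry a 'type' column")
  TRUE
})

#' Construct a GenotypeData object
#'
#' @param geno integer matrix of codes in \{0,1,2,5\}, markers x samples.
#' @param ranges \link[GenomicRanges]{GRanges} of marker coordinates, one per
#'   row of \code{geno}, with a \code{type} metadata column.
#' @param samples optional \code{data.frame} of per-sample metadata (columns
#'   such as \code{sex}, \code{breedFraction}, \code{sireId},
#'   \code{duplicateOf}); row order must match the columns of \code{geno}.
#' @param depth optional integer matrix of per-call read depth, same
#'   dimensions as \code{geno}.
#' @return A \linkS4class{GenotypeData} object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1),
#'                              type = "SNP")
#' g <- matrix(c(0L, 1L, 2L, 1L), nrow = 2,
#'             dimnames = list(c("m1", "m2"), c("s1", "s2")))
#' genotypeData(g, gr)
#' @export
genotypeData <- function(geno, ranges, samples = NULL, depth = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (length(ranges) != nrow(geno))
    stop("length(ranges) must equal nrow(geno)")
  if (is.null(mcols(ranges)$type))
    mcols(ranges)$type <- "SNP"
  if (is.null(rownames(geno)))
    rownames(geno) <- if (!is.null(names(ranges))) names(ranges) else
      paste0("m", seq_len(nrow(geno)))
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("id", seq_len(ncol(geno)))
  names(ranges) <- rownames(geno)
  assays <- list(geno = geno)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    stopifnot(all(dim(depth) == dim(geno)))
    dimnames(depth) <- dimnames(geno)
    assays$depth <- depth
  }
  cd <- if (is.null(samples)) DataFrame(row.names = colnames(geno)) else {
    samples <- as.data.frame(samples)
    rownames(samples) <- colnames(geno)
    DataFrame(samples)
  }
  se <- SummarizedExperiment(assays = assays, rowRanges = ranges, colData = cd)
  new("GenotypeData", se)
}

#' @describeIn genotypeData extract the code matrix (markers x samples).
#' @param x a \code{GenotypeData} object.
#' @export
genoCodes <- function(x) assay(x, "geno")

#' @describeIn genotypeData extract the read-depth matrix or NULL.
#' @export
readDepth <- function(x) if ("depth" %in% assayNames(x)) assay(x, "depth") else NULL

#' @describeIn genotypeData marker coordinates as GRanges.
#' @export
markerRanges <- function(x) rowRanges(x)

#' @describeIn genotypeData sample metadata as a data.frame with an \code{id}
#'   column.
#' @export
sampleData <- function(x) {
  d <- as.data.frame(colData(x))
  if (!"id" %in% names(d))
    d <- cbind(id = colnames(x), d, stringsAsFactors = FALSE)
  rownames(d) <- NULL
  d
}

#' Numeric dosage matrix from genotype codes
#'
#' Returns an individuals x markers numeric matrix. Missing calls (code 5 or
#' NA) are returned as \code{NA} by default, or replaced by the marker mean
#' dosage \eqn{2p} (\code{missing = "mean"}), the convention used before
#' building relationship matrices.
#'
#' @param x a \linkS4class{GenotypeData} object or a code matrix
#'   (markers x samples).
#' @param missing one of \code{"NA"} or \code{"mean"}.
#' @return numeric matrix, individuals in rows, markers in columns.
#' @export
dosageMatrix <- function(x, missing = c("NA", "mean")) {
  missing <- match.arg(missing)
  g <- if (is(x, "GenotypeData")) genoCodes(x) else as.matrix(x)
  d <- t(g) * 1.0
  d[d == MISSING_CODE] <- NA_real_
  if (missing == "mean") {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    if (nrow(idx)) d[idx] <- mu[idx[, 2L]]
  }
  d
}

setMethod("show", "GenotypeData", function(object) {
  tab <- table(factor(mcols(rowRanges(object))$type,
                      levels = c("SNP", SV_TYPES)))
  cat("GenotypeData:", nrow(object), "markers x", ncol(object), "samples\n")
  cat("  marker types:",
      paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]),
            collapse = ", "), "\n")
  g <- assay(object, "geno")
  cat(sprintf("  missing calls (code 5): %.2f%%\n",
              100 * mean(g == MISSING_CODE, na.rm = TRUE)))
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  invisible(NULL)
})

#' GRM: genomic relationship matrix
#'
#' Symmetric n x n additive relationship matrix built from standardized
#' dosages, together with the allele frequencies and marker count used.
#'
#' @slot mat symmetric numeric matrix with sample ids as dimnames.
#' @slot freq alternative-allele frequencies of the markers used.
#' @slot nMarkers number of markers used.
#' @export
setClass("GRM", representation(mat = "matrix", freq = "numeric",
                               nMarkers = "integer"))

setValidity("GRM", function(object) {
  m <- object@mat
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (!all(is.finite(m))) return("matrix entries must be finite")
  if (max(abs(m - t(m))) > 1e-12) return("matrix must be symmetric (1e-12)")
  if (object@nMarkers < 1L) return("GRM needs >= 1 marker")
  TRUE
})

#' @describeIn GRM-class number of individuals.
#' @param x,object a \code{GRM}.
#' @export
setMethod("dim", "GRM", function(x) dim(x@mat))

#' @describeIn GRM-class the relationship matrix itself.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "GRM", function(x, ...) x@mat)

setMethod("show", "GRM", function(object) {
  cat("GRM:", nrow(object@mat), "individuals,", object@nMarkers, "markers\n")
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.4f\n",
              mean(diag(object@mat)),
              mean(object@mat[upper.tri(object@mat)])))
  invisible(NULL)
})

#' VarianceComponents: REML estimates for a GBLUP model
#'
#' @slot components named estimates; one entry per genetic component (named
#'   after its GRM) plus \code{"residual"}.
#' @slot se standard errors from the inverse average-information matrix.
#' @slot logLik restricted log-likelihood at the optimum.
#' @slot converged convergence flag.
#' @slot iterations iterations used.
#' @slot ai average-information matrix at the optimum.
#' @slot trace per-iteration log-likelihood trace.
#' @export
setClass("VarianceComponents",
         representation(components = "numeric", se = "numeric",
                        logLik = "numeric", converged = "logical",
                        iterations = "integer", ai = "matrix",
                        trace = "numeric"))

setValidity("VarianceComponents", function(object) {
  if (any(object@components < 0)) return("components must be >= 0")
  if (any(object@se < 0, na.rm = TRUE)) return("SEs must be >= 0")
  TRUE
})

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents (", if (object@converged) "converged"
      else "NOT converged", ", ", object@iterations, " iterations)\n",
      sep = "")
  print(data.frame(component = names(object@components),
                   estimate = unname(object@components),
                   se = unname(object@se), row.names = NULL))
  cat(sprintf("  restricted logLik: %.4f\n", object@logLik))
  invisible(NULL)
})
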