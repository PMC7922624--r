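## SV call-set representation and merging.
##
## SV records are GRanges (1-based, inclusive) with metadata columns `type`
## (DEL/INS/INV/DUP) and `source` (caller label). Merging follows the
## >= 1 bp overlap rule used when combining caller outputs: records of the
## same type on the same chromosome that overlap by at least `minOverlapBp`
## collapse transitively (union-find over the overlap graph) into one
## record spanning the union of the inputs.

.checkSorted <- function(gr, what) {
  o <- order(as.character(seqnames(gr)), start(gr))
  if (!identical(o, seq_along(gr))) {
    warning(what, " not sorted by (chrom, start); sorting internally")
    gr <- gr[o]
  }
  gr
}

.withSource <- function(gr, default) {
  if (is.null(mcols(gr)$source)) mcols(gr)$source <- rep(default, length(gr))
  if (is.null(mcols(gr)$type)) stop("SV records need a 'type' column")
  bad <- setdiff(unique(mcols(gr)$type), SV_TYPES)
  if (length(bad)) stop("unknown SV type(s): ", paste(bad, collapse = ", "))
  gr
}

## Transitive collapse of same-type records overlapping by >= minOverlapBp.
.collapseByType <- function(gr, minOverlapBp) {
  if (length(gr) == 0) return(gr)
  out <- lapply(split(seq_along(gr), mcols(gr)$type), function(idx) {
    g <- gr[idx]
    h <- findOverlaps(g, g, minoverlap = minOverlapBp)
    parent <- seq_along(g)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (e in seq_along(h)) {
      a <- find(queryHits(h)[e]); b <- find(subjectHits(h)[e])
      if (a != b) parent[b] <- a
    }
    comp <- vapply(seq_along(g), find, integer(1))
    groups <- split(seq_along(g), comp)
    merged <- lapply(groups, function(ii) {
      GRanges(seqnames(g)[ii[1L]],
              IRanges(min(start(g)[ii]), max(end(g)[ii])),
              type = mcols(g)$type[ii[1L]],
              source = paste(sort(unique(unlist(
                strsplit(mcols(g)$source[ii], "\\+")))), collapse = "+"))
    })
    do.call(c, unname(merged))
  })
  res <- do.call(c, unname(out))
  GenomeInfoDb::seqlevels(res) <- sort(GenomeInfoDb::seqlevels(res))
  res[order(as.character(seqnames(res)), start(res), end(res),
            mcols(res)$type)]
}

#' Merge two SV call sets by interval overlap
#'
#' Records of the same SV type that overlap by at least \code{minOverlapBp}
#' on the same chromosome are merged into a single record spanning the
#' union of their intervals (multi-way overlaps collapse transitively).
#' Non-overlapping records are kept as singletons; the \code{source} column
#' records which caller(s) contributed to each merged record.
#'
#' @param a,b \link[GenomicRanges]{GRanges} with \code{type} (and optionally
#'   \code{source}) metadata columns, sorted by (chrom, start); unsorted
#'   input is sorted with a warning.
#' @param minOverlapBp minimum overlap in bp (default 1).
#' @return merged \code{GRanges}, sorted, with \code{type} and \code{source}.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), type = "DEL")
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300), type = "DEL")
#' mergeSVCalls(a, b)   # 1 bp overlap -> one record chr1:101-300
#' @export
mergeSVCalls <- function(a, b, minOverlapBp = 1) {
  stopifnot(minOverlapBp >= 1)
  a <- .withSource(.checkSorted(a, "set a"), "setA")
  b <- .withSource(.checkSorted(b, "set b"), "setB")
  combined <- c(granges(a), granges(b))
  mcols(combined)$type <- c(mcols(a)$type, mcols(b)$type)
  mcols(combined)$source <- c(mcols(a)$source, mcols(b)$source)
  .collapseByType(combined, minOverlapBp)
}

#' Keep only calls overlapping a target SV set
#'
#' A call is retained exactly when it overlaps (>= \code{minOverlapBp},
#' same type) at least one record of the target set; all other calls are
#' dropped. This is the validation filter applied to raw caller output
#' against a trusted SV list.
#'
#' @param calls,target \code{GRanges} with a \code{type} column.
#' @param minOverlapBp minimum overlap in bp.
#' @return the retained subset of \code{calls}; the number dropped is
#'   reported via \code{message()}.
#' @export
intersectWithTarget <- function(calls, target, minOverlapBp = 1) {
  calls <- .withSource(.checkSorted(calls, "calls"), "calls")
  if (length(target) == 0) {
    warning("empty target set; returning no calls")
    return(calls[0])
  }
  target <- .withSource(.checkSorted(target, "target"), "target")
  keep <- rep(FALSE, length(calls))
  for (tp in unique(mcols(calls)$type)) {
    ci <- which(mcols(calls)$type == tp)
    ti <- which(mcols(target)$type == tp)
    if (length(ti))
      keep[ci] <- overlapsAny(calls[ci], target[ti], minoverlap = minOverlapBp)
  }
  message(sum(!keep), " of ", length(calls),
          " calls dropped (no target overlap)")
  calls[keep]
}

#' Build validated SV sets from replicate and pedigree links
#'
#' \code{TWICE_SEQ} contains SVs called in both sequencing replicates of at
#' least one twice-sequenced individual; \code{FAM} contains SVs called in
#' both members of at least one sire-son pair. "Called in both" means the
#' two per-sample records overlap by >= 1 bp and share the SV type; the
#' validated record spans their union, and records validated in several
#' pairs are collapsed by the usual >= 1 bp merge.
#'
#' @param calls named \link[GenomicRanges]{GRangesList}: per-sample SV calls
#'   (names are sample ids).
#' @param samples data.frame with columns \code{id}, \code{duplicateOf},
#'   \code{sireId} (NA when absent).
#' @return list with \code{GRanges} elements \code{TWICE_SEQ} and \code{FAM}.
#' @export
buildValidationSets <- function(calls, samples) {
  stopifnot(all(c("id", "duplicateOf", "sireId") %in% names(samples)))
  empty <- GRanges()
  mcols(empty)$type <- character(0); mcols(empty)$source <- character(0)

  validatePairs <- function(pairs, label) {
    if (nrow(pairs) == 0) {
      warning("no ", label, " links; returning empty set")
      return(empty)
    }
    validated <- empty
    for (r in seq_len(nrow(pairs))) {
      ga <- calls[[pairs$a[r]]]; gb <- calls[[pairs$b[r]]]
      if (is.null(ga) || is.null(gb) || length(ga) == 0 || length(gb) == 0) next
      for (tp in intersect(unique(mcols(ga)$type), unique(mcols(gb)$type))) {
        ai <- ga[mcols(ga)$type == tp]; bi <- gb[mcols(gb)$type == tp]
        h <- findOverlaps(ai, bi, minoverlap = 1L)
        if (length(h) == 0) next
        u <- GRanges(seqnames(ai)[queryHits(h)],
                     IRanges(pmin(start(ai)[queryHits(h)], start(bi)[subjectHits(h)]),
                             pmax(end(ai)[queryHits(h)], end(bi)[subjectHits(h)])),
                     type = tp, source = label)
        validated <- c(validated, u)
      }
    }
    if (length(validated) == 0) return(empty)
    .collapseByType(validated, 1L)
  }

  dup <- samples[!is.na(samples$duplicateOf), c("id", "duplicateOf")]
  names(dup) <- c("a", "b")
  fam <- samples[!is.na(samples$sireId), c("id", "sireId")]
  names(fam) <- c("a", "b")
  bad <- setdiff(fam$b, samples$id)
  if (length(bad)) stop("sireId refers to unknown sample(s): ",
                        paste(bad, collapse = ", "))
  list(TWICE_SEQ = validatePairs(dup, "TWICE_SEQ"),
       FAM = validatePairs(fam, "FAM"))
}

#' Encode caller genotypes as 0/1/2 dosages with a depth filter
#'
#' Transforms diploid genotype strings into alternative-allele counts
#' (0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternative)
#' and recodes calls whose read depth is below the threshold as missing
#' (code 5), the convention for unreliable sequencing-derived SV calls.
#'
#' @param gt character matrix (markers x samples) of genotype strings such
#'   as \code{"0/0"}, \code{"0/1"}, \code{"1|1"}, \code{"./."}.
#' @param depths integer matrix of per-call read depth, same shape;
#'   \code{NULL} disables the depth filter.
#' @param ranges \code{GRanges} describing the markers (one per row).
#' @param threshold depth below which a call is missing; default 5.
#' @return a \linkS4class{GenotypeData} with assays \code{geno} (and
#'   \code{depth} when given).
#' @export
encodeGenotypes <- function(gt, depths = NULL, ranges, threshold = 5) {
  gt <- as.matrix(gt)
  lookup <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
              "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L,
              "./." = MISSING_CODE, ".|." = MISSING_CODE, "." = MISSING_CODE)
  codes <- matrix(lookup[gt], nrow(gt), ncol(gt))
  if (anyNA(codes)) {
    bad <- which(is.na(codes), arr.ind = TRUE)[1L, ]
    stop("unknown genotype symbol '", gt[bad[1L], bad[2L]], "' at record '",
         if (!is.null(rownames(gt))) rownames(gt)[bad[1L]] else bad[1L],
         "', sample ",
         if (!is.null(colnames(gt))) colnames(gt)[bad[2L]] else bad[2L])
  }
  dimnames(codes) <- dimnames(gt)
  if (!is.null(depths)) {
    stopifnot(all(dim(depths) == dim(gt)))
    codes[depths < threshold] <- MISSING_CODE
  }
  genotypeData(codes, ranges, depth = depths)
}
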