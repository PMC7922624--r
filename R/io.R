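## Readers and writers. Dosage matrices, marker maps, phenotypes and GRMs
## are plain TSV for inspectability; marker maps follow the BED convention
## (0-based, half-open) on disk and convert to 1-based inclusive GRanges in
## memory. VCF is used only at the SV-call boundary.

#' Write / read a dosage matrix as TSV
#'
#' Rows are individuals (first column \code{id}), columns are markers; the
#' codes \{0,1,2,5\} are stored verbatim, so files round-trip bit-exactly.
#'
#' @param x \linkS4class{GenotypeData} or code matrix (markers x samples).
#' @param path output file.
#' @export
writeDosageTsv <- function(x, path) {
  g <- if (is(x, "GenotypeData")) genoCodes(x) else as.matrix(x)
  d <- data.frame(id = colnames(g), t(g), check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDosageTsv
#' @return \code{readDosageTsv}: integer code matrix, markers x samples.
#' @export
readDosageTsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  g <- t(as.matrix(d[, -1, drop = FALSE]))
  storage.mode(g) <- "integer"
  colnames(g) <- d$id
  g
}

#' Write / read a marker map as BED-like TSV
#'
#' Columns: chrom, start (0-based), end (half-open), id, type. In-memory
#' coordinates are 1-based inclusive GRanges; the conversion happens here.
#'
#' @param gr \code{GRanges} with a \code{type} column.
#' @param path file path.
#' @export
writeMarkerMap <- function(gr, path) {
  d <- data.frame(chrom = as.character(seqnames(gr)),
                  start = start(gr) - 1L, end = end(gr),
                  id = if (!is.null(names(gr))) names(gr)
                       else paste0("m", seq_along(gr)),
                  type = mcols(gr)$type, stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMarkerMap
#' @return \code{readMarkerMap}: a \code{GRanges}.
#' @export
readMarkerMap <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  gr <- GRanges(d$chrom, IRanges(d$start + 1L, d$end), type = d$type)
  names(gr) <- d$id
  gr
}

#' Write / read a phenotype table
#'
#' @param phenotypes data.frame with an \code{id} column and one column per
#'   trait.
#' @param path file path.
#' @export
writePhenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read sample metadata
#'
#' Columns: id, sex, breedFraction, sireId, duplicateOf (NA where absent).
#'
#' @param samples data.frame as returned by \code{\link{sampleData}}.
#' @param path file path.
#' @export
writeSamples <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname writeSamples
#' @export
readSamples <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA")
}

#' Write / read a GRM
#'
#' Two formats round-trip: \code{"tsv"}, the full matrix with an id header
#' column, and \code{"bin"}, the packed lower triangle (including the
#' diagonal) as doubles with a JSON sidecar (\code{<path>.json}) carrying
#' ids, marker count and allele frequencies.
#'
#' @param grm a \linkS4class{GRM}.
#' @param path file path.
#' @param format \code{"tsv"} or \code{"bin"}.
#' @export
writeGRM <- function(grm, path, format = c("tsv", "bin")) {
  format <- match.arg(format)
  m <- as.matrix(grm)
  if (format == "tsv") {
    d <- data.frame(id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
    write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(m[lower.tri(m, diag = TRUE)], con, size = 8)
    jsonlite::write_json(list(ids = rownames(m), nMarkers = grm@nMarkers,
                              freq = grm@freq),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname writeGRM
#' @return \code{readGRM}: a \linkS4class{GRM}.
#' @export
readGRM <- function(path, format = c("tsv", "bin")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d$id
    m <- (m + t(m)) / 2
    new("GRM", mat = m, freq = NA_real_, nMarkers = 1L)
  } else {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    n <- length(meta$ids)
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, "double", n * (n + 1) / 2, size = 8)
    m <- matrix(0, n, n, dimnames = list(meta$ids, meta$ids))
    m[lower.tri(m, diag = TRUE)] <- v
    m <- m + t(m) - diag(diag(m))
    new("GRM", mat = m, freq = as.numeric(meta$freq),
        nMarkers = as.integer(meta$nMarkers))
  }
}

## -- VCF boundary ----------------------------------------------------------

#' Read SV/SNP genotypes from a VCF file
#'
#' Uses POS, INFO/END, INFO/SVTYPE, FORMAT/GT and FORMAT/DP. Genotypes
#' become codes \{0,1,2\}; missing GT becomes 5. VCF coordinates (1-based
#' inclusive, with END for interval variants) map directly onto the
#' internal GRanges representation.
#'
#' @param path path to an (uncompressed or bgzipped) VCF.
#' @return a \linkS4class{GenotypeData} with \code{geno} (and \code{depth}
#'   when DP is present).
#' @export
readGenotypeVcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readGenotypeVcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  lookup <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
              "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  codes <- lookup[gt]
  codes[is.na(codes)] <- MISSING_CODE
  codes <- matrix(codes, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  endPos <- end(rr)
  if ("END" %in% names(info)) {
    e <- suppressWarnings(as.integer(unlist(info$END)))
    endPos <- ifelse(is.na(e), endPos, e)
  }
  type <- rep("SNP", length(rr))
  if ("SVTYPE" %in% names(info)) {
    tp <- as.character(unlist(info$SVTYPE))
    type <- ifelse(is.na(tp) | tp == "", "SNP", tp)
  }
  gr <- GRanges(as.character(seqnames(rr)), IRanges(start(rr), endPos),
                type = type)
  names(gr) <- rownames(gt)
  depth <- VariantAnnotation::geno(vcf)$DP
  if (!is.null(depth)) storage.mode(depth) <- "integer"
  genotypeData(codes, gr, depth = depth)
}

#' Write genotypes as a minimal VCF
#'
#' Emits a spec-compliant VCF 4.2 file with INFO END/SVTYPE and FORMAT
#' GT:DP (DP only when depths are present); codes map to 0/0, 0/1, 1/1 and
#' 5 to ./.. Intended for the SV-call boundary and for round-trip tests
#' with \code{\link{readGenotypeVcf}}.
#'
#' @param x a \linkS4class{GenotypeData}.
#' @param path output path (plain text).
#' @export
writeGenotypeVcf <- function(x, path) {
  g <- genoCodes(x)
  gr <- markerRanges(x)
  dp <- readDepth(x)
  gtStr <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1", `5` = "./.")
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
              "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              if (!is.null(dp))
                "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  type <- mcols(gr)$type
  rows <- vapply(seq_len(nrow(g)), function(i) {
    cells <- gtStr[as.character(g[i, ])]
    if (!is.null(dp)) cells <- paste0(cells, ":", dp[i, ])
    paste(c(as.character(seqnames(gr))[i], start(gr)[i], rownames(g)[i],
            "N", if (type[i] == "SNP") "A" else paste0("<", type[i], ">"),
            ".", "PASS",
            paste0("END=", end(gr)[i],
                   if (type[i] != "SNP") paste0(";SVTYPE=", type[i])),
            if (!is.null(dp)) "GT:DP" else "GT", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
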