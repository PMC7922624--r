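## Synthetic-population generator.
##
## Haplotypes arise from a founder-mosaic copying process: each gamete walks
## along the marker map copying from one founder haplotype at a time and
## switches to a freshly drawn founder with per-bp probability ldRho, so
## adjacent-marker LD decays with physical distance and is tunable from
## complete (ldRho = 0) to none (switch certain between markers). Two breed
## founder pools give between-breed differentiation; an admixed individual's
## gametes copy from the Holstein pool with probability equal to its breed
## fraction. SVs sit at random positions between flanking SNPs and their
## alleles ride on the same haplotypes as SNP alleles, which is what makes
## them imputable from SNPs downstream.

#' Simulation configuration
#'
#' Holds every parameter of the synthetic population. Defaults emulate the
#' reference cohort of a dairy-cattle SV imputation study at desk scale:
#' 478 sequenced individuals from two breeds (Holstein-fraction covariate in
#' \{0, 0.25, 0.5, 0.75, 1\}), 133 sire-son pairs and 38 twice-sequenced
#' duplicates, LD-structured SNP haplotypes with SVs nested among the SNPs,
#' additive variance split into a large SNP component and a small SV
#' component (roughly 0.75 and 0.04 of phenotypic variance), and
#' Poisson-distributed read depth governing missing SV calls.
#'
#' @slot nIndividuals,nSnp,nSv,nChrom counts.
#' @slot chromLengthBp chromosome length in bp.
#' @slot ldRho per-bp founder-switch probability in [0, 1]; between
#'   consecutive markers separated by d bp a gamete switches founder with
#'   probability 1 - (1 - ldRho)^d.
#' @slot breedFractions named mixture weights over the allowed Holstein
#'   fractions \{0, 0.25, 0.5, 0.75, 1\}.
#' @slot propVarSnp,propVarSv fractions of phenotypic variance assigned to
#'   the SNP and SV additive components (their sum must be <= 1).
#' @slot depthMean mean per-call sequencing depth (Poisson).
#' @slot nSireSonPairs,nDuplicates pedigree links and sequencing replicates.
#' @slot nFounders founder haplotypes per breed pool.
#' @slot mafShape Beta(mafShape, mafShape) shape for founder allele
#'   frequencies (1 = uniform; < 1 skews towards rare alleles).
#' @slot propCausal fraction of markers carrying effects per trait.
#' @slot nTraits number of simulated traits.
#' @slot seed integer seed; the whole dataset is a pure function of the
#'   configuration.
#' @export
setClass("SimConfig",
         representation(nIndividuals = "integer", nSnp = "integer",
                        nSv = "integer", nChrom = "integer",
                        chromLengthBp = "numeric", ldRho = "numeric",
                        breedFractions = "numeric", propVarSnp = "numeric",
                        propVarSv = "numeric", depthMean = "numeric",
                        nSireSonPairs = "integer", nDuplicates = "integer",
                        nFounders = "integer", mafShape = "numeric",
                        propCausal = "numeric", nTraits = "integer",
                        seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@nIndividuals < 1L || object@nSnp < 1L || object@nSv < 0L ||
      object@nChrom < 1L)
    return("counts must be positive")
  if (object@ldRho < 0 || object@ldRho > 1)
    return("ldRho must lie in [0, 1]")
  if (object@nSnp < 2L * object@nSv)
    return("need nSnp >= 2 * nSv")
  if (object@propVarSnp < 0 || object@propVarSv < 0 ||
      object@propVarSnp + object@propVarSv > 1)
    return("variance proportions must be in [0, 1] and sum to <= 1")
  f <- suppressWarnings(as.numeric(names(object@breedFractions)))
  if (anyNA(f) || !all(f %in% BREED_FRACTIONS))
    return("breedFractions names must be in {0, 0.25, 0.5, 0.75, 1}")
  if (any(object@breedFractions < 0) || sum(object@breedFractions) <= 0)
    return("breedFractions weights must be non-negative with positive sum")
  if (object@nSireSonPairs * 2L > object@nIndividuals)
    return("too many sire-son pairs for the cohort size")
  if (object@depthMean <= 0) return("depthMean must be positive")
  TRUE
})

#' @describeIn SimConfig-class constructor with study-scale defaults.
#' @param nIndividuals,nSnp,nSv,nChrom,chromLengthBp,ldRho,breedFractions
#'   see slots.
#' @param propVarSnp,propVarSv,depthMean,nSireSonPairs,nDuplicates see slots.
#' @param nFounders,mafShape,propCausal,nTraits,seed see slots.
#' @export
simConfig <- function(nIndividuals = 478, nSnp = 6000, nSv = 240,
                      nChrom = 5, chromLengthBp = 1e7, ldRho = 5e-6,
                      breedFractions = c(`0` = 0.20, `0.25` = 0.004,
                                         `0.5` = 0.018, `0.75` = 0.036,
                                         `1` = 0.742),
                      propVarSnp = 0.75, propVarSv = 0.04, depthMean = 12,
                      nSireSonPairs = 133, nDuplicates = 38,
                      nFounders = 16, mafShape = 1, propCausal = 0.1,
                      nTraits = 3, seed = 1) {
  new("SimConfig", nIndividuals = as.integer(nIndividuals),
      nSnp = as.integer(nSnp), nSv = as.integer(nSv),
      nChrom = as.integer(nChrom), chromLengthBp = as.numeric(chromLengthBp),
      ldRho = as.numeric(ldRho), breedFractions = breedFractions,
      propVarSnp = as.numeric(propVarSnp), propVarSv = as.numeric(propVarSv),
      depthMean = as.numeric(depthMean),
      nSireSonPairs = as.integer(nSireSonPairs),
      nDuplicates = as.integer(nDuplicates), nFounders = as.integer(nFounders),
      mafShape = as.numeric(mafShape), propCausal = as.numeric(propCausal),
      nTraits = as.integer(nTraits), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nIndividuals, "individuals,", object@nSnp,
      "SNPs,", object@nSv, "SVs on", object@nChrom, "chromosomes\n")
  cat(sprintf("  ldRho=%g, depthMean=%g, varProps snp=%g sv=%g, seed=%d\n",
              object@ldRho, object@depthMean, object@propVarSnp,
              object@propVarSv, object@seed))
  invisible(NULL)
})

#' Synthetic population container
#'
#' @slot snp SNP \linkS4class{GenotypeData} (complete calls).
#' @slot sv SV \linkS4class{GenotypeData}; assay \code{geno} carries the
#'   depth-masked codes (5 = missing), \code{truth} the pre-masking codes
#'   and \code{depth} the simulated read depths.
#' @slot phenotypes data.frame: \code{id} plus one column per trait.
#' @slot components per-trait list of data.frames with the true additive
#'   SNP component, SV component and residual for every individual.
#' @slot config the \linkS4class{SimConfig} that generated the data.
#' @export
setClass("SyntheticPopulation",
         representation(snp = "GenotypeData", sv = "GenotypeData",
                        phenotypes = "data.frame", components = "list",
                        config = "SimConfig"))

setMethod("show", "SyntheticPopulation", function(object) {
  cat("SyntheticPopulation:", ncol(object@snp), "samples (",
      object@config@nDuplicates, "replicates ),",
      nrow(object@snp), "SNPs,", nrow(object@sv), "SVs,",
      ncol(object@phenotypes) - 1L, "traits\n")
  invisible(NULL)
})

## -- marker map ------------------------------------------------------------

## SNP positions uniform per chromosome; SV anchors dropped into random
## interior SNP gaps, interval lengths log-uniform on [100 bp, 10 kb].
.simulateMap <- function(config) {
  perChromSnp <- diff(round(seq(0, config@nSnp, length.out = config@nChrom + 1)))
  perChromSv <- diff(round(seq(0, config@nSv, length.out = config@nChrom + 1)))
  chrom <- integer(0); pos <- integer(0); endp <- integer(0); type <- character(0)
  for (c in seq_len(config@nChrom)) {
    ns <- perChromSnp[c]; nv <- perChromSv[c]
    sp <- sort(sample.int(config@chromLengthBp - 1L, ns))
    svStart <- integer(0); svEnd <- integer(0); svType <- character(0)
    if (nv > 0) {
      gaps <- sample(seq_len(ns - 1L), nv)
      svStart <- sp[gaps] + 1L +
        floor(runif(nv) * pmax(sp[gaps + 1L] - sp[gaps] - 1L, 1L))
      len <- round(10 ^ runif(nv, 2, 4))
      svEnd <- pmin(svStart + len, config@chromLengthBp)
      svType <- sample(c("DEL", "INV", "DUP"), nv, replace = TRUE,
                       prob = c(0.8, 0.1, 0.1))
    }
    chrom <- c(chrom, rep(c, ns + nv))
    pos <- c(pos, sp, svStart)
    endp <- c(endp, sp, svEnd)
    type <- c(type, rep("SNP", ns), svType)
  }
  gr <- GRanges(paste0("chr", chrom), IRanges(pos, endp), type = type)
  names(gr) <- ifelse(type == "SNP",
                      paste0("snp_chr", chrom, "_", pos),
                      paste0("sv_chr", chrom, "_", pos))
  ord <- order(chrom, pos)
  gr[ord]
}

## -- founder pools ---------------------------------------------------------

.simulateFounders <- function(config, nMarkers) {
  lapply(c(jersey = 1, holstein = 2), function(b) {
    p <- rbeta(nMarkers, config@mafShape, config@mafShape)
    matrix(rbinom(config@nFounders * nMarkers, 1L, rep(p, each = config@nFounders)),
           nrow = config@nFounders)
  })
}

## Per-interval switch probabilities along the sorted map; the first marker
## of each chromosome always re-draws its founder.
.switchProbs <- function(map, ldRho) {
  d <- c(0L, diff(start(map)))
  newChrom <- c(TRUE, as.character(seqnames(map))[-1] !=
                  as.character(seqnames(map))[-length(map)])
  p <- 1 - (1 - ldRho) ^ pmax(d, 1L)
  p[newChrom] <- 1
  p
}

## One mosaic gamete: copy founder rows of the stacked pool matrix
## (jersey founders then holstein founders) along segment boundaries.
.mosaicGamete <- function(stacked, nF, holsteinFraction, switchProb) {
  m <- length(switchProb)
  sw <- rbinom(m, 1L, switchProb)
  sw[1L] <- 1L
  seg <- cumsum(sw)
  nSeg <- seg[m]
  pool <- rbinom(nSeg, 1L, holsteinFraction)      # 1 = holstein
  fid <- sample.int(nF, nSeg, replace = TRUE) + pool * nF
  stacked[cbind(fid[seg], seq_len(m))]
}

## Gamete transmitted by a sire: a recombinant mosaic of his two haplotypes.
.transmitGamete <- function(h1, h2, switchProb) {
  m <- length(switchProb)
  sw <- rbinom(m, 1L, switchProb)
  sw[1L] <- 1L
  seg <- cumsum(sw)
  which2 <- rbinom(seg[m], 1L, 0.5)
  ifelse(which2[seg] == 1L, h2, h1)
}

#' Simulate breed-structured haplotypes with nested SVs
#'
#' Builds the marker map (SNPs plus SV intervals), two breed founder pools,
#' and one pair of mosaic gametes per individual, including transmitted
#' gametes for sire-son pairs. Returns the raw haplotypes so callers can
#' verify transmission and LD structure directly; most users want
#' \code{\link{simulatePopulation}}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param seed optional integer overriding \code{config@seed}; use
#'   \code{NA} to leave the RNG state untouched (internal chaining).
#' @return list with elements \code{map} (GRanges, sorted), \code{hap1} and
#'   \code{hap2} (individuals x markers 0/1 matrices), \code{samples}
#'   (data.frame: id, sex, breedFraction, sireId, duplicateOf) covering the
#'   distinct individuals only, and \code{founders}.
#' @export
simulateHaplotypes <- function(config, seed = NULL) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (is.null(seed)) seed <- config@seed
  if (!is.na(seed)) set.seed(seed)
  map <- .simulateMap(config)
  m <- length(map)
  founders <- .simulateFounders(config, m)
  stacked <- rbind(founders$jersey, founders$holstein)
  sp <- .switchProbs(map, config@ldRho)
  n <- config@nIndividuals
  nPairs <- config@nSireSonPairs

  fracs <- as.numeric(names(config@breedFractions))
  breedFraction <- sample(fracs, n, replace = TRUE,
                          prob = config@breedFractions / sum(config@breedFractions))
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sireId <- rep(NA_character_, n)
  ids <- sprintf("id%04d", seq_len(n))

  ## sons occupy the tail of the cohort; sires are drawn (without
  ## replacement while possible) from earlier pure-Holstein males
  sonIdx <- if (nPairs > 0) (n - nPairs + 1L):n else integer(0)
  if (nPairs > 0) {
    breedFraction[sonIdx] <- 1
    sex[sonIdx] <- "M"
    candidates <- setdiff(which(breedFraction == 1 & sex == "M"), sonIdx)
    if (length(candidates) < nPairs) {       # promote enough sires
      promote <- setdiff(seq_len(n - nPairs), candidates)[
        seq_len(nPairs - length(candidates))]
      breedFraction[promote] <- 1
      sex[promote] <- "M"
      candidates <- c(candidates, promote)
    }
    sires <- sample(candidates, nPairs,
                    replace = length(candidates) < nPairs)
    sireId[sonIdx] <- ids[sires]
  }

  hap1 <- matrix(0L, n, m); hap2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    if (i %in% sonIdx) next
    hap1[i, ] <- .mosaicGamete(stacked, config@nFounders, breedFraction[i], sp)
    hap2[i, ] <- .mosaicGamete(stacked, config@nFounders, breedFraction[i], sp)
  }
  if (nPairs > 0) {
    sires <- match(sireId[sonIdx], ids)
    for (k in seq_along(sonIdx)) {
      i <- sonIdx[k]; s <- sires[k]
      hap1[i, ] <- .transmitGamete(hap1[s, ], hap2[s, ], sp)
      hap2[i, ] <- .mosaicGamete(stacked, config@nFounders, breedFraction[i], sp)
    }
  }
  rownames(hap1) <- rownames(hap2) <- ids
  samples <- data.frame(id = ids, sex = sex, breedFraction = breedFraction,
                        sireId = sireId, duplicateOf = NA_character_,
                        stringsAsFactors = FALSE)
  list(map = map, hap1 = hap1, hap2 = hap2, samples = samples,
       founders = founders)
}

#' Simulate phenotypes from stored genotypes
#'
#' Per trait, Gaussian effects are assigned to a random subset of SNPs and
#' SVs; the SNP and SV additive components and the residual are constructed
#' mutually orthogonal in-sample (sequential projection then rescaling) so
#' each attains exactly its requested share of the unit phenotypic variance
#' and the variance bookkeeping is exact. True per-individual components are
#' returned alongside the phenotype.
#'
#' @param snpDosage,svDosage individuals x markers numeric dosage matrices
#'   (complete, un-masked codes).
#' @param propVarSnp,propVarSv target fractions of phenotypic variance
#'   (sum <= 1).
#' @param nTraits number of traits to draw.
#' @param propCausal fraction of markers with non-zero effect per trait.
#' @param seed integer seed, or NA to continue the current RNG stream.
#' @return list: \code{phenotypes} (data.frame id + trait columns),
#'   \code{components} (per-trait data.frame gSnp, gSv, e).
#' @export
simulatePhenotypes <- function(snpDosage, svDosage, propVarSnp, propVarSv,
                               nTraits = 1, propCausal = 0.1, seed = NULL) {
  if (propVarSnp < 0 || propVarSv < 0 || propVarSnp + propVarSv > 1)
    stop("variance proportions must be non-negative and sum to <= 1")
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  n <- nrow(snpDosage)
  ids <- rownames(snpDosage)
  if (is.null(ids)) ids <- sprintf("id%04d", seq_len(n))

  component <- function(dosage, prop) {
    if (prop <= 0 || ncol(dosage) == 0) return(rep(0, n))
    nc <- max(1L, round(propCausal * ncol(dosage)))
    idx <- sample.int(ncol(dosage), nc)
    g <- drop(dosage[, idx, drop = FALSE] %*% rnorm(nc))
    g - mean(g)
  }
  rescale <- function(v, target) {
    s <- var(v)
    if (target <= 0) return(rep(0, n))
    if (s < .Machine$double.eps) stop("degenerate genetic component (no variation)")
    v * sqrt(target / s)
  }
  orth <- function(v, basis) {        # residualize v on centered basis
    for (b in basis) if (var(b) > 0) v <- v - b * (sum(v * b) / sum(b * b))
    v - mean(v)
  }

  phen <- data.frame(id = ids, stringsAsFactors = FALSE)
  comps <- vector("list", nTraits)
  for (tr in seq_len(nTraits)) {
    gSnp <- rescale(component(snpDosage, propVarSnp), propVarSnp)
    gSv <- component(svDosage, propVarSv)
    gSv <- rescale(orth(gSv, list(gSnp)), propVarSv)
    e <- rnorm(n)
    e <- rescale(orth(e - mean(e), list(gSnp, gSv)), 1 - propVarSnp - propVarSv)
    phen[[paste0("trait", tr)]] <- gSnp + gSv + e
    comps[[tr]] <- data.frame(id = ids, gSnp = gSnp, gSv = gSv, e = e,
                              stringsAsFactors = FALSE)
  }
  names(comps) <- paste0("trait", seq_len(nTraits))
  list(phenotypes = phen, components = comps)
}

#' Apply depth-dependent missingness to SV calls
#'
#' Draws a Poisson read depth per call (unless depths are supplied) and
#' recodes calls with depth below the threshold as missing (code 5),
#' mirroring the depth filter applied to sequencing-derived SV genotypes.
#'
#' @param geno integer matrix of SV codes (markers x samples) or a
#'   \linkS4class{GenotypeData}.
#' @param depthMean mean of the per-call Poisson depth.
#' @param threshold calls with depth < threshold become missing; default 5.
#' @param depth optional pre-drawn depth matrix.
#' @param seed integer seed, or NA to continue the current RNG stream.
#' @return list: \code{geno} (masked codes), \code{depth},
#'   \code{missingRate} (fraction of calls set to 5).
#' @export
applyDepthMissingness <- function(geno, depthMean, threshold = 5,
                                  depth = NULL, seed = NULL) {
  if (threshold < 0) stop("threshold must be non-negative")
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  g <- if (is(geno, "GenotypeData")) genoCodes(geno) else as.matrix(geno)
  if (is.null(depth)) {
    depth <- matrix(rpois(length(g), depthMean), nrow(g), ncol(g),
                    dimnames = dimnames(g))
  }
  masked <- g
  low <- depth < threshold
  masked[low] <- MISSING_CODE
  list(geno = masked, depth = depth, missingRate = mean(low))
}

#' Simulate a complete synthetic population
#'
#' Runs the full generator: haplotypes, SNP/SV genotype matrices,
#' depth-based SV missingness, twice-sequenced duplicate samples, and
#' phenotypes with stored true components. Everything is a pure function of
#' the configuration (including its seed).
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{SyntheticPopulation}.
#' @examples
#' pop <- simulatePopulation(simConfig(nIndividuals = 60, nSnp = 300,
#'                                     nSv = 20, nSireSonPairs = 5,
#'                                     nDuplicates = 3, seed = 7))
#' pop
#' @export
simulatePopulation <- function(config = simConfig()) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  hp <- simulateHaplotypes(config, seed = NA)
  map <- hp$map
  isSnp <- mcols(map)$type == "SNP"
  geno <- t(hp$hap1 + hp$hap2)            # markers x individuals
  storage.mode(geno) <- "integer"

  samples <- hp$samples
  nDup <- config@nDuplicates
  if (nDup > 0) {
    dupOf <- sample(samples$id, nDup)
    dup <- samples[match(dupOf, samples$id), ]
    dup$duplicateOf <- dupOf
    dup$id <- paste0(dupOf, "_rep2")
    dup$sireId <- NA_character_          # pedigree link lives on the animal
    samples <- rbind(samples, dup)
    geno <- cbind(geno, geno[, match(dupOf, colnames(geno)), drop = FALSE])
  }
  colnames(geno) <- samples$id

  snpGeno <- geno[isSnp, , drop = FALSE]
  svTruth <- geno[!isSnp, , drop = FALSE]
  dm <- applyDepthMissingness(svTruth, config@depthMean, threshold = 5,
                              seed = NA)

  snp <- genotypeData(snpGeno, map[isSnp], samples = samples)
  sv <- genotypeData(dm$geno, map[!isSnp], samples = samples,
                     depth = dm$depth)
  dimnames(svTruth) <- dimnames(genoCodes(sv))
  assays(sv, withDimnames = FALSE)$truth <- svTruth
  metadata(sv)$missingRate <- dm$missingRate

  base <- !grepl("_rep2$", samples$id)
  ph <- simulatePhenotypes(t(snpGeno[, base, drop = FALSE]),
                           t(svTruth[, base, drop = FALSE]),
                           config@propVarSnp, config@propVarSv,
                           nTraits = config@nTraits,
                           propCausal = config@propCausal, seed = NA)
  new("SyntheticPopulation", snp = snp, sv = sv,
      phenotypes = ph$phenotypes, components = ph$components,
      config = config)
}
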