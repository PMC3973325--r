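## S4 classes for the central containers: genome records, simulation plans,
## IPD calibration models, motif partition counts and DE classifications.

setOldClass("data.frame")

#' GenomeRecord: a single (optionally circular) contig
#'
#' Thin wrapper around a [Biostrings::DNAString] carrying the contig name and
#' a circularity flag.  Most functions in the package accept a `GenomeRecord`
#' wherever a sequence is needed and honour its circularity for coordinate
#' arithmetic (motif scanning across the origin junction, promoter wrapping).
#'
#' @slot contig contig name.
#' @slot sequence a [Biostrings::DNAString] (alphabet A/C/G/T/N).
#' @slot circular logical; `TRUE` for a circular bacterial chromosome.
#'
#' @exportClass GenomeRecord
setClass("GenomeRecord",
         slots = c(contig = "character",
                   sequence = "DNAString",
                   circular = "logical"))

setValidity("GenomeRecord", function(object) {
    msg <- character()
    if (length(object@contig) != 1L || !nzchar(object@contig))
        msg <- c(msg, "'contig' must be a single non-empty string")
    if (length(object@circular) != 1L || is.na(object@circular))
        msg <- c(msg, "'circular' must be TRUE or FALSE")
    bad <- setdiff(unique(strsplit(as.character(object@sequence), "")[[1]]),
                   c("A", "C", "G", "T", "N"))
    if (length(bad))
        msg <- c(msg, paste0("sequence contains letters outside A/C/G/T/N: ",
                             paste(bad, collapse = ",")))
    if (length(msg)) msg else TRUE
})

#' Construct a GenomeRecord
#'
#' @param sequence character string, [Biostrings::DNAString], or a
#'   length-one [Biostrings::DNAStringSet].
#' @param contig contig name.
#' @param circular logical circularity flag.
#'
#' @return A [GenomeRecord-class] object.  A warning is emitted when more
#'   than 10\% of the bases are `N`.
#' @export
GenomeRecord <- function(sequence, contig = "chr", circular = TRUE) {
    if (is(sequence, "DNAStringSet")) {
        stopifnot(length(sequence) == 1L)
        if (is.null(contig) || identical(contig, "chr")) {
            nm <- names(sequence)
            if (!is.null(nm) && nzchar(nm[1L]))
                contig <- sub("\\s.*$", "", nm[1L])
        }
        sequence <- sequence[[1L]]
    }
    if (is.character(sequence))
        sequence <- DNAString(toupper(sequence))
    obj <- new("GenomeRecord", contig = contig, sequence = sequence,
               circular = circular)
    nfrac <- sum(strsplit(as.character(sequence), "")[[1]] == "N") /
        max(1L, length(sequence))
    if (nfrac >= 0.1)
        warning(sprintf("contig %s: %.1f%% of bases are N", contig,
                        100 * nfrac))
    obj
}

#' @describeIn GenomeRecord contig name accessor
#' @param x a `GenomeRecord`.
#' @export
contigName <- function(x) x@contig

#' @describeIn GenomeRecord sequence accessor (returns a `DNAString`)
#' @export
genomeSequence <- function(x) x@sequence

setMethod("length", "GenomeRecord", function(x) length(x@sequence))

setMethod("isCircular", "GenomeRecord", function(x) x@circular)

setMethod("show", "GenomeRecord", function(object) {
    cat(sprintf("GenomeRecord '%s': %d bp, %s\n", object@contig,
                length(object@sequence),
                if (object@circular) "circular" else "linear"))
})

#' SyntheticPlan: parameters of the synthetic-data generator
#'
#' Holds every tunable of the simulation: genome geometry, planted GANTC
#' densities in coding versus intergenic DNA, the replication-timing
#' hemi-methylation gradient from origin to terminus, counts of planted
#' bilaterally under-methylated and asymmetrically methylated sites, the
#' IPD kinetics noise model, and the expression experiment layout.
#'
#' The defaults describe the wild-type-like study condition used throughout
#' the test suite: a 1-Mb circular chromosome carrying roughly 2000 GANTC
#' sites, a hemi-methylation gradient falling from 0.8 near the origin to
#' 0.1 near the terminus, 24 bilaterally under-methylated plus 11
#' asymmetric sites, a fully methylated IPD ratio of 7.68, per-molecule
#' IPD coefficient of variation 0.3 and mean coverage 50.
#'
#' @slot seed integer RNG seed; identical seed and plan give byte-identical
#'   outputs.
#' @slot genomeLength chromosome length in bp.
#' @slot circular logical.
#' @slot nGenes number of genes to place.
#' @slot geneLengthMean mean gene length (bp).
#' @slot motifDensityCoding,motifDensityIntergenic expected planted GANTC
#'   per kb of coding / intergenic DNA.
#' @slot originPosition replication origin coordinate (0-based bp).
#' @slot gradient length-2 numeric: hemi-methylated population fraction at
#'   the origin and at the terminus.
#' @slot nUnder,nAsym planted sites under-methylated on both / exactly one
#'   strand.
#' @slot rFullTrue population-average IPD ratio of a fully methylated
#'   adenine.
#' @slot ipdCv per-molecule lognormal coefficient of variation of the IPD
#'   ratio.
#' @slot coverageMean Poisson mean read coverage per position (floored at
#'   one read).
#' @slot nReplicates expression replicates per condition.
#' @slot deFraction fraction of genes planted as differentially expressed.
#' @slot deEffect planted absolute log2 effect size.
#' @slot motifDeCoupling odds multiplier linking promoter-motif presence to
#'   planted down-regulation (1 = independence).
#' @slot noiseSd replicate-level log2 intensity noise SD.
#' @slot baseFreq length-4 background base frequencies (A, C, G, T).
#'
#' @exportClass SyntheticPlan
setClass("SyntheticPlan",
         slots = c(seed = "integer", genomeLength = "numeric",
                   circular = "logical", nGenes = "integer",
                   geneLengthMean = "numeric",
                   motifDensityCoding = "numeric",
                   motifDensityIntergenic = "numeric",
                   originPosition = "numeric", gradient = "numeric",
                   nUnder = "integer", nAsym = "integer",
                   rFullTrue = "numeric", ipdCv = "numeric",
                   coverageMean = "numeric", nReplicates = "integer",
                   deFraction = "numeric", deEffect = "numeric",
                   motifDeCoupling = "numeric", noiseSd = "numeric",
                   baseFreq = "numeric"))

setValidity("SyntheticPlan", function(object) {
    msg <- character()
    chk1 <- function(x, nm) if (length(x) != 1L || is.na(x))
        paste0("'", nm, "' must be a single non-missing value") else NULL
    for (nm in c("seed", "genomeLength", "nGenes", "geneLengthMean",
                 "motifDensityCoding", "motifDensityIntergenic",
                 "originPosition", "nUnder", "nAsym", "rFullTrue", "ipdCv",
                 "coverageMean", "nReplicates", "deFraction", "deEffect",
                 "motifDeCoupling", "noiseSd"))
        msg <- c(msg, chk1(slot(object, nm), nm))
    if (length(msg)) return(msg)
    if (object@genomeLength < 1000)
        msg <- c(msg, "'genomeLength' must be at least 1000 bp")
    for (nm in c("nGenes", "geneLengthMean", "motifDensityCoding",
                 "motifDensityIntergenic", "nUnder", "nAsym", "ipdCv",
                 "coverageMean", "noiseSd"))
        if (slot(object, nm) < 0)
            msg <- c(msg, paste0("'", nm, "' must be >= 0"))
    if (length(object@gradient) != 2L || any(object@gradient < 0) ||
        any(object@gradient > 1))
        msg <- c(msg, "'gradient' must be two values in [0, 1]")
    if (object@deFraction < 0 || object@deFraction > 1)
        msg <- c(msg, "'deFraction' must be in [0, 1]")
    if (object@rFullTrue <= 1)
        msg <- c(msg, "'rFullTrue' must exceed 1 (unmethylated baseline)")
    if (object@motifDeCoupling <= 0)
        msg <- c(msg, "'motifDeCoupling' must be positive")
    if (object@nReplicates < 2L)
        msg <- c(msg, "'nReplicates' must be at least 2")
    if (length(object@baseFreq) != 4L || any(object@baseFreq < 0) ||
        abs(sum(object@baseFreq) - 1) > 1e-8)
        msg <- c(msg, "'baseFreq' must be 4 non-negative values summing to 1")
    if (object@originPosition < 0 ||
        object@originPosition >= object@genomeLength)
        msg <- c(msg, "'originPosition' must lie within the genome")
    if (length(msg)) msg else TRUE
})

#' Create a synthetic-data plan
#'
#' See [SyntheticPlan-class] for the meaning of every parameter; the
#' defaults are the wild-type-like study condition.
#'
#' @param seed integer RNG seed.
#' @param genomeLength,circular,nGenes,geneLengthMean genome geometry.
#' @param motifDensityCoding,motifDensityIntergenic planted GANTC per kb.
#' @param originPosition,gradient replication-timing gradient.
#' @param nUnder,nAsym planted special site classes.
#' @param rFullTrue,ipdCv,coverageMean kinetics model.
#' @param nReplicates,deFraction,deEffect,motifDeCoupling,noiseSd expression
#'   model.
#' @param baseFreq background base composition (A, C, G, T).
#'
#' @return A validated [SyntheticPlan-class].
#' @examples
#' plan <- syntheticPlan(seed = 1, genomeLength = 5e4, nGenes = 25)
#' @export
syntheticPlan <- function(seed = 1L, genomeLength = 1e6, circular = TRUE,
                          nGenes = 500L, geneLengthMean = 1000,
                          motifDensityCoding = 1.5,
                          motifDensityIntergenic = 2.5,
                          originPosition = 0, gradient = c(0.8, 0.1),
                          nUnder = 24L, nAsym = 11L, rFullTrue = 7.68,
                          ipdCv = 0.3, coverageMean = 50,
                          nReplicates = 3L, deFraction = 0.1,
                          deEffect = 2, motifDeCoupling = 2,
                          noiseSd = 0.25,
                          baseFreq = c(A = 0.25, C = 0.25, G = 0.25,
                                       T = 0.25)) {
    new("SyntheticPlan", seed = as.integer(seed),
        genomeLength = genomeLength, circular = circular,
        nGenes = as.integer(nGenes), geneLengthMean = geneLengthMean,
        motifDensityCoding = motifDensityCoding,
        motifDensityIntergenic = motifDensityIntergenic,
        originPosition = originPosition, gradient = as.numeric(gradient),
        nUnder = as.integer(nUnder), nAsym = as.integer(nAsym),
        rFullTrue = rFullTrue, ipdCv = ipdCv, coverageMean = coverageMean,
        nReplicates = as.integer(nReplicates), deFraction = deFraction,
        deEffect = deEffect, motifDeCoupling = motifDeCoupling,
        noiseSd = noiseSd, baseFreq = as.numeric(baseFreq))
}

setMethod("show", "SyntheticPlan", function(object) {
    cat(sprintf(paste0(
        "SyntheticPlan: %d bp %s genome, %d genes, seed %d\n",
        "  GANTC density (coding/intergenic): %.2f / %.2f per kb\n",
        "  gradient (origin/terminus hemi fraction): %.2f / %.2f\n",
        "  planted sites: %d under-methylated, %d asymmetric\n",
        "  IPD: r_full %.2f, cv %.2f, coverage %.0f\n",
        "  expression: %d reps, DE fraction %.2f, effect %.2f,",
        " coupling %.1f\n"),
        round(object@genomeLength),
        if (object@circular) "circular" else "linear",
        object@nGenes, object@seed, object@motifDensityCoding,
        object@motifDensityIntergenic, object@gradient[1],
        object@gradient[2], object@nUnder, object@nAsym,
        object@rFullTrue, object@ipdCv, object@coverageMean,
        object@nReplicates, object@deFraction, object@deEffect,
        object@motifDeCoupling))
})

#' CalibrationModel: two-state IPD mixing calibration
#'
#' The population-average IPD ratio at a motif adenine is modelled as the
#' linear mixture `r = f * r_full + (1 - f) * 1`, where `f` is the fraction
#' of chromosomes in the population methylated at that strand position.
#' `r_full` is estimated from a constitutively methylated reference sample;
#' the theoretical hemi-methylated average is `r_hemi = (r_full + 1) / 2`.
#' Strand adenines with mean IPD ratio below the threshold `tau` are called
#' under-methylated.
#'
#' @slot rFull population-average IPD ratio of a fully methylated adenine.
#' @slot rHemi `(rFull + 1) / 2`.
#' @slot rUnmeth unmethylated baseline, fixed at 1.
#' @slot tau under-methylation threshold (default 2.4).
#'
#' @exportClass CalibrationModel
setClass("CalibrationModel",
         slots = c(rFull = "numeric", rHemi = "numeric",
                   rUnmeth = "numeric", tau = "numeric"))

setValidity("CalibrationModel", function(object) {
    msg <- character()
    if (!(object@rFull > object@rHemi && object@rHemi > object@rUnmeth))
        msg <- c(msg, "need rFull > rHemi > rUnmeth")
    if (!(object@tau > object@rUnmeth && object@tau < object@rFull))
        msg <- c(msg, "'tau' must lie strictly between rUnmeth and rFull")
    if (length(msg)) msg else TRUE
})

#' Construct a calibration model from a known fully methylated IPD ratio
#'
#' @param rFull population-average IPD ratio of fully methylated adenines.
#' @param tau under-methylation threshold.
#' @return A [CalibrationModel-class].
#' @examples
#' calibrationModel(7.68)   # rHemi = 4.34
#' @export
calibrationModel <- function(rFull, tau = 2.4) {
    new("CalibrationModel", rFull = rFull, rHemi = (rFull + 1) / 2,
        rUnmeth = 1, tau = tau)
}

#' @describeIn CalibrationModel fully methylated IPD ratio
#' @param x a `CalibrationModel`.
#' @export
rFull <- function(x) x@rFull

#' @describeIn CalibrationModel theoretical hemi-methylated IPD ratio
#' @export
rHemi <- function(x) x@rHemi

#' @describeIn CalibrationModel under-methylation threshold
#' @export
tauThreshold <- function(x) x@tau

setMethod("show", "CalibrationModel", function(object) {
    cat(sprintf(
        "CalibrationModel: r_full = %.4g, r_hemi = %.4g, tau = %.4g\n",
        object@rFull, object@rHemi, object@tau))
})

#' PartitionCounts: observed and expected motif counts per genome partition
#'
#' Observed counts of a pentanucleotide in the whole genome, in coding
#' sequences, in RNA gene sequences and (by subtraction) in intergenic DNA,
#' together with the expected counts under a single-base composition null
#' and the proportional length allocation, and the resulting obs/exp
#' ratios.
#'
#' @slot pattern the IUPAC motif (e.g. `"GANTC"`).
#' @slot contig contig name.
#' @slot observed,expected,ratio named numeric vectors over partitions
#'   `genome`, `coding`, `rna`, `intergenic`.
#' @slot baseFreq genome base frequencies (A, C, G, T; N excluded).
#' @slot genomeLength genome length in bp.
#' @slot partitionLength named partition lengths in bp.
#'
#' @exportClass PartitionCounts
setClass("PartitionCounts",
         slots = c(pattern = "character", contig = "character",
                   observed = "numeric", expected = "numeric",
                   ratio = "numeric", baseFreq = "numeric",
                   genomeLength = "numeric", partitionLength = "numeric"))

#' @describeIn PartitionCounts observed counts accessor
#' @param x a `PartitionCounts`.
#' @export
observedCounts <- function(x) x@observed

#' @describeIn PartitionCounts expected counts accessor
#' @export
expectedCounts <- function(x) x@expected

#' @describeIn PartitionCounts observed/expected ratio accessor
#' @export
obsExpRatio <- function(x) x@ratio

setMethod("show", "PartitionCounts", function(object) {
    cat(sprintf("PartitionCounts for %s on '%s' (%d bp)\n", object@pattern,
                object@contig, round(object@genomeLength)))
    df <- data.frame(partition = names(object@observed),
                     observed = object@observed,
                     expected = signif(object@expected, 6),
                     ratio = signif(object@ratio, 4), row.names = NULL)
    print(df)
})

#' Coerce PartitionCounts to a data.frame
#'
#' @param x a [PartitionCounts-class].
#' @param row.names,optional,... ignored; present for S3 compatibility.
#' @return One row per partition with observed, expected and ratio columns.
#' @export
as.data.frame.PartitionCounts <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
    data.frame(contig = x@contig, pattern = x@pattern,
               partition = names(x@observed), observed = x@observed,
               expected = x@expected, ratio = x@ratio,
               length_bp = x@partitionLength[names(x@observed)],
               row.names = NULL)
}

#' DEClassification: significance and strength sets of a DE analysis
#'
#' Genes with BH-adjusted p below `alpha` are significant; significant
#' genes split into up- and downregulated by the sign of the log2 ratio,
#' and into strong sets by `|log2 ratio| >= log2(strongFold)`.
#'
#' @slot universe all genes with expression data.
#' @slot significant,up,down,strongUp,strongDown gene id sets (characters).
#' @slot alpha adjusted-p significance threshold (strict `<`).
#' @slot strongFold fold-change threshold on the linear scale.
#'
#' @exportClass DEClassification
setClass("DEClassification",
         slots = c(universe = "character", significant = "character",
                   up = "character", down = "character",
                   strongUp = "character", strongDown = "character",
                   alpha = "numeric", strongFold = "numeric"))

setValidity("DEClassification", function(object) {
    msg <- character()
    if (!all(object@significant %in% object@universe))
        msg <- c(msg, "significant set not contained in universe")
    if (!all(object@up %in% object@significant) ||
        !all(object@down %in% object@significant))
        msg <- c(msg, "up/down sets not contained in significant set")
    if (!all(object@strongUp %in% object@up) ||
        !all(object@strongDown %in% object@down))
        msg <- c(msg, "strong sets not contained in up/down sets")
    if (length(intersect(object@up, object@down)))
        msg <- c(msg, "up and down sets overlap")
    if (length(msg)) msg else TRUE
})

#' @describeIn DEClassification universe accessor
#' @param x a `DEClassification`.
#' @export
deUniverse <- function(x) x@universe

#' @describeIn DEClassification significant genes
#' @export
significantGenes <- function(x) x@significant

#' @describeIn DEClassification significantly upregulated genes
#' @export
upGenes <- function(x) x@up

#' @describeIn DEClassification significantly downregulated genes
#' @export
downGenes <- function(x) x@down

#' @describeIn DEClassification strongly upregulated genes
#' @export
strongUpGenes <- function(x) x@strongUp

#' @describeIn DEClassification strongly downregulated genes
#' @export
strongDownGenes <- function(x) x@strongDown

setMethod("show", "DEClassification", function(object) {
    cat(sprintf(paste0(
        "DEClassification (alpha = %g, strong fold = %g):\n",
        "  universe %d | significant %d | up %d | down %d | ",
        "strong up %d | strong down %d\n"),
        object@alpha, object@strongFold, length(object@universe),
        length(object@significant), length(object@up),
        length(object@down), length(object@strongUp),
        length(object@strongDown)))
})
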