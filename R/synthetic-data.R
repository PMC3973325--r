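## Synthetic-data generators.  Every generator is deterministic given the
## plan seed (each one seeds its own stream with a fixed offset so the
## outputs do not depend on call order) and emits a truth table so each
## downstream stage has a recovery target.

.seedOffset <- c(genome = 0L, methylation = 1L, ipd = 2L, expression = 3L,
                 sets = 4L, panel = 5L)

## remove every GANTC occurrence from a background letter vector by
## rewriting the motif's adenine; iterates because an edit can create a
## new occurrence in an overlapping window
.scrubMotif <- function(letters, pattern = "GANTC") {
    repeat {
        occ <- scanMotif(paste(letters, collapse = ""), pattern,
                         circular = TRUE)
        if (!length(occ)) break
        letters[(occ + 1L) %% length(letters) + 1L] <- "C"
    }
    letters
}

## k non-overlapping 5-mer start offsets inside a region of length m,
## without rejection: distinct draws from 0..(m - 5k) spread by 5
.packedStarts <- function(m, k, motifLen = 5L) {
    if (k == 0L) return(integer(0))
    slots <- m - motifLen * k
    if (slots < 0)
        stop("requested motif density is infeasible for the genome length")
    y <- sort(sample.int(slots + 1L, k, replace = FALSE) - 1L)
    y + motifLen * (seq_len(k) - 1L)
}

#' Generate a synthetic genome with planted GANTC sites
#'
#' Builds a random background sequence with the plan's base composition,
#' scrubs it of incidental GANTC occurrences, lays out non-overlapping
#' genes (about 5\% tagged as RNA genes) separated by random intergenic
#' gaps, and plants GANTC motifs at the requested densities -- sites fully
#' inside gene bodies count as coding, sites fully inside gaps as
#' intergenic.  Because GANTC cannot overlap itself and planted motifs
#' cannot combine with their surroundings into new occurrences, the motif
#' content of the genome is exactly the planted set.
#'
#' @param plan a [SyntheticPlan-class].
#' @return list with `genome` (a [GenomeRecord-class]), `features`
#'   (a [GenomicRanges::GRanges] with `id` and `class` columns) and
#'   `sites` (truth data.frame: `position0`, `partition`, `center`).
#' @export
generateGenome <- function(plan) {
    stopifnot(is(plan, "SyntheticPlan"))
    set.seed(plan@seed + .seedOffset[["genome"]])
    L <- as.integer(plan@genomeLength)
    bases <- c("A", "C", "G", "T")
    letters <- sample(bases, L, replace = TRUE, prob = plan@baseFreq)
    letters <- .scrubMotif(letters)

    ## gene layout
    nG <- plan@nGenes
    glen <- pmax(150L, as.integer(round(
        rgamma(nG, shape = 10, rate = 10 / plan@geneLengthMean))))
    spare <- L - sum(glen)
    if (spare < nG)
        stop("genes do not fit: reduce nGenes or geneLengthMean")
    ## one gap before each gene; the gap before gene 1 doubles as the
    ## gap between the last and first gene on the circle
    gaps <- as.vector(rmultinom(1, spare - nG, rep(1, nG))) + 1L
    starts0 <- cumsum(gaps) + cumsum(c(0L, glen[-nG]))
    ends0 <- starts0 + glen
    stopifnot(max(ends0) <= L)
    strandv <- sample(c("+", "-"), nG, replace = TRUE)
    cls <- ifelse(runif(nG) < 0.05, "rna", "protein_coding")
    ids <- sprintf("gene_%04d", seq_len(nG))

    ## plant motifs
    codingLen <- sum(glen)
    gapStarts <- c(0L, ends0[-nG])
    gapEnds <- starts0
    gapLen <- gapEnds - gapStarts
    interLen <- sum(gapLen)
    nCoding <- rpois(1, plan@motifDensityCoding * codingLen / 1000)
    nInter <- rpois(1, plan@motifDensityIntergenic * interLen / 1000)
    plantIn <- function(rStarts, rLens, k) {
        if (k == 0L) return(integer(0))
        if (sum(pmax(0L, rLens - 4L)) < 5L * k + k)
            stop("requested motif density is infeasible for the genome length")
        per <- as.vector(rmultinom(1, k, pmax(0, rLens - 4)))
        unlist(lapply(seq_along(per), function(i) {
            if (per[i] == 0L) return(integer(0))
            rStarts[i] + .packedStarts(rLens[i], per[i])
        }), use.names = FALSE)
    }
    posCoding <- plantIn(starts0, glen, as.integer(nCoding))
    posInter <- plantIn(gapStarts, gapLen, as.integer(nInter))
    centers <- sample(bases, length(posCoding) + length(posInter),
                      replace = TRUE)
    allPos <- c(posCoding, posInter)
    ord <- order(allPos)
    allPos <- allPos[ord]
    centers <- centers[ord]
    partition <- c(rep("coding", length(posCoding)),
                   rep("intergenic", length(posInter)))[ord]
    for (i in seq_along(allPos)) {
        p <- allPos[i]
        letters[(p:(p + 4L)) + 1L] <- c("G", "A", centers[i], "T", "C")
    }
    genome <- GenomeRecord(paste(letters, collapse = ""), contig = "chr",
                           circular = plan@circular)
    gr <- GRanges("chr", IRanges(start = starts0 + 1L, end = ends0),
                  strand = strandv)
    mcols(gr)$id <- ids
    mcols(gr)$class <- cls
    seqlengths(gr) <- c(chr = L)
    isCircular(gr) <- c(chr = plan@circular)
    list(genome = genome, features = gr,
         sites = data.frame(position0 = allPos, partition = partition,
                            center = centers))
}

#' Assign per-site per-strand methylated fractions
#'
#' Non-planted sites follow the replication-timing gradient: the
#' hemi-methylated population fraction `h` interpolates linearly in
#' circular distance from the origin between `gradient[1]` (origin) and
#' `gradient[2]` (terminus), and both strands carry the methylated
#' fraction `f = 1 - h / 2` (a hemi-methylated chromosome contributes one
#' methylated strand, symmetrically across the population).  `nUnder`
#' randomly chosen sites are set to fraction 0 on both strands and `nAsym`
#' further sites to 0 on one uniformly chosen strand.
#'
#' @param plan a [SyntheticPlan-class].
#' @param sites truth data.frame from [generateGenome()] (needs
#'   `position0`).
#' @return data.frame with `position0`, `class`
#'   (`gradient`/`under`/`asym`), `asym_strand` (NA, `"+"` or `"-"`),
#'   `hemi_fraction`, `full_fraction` (= 1 - h for gradient sites),
#'   `f_plus`, `f_minus`.
#' @export
generateMethylationPlan <- function(plan, sites) {
    stopifnot(is(plan, "SyntheticPlan"), nrow(sites) > 0)
    if (plan@nUnder + plan@nAsym > nrow(sites))
        stop("nUnder + nAsym exceeds the number of planted sites")
    set.seed(plan@seed + .seedOffset[["methylation"]])
    L <- plan@genomeLength
    d <- abs(sites$position0 - plan@originPosition)
    d <- pmin(d, L - d)
    h <- plan@gradient[1] +
        (plan@gradient[2] - plan@gradient[1]) * d / (L / 2)
    f <- 1 - h / 2
    n <- nrow(sites)
    cls <- rep("gradient", n)
    asym <- rep(NA_character_, n)
    special <- sample.int(n, plan@nUnder + plan@nAsym)
    iU <- special[seq_len(plan@nUnder)]
    iA <- special[plan@nUnder + seq_len(plan@nAsym)]
    cls[iU] <- "under"
    cls[iA] <- "asym"
    fp <- f
    fm <- f
    fp[iU] <- 0
    fm[iU] <- 0
    asym[iA] <- sample(c("+", "-"), length(iA), replace = TRUE)
    fp[iA][asym[iA] == "+"] <- 0
    fm[iA][asym[iA] == "-"] <- 0
    data.frame(position0 = sites$position0, class = cls,
               asym_strand = asym, hemi_fraction = h,
               full_fraction = 1 - h, f_plus = fp, f_minus = fm)
}

#' Force a methylation plan to the fully methylated state
#'
#' Companion reference for calibration: every strand fraction set to 1.
#'
#' @param methylation data.frame from [generateMethylationPlan()].
#' @return The plan with `f_plus = f_minus = 1` everywhere.
#' @export
fullyMethylatedPlan <- function(methylation) {
    methylation$class <- "full_reference"
    methylation$f_plus <- 1
    methylation$f_minus <- 1
    methylation
}

#' Simulate coverage-averaged IPD ratios at motif adenines
#'
#' For each motif adenine on each strand, coverage is drawn as
#' Poisson(`coverageMean`) floored at one read; each molecule is
#' methylated with the strand's planted fraction, and its IPD ratio is
#' lognormal with mean `rFullTrue` (methylated) or 1 (unmethylated) and
#' coefficient of variation `ipdCv`.  The observed value is the mean over
#' the molecules, so its expectation is the two-state mixture
#' `f * rFullTrue + (1 - f)`; with `ipdCv = 0` and fraction 0 or 1 the
#' observation is exact.
#'
#' @param plan a [SyntheticPlan-class].
#' @param methylation data.frame from [generateMethylationPlan()] (or
#'   [fullyMethylatedPlan()]).
#' @param contig contig name for the kinetics table.
#' @param seedOffset added to the plan seed; use a different value for the
#'   reference dataset so it draws an independent stream.
#' @return Kinetics data.frame with columns `contig`, `position0`,
#'   `strand`, `ipd_ratio`, `coverage` plus `motif_start0` linking each
#'   adenine to its motif.
#' @export
generateIpdDataset <- function(plan, methylation, contig = "chr",
                               seedOffset = 0L) {
    stopifnot(is(plan, "SyntheticPlan"))
    set.seed(plan@seed + .seedOffset[["ipd"]] + as.integer(seedOffset))
    L <- as.integer(plan@genomeLength)
    ad <- motifAdenines(methylation$position0, L,
                        circular = plan@circular)
    tab <- rbind(
        data.frame(motif_start0 = ad$site, position0 = ad$plus_pos,
                   strand = "+", f = methylation$f_plus),
        data.frame(motif_start0 = ad$site, position0 = ad$minus_pos,
                   strand = "-", f = methylation$f_minus))
    n <- nrow(tab)
    cov <- pmax(1L, rpois(n, plan@coverageMean))
    m <- rbinom(n, cov, tab$f)
    cv <- plan@ipdCv
    sdlog <- sqrt(log(1 + cv^2))
    drawSum <- function(counts, mu) {
        tot <- sum(counts)
        if (tot == 0L) return(numeric(n))
        z <- rlnorm(tot, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
        grp <- rep.int(seq_len(n), counts)
        out <- numeric(n)
        s <- rowsum(z, grp)
        out[as.integer(rownames(s))] <- s
        out
    }
    obs <- (drawSum(m, plan@rFullTrue) + drawSum(cov - m, 1)) / cov
    data.frame(contig = contig, position0 = tab$position0,
               strand = tab$strand, ipd_ratio = obs, coverage = cov,
               motif_start0 = tab$motif_start0)
}

#' Simulate a replicate expression matrix with planted DE
#'
#' Per-gene baseline log2 intensities are normal(9, 1.5); a fraction
#' `deFraction` of genes is planted as differentially expressed with
#' effect `+/- deEffect` in the mutant condition, and replicate noise is
#' normal with SD `noiseSd`.  Down-regulated genes are drawn with
#' selection weight `motifDeCoupling` for promoter-motif-bearing genes
#' (weight 1 otherwise, renormalised), so `motifDeCoupling = 1` makes
#' planted DE independent of motif presence.
#'
#' @param plan a [SyntheticPlan-class].
#' @param geneIds character vector of gene identifiers.
#' @param promoterFlags logical vector: gene has a promoter GANTC motif.
#' @return list with `matrix` (genes x replicates, columns
#'   `wt_1..n`, `mut_1..n`) and `truth` (`gene_id`, `planted` in
#'   none/up/down, `has_motif`).
#' @export
generateExpressionDataset <- function(plan, geneIds, promoterFlags) {
    stopifnot(is(plan, "SyntheticPlan"),
              length(geneIds) == length(promoterFlags))
    set.seed(plan@seed + .seedOffset[["expression"]])
    n <- length(geneIds)
    nDE <- round(plan@deFraction * n)
    nDown <- floor(nDE / 2)
    nUp <- nDE - nDown
    w <- ifelse(promoterFlags, plan@motifDeCoupling, 1)
    downIdx <- if (nDown > 0) sample.int(n, nDown, prob = w) else integer(0)
    rest <- setdiff(seq_len(n), downIdx)
    upIdx <- if (nUp > 0) sample(rest, nUp) else integer(0)
    planted <- rep("none", n)
    planted[downIdx] <- "down"
    planted[upIdx] <- "up"
    delta <- ifelse(planted == "down", -plan@deEffect,
                    ifelse(planted == "up", plan@deEffect, 0))
    mu <- rnorm(n, 9, 1.5)
    R <- plan@nReplicates
    wt <- matrix(rnorm(n * R, mu, plan@noiseSd), nrow = n)
    mut <- matrix(rnorm(n * R, mu + delta, plan@noiseSd), nrow = n)
    mat <- cbind(wt, mut)
    dimnames(mat) <- list(geneIds,
                          c(sprintf("wt_%d", seq_len(R)),
                            sprintf("mut_%d", seq_len(R))))
    list(matrix = mat,
         truth = data.frame(gene_id = geneIds, planted = planted,
                            has_motif = promoterFlags))
}

#' Simulate gene-set catalogs (regulons, COG letters, essential genes)
#'
#' Assigns one single-letter COG category per gene, builds one regulon
#' with a planted overlap with the down-regulated truth set plus
#' independent control regulons, and samples an essential-gene set.
#'
#' @param plan a [SyntheticPlan-class].
#' @param geneIds character vector of gene identifiers.
#' @param deTruth `truth` data.frame from [generateExpressionDataset()].
#' @param setSize genes per regulon.
#' @param overlapFrac fraction of the coupled regulon drawn from planted
#'   down-regulated genes.
#' @param nNull number of independent control regulons.
#' @return list with `cog` (data.frame `gene_id`, `cog`) and `sets`
#'   (named list of gene-id vectors, including `essential`).
#' @export
generateGeneSets <- function(plan, geneIds, deTruth, setSize = 50,
                             overlapFrac = 0.5, nNull = 2) {
    set.seed(plan@seed + .seedOffset[["sets"]])
    n <- length(geneIds)
    setSize <- min(setSize, n)
    cogLetters <- c("J", "K", "L", "D", "M", "N", "T", "C", "G", "E",
                    "P", "R", "S")
    cog <- data.frame(gene_id = geneIds,
                      cog = sample(cogLetters, n, replace = TRUE))
    downGenes <- deTruth$gene_id[deTruth$planted == "down"]
    nOv <- min(length(downGenes), round(overlapFrac * setSize))
    coupled <- union(sample(downGenes, nOv),
                     sample(setdiff(geneIds, downGenes), setSize - nOv))
    sets <- list(regulon_coupled = coupled)
    for (i in seq_len(nNull))
        sets[[sprintf("regulon_null_%d", i)]] <- sample(geneIds, setSize)
    sets$essential <- sample(geneIds, max(1L, round(0.15 * n)))
    list(cog = cog, sets = sets)
}

#' Simulate a cross-species promoter motif presence panel
#'
#' Bernoulli presence matrix: gene i has a promoter motif in species j
#' with probability `conservationProbs[i]`.
#'
#' @param plan a [SyntheticPlan-class].
#' @param geneIds character vector of gene identifiers.
#' @param nSpecies number of related species.
#' @param conservationProbs per-gene conservation propensity, recycled to
#'   the number of genes.
#' @return Integer 0/1 matrix genes x species.
#' @export
generateOrthologPanel <- function(plan, geneIds, nSpecies = 5,
                                  conservationProbs = 0.5) {
    set.seed(plan@seed + .seedOffset[["panel"]])
    n <- length(geneIds)
    p <- rep_len(conservationProbs, n)
    m <- matrix(rbinom(n * nSpecies, 1L, rep(p, nSpecies)), nrow = n)
    dimnames(m) <- list(geneIds, sprintf("species_%d", seq_len(nSpecies)))
    m
}
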