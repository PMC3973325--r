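## Pentanucleotide counting and observed/expected statistics.
##
## Conventions: motif occurrence positions are 0-based starts on the
## forward strand; overlapping matches are all counted; windows containing
## an N never match; on circular contigs matches spanning the end-start
## junction are counted once.

.validMotif <- function(pattern) {
    if (length(pattern) != 1L || !nzchar(pattern))
        stop("'pattern' must be a single non-empty IUPAC string")
    pattern <- toupper(pattern)
    bad <- setdiff(strsplit(pattern, "")[[1]], names(IUPAC_CODE_MAP))
    if (length(bad))
        stop("invalid IUPAC letters in pattern: ", paste(bad, collapse = ","))
    pattern
}

.seqChar <- function(x) {
    if (is(x, "GenomeRecord")) as.character(genomeSequence(x))
    else if (is(x, "DNAString")) as.character(x)
    else toupper(as.character(x))
}

## forward-strand extraction of [start0, start0+len) with circular wrap
.substrCircular <- function(s, start0, len, L, circular) {
    if (len <= 0) return("")
    if (start0 < 0) start0 <- start0 %% L
    if (start0 + len <= L) return(substr(s, start0 + 1L, start0 + len))
    if (!circular)
        stop("interval extends past the end of a linear contig")
    paste0(substr(s, start0 + 1L, L), substr(s, 1L, start0 + len - L))
}

#' Scan a sequence for an IUPAC motif
#'
#' Finds all occurrences of a degenerate motif, overlaps allowed.  Windows
#' containing `N` in the subject never match.  On circular sequences,
#' occurrences spanning the end-start junction are reported once, at their
#' (0-based) start position.
#'
#' @param x a character string, [Biostrings::DNAString] or
#'   [GenomeRecord-class].
#' @param pattern IUPAC motif, default `"GANTC"`.
#' @param circular treat the sequence as circular; defaults to the record's
#'   flag for a `GenomeRecord` and `FALSE` otherwise.
#'
#' @return Sorted integer vector of 0-based start positions (empty when the
#'   sequence is shorter than the pattern).
#' @examples
#' scanMotif("GACTCGAGTC")        # 0 and 5
#' scanMotif("TCGAN", circular = TRUE)  # wraps: GANTC starting at 2
#' @export
scanMotif <- function(x, pattern = "GANTC", circular = NULL) {
    pattern <- .validMotif(pattern)
    if (is.null(circular))
        circular <- if (is(x, "GenomeRecord")) isCircular(x) else FALSE
    s <- .seqChar(x)
    L <- nchar(s)
    k <- nchar(pattern)
    if (L < k) return(integer(0))
    s2 <- if (circular) paste0(s, substr(s, 1L, k - 1L)) else s
    hits <- matchPattern(pattern, DNAString(s2), fixed = "subject")
    starts <- GenomicRanges::start(hits) - 1L
    starts <- starts[starts < L]
    if (length(starts) && grepl("N", s2, fixed = TRUE)) {
        keep <- !vapply(starts, function(p)
            grepl("N", substr(s2, p + 1L, p + k), fixed = TRUE), logical(1))
        starts <- starts[keep]
    }
    sort(as.integer(starts))
}

#' Single-base frequencies of a genome
#'
#' Frequencies of A, C, G and T; `N` bases are excluded from both the
#' numerator and the denominator.
#'
#' @param x a character string, [Biostrings::DNAString] or
#'   [GenomeRecord-class].
#' @return Named numeric vector over A, C, G, T summing to 1.
#' @examples
#' baseFrequencies("ACGT")
#' @export
baseFrequencies <- function(x) {
    s <- if (is(x, "GenomeRecord")) genomeSequence(x)
         else if (is(x, "DNAString")) x
         else DNAString(toupper(as.character(x)))
    cnt <- alphabetFrequency(s)[c("A", "C", "G", "T")]
    tot <- sum(cnt)
    if (tot == 0) stop("sequence contains no unambiguous bases")
    cnt / tot
}

#' Expected genome-wide count of a motif under the composition null
#'
#' The expected count is the genome length times the product, over motif
#' positions, of the summed frequencies of the bases each IUPAC letter
#' admits.  A fully degenerate `N` position contributes a factor of one, so
#' for `GANTC` the product runs over the four informative letters G, A, T
#' and C.
#'
#' @param pattern IUPAC motif.
#' @param freqs base frequencies as returned by [baseFrequencies()].
#' @param genomeLength genome length in bp.
#' @return Expected count (numeric).
#' @examples
#' expectedCountGenome("GANTC", c(A=.25, C=.25, G=.25, T=.25), 25600)  # 100
#' @export
expectedCountGenome <- function(pattern, freqs, genomeLength) {
    pattern <- .validMotif(pattern)
    stopifnot(all(c("A", "C", "G", "T") %in% names(freqs)))
    letters <- strsplit(pattern, "")[[1]]
    fac <- vapply(letters, function(l) {
        members <- strsplit(IUPAC_CODE_MAP[[l]], "")[[1]]
        sum(freqs[members])
    }, numeric(1))
    prod(fac) * genomeLength
}

#' Expected motif count in a genome partition by proportional allocation
#'
#' Allocates the genome-wide observed total to a partition in proportion to
#' its length; allocations over partitions that tile the genome sum to the
#' total.
#'
#' @param subLength partition length in bp.
#' @param genomeLength genome length in bp.
#' @param totalObserved genome-wide observed count.
#' @return Expected count in the partition.
#' @export
expectedCountSubsequence <- function(subLength, genomeLength,
                                     totalObserved) {
    if (genomeLength <= 0) stop("'genomeLength' must be positive")
    subLength / genomeLength * totalObserved
}

.featureClass <- function(features) {
    cls <- mcols(features)$class
    if (is.null(cls)) {
        type <- mcols(features)$type
        if (is.null(type))
            stop("features need a 'class' (or GFF 'type') metadata column")
        cls <- ifelse(as.character(type) %in%
                          c("CDS", "gene", "protein_coding"),
                      "protein_coding",
                      ifelse(grepl("RNA|rna", as.character(type)),
                             "rna", "other"))
    }
    as.character(cls)
}

.featureId <- function(features) {
    id <- mcols(features)$id
    if (is.null(id)) id <- mcols(features)$ID
    if (is.null(id)) id <- sprintf("feature_%05d", seq_along(features))
    as.character(id)
}

## 5'->3' sequence of one feature on its own strand
.featureSeq <- function(s, L, circular, start1, end1, strandChr, id) {
    if (start1 < 1L || end1 > L)
        stop(sprintf("feature '%s' lies outside the contig (1..%d)", id, L))
    sub <- substr(s, start1, end1)
    if (identical(strandChr, "-"))
        sub <- as.character(reverseComplement(DNAString(sub)))
    sub
}

#' Observed and expected motif counts per genome partition
#'
#' Counts the motif in the whole genome (forward strand, honouring
#' circularity), in the protein-coding gene sequences and in RNA gene
#' sequences (each feature extracted 5'->3' on its own strand), and derives
#' the intergenic count by subtraction:
#' genome - (coding + rna).  Expected genome-wide counts come from the
#' single-base composition null ([expectedCountGenome()]); expected
#' partition counts allocate the observed genome total proportionally to
#' partition length ([expectedCountSubsequence()]).
#'
#' Because overlapping genes are counted in full, the subtraction-based
#' intergenic count can undershoot (even below zero, which triggers a
#' warning); this mirrors the whole-genome/.ffn/.frn bookkeeping the
#' obs/exp statistics are defined on.
#'
#' @param genome a [GenomeRecord-class].
#' @param features a [GenomicRanges::GRanges] (1-based, inclusive) with
#'   metadata columns `id` and `class` (`protein_coding`, `rna`, `other`);
#'   `other` features are ignored.
#' @param pattern IUPAC motif.
#' @return A [PartitionCounts-class].
#' @export
partitionCounts <- function(genome, features, pattern = "GANTC") {
    stopifnot(is(genome, "GenomeRecord"))
    pattern <- .validMotif(pattern)
    s <- .seqChar(genome)
    L <- nchar(s)
    circ <- isCircular(genome)
    obsGenome <- length(scanMotif(genome, pattern))
    cls <- if (length(features)) .featureClass(features) else character(0)
    ids <- if (length(features)) .featureId(features) else character(0)
    countClass <- function(which) {
        idx <- which(cls == which)
        n <- 0L
        len <- 0
        for (i in idx) {
            fs <- .featureSeq(s, L, circ, GenomicRanges::start(features)[i],
                              GenomicRanges::end(features)[i],
                              as.character(strand(features))[i], ids[i])
            n <- n + length(scanMotif(fs, pattern, circular = FALSE))
            len <- len + nchar(fs)
        }
        list(n = n, len = len)
    }
    cod <- countClass("protein_coding")
    rna <- countClass("rna")
    obsInter <- obsGenome - cod$n - rna$n
    if (obsInter < 0)
        warning(sprintf(
            "intergenic count for %s is negative (%d); overlapping genes",
            pattern, obsInter))
    lenInter <- L - cod$len - rna$len
    freqs <- baseFrequencies(genome)
    expGenome <- expectedCountGenome(pattern, freqs, L)
    observed <- c(genome = obsGenome, coding = cod$n, rna = rna$n,
                  intergenic = obsInter)
    expected <- c(genome = expGenome,
                  coding = expectedCountSubsequence(cod$len, L, obsGenome),
                  rna = expectedCountSubsequence(rna$len, L, obsGenome),
                  intergenic = expectedCountSubsequence(lenInter, L,
                                                        obsGenome))
    ratio <- ifelse(expected > 0, observed / expected, NA_real_)
    new("PartitionCounts", pattern = pattern, contig = contigName(genome),
        observed = observed, expected = expected, ratio = ratio,
        baseFreq = freqs, genomeLength = L,
        partitionLength = c(genome = L, coding = cod$len, rna = rna$len,
                            intergenic = lenInter))
}

#' The 24 GANTC-structured pentanucleotides
#'
#' All patterns `X1 X2 N X3 X4` in which each of the four bases A, C, G and
#' T appears exactly once around a central fully degenerate position --
#' the structural family GANTC belongs to, which also contains CTNAG.
#'
#' @return Sorted character vector of 24 patterns.
#' @examples
#' length(enumerateGantcLike())  # 24
#' @export
enumerateGantcLike <- function() {
    bases <- c("A", "C", "G", "T")
    perms <- expand.grid(b1 = bases, b2 = bases, b3 = bases, b4 = bases,
                         stringsAsFactors = FALSE)
    keep <- apply(perms, 1L, function(r) length(unique(r)) == 4L)
    perms <- perms[keep, , drop = FALSE]
    sort(paste0(perms$b1, perms$b2, "N", perms$b3, perms$b4))
}

#' Obs/exp ratios across a panel of genomes, with group quartiles
#'
#' Runs [partitionCounts()] on each genome of a panel and summarises the
#' obs/exp ratios per group by the median and the first and third
#' quartiles, the statistics drawn in panel box plots.
#'
#' @param panel a list; each element a list with components `genome`
#'   (a [GenomeRecord-class]), `features` (GRanges), and optionally `name`
#'   and `group`.
#' @param pattern IUPAC motif.
#' @return A list with `perGenome` (one row per genome: ratios for the
#'   genome, coding and intergenic partitions) and `summary` (per group and
#'   partition: `q1`, `median`, `q3`, `n`).
#' @export
speciesPanelSummary <- function(panel, pattern = "GANTC") {
    stopifnot(is.list(panel), length(panel) > 0)
    rows <- lapply(seq_along(panel), function(i) {
        e <- panel[[i]]
        pc <- partitionCounts(e$genome, e$features, pattern)
        r <- obsExpRatio(pc)
        data.frame(name = if (!is.null(e$name)) e$name else
                       contigName(e$genome),
                   group = if (!is.null(e$group)) e$group else "all",
                   pattern = pattern,
                   ratio_genome = r[["genome"]],
                   ratio_coding = r[["coding"]],
                   ratio_intergenic = r[["intergenic"]],
                   stringsAsFactors = FALSE)
    })
    perGenome <- do.call(rbind, rows)
    parts <- c("ratio_genome", "ratio_coding", "ratio_intergenic")
    sm <- do.call(rbind, lapply(split(perGenome, perGenome$group),
                                function(g) {
        do.call(rbind, lapply(parts, function(p) {
            q <- quantile(g[[p]], c(0.25, 0.5, 0.75), na.rm = TRUE,
                          names = FALSE)
            data.frame(group = g$group[1], partition = sub("ratio_", "", p),
                       q1 = q[1], median = q[2], q3 = q[3], n = nrow(g),
                       stringsAsFactors = FALSE)
        }))
    }))
    rownames(sm) <- NULL
    list(perGenome = perGenome, summary = sm)
}
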