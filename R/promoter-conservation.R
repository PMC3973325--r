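## Promoter extraction (200 bp upstream of the translational start),
## promoter motif flags and cross-species conservation counts.

## 0-based half-open promoter window for a gene given in 0-based
## half-open coordinates; splits into two segments when it wraps the
## circular junction, truncates (with a warning) at the edge of a linear
## contig
.promoterWindow <- function(start0, end0, strandChr, promoterLength, L,
                            circular, id = "gene") {
    if (promoterLength <= 0)
        stop("'promoterLength' must be positive")
    if (strandChr == "-") {
        a <- end0
        b <- end0 + promoterLength
        if (b > L) {
            if (circular)
                return(rbind(c(a, L), c(0, b - L)))
            warning(sprintf("promoter of '%s' truncated at contig end", id))
            return(rbind(c(a, min(b, L))))
        }
        return(rbind(c(a, b)))
    }
    a <- start0 - promoterLength
    b <- start0
    if (a < 0) {
        if (circular)
            return(rbind(c(L + a, L), c(0, b)))
        warning(sprintf("promoter of '%s' truncated at contig start", id))
        return(rbind(c(0, b)))
    }
    rbind(c(a, b))
}

#' Extract the promoter region of one gene
#'
#' The promoter is the `promoterLength` bp immediately upstream of the
#' translational start codon: for a plus-strand gene with 0-based start
#' `g` the forward interval `[g - length, g)`; for a minus-strand gene
#' with 0-based half-open end `e` the interval `[e, e + length)`.  On
#' circular contigs the window wraps (two segments); on linear contigs it
#' truncates at the edge with a warning.
#'
#' @param start0,end0 0-based half-open gene coordinates.
#' @param strand `"+"` or `"-"`.
#' @param genome a [GenomeRecord-class].
#' @param promoterLength window length in bp (default 200).
#' @return list with `segments` (matrix of 0-based half-open intervals in
#'   genome order) and `seq` (promoter sequence 5'->3' on the gene
#'   strand).
#' @examples
#' g <- GenomeRecord(strrep("ACGT", 750), circular = FALSE)
#' extractPromoter(1000, 2000, "+", g)$segments   # [800, 1000)
#' @export
extractPromoter <- function(start0, end0, strand, genome,
                            promoterLength = 200) {
    stopifnot(is(genome, "GenomeRecord"))
    L <- length(genome)
    seg <- .promoterWindow(start0, end0, strand, promoterLength, L,
                           isCircular(genome))
    s <- .seqChar(genome)
    fwd <- paste(vapply(seq_len(nrow(seg)), function(i)
        substr(s, seg[i, 1] + 1L, seg[i, 2]), character(1)),
        collapse = "")
    if (strand == "-")
        fwd <- as.character(reverseComplement(DNAString(fwd)))
    list(segments = seg, seq = fwd)
}

#' Promoter motif presence for every gene
#'
#' Scans the genome once for the motif and flags each gene whose promoter
#' window contains at least one occurrence.  An occurrence belongs to a
#' promoter when its 0-based forward start coordinate lies inside the
#' window, so occurrences straddling the downstream window boundary still
#' count.  GANTC is its own reverse complement, so a forward-strand scan
#' covers both strands; for non-palindromic patterns set
#' `bothStrands = TRUE` to also count occurrences whose reverse-complement
#' start lies in the window.
#'
#' @param features a [GenomicRanges::GRanges] of genes (1-based,
#'   inclusive) with an `id` metadata column.
#' @param genome a [GenomeRecord-class].
#' @param pattern IUPAC motif.
#' @param promoterLength window length in bp.
#' @param bothStrands also scan the reverse strand (unnecessary for
#'   palindromic patterns).
#' @return data.frame with one row per gene: `gene_id`, `strand`,
#'   `segments` (text `a-b` intervals, 0-based half-open), `has_motif`,
#'   `n_motifs` and `motif_positions` (comma-separated 0-based forward
#'   starts).
#' @export
promoterMotifFlags <- function(features, genome, pattern = "GANTC",
                               promoterLength = 200, bothStrands = FALSE) {
    stopifnot(is(genome, "GenomeRecord"))
    L <- length(genome)
    circ <- isCircular(genome)
    occ <- scanMotif(genome, pattern)
    if (bothStrands) {
        rc <- as.character(reverseComplement(DNAString(.validMotif(pattern))))
        if (rc != .validMotif(pattern)) {
            k <- nchar(pattern)
            occRc <- scanMotif(genome, rc)
            occ <- sort(unique(c(occ, occRc)))
        }
    }
    ids <- .featureId(features)
    rows <- lapply(seq_along(features), function(i) {
        st <- as.character(strand(features))[i]
        seg <- .promoterWindow(start(features)[i] - 1L, end(features)[i],
                               st, promoterLength, L, circ, ids[i])
        inWin <- occ[vapply(occ, function(p)
            any(p >= seg[, 1] & p < seg[, 2]), logical(1))]
        data.frame(gene_id = ids[i], strand = st,
                   segments = paste(sprintf("%d-%d", seg[, 1], seg[, 2]),
                                    collapse = ";"),
                   has_motif = length(inWin) > 0,
                   n_motifs = length(inWin),
                   motif_positions = paste(inWin, collapse = ","),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Cross-species promoter motif conservation counts
#'
#' Counts, for each gene, the number of species whose orthologous promoter
#' contains the motif, from a presence matrix (genes x species, 0/1 or
#' logical).  The count is invariant to consistent permutations of the
#' species columns.
#'
#' @param presence matrix or data.frame of 0/1 presence flags with gene
#'   identifiers as row names (or a `gene_id` column).
#' @return data.frame with `gene_id` and `count`.
#' @examples
#' m <- rbind(ftsZ = c(1, 1, 1, 1, 1), x = c(1, 0, 1, 0, 1))
#' conservationCounts(m)
#' @export
conservationCounts <- function(presence) {
    if (is.data.frame(presence)) {
        if ("gene_id" %in% names(presence)) {
            ids <- presence$gene_id
            presence <- as.matrix(presence[setdiff(names(presence),
                                                   "gene_id")])
            rownames(presence) <- ids
        } else presence <- as.matrix(presence)
    }
    if (is.null(rownames(presence)))
        stop("'presence' needs gene identifiers as row names")
    storage.mode(presence) <- "numeric"
    if (any(!presence %in% c(0, 1)))
        stop("'presence' must contain only 0/1 flags")
    data.frame(gene_id = rownames(presence),
               count = as.integer(rowSums(presence)), row.names = NULL)
}
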