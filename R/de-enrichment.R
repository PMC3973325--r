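## Differential-expression classification and Fisher exact gene-set
## enrichment, including the excess-direct-target estimate.

#' Classify gene-level DE statistics into significance and strength sets
#'
#' Significant genes have BH-adjusted p strictly below `alpha`; they split
#' into up- and downregulated by the sign of the log2 ratio, and into
#' strong sets by `|log2 ratio| >= log2(strongFold)`.
#'
#' @param stats data.frame with `gene_id`, `log_ratio` (log2 mutant vs
#'   wild type), `p_raw` and `p_adj`.
#' @param alpha adjusted-p threshold (strict `<`).
#' @param strongFold linear fold-change threshold for the strong sets.
#' @return A [DEClassification-class].
#' @export
classifyDE <- function(stats, alpha = 0.01, strongFold = 2) {
    need <- c("gene_id", "log_ratio", "p_raw", "p_adj")
    miss <- setdiff(need, names(stats))
    if (length(miss))
        stop("stats table lacks column(s): ", paste(miss, collapse = ", "))
    if (any(stats$p_adj < stats$p_raw - 1e-12, na.rm = TRUE))
        warning("some adjusted p-values are below the raw p-values")
    if (anyDuplicated(stats$gene_id))
        stop("duplicated gene identifiers in stats table")
    sig <- !is.na(stats$p_adj) & stats$p_adj < alpha
    up <- sig & stats$log_ratio > 0
    down <- sig & stats$log_ratio < 0
    strong <- abs(stats$log_ratio) >= log2(strongFold)
    new("DEClassification",
        universe = as.character(stats$gene_id),
        significant = as.character(stats$gene_id[sig]),
        up = as.character(stats$gene_id[up]),
        down = as.character(stats$gene_id[down]),
        strongUp = as.character(stats$gene_id[up & strong]),
        strongDown = as.character(stats$gene_id[down & strong]),
        alpha = alpha, strongFold = strongFold)
}

#' Two-sample differential expression on a replicate intensity matrix
#'
#' Lightweight per-gene Welch (unequal variance) t-test on log2
#' intensities with Benjamini-Hochberg adjustment; the log ratio is the
#' difference of group means (second group minus reference).  Intended for
#' synthetic replicate matrices; gene-level statistics from a dedicated
#' microarray/RNA-seq fit can be supplied to [classifyDE()] directly
#' instead.
#'
#' @param mat numeric matrix, genes x samples, log2 scale, with gene row
#'   names.
#' @param groups character/factor of length `ncol(mat)` with exactly two
#'   levels.
#' @param reference the group to treat as baseline (default: first level
#'   encountered).
#' @return data.frame with `gene_id`, `log_ratio`, `t`, `df`, `p_raw`,
#'   `p_adj`.
#' @export
simpleDE <- function(mat, groups, reference = NULL) {
    stopifnot(is.matrix(mat), ncol(mat) == length(groups))
    groups <- as.character(groups)
    lev <- unique(groups)
    if (length(lev) != 2L) stop("'groups' must have exactly two levels")
    if (is.null(reference)) reference <- lev[1L]
    other <- setdiff(lev, reference)
    i1 <- groups == reference
    i2 <- groups == other
    n1 <- sum(i1)
    n2 <- sum(i2)
    if (n1 < 2L || n2 < 2L) stop("need at least two replicates per group")
    m1 <- rowMeans(mat[, i1, drop = FALSE])
    m2 <- rowMeans(mat[, i2, drop = FALSE])
    v1 <- apply(mat[, i1, drop = FALSE], 1L, var)
    v2 <- apply(mat[, i2, drop = FALSE], 1L, var)
    se2 <- v1 / n1 + v2 / n2
    tstat <- ifelse(se2 > 0, (m2 - m1) / sqrt(se2),
                    ifelse(m2 == m1, 0, Inf * sign(m2 - m1)))
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                 n1 + n2 - 2)
    p <- ifelse(is.finite(tstat), 2 * pt(-abs(tstat), df),
                ifelse(tstat == 0, 1, 0))
    p <- pmin(1, p)
    ids <- rownames(mat)
    if (is.null(ids)) ids <- sprintf("gene_%05d", seq_len(nrow(mat)))
    data.frame(gene_id = ids, log_ratio = m2 - m1, t = tstat, df = df,
               p_raw = p, p_adj = p.adjust(p, method = "BH"),
               row.names = NULL)
}

#' Fisher exact enrichment of a property within a gene set
#'
#' Builds the 2x2 table (a = genes in the set with the property, b = in
#' the set without, c = with the property outside the set, d = the rest)
#' and computes the fold enrichment `(a / (a + b)) / ((a + c) / N)` --
#' the frequency of the property in the set relative to the whole
#' universe -- the sample odds ratio `ad / bc`, and the exact
#' hypergeometric p-value (one-sided over-representation by default).
#'
#' @param geneSet,propertySet character vectors; must be subsets of
#'   `universe`.
#' @param universe character vector of all genes considered.
#' @param alternative `"greater"` (over-representation, default),
#'   `"less"`, or `"two.sided"`.
#' @param setName,propertyName labels carried into the result row.
#' @return One-row data.frame: `set_name`, `property_name`, `a`, `b`,
#'   `c`, `d`, `fold`, `odds_ratio`, `p_value`, `direction`,
#'   `alternative`.
#' @examples
#' fisherEnrichment(c("g1", "g2"), c("g1", "g3"), paste0("g", 1:4))
#' @export
fisherEnrichment <- function(geneSet, propertySet, universe,
                             alternative = c("greater", "less",
                                             "two.sided"),
                             setName = "set", propertyName = "property") {
    alternative <- match.arg(alternative)
    universe <- unique(as.character(universe))
    geneSet <- unique(as.character(geneSet))
    propertySet <- unique(as.character(propertySet))
    if (length(universe) == 0L) stop("empty universe")
    if (length(geneSet) == 0L) stop("empty gene set")
    if (!all(geneSet %in% universe))
        stop("gene set is not a subset of the universe")
    if (!all(propertySet %in% universe))
        stop("property set is not a subset of the universe")
    N <- length(universe)
    a <- length(intersect(geneSet, propertySet))
    b <- length(geneSet) - a
    cc <- length(propertySet) - a
    d <- N - a - b - cc
    fold <- (a / (a + b)) / ((a + cc) / N)
    or <- if (b > 0 && cc > 0) (a * d) / (b * cc)
          else if (a > 0 || d > 0) Inf else NaN
    p <- switch(alternative,
        greater = phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE),
        less = phyper(a, a + cc, b + d, a + b),
        two.sided = fisher.test(matrix(c(a, b, cc, d), 2L,
                                       byrow = TRUE))$p.value)
    data.frame(set_name = setName, property_name = propertyName,
               a = a, b = b, c = cc, d = d, fold = fold, odds_ratio = or,
               p_value = p,
               direction = if (fold >= 1) "over" else "under",
               alternative = alternative, stringsAsFactors = FALSE)
}

#' Enrichment battery over DE sets, catalogs, promoter flags and
#' conservation strata
#'
#' Runs [fisherEnrichment()] for every combination of a DE gene set
#' (significant, down, up, strong down, strong up, strong) with every
#' property: membership of each catalog set, promoter motif presence, and
#' motif conservation at each requested threshold.  Raw exact p-values are
#' reported to mirror per-panel testing; a BH-adjusted column over the
#' whole battery is appended for reference.
#'
#' @param classification a [DEClassification-class].
#' @param catalog named list of gene-id vectors (may be empty).
#' @param promoterFlags optional data.frame from [promoterMotifFlags()].
#' @param conservation optional data.frame from [conservationCounts()];
#'   genes with a promoter motif conserved in at least each of
#'   `consThresholds` species form extra property sets (a gene counts
#'   only when it also carries a focal promoter motif if `promoterFlags`
#'   is given).
#' @param consThresholds integer vector of conservation thresholds.
#' @param alternative passed to [fisherEnrichment()].
#' @return data.frame of enrichment rows plus a `p_adj` column; empty
#'   combinations (empty DE set or property) are skipped.
#' @export
enrichmentBattery <- function(classification, catalog = list(),
                              promoterFlags = NULL, conservation = NULL,
                              consThresholds = 2,
                              alternative = "greater") {
    stopifnot(is(classification, "DEClassification"))
    universe <- deUniverse(classification)
    deSets <- list(
        significant = significantGenes(classification),
        down = downGenes(classification),
        up = upGenes(classification),
        strong_down = strongDownGenes(classification),
        strong_up = strongUpGenes(classification),
        strong = union(strongUpGenes(classification),
                       strongDownGenes(classification)))
    props <- list()
    for (nm in names(catalog))
        props[[nm]] <- intersect(catalog[[nm]], universe)
    if (!is.null(promoterFlags))
        props[["promoter_motif"]] <-
            intersect(promoterFlags$gene_id[promoterFlags$has_motif],
                      universe)
    if (!is.null(conservation)) {
        for (k in consThresholds) {
            genes <- conservation$gene_id[conservation$count >= k]
            if (!is.null(promoterFlags))
                genes <- intersect(genes, props[["promoter_motif"]])
            props[[sprintf("motif_cons_ge_%d", k)]] <-
                intersect(genes, universe)
        }
    }
    rows <- list()
    for (s in names(deSets)) for (p in names(props)) {
        if (length(deSets[[s]]) == 0L || length(props[[p]]) == 0L) next
        rows[[length(rows) + 1L]] <-
            fisherEnrichment(deSets[[s]], props[[p]], universe,
                             alternative = alternative, setName = s,
                             propertyName = p)
    }
    if (length(rows) == 0L)
        return(data.frame(set_name = character(), property_name =
                              character(), a = integer(), b = integer(),
                          c = integer(), d = integer(), fold = numeric(),
                          odds_ratio = numeric(), p_value = numeric(),
                          direction = character(),
                          alternative = character(),
                          p_adj = numeric()))
    out <- do.call(rbind, rows)
    out$p_adj <- p.adjust(out$p_value, method = "BH")
    out
}

#' Excess count of directly regulated genes implied by a fold enrichment
#'
#' If `n` property-bearing genes are observed in a misregulated set and
#' that number is `fold`-times higher than expected by chance, then
#' `n / fold` of them are expected even without a direct link, and the
#' excess `n * (1 - 1 / fold)`, rounded to the nearest integer, estimates
#' the directly regulated genes.
#'
#' @param nObserved observed count of property-bearing genes in the set.
#' @param foldEnrichment fold enrichment over the chance expectation.
#' @return Integer estimate (0 when there is no enrichment).
#' @examples
#' excessDirectTargets(80, 2)   # 40
#' @export
excessDirectTargets <- function(nObserved, foldEnrichment) {
    stopifnot(nObserved >= 0)
    if (foldEnrichment <= 0)
        stop("'foldEnrichment' must be positive")
    as.integer(round(nObserved * (1 - 1 / foldEnrichment)))
}

#' Candidate directly regulated genes
#'
#' Genes that are significantly misregulated, carry a promoter motif, and
#' whose motif is conserved in at least `minConservation` related species;
#' an essential-gene flag is joined and the table is sorted by log ratio
#' so that the most strongly repressed genes come first.
#'
#' @param stats data.frame with `gene_id`, `log_ratio`, `p_adj` (as for
#'   [classifyDE()]).
#' @param classification a [DEClassification-class] built from `stats`.
#' @param promoterFlags data.frame from [promoterMotifFlags()].
#' @param conservation optional data.frame from [conservationCounts()];
#'   required when `minConservation > 0`.
#' @param essentialSet character vector of essential gene ids.
#' @param minConservation minimum conservation count.
#' @return data.frame: `gene_id`, `log_ratio`, `p_adj`, `direction`
#'   (`repressed` for genes down in the mutant, `activated` otherwise),
#'   `has_motif`, `conservation`, `essential`.
#' @export
candidateDirectTargets <- function(stats, classification, promoterFlags,
                                   conservation = NULL,
                                   essentialSet = character(),
                                   minConservation = 0) {
    stopifnot(is(classification, "DEClassification"))
    if (minConservation > 0 && is.null(conservation))
        stop("'conservation' is required when minConservation > 0")
    sig <- significantGenes(classification)
    flags <- promoterFlags$gene_id[promoterFlags$has_motif]
    keep <- intersect(sig, flags)
    cons <- rep(NA_integer_, length(keep))
    if (!is.null(conservation)) {
        cons <- conservation$count[match(keep, conservation$gene_id)]
        keep <- keep[!is.na(cons) & cons >= minConservation]
        cons <- conservation$count[match(keep, conservation$gene_id)]
    }
    i <- match(keep, stats$gene_id)
    out <- data.frame(gene_id = keep, log_ratio = stats$log_ratio[i],
                      p_adj = stats$p_adj[i],
                      direction = ifelse(stats$log_ratio[i] < 0,
                                         "repressed", "activated"),
                      has_motif = rep(TRUE, length(keep)),
                      conservation = cons,
                      essential = keep %in% essentialSet,
                      stringsAsFactors = FALSE)
    out[order(out$log_ratio), , drop = FALSE]
}
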