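## Readers and writers for the plain-text interchange formats: FASTA,
## GFF3, kinetics TSV, expression TSV, gene-set catalogs, ortholog
## panels and the flat key-value pipeline config.

## numeric columns written with 6 significant digits so repeated runs
## produce byte-identical files
writeTsv <- function(df, path, digits = 6) {
    for (col in names(df))
        if (is.double(df[[col]])) df[[col]] <- signif(df[[col]], digits)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a genome FASTA into a GenomeRecord
#'
#' @param path FASTA file (first record used; a warning is emitted when
#'   more records are present).
#' @param circular circularity flag to attach.
#' @return A [GenomeRecord-class].
#' @export
readGenomeFasta <- function(path, circular = TRUE) {
    ss <- readDNAStringSet(path)
    if (length(ss) == 0L) stop("no sequences in ", path)
    if (length(ss) > 1L)
        warning("using first of ", length(ss), " records in ", path)
    GenomeRecord(ss[1L], circular = circular)
}

#' Write a GenomeRecord as FASTA
#'
#' @param genome a [GenomeRecord-class].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
    ss <- DNAStringSet(genomeSequence(genome))
    names(ss) <- contigName(genome)
    writeXStringSet(ss, path)
    invisible(path)
}

#' Read gene features from GFF3
#'
#' Maps GFF types to the three feature classes used by the partition
#' statistics: `CDS`/`gene` to `protein_coding`, `*RNA*` types to `rna`,
#' anything else to `other`.
#'
#' @param path GFF3 file.
#' @return A [GenomicRanges::GRanges] with `id` and `class` columns.
#' @export
readFeaturesGFF3 <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(mcols(gr)$type)
    cls <- ifelse(type %in% c("CDS", "gene"), "protein_coding",
                  ifelse(grepl("RNA|rna", type), "rna", "other"))
    id <- mcols(gr)$ID
    if (is.null(id)) id <- mcols(gr)$Name
    if (is.null(id)) id <- sprintf("feature_%05d", seq_along(gr))
    mcols(gr) <- NULL
    mcols(gr)$id <- as.character(id)
    mcols(gr)$class <- cls
    gr
}

#' Write gene features as GFF3
#'
#' Protein-coding features are written as `CDS`, RNA features as `rRNA`,
#' others as `region`.
#'
#' @param features a [GenomicRanges::GRanges] with `id` and `class`
#'   columns.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeFeaturesGFF3 <- function(features, path) {
    cls <- .featureClass(features)
    gr <- features
    mcols(gr) <- NULL
    mcols(gr)$type <- ifelse(cls == "protein_coding", "CDS",
                             ifelse(cls == "rna", "rRNA", "region"))
    mcols(gr)$ID <- .featureId(features)
    mcols(gr)$phase <- ifelse(mcols(gr)$type == "CDS", 0L, NA_integer_)
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

#' Read a kinetics TSV
#'
#' Expects the tab-separated header
#' `contig  position0  strand  ipd_ratio  coverage` with 0-based
#' positions and `+`/`-` strands.
#'
#' @param path TSV file.
#' @return Kinetics data.frame.
#' @export
readKinetics <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("contig", "position0", "strand", "ipd_ratio", "coverage")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop(sprintf("kinetics file '%s' lacks column(s): %s", path,
                     paste(miss, collapse = ", ")))
    if (!all(df$strand %in% c("+", "-")))
        stop(sprintf("kinetics file '%s': column 'strand' must be +/-",
                     path))
    .checkIpd(df)
    df
}

#' Write a kinetics TSV
#'
#' @param ipd kinetics data.frame (extra columns are dropped).
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeKinetics <- function(ipd, path) {
    .checkIpd(ipd)
    writeTsv(ipd[c("contig", "position0", "strand", "ipd_ratio",
                   "coverage")], path)
}

#' Convert a PacBio modifications-style kinetics table
#'
#' Converts 1-based `tpl` template positions and 0/1 strand codes (as in
#' SMRT-portal modification CSVs) to the package's 0-based `+`/`-`
#' convention.
#'
#' @param df data.frame (or path to a comma/tab file) with columns
#'   `refName`, `tpl` (1-based), `strand` (0 = forward, 1 = reverse),
#'   `ipdRatio` and `coverage`.
#' @return Standard kinetics data.frame.
#' @export
convertPacBioKinetics <- function(df) {
    if (is.character(df)) {
        first <- readLines(df, n = 1L)
        sepc <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
        df <- read.delim(df, sep = sepc, stringsAsFactors = FALSE)
    }
    need <- c("refName", "tpl", "strand", "ipdRatio", "coverage")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("PacBio kinetics table lacks column(s): ",
             paste(miss, collapse = ", "))
    if (!all(df$strand %in% c(0, 1)))
        stop("PacBio 'strand' column must contain 0/1")
    data.frame(contig = as.character(df$refName),
               position0 = as.integer(df$tpl) - 1L,
               strand = ifelse(df$strand == 0, "+", "-"),
               ipd_ratio = df$ipdRatio, coverage = df$coverage,
               stringsAsFactors = FALSE)
}

#' Read an expression matrix TSV
#'
#' First column `gene_id`, remaining columns one replicate each; the
#' condition of a replicate is the column name up to the last underscore
#' (`wt_1`, `mut_2`, ...).
#'
#' @param path TSV file.
#' @return list with `matrix` (genes x replicates) and `groups`.
#' @export
readExpression <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(df)[1L] != "gene_id")
        stop(sprintf("expression file '%s': first column must be gene_id",
                     path))
    mat <- as.matrix(df[-1L])
    rownames(mat) <- df$gene_id
    storage.mode(mat) <- "double"
    list(matrix = mat, groups = sub("_[^_]*$", "", colnames(mat)))
}

#' Write an expression matrix TSV
#' @param mat genes x replicates matrix with dimnames.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeExpression <- function(mat, path) {
    df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
    writeTsv(df, path)
}

#' Read a gene-set catalog TSV (`set_name  gene_id`)
#' @param path TSV file.
#' @return Named list of gene-id vectors.
#' @export
readCatalog <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("set_name", "gene_id") %in% names(df)))
        stop(sprintf("catalog file '%s' needs columns set_name, gene_id",
                     path))
    split(df$gene_id, df$set_name)
}

#' Write a gene-set catalog TSV
#' @param sets named list of gene-id vectors.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeCatalog <- function(sets, path) {
    df <- data.frame(
        set_name = rep(names(sets), lengths(sets)),
        gene_id = unlist(sets, use.names = FALSE))
    writeTsv(df, path)
}

#' Read an ortholog presence panel TSV (wide: gene_id + one 0/1 column
#' per species)
#' @param path TSV file.
#' @return Integer matrix genes x species.
#' @export
readPanel <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(df)[1L] != "gene_id")
        stop(sprintf("panel file '%s': first column must be gene_id",
                     path))
    m <- as.matrix(df[-1L])
    rownames(m) <- df$gene_id
    storage.mode(m) <- "integer"
    m
}

#' Write an ortholog presence panel TSV
#' @param panel genes x species 0/1 matrix with row names.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writePanel <- function(panel, path) {
    df <- data.frame(gene_id = rownames(panel), panel,
                     check.names = FALSE)
    writeTsv(df, path)
}

#' Read a flat key-value config file (`key = value` or `key<TAB>value`)
#' @param path config file; `#` starts a comment.
#' @return Named character list.
#' @export
readConfig <- function(path) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- lapply(lines, function(l) {
        parts <- if (grepl("=", l, fixed = TRUE))
            strsplit(l, "=", fixed = TRUE)[[1]]
        else strsplit(l, "\t", fixed = TRUE)[[1]]
        if (length(parts) < 2L)
            stop("malformed config line: ", l)
        c(trimws(parts[1L]), trimws(paste(parts[-1L], collapse = "=")))
    })
    out <- lapply(kv, `[`, 2L)
    names(out) <- vapply(kv, `[`, character(1), 1L)
    out
}

#' Write a flat key-value config file
#' @param config named list of scalar values.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeConfig <- function(config, path) {
    writeLines(sprintf("%s = %s", names(config),
                       vapply(config, as.character, character(1))), path)
    invisible(path)
}
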