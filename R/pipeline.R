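## End-to-end orchestration: write a synthetic bundle to disk, run the
## analysis stages over a flat config, and emit TSV/JSON artifacts.

.cfgNum <- function(config, key, default) {
    if (!is.null(config[[key]])) as.numeric(config[[key]]) else default
}

.cfgPath <- function(config, key) {
    p <- config[[key]]
    if (is.null(p) || !nzchar(p)) return(NULL)
    if (!file.exists(p)) stop(sprintf("config path '%s' (%s) not found",
                                      p, key))
    p
}

#' Write a complete synthetic bundle to disk
#'
#' Runs every generator of the plan and writes genome FASTA, GFF3
#' features, wild-type and fully methylated reference kinetics TSVs,
#' expression matrix, gene-set catalog, ortholog panel, truth tables and
#' a ready-made pipeline config.
#'
#' @param plan a [SyntheticPlan-class].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with all file paths and the in-memory
#'   objects.
#' @export
simulateBundle <- function(plan, outdir) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    gen <- generateGenome(plan)
    meth <- generateMethylationPlan(plan, gen$sites)
    ipdWt <- generateIpdDataset(plan, meth)
    ipdFull <- generateIpdDataset(plan, fullyMethylatedPlan(meth),
                                  seedOffset = 1000L)
    flags <- promoterMotifFlags(gen$features, gen$genome)
    expr <- generateExpressionDataset(plan, flags$gene_id,
                                      flags$has_motif)
    sets <- generateGeneSets(plan, flags$gene_id, expr$truth)
    panel <- generateOrthologPanel(plan, flags$gene_id,
                                   conservationProbs =
                                       ifelse(flags$has_motif, 0.7, 0.2))
    writeGenomeFasta(gen$genome, p("genome.fna"))
    writeFeaturesGFF3(gen$features, p("features.gff3"))
    writeKinetics(ipdWt, p("kinetics_wt.tsv"))
    writeKinetics(ipdFull, p("kinetics_full.tsv"))
    writeExpression(expr$matrix, p("expression.tsv"))
    writeCatalog(sets$sets, p("catalog.tsv"))
    writePanel(panel, p("panel.tsv"))
    writeTsv(gen$sites, p("truth_sites.tsv"))
    writeTsv(meth, p("truth_methylation.tsv"))
    writeTsv(expr$truth, p("truth_genes.tsv"))
    writeTsv(sets$cog, p("truth_cog.tsv"))
    config <- list(
        genome = p("genome.fna"), features = p("features.gff3"),
        kinetics = p("kinetics_wt.tsv"),
        reference_kinetics = p("kinetics_full.tsv"),
        expression = p("expression.tsv"), catalog = p("catalog.tsv"),
        panel = p("panel.tsv"), outdir = file.path(outdir, "results"),
        circular = plan@circular, window = 20000, tau = 2.4,
        min_coverage = 5, promoter_length = 200, alpha = 0.01,
        strong_fold = 2, span = 0.75, min_conservation = 2,
        origin_position = plan@originPosition, n_perm = 10000,
        seed = plan@seed)
    writeConfig(config, p("config.txt"))
    invisible(list(paths = c(config["genome"], config["features"],
                             config["kinetics"],
                             config["reference_kinetics"],
                             config["expression"], config["catalog"],
                             config["panel"],
                             config = p("config.txt")),
                   config = config, genome = gen$genome,
                   features = gen$features, sites = gen$sites,
                   methylation = meth, ipd = ipdWt, ipdRef = ipdFull,
                   promoterFlags = flags, expression = expr,
                   geneSets = sets, panel = panel))
}

#' Run the analysis pipeline over a flat config
#'
#' Executes, in order, the motif partition statistics, the IPD methylome
#' calling, the promoter motif/conservation scan and the DE/enrichment
#' stage, skipping any stage whose inputs are absent from the config, and
#' writes one TSV per output table plus a JSON run report.
#'
#' Recognised config keys: `genome`, `features`, `kinetics`,
#' `reference_kinetics`, `expression`, `catalog`, `panel`, `outdir`, and
#' the stage parameters `circular`, `window`, `tau`, `min_coverage`,
#' `promoter_length`, `alpha`, `strong_fold`, `span`, `min_conservation`,
#' `origin_position`, `n_perm`, `seed`.
#'
#' @param config path to a key-value config file, or an equivalent named
#'   list.
#' @param outdir optional override of the config's output directory.
#' @return The run report (a nested list, also written as
#'   `report.json`), invisibly.
#' @export
runPipeline <- function(config, outdir = NULL) {
    if (is.character(config)) config <- readConfig(config)
    if (is.null(outdir)) outdir <- config[["outdir"]]
    if (is.null(outdir)) stop("no output directory configured")
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    report <- list(package = "gantcscope",
                   version = as.character(utils::packageVersion(
                       "gantcscope")),
                   stages = list(), warnings = character())
    note <- function(...) message(sprintf(...))
    warnTo <- function(expr) withCallingHandlers(expr, warning = function(w) {
        report$warnings <<- c(report$warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
    })
    set.seed(as.integer(.cfgNum(config, "seed", 1)))
    circular <- is.null(config[["circular"]]) ||
        tolower(as.character(config[["circular"]])) %in%
            c("true", "1", "yes")

    genomePath <- .cfgPath(config, "genome")
    featPath <- .cfgPath(config, "features")
    genome <- NULL
    features <- NULL
    if (!is.null(genomePath))
        genome <- readGenomeFasta(genomePath, circular = circular)
    if (!is.null(featPath)) features <- readFeaturesGFF3(featPath)

    ## stage 1: motif partition statistics
    if (!is.null(genome) && !is.null(features)) {
        pc <- warnTo(partitionCounts(genome, features, "GANTC"))
        writeTsv(as.data.frame(pc), file.path(outdir, "motif_stats.tsv"))
        report$stages$motif_statistics <- list(
            observed = as.list(observedCounts(pc)),
            expected = as.list(expectedCounts(pc)),
            ratio = as.list(obsExpRatio(pc)))
    } else note("motif statistics skipped: genome or features absent")

    ## stage 2: IPD methylome
    kinPath <- .cfgPath(config, "kinetics")
    refPath <- .cfgPath(config, "reference_kinetics")
    siteCalls <- NULL
    if (!is.null(genome) && !is.null(kinPath) && !is.null(refPath)) {
        ipd <- readKinetics(kinPath)
        ref <- readKinetics(refPath)
        minCov <- .cfgNum(config, "min_coverage", 5)
        model <- calibrate(ref, minCoverage = minCov,
                           tau = .cfgNum(config, "tau", 2.4))
        occ <- scanMotif(genome)
        ad <- motifAdenines(occ, length(genome), circular = circular)
        strands <- callStrands(ipd, ad, model, minCoverage = minCov)
        sites <- callSites(strands)
        siteCalls <- sites$calls
        writeTsv(siteCalls, file.path(outdir, "site_calls.tsv"))
        prof <- windowProfile(ipd, model,
                              window = .cfgNum(config, "window", 20000),
                              chromLength = length(genome))
        prof <- smoothProfile(prof, span = .cfgNum(config, "span", 0.75),
                              circular = circular,
                              chromLength = length(genome))
        writeTsv(prof, file.path(outdir, "window_profile.tsv"))
        grad <- originGradientStat(
            siteCalls[siteCalls$site_label != "no_data", , drop = FALSE],
            originPosition = .cfgNum(config, "origin_position", 0),
            chromLength = length(genome),
            nPerm = .cfgNum(config, "n_perm", 10000))
        report$stages$ipd_methylome <- list(
            r_full = rFull(model), r_hemi = rHemi(model),
            tau = tauThreshold(model), n_sites = length(occ),
            tally = as.list(sites$tally),
            gradient_rho = grad$rho, gradient_p = grad$p_value)
    } else note("methylome stage skipped: genome or kinetics absent")

    ## stage 3: promoter motifs and conservation
    flags <- NULL
    consv <- NULL
    if (!is.null(genome) && !is.null(features)) {
        flags <- warnTo(promoterMotifFlags(
            features, genome,
            promoterLength = .cfgNum(config, "promoter_length", 200)))
        panelPath <- .cfgPath(config, "panel")
        if (!is.null(panelPath))
            consv <- conservationCounts(readPanel(panelPath))
        out <- flags
        if (!is.null(consv))
            out$conservation <- consv$count[match(out$gene_id,
                                                  consv$gene_id)]
        writeTsv(out, file.path(outdir, "promoters.tsv"))
        report$stages$promoters <- list(
            n_genes = nrow(flags), n_with_motif = sum(flags$has_motif))
    } else note("promoter stage skipped: genome or features absent")

    ## stage 4: DE classification and enrichment
    exprPath <- .cfgPath(config, "expression")
    if (!is.null(exprPath)) {
        ex <- readExpression(exprPath)
        stats <- simpleDE(ex$matrix, ex$groups, reference = "wt")
        cls <- classifyDE(stats, alpha = .cfgNum(config, "alpha", 0.01),
                          strongFold = .cfgNum(config, "strong_fold", 2))
        writeTsv(stats, file.path(outdir, "de_stats.tsv"))
        catalogPath <- .cfgPath(config, "catalog")
        catalog <- if (!is.null(catalogPath)) readCatalog(catalogPath)
                   else list()
        battery <- enrichmentBattery(
            cls, catalog = catalog, promoterFlags = flags,
            conservation = consv,
            consThresholds = .cfgNum(config, "min_conservation", 2))
        writeTsv(battery, file.path(outdir, "enrichment.tsv"))
        cand <- NULL
        if (!is.null(flags)) {
            cand <- candidateDirectTargets(
                stats, cls, flags, conservation = consv,
                essentialSet = if ("essential" %in% names(catalog))
                    catalog$essential else character(),
                minConservation = if (!is.null(consv))
                    .cfgNum(config, "min_conservation", 2) else 0)
            writeTsv(cand, file.path(outdir, "candidates.tsv"))
        }
        report$stages$de_enrichment <- list(
            n_universe = length(deUniverse(cls)),
            n_significant = length(significantGenes(cls)),
            n_up = length(upGenes(cls)), n_down = length(downGenes(cls)),
            n_strong = length(union(strongUpGenes(cls),
                                    strongDownGenes(cls))),
            n_enrichment_rows = nrow(battery),
            n_candidates = if (is.null(cand)) NA_integer_ else nrow(cand))
    } else note("DE stage skipped: expression matrix absent")

    write_json(report, file.path(outdir, "report.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
}
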