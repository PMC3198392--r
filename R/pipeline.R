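#' Flatten a HapGlmFit to a report data.frame
#'
#' @param fit a \code{\linkS4class{HapGlmFit}}
#' @return data.frame with the haplotype table plus global-test columns
#' @export
hapGlmTable <- function(fit) {
    tb <- fit@table
    tb$globalStat <- c(fit@globalStat, rep(NA, nrow(tb) - 1L))
    tb$globalDf <- c(fit@globalDf, rep(NA, nrow(tb) - 1L))
    tb$globalP <- c(fit@globalP, rep(NA, nrow(tb) - 1L))
    tb$window <- paste(fit@window, collapse = ",")
    tb
}

#' Flatten a stratified result to a report data.frame
#'
#' One row per haplotype x stratum in the Table-4 style layout (per
#' stratum OR and CI, per-haplotype interaction p, per-stratum global p).
#'
#' @param sres result of \code{\link{stratifiedBlocks}}
#' @return data.frame
#' @export
stratifiedTable <- function(sres) {
    rows <- list()
    for (L in names(sres$strata)) {
        r <- sres$strata[[L]]
        if (is.null(r)) {
            rows[[L]] <- data.frame(
                stratum = L, haplotype = NA_character_, or = NA_real_,
                lo = NA_real_, hi = NA_real_, p = NA_real_,
                globalP = NA_real_, stringsAsFactors = FALSE)
            next
        }
        tb <- r@table
        rows[[L]] <- data.frame(
            stratum = L, haplotype = tb$haplotype, or = tb$or,
            lo = tb$lo, hi = tb$hi, p = tb$p,
            globalP = c(r@globalP, rep(NA, nrow(tb) - 1L)),
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out <- merge(out, stats::setNames(
        sres$interaction[, c("haplotype", "pInt")],
        c("haplotype", "pInt")), by = "haplotype", all.x = TRUE,
        sort = FALSE)
    out[order(match(out$stratum, names(sres$strata))), ]
}

.defaultAnalysisConfig <- function() {
    list(simulate = list(enabled = TRUE, seed = 1L),
         input = NULL,
         covariates = list(snp = c("age", "sex", "center"),
                           haplotype = c("ageClass", "sex", "center")),
         qc = list(callRate = 0.98, hweP = 0.05, maf = 0.05),
         minp = list(B = 999L, seed = 1L, strata = "center"),
         haplowalk = list(width = 3L, fdrThreshold = 0.1),
         poolThreshold = 0.05,
         blocks = list(SLC19A1_block1 = c("rs12483553", "rs2838950",
                                          "rs2838951", "rs17004785")),
         stratifyBy = c("vegetableTertile", "alcoholTertile"),
         outputDir = "snphapscan-out")
}

#' Read an analysis configuration file
#'
#' YAML key-value file; unset keys fall back to package defaults.
#' Validates thresholds and referenced input files before any
#' computation.
#'
#' @param path YAML file path
#' @return list of class \code{"analysisConfig"}
#' @export
readAnalysisConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(.defaultAnalysisConfig(), user)
    # list-valued selections replace the defaults outright
    for (k in c("blocks", "stratifyBy"))
        if (!is.null(user[[k]]) || (k %in% names(user)))
            cfg[[k]] <- user[[k]]
    if (!is.null(user$input)) cfg$simulate <- NULL
    validateAnalysisConfig(cfg)
}

#' Validate an analysis configuration
#' @param cfg list in the \code{\link{readAnalysisConfig}} layout
#' @return the config, invisibly classed \code{"analysisConfig"}
#' @export
validateAnalysisConfig <- function(cfg) {
    for (th in c(cfg$poolThreshold, cfg$haplowalk$fdrThreshold))
        if (!is.numeric(th) || th <= 0 || th >= 1)
            stop("thresholds must lie in (0, 1)")
    if (!is.null(cfg$input)) {
        for (f in unlist(cfg$input))
            if (is.character(f) && !file.exists(f))
                stop("input file not found: ", f)
    }
    class(cfg) <- "analysisConfig"
    cfg
}

.pipelineStages <- c("load", "qc", "descriptives", "assoc", "minp",
                     "haplowalk", "block", "stratify")

#' Run the full multi-stage analysis
#'
#' Executes, in order: cohort load (or simulation), genotype QC,
#' descriptive statistics with control-based tertiles, single-SNP trend
#' scan with within-gene FDR, gene-level min-P permutation tests,
#' haplowalk window scan with LD matrices for flagged genes, named
#' block analyses, and stratified block analyses with interaction
#' tests. Each stage writes a tab-separated report into
#' \code{cfg$outputDir}; a failure halts with a stage-named error,
#' keeping reports already written. A machine-readable manifest
#' (seed, parameters, versions, per-stage wall time, collected
#' warnings) is written last.
#'
#' @param cfg an \code{\link{readAnalysisConfig}}-style configuration
#' @param stages subset of stages to run (dependencies are loaded
#'   automatically); default all
#' @param seed optional override of the simulation seed
#' @return invisible list with the in-memory results (cohort, qc, scan,
#'   minp, haplowalk, blocks, stratified, manifest)
#' @export
runPipeline <- function(cfg, stages = .pipelineStages, seed = NULL) {
    cfg <- validateAnalysisConfig(unclass(cfg))
    dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(package = "SnpHapScan",
                     version = as.character(utils::packageVersion("SnpHapScan")),
                     rversion = as.character(getRversion()),
                     parameters = cfg[c("qc", "minp", "haplowalk",
                                        "poolThreshold", "blocks",
                                        "stratifyBy")],
                     timings = list(), warnings = character())
    res <- list()
    collected <- character()

    stage <- function(name, expr) {
        t0 <- proc.time()[3]
        out <- withCallingHandlers(
            tryCatch(expr, error = function(e)
                stop("stage ", name, ": ", conditionMessage(e),
                     call. = FALSE)),
            warning = function(w) {
                collected <<- c(collected,
                                paste0(name, ": ", conditionMessage(w)))
                invokeRestart("muffleWarning")
            })
        manifest$timings[[name]] <<- round(proc.time()[3] - t0, 3)
        out
    }

    # load / simulate
    loaded <- stage("load", {
        if (!is.null(cfg$input)) {
            x <- readPedMap(cfg$input$ped, cfg$input$map,
                            geneMap = if (!is.null(cfg$input$geneMapFile))
                                yaml::read_yaml(cfg$input$geneMapFile)
                            else NULL)
            if (!is.null(cfg$input$subjects)) {
                su <- readSubjectTable(cfg$input$subjects)
                ri <- match(colnames(x), as.character(su$id))
                if (anyNA(ri)) stop("subject table missing id: ",
                                    colnames(x)[which(is.na(ri))[1]])
                colData(x) <- DataFrame(su[ri, , drop = FALSE])
            }
            list(cohort = x)
        } else {
            sc <- defaultStudyConfig(
                genes = cfg$simulate$genes,
                nCases = if (is.null(cfg$simulate$nCases)) 777L
                         else cfg$simulate$nCases,
                nControls = if (is.null(cfg$simulate$nControls)) 1035L
                            else cfg$simulate$nControls)
            s <- if (!is.null(seed)) seed else cfg$simulate$seed
            sim <- simulateCohort(sc, seed = s)
            writeTruthRecord(sim$truth, sim$cohort,
                             file.path(cfg$outputDir, "truth.tsv"))
            list(cohort = sim$cohort, truth = sim$truth, seed = s)
        }
    })
    res$cohort <- loaded$cohort
    res$truth <- loaded$truth
    if (!is.null(loaded$seed)) manifest$seed <- loaded$seed
    x <- res$cohort
    rsidsAll <- as.character(rowData(x)$rsid)
    for (b in cfg$blocks) {
        bad <- setdiff(b, rsidsAll)
        if (length(bad)) stop("stage load: block rsid not in cohort: ",
                              bad[1], call. = FALSE)
    }
    x <- assignTertiles(x)

    if ("qc" %in% stages) {
        res$qc <- stage("qc", qcSummary(x, thresholds = cfg$qc))
        writeQcReport(res$qc, file.path(cfg$outputDir, "qc.tsv"))
    }
    if ("descriptives" %in% stages) {
        res$descriptives <- stage("descriptives",
                                  descriptivesTable(colData(x)))
        utils::write.table(res$descriptives,
                           file.path(cfg$outputDir, "descriptives.tsv"),
                           quote = FALSE, sep = "\t", row.names = FALSE)
    }
    if ("assoc" %in% stages) {
        res$scan <- stage("assoc",
                          snpScan(x, covariates = cfg$covariates$snp))
        utils::write.table(res$scan,
                           file.path(cfg$outputDir, "snp_assoc.tsv"),
                           quote = FALSE, sep = "\t", row.names = FALSE)
    }
    if ("minp" %in% stages) {
        res$minp <- stage("minp", {
            genes <- names(geneRegions(x))
            rl <- lapply(seq_along(genes), function(i)
                minPTest(x, genes[i], covariates = cfg$covariates$snp,
                         B = cfg$minp$B, seed = cfg$minp$seed + i,
                         strata = cfg$minp$strata))
            tab <- minPFdr(rl)
            if (!is.null(res$scan)) geneSummaryTable(res$scan, tab)
            else tab
        })
        utils::write.table(res$minp,
                           file.path(cfg$outputDir, "gene_minp.tsv"),
                           quote = FALSE, sep = "\t", row.names = FALSE)
    }
    if ("haplowalk" %in% stages) {
        res$haplowalk <- stage("haplowalk",
            haplowalk(x, width = cfg$haplowalk$width,
                      fdrThreshold = cfg$haplowalk$fdrThreshold,
                      covariates = cfg$covariates$haplotype,
                      poolThreshold = cfg$poolThreshold))
        utils::write.table(res$haplowalk,
                           file.path(cfg$outputDir, "haplowalk.tsv"),
                           quote = FALSE, sep = "\t", row.names = FALSE)
        flagged <- unique(res$haplowalk$gene[res$haplowalk$flag])
        for (g in flagged) {
            M <- stage(paste0("ld:", g), ldMatrix(x, g))
            utils::write.table(M, file.path(cfg$outputDir,
                                            paste0("ld_", g, ".tsv")),
                               quote = FALSE, sep = "\t")
        }
    }
    if ("block" %in% stages) {
        res$blocks <- list()
        for (bn in names(cfg$blocks)) {
            res$blocks[[bn]] <- stage(paste0("block:", bn),
                blockAnalysis(x, cfg$blocks[[bn]],
                              covariates = cfg$covariates$haplotype,
                              poolThreshold = cfg$poolThreshold))
            utils::write.table(hapGlmTable(res$blocks[[bn]]),
                               file.path(cfg$outputDir,
                                         paste0("block_", bn, ".tsv")),
                               quote = FALSE, sep = "\t",
                               row.names = FALSE)
        }
    }
    if ("stratify" %in% stages) {
        res$stratified <- list()
        for (bn in names(cfg$blocks)) for (sv in cfg$stratifyBy) {
            key <- paste0(bn, "_", sv)
            res$stratified[[key]] <- stage(paste0("stratify:", key),
                stratifiedBlocks(x, cfg$blocks[[bn]], stratifyBy = sv,
                                 covariates = cfg$covariates$haplotype,
                                 poolThreshold = cfg$poolThreshold))
            utils::write.table(stratifiedTable(res$stratified[[key]]),
                               file.path(cfg$outputDir,
                                         paste0("stratified_", key,
                                                ".tsv")),
                               quote = FALSE, sep = "\t",
                               row.names = FALSE)
        }
    }

    manifest$warnings <- collected
    yaml::write_yaml(manifest, file.path(cfg$outputDir, "manifest.yaml"))
    res$manifest <- manifest
    invisible(res)
}

.cliUsage <- function() {
    paste(
        "usage: snphapscan <subcommand> [--config FILE] [--seed N]",
        "                  [--B N] [--out DIR]",
        "subcommands: simulate qc descriptives assoc minp haplowalk",
        "             block stratify run-all",
        sep = "\n")
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher over \code{\link{runPipeline}}; used by
#' the installed \code{inst/scripts/snphapscan} wrapper. Returns an exit
#' code instead of quitting so it can be driven programmatically.
#'
#' @param args character vector of command-line arguments
#' @return integer exit code: 0 success, 1 stage failure, 2 usage error
#' @export
snpHapCli <- function(args = commandArgs(trailingOnly = TRUE)) {
    subMap <- c(simulate = "load", qc = "qc",
                descriptives = "descriptives", assoc = "assoc",
                minp = "minp", haplowalk = "haplowalk", block = "block",
                stratify = "stratify", "run-all" = "all")
    if (!length(args) || args[1] %in% c("--help", "-h", "help")) {
        cat(.cliUsage(), "\n")
        return(invisible(0L))
    }
    sub <- args[1]
    if (!sub %in% names(subMap)) {
        cat("unknown subcommand: ", sub, "\n", .cliUsage(), "\n",
            sep = "")
        return(invisible(2L))
    }
    rest <- args[-1]
    if ("--help" %in% rest || "-h" %in% rest) {
        cat(.cliUsage(), "\n")
        return(invisible(0L))
    }
    getOpt <- function(flag) {
        i <- which(rest == flag)
        if (length(i) == 1 && i < length(rest)) rest[i + 1] else NULL
    }
    cfg <- tryCatch({
        cf <- getOpt("--config")
        if (!is.null(cf)) readAnalysisConfig(cf)
        else validateAnalysisConfig(.defaultAnalysisConfig())
    }, error = function(e) e)
    if (inherits(cfg, "error")) {
        message("config error: ", conditionMessage(cfg))
        return(invisible(2L))
    }
    cfg <- unclass(cfg)
    sd <- getOpt("--seed")
    if (!is.null(sd)) cfg$simulate$seed <- as.integer(sd)
    B <- getOpt("--B")
    if (!is.null(B)) cfg$minp$B <- as.integer(B)
    out <- getOpt("--out")
    if (!is.null(out)) cfg$outputDir <- out

    stages <- if (subMap[[sub]] == "all") .pipelineStages
              else unique(c("load", subMap[[sub]]))
    ok <- tryCatch({
        runPipeline(cfg, stages = stages)
        TRUE
    }, error = function(e) {
        message(conditionMessage(e))
        FALSE
    })
    invisible(if (ok) 0L else 1L)
}
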