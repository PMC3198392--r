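#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#'   rowData<- colData<-
NULL

#' SnpCohort: genotypes plus subject and SNP metadata
#'
#' The central container of the package. A \code{SnpCohort} extends
#' \linkS4class{SummarizedExperiment} with a single \code{"calls"} assay
#' holding minor-allele counts (0, 1, 2, or \code{NA} for a failed call),
#' SNPs as rows and subjects as columns. \code{rowData} carries the SNP
#' metadata (rsid, gene region, cytogenetic band, 5'-to-3' position index
#' within the gene, major/minor alleles); \code{colData} carries the
#' subject records (case-control status, age, sex, center, country and
#' lifestyle covariates).
#'
#' Validity requires: all non-missing calls in \{0,1,2\}; unique rsids;
#' within each gene a contiguous 0-based \code{positionIndex}; status
#' binary; and distinct major/minor alleles per SNP.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}; no extra slots.
#' @seealso \code{\link{SnpCohort}} (constructor), \code{\link{genotypes}},
#'   \code{\link{snpInfo}}, \code{\link{subjectData}}, \code{\link{geneRegions}}
#' @export
setClass("SnpCohort", contains = "SummarizedExperiment")

.validSnpCohort <- function(object) {
    msg <- character()
    if (!"calls" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'calls' is required")
    else {
        g <- assay(object, "calls")
        ok <- is.na(g) | g %in% c(0L, 1L, 2L)
        if (!all(ok))
            msg <- c(msg, "non-missing genotype calls must be 0, 1 or 2")
    }
    rd <- rowData(object)
    need <- c("rsid", "gene", "positionIndex", "majorAllele", "minorAllele")
    miss <- setdiff(need, colnames(rd))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        if (anyDuplicated(rd$rsid))
            msg <- c(msg, "rsids must be unique")
        if (any(rd$majorAllele == rd$minorAllele))
            msg <- c(msg, "major and minor allele must differ")
        for (g in unique(rd$gene)) {
            idx <- sort(rd$positionIndex[rd$gene == g])
            if (!identical(as.integer(idx), seq_along(idx) - 1L)) {
                msg <- c(msg, paste0("positionIndex not contiguous 0-based ",
                                     "within gene ", g))
                break
            }
        }
    }
    cd <- colData(object)
    if ("status" %in% colnames(cd)) {
        if (!all(cd$status %in% c(0L, 1L)))
            msg <- c(msg, "status must be 0 (control) or 1 (case)")
    } else msg <- c(msg, "colData lacks 'status'")
    if (length(msg)) msg else TRUE
}
setValidity("SnpCohort", .validSnpCohort)

#' Construct a SnpCohort
#'
#' @param genotypes integer matrix of minor-allele counts, SNPs x subjects
#'   (0/1/2, \code{NA} = missing call). Row names are ignored; SNP identity
#'   comes from \code{snpInfo$rsid}.
#' @param snpInfo data.frame (or DataFrame) with columns \code{rsid},
#'   \code{gene}, \code{positionIndex} (0-based, 5' to 3' within gene),
#'   \code{majorAllele}, \code{minorAllele}, optionally \code{chromBand}.
#' @param subjects data.frame with one row per subject; must contain
#'   \code{id} and \code{status} (1 = case, 0 = control) and may contain
#'   \code{age}, \code{ageClass}, \code{sex}, \code{center}, \code{country},
#'   \code{bmiClass}, \code{smoking}, \code{hypertension}, \code{familyHistory},
#'   \code{vegetableFreq}, \code{alcoholFreq} and derived tertiles.
#' @return a validated \code{SnpCohort}
#' @examples
#' g <- matrix(c(1L, 2L, 0L), nrow = 1,
#'             dimnames = list(NULL, c("s1", "s2", "s3")))
#' si <- data.frame(rsid = "rs1", gene = "G1", positionIndex = 0L,
#'                  majorAllele = "A", minorAllele = "G")
#' su <- data.frame(id = c("s1", "s2", "s3"), status = c(1L, 0L, 0L))
#' SnpCohort(g, si, su)
#' @export
SnpCohort <- function(genotypes, snpInfo, subjects) {
    genotypes <- as.matrix(genotypes)
    storage.mode(genotypes) <- "integer"
    snpInfo <- DataFrame(snpInfo)
    rownames(snpInfo) <- NULL
    subjects <- DataFrame(subjects)
    rownames(subjects) <- NULL
    if (nrow(genotypes) != nrow(snpInfo))
        stop("genotypes rows (", nrow(genotypes), ") != snpInfo rows (",
             nrow(snpInfo), ")")
    if (ncol(genotypes) != nrow(subjects))
        stop("genotypes columns (", ncol(genotypes), ") != subject rows (",
             nrow(subjects), ")")
    rownames(genotypes) <- snpInfo$rsid
    colnames(genotypes) <- as.character(subjects$id)
    se <- SummarizedExperiment(assays = list(calls = genotypes),
                               rowData = snpInfo, colData = subjects)
    new("SnpCohort", se)
}

#' @describeIn SnpCohort display a short summary
#' @param object a SnpCohort
#' @export
setMethod("show", "SnpCohort", function(object) {
    cd <- colData(object)
    cat("SnpCohort:", nrow(object), "SNPs x", ncol(object), "subjects\n")
    cat("  genes:", length(unique(rowData(object)$gene)),
        " | cases:", sum(cd$status == 1L),
        " controls:", sum(cd$status == 0L), "\n")
    cr <- mean(!is.na(assay(object, "calls")))
    cat(sprintf("  overall call rate: %.4f\n", cr))
})

#' HaploTable: EM haplotype-frequency estimate over a SNP window
#'
#' Result of \code{\link{emHaplotypes}}. Haplotypes are stored as a 0/1
#' matrix over the window's SNPs (1 = minor allele) with estimated
#' population frequencies, plus per-subject phase posteriors (as an index
#' into genotype-pattern groups, so that posterior dosages can be formed
#' without storing one list per subject).
#'
#' @slot rsids character, ordered SNP window (5' to 3')
#' @slot alleles character matrix 2 x m: major/minor allele per SNP
#' @slot hap integer matrix H x m of 0/1 minor-allele indicators
#' @slot freq numeric length H, sums to 1
#' @slot subjectIds character, subjects retained (complete in window)
#' @slot patternOf integer, per-subject index into the pattern list
#' @slot pairs list, one element per pattern: list(h1, h2, post) with
#'   haplotype row indices and posterior probabilities summing to 1
#' @slot logLik numeric, maximized log-likelihood
#' @slot iterations integer, EM iterations used
#' @slot converged logical
#' @export
setClass("HaploTable", representation(
    rsids = "character", alleles = "matrix", hap = "matrix",
    freq = "numeric", subjectIds = "character", patternOf = "integer",
    pairs = "list", logLik = "numeric", iterations = "integer",
    converged = "logical"))

setValidity("HaploTable", function(object) {
    msg <- character()
    if (abs(sum(object@freq) - 1) > 1e-6)
        msg <- c(msg, "haplotype frequencies must sum to 1")
    if (nrow(object@hap) != length(object@freq))
        msg <- c(msg, "hap rows != freq length")
    for (pp in object@pairs)
        if (abs(sum(pp$post) - 1) > 1e-6) {
            msg <- c(msg, "phase posteriors must sum to 1"); break
        }
    if (length(msg)) msg else TRUE
})

#' @describeIn HaploTable display the estimated haplotypes
#' @param object a HaploTable
#' @export
setMethod("show", "HaploTable", function(object) {
    cat("HaploTable over", length(object@rsids), "SNPs (",
        paste(object@rsids, collapse = ", "), ")\n")
    cat("  ", length(object@subjectIds), "subjects,",
        nrow(object@hap), "haplotypes, logLik",
        sprintf("%.4f", object@logLik), "in", object@iterations,
        "EM iterations\n")
    lab <- hapLabels(object)
    o <- order(object@freq, decreasing = TRUE)
    for (i in o)
        cat(sprintf("   %-20s %.4f\n", lab[i], object@freq[i]))
})

#' HapGlmFit: haplotype odds ratios from a posterior-dosage logistic model
#'
#' Result of \code{\link{haplotypeGlm}}: per-haplotype odds ratios against
#' the most frequent (reference) haplotype, with haplotypes below the
#' pooling threshold combined into a single "rare" term, plus a global
#' Wald test across all haplotype terms.
#'
#' @slot window character, SNP window rsids
#' @slot table data.frame: haplotype label, frequency (overall, cases,
#'   controls), OR, CI bounds, Wald p; reference row has OR 1 and NA p
#' @slot reference character, reference haplotype label
#' @slot globalStat numeric Wald chi-square
#' @slot globalDf integer
#' @slot globalP numeric
#' @slot fit list, the underlying \code{\link{fitLogistic}} result
#' @slot covariates character, covariate set descriptor
#' @export
setClass("HapGlmFit", representation(
    window = "character", table = "data.frame", reference = "character",
    globalStat = "numeric", globalDf = "integer", globalP = "numeric",
    fit = "list", covariates = "character"))

#' @describeIn HapGlmFit display the haplotype association table
#' @param object a HapGlmFit
#' @export
setMethod("show", "HapGlmFit", function(object) {
    cat("Haplotype association, window 5' -",
        paste(object@window, collapse = ", "), "- 3'\n")
    cat("  reference:", object@reference,
        "| adjusted for:", object@covariates, "\n")
    tb <- object@table
    for (i in seq_len(nrow(tb))) {
        if (is.na(tb$p[i]) && tb$haplotype[i] == object@reference)
            cat(sprintf("   %-16s %5.1f%% / %5.1f%%  1.00 (ref)\n",
                        tb$haplotype[i], 100 * tb$freqCases[i],
                        100 * tb$freqControls[i]))
        else
            cat(sprintf("   %-16s %5.1f%% / %5.1f%%  %.2f (%.2f-%.2f) p=%.3g\n",
                        tb$haplotype[i], 100 * tb$freqCases[i],
                        100 * tb$freqControls[i], tb$or[i], tb$lo[i],
                        tb$hi[i], tb$p[i]))
    }
    cat(sprintf("  global Wald chi2 = %.3f, df = %d, p = %.3g\n",
                object@globalStat, object@globalDf, object@globalP))
})
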