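#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom Pearson chi-square of observed genotype counts
#' against the proportions expected under random mating at the sample
#' allele frequency (p^2, 2pq, q^2). A monomorphic SNP carries no
#' information about mating structure, so its p-value is defined as 1.
#'
#' @param nAA,nAa,naa genotype counts (major homozygote, heterozygote,
#'   minor homozygote); non-negative, total > 0
#' @return named numeric: \code{chi2}, \code{p}
#' @examples
#' hweTest(25, 50, 25)  # exact HWE proportions: chi2 0, p 1
#' hweTest(30, 40, 30)  # chi2 4, p 0.0455
#' @export
hweTest <- function(nAA, nAa, naa) {
    if (any(c(nAA, nAa, naa) < 0)) stop("genotype counts must be >= 0")
    n <- nAA + nAa + naa
    if (n <= 0) stop("total genotype count must be positive")
    p <- (2 * nAA + nAa) / (2 * n)
    if (p == 0 || p == 1)
        return(c(chi2 = 0, p = 1))
    expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    chi2 <- sum((c(nAA, nAa, naa) - expd)^2 / expd)
    c(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Genotype quality-control summary
#'
#' Per-SNP call rate, duplicate concordance (when duplicate sample pairs
#' are supplied), control-only Hardy-Weinberg test and control minor-allele
#' frequency, with flags against the study thresholds. SNPs failing a
#' threshold are flagged, not removed.
#'
#' @param x a \code{\linkS4class{SnpCohort}}
#' @param duplicates optional list of length-2 character vectors (subject
#'   id pairs genotyped twice); concordance is the fraction of SNP calls
#'   agreeing across pairs where both calls are non-missing, \code{NA}
#'   when no duplicate pairs (or no doubly-called genotypes) exist
#' @param thresholds named list: \code{callRate} (default 0.98),
#'   \code{hweP} (0.05), \code{maf} (0.05)
#' @return data.frame, one row per SNP: rsid, gene, callRate, concordance,
#'   hweChi2, hweP, controlMaf and logical flag columns
#' @export
qcSummary <- function(x, duplicates = list(),
                      thresholds = list(callRate = 0.98, hweP = 0.05,
                                        maf = 0.05)) {
    g <- genotypes(x)
    rd <- rowData(x)
    status <- caseStatus(x)
    cr <- rowMeans(!is.na(g))

    conc <- rep(NA_real_, nrow(g))
    if (length(duplicates)) {
        agree <- total <- numeric(nrow(g))
        ids <- colnames(g)
        for (pr in duplicates) {
            i <- match(pr[1], ids); j <- match(pr[2], ids)
            if (is.na(i) || is.na(j))
                stop("duplicate pair id not in cohort: ",
                     pr[which(c(is.na(i), is.na(j)))[1]])
            both <- !is.na(g[, i]) & !is.na(g[, j])
            total <- total + both
            agree <- agree + (both & g[, i] == g[, j])
        }
        conc <- ifelse(total > 0, agree / total, NA_real_)
    }

    gc <- g[, status == 0L, drop = FALSE]
    nAA <- rowSums(gc == 0L, na.rm = TRUE)
    nAa <- rowSums(gc == 1L, na.rm = TRUE)
    naa <- rowSums(gc == 2L, na.rm = TRUE)
    hwe <- t(mapply(function(a, b, c) hweTest(a, b, c), nAA, nAa, naa))
    maf <- (nAa + 2 * naa) / (2 * (nAA + nAa + naa))

    data.frame(rsid = rd$rsid, gene = rd$gene, callRate = cr,
               concordance = conc, hweChi2 = hwe[, "chi2"],
               hweP = hwe[, "p"], controlMaf = maf,
               flagCallRate = cr < thresholds$callRate,
               flagHwe = hwe[, "p"] < thresholds$hweP,
               flagMaf = maf < thresholds$maf,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a QC report as a tab-separated table
#' @param qc data.frame from \code{\link{qcSummary}}
#' @param path output path
#' @export
writeQcReport <- function(qc, path) {
    utils::write.table(qc, path, quote = FALSE, sep = "\t",
                       row.names = FALSE)
    invisible(path)
}
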