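#' Accessors for SnpCohort objects
#'
#' \code{genotypes} returns the minor-allele count matrix (SNPs x subjects,
#' \code{NA} = missing call). \code{snpInfo} returns the SNP metadata,
#' \code{subjectData} the subject records, \code{geneRegions} the ordered
#' (5' to 3') rsid list per gene region, \code{caseStatus} the 0/1 status
#' vector, \code{callRate} the per-SNP non-missing fraction and
#' \code{controlMaf} the per-SNP minor-allele frequency among controls.
#'
#' @param x a \code{\linkS4class{SnpCohort}}
#' @return see individual descriptions
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname cohort-accessors
#' @export
setMethod("genotypes", "SnpCohort", function(x) assay(x, "calls"))

#' @rdname cohort-accessors
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @rdname cohort-accessors
#' @export
setMethod("snpInfo", "SnpCohort", function(x) rowData(x))

#' @rdname cohort-accessors
#' @export
setGeneric("subjectData", function(x) standardGeneric("subjectData"))

#' @rdname cohort-accessors
#' @export
setMethod("subjectData", "SnpCohort", function(x) colData(x))

#' @rdname cohort-accessors
#' @export
setGeneric("geneRegions", function(x) standardGeneric("geneRegions"))

#' @rdname cohort-accessors
#' @export
setMethod("geneRegions", "SnpCohort", function(x) {
    rd <- rowData(x)
    out <- lapply(split(seq_len(nrow(rd)), rd$gene), function(i) {
        i <- i[order(rd$positionIndex[i])]
        as.character(rd$rsid[i])
    })
    out[unique(as.character(rd$gene))]
})

#' @rdname cohort-accessors
#' @export
setGeneric("caseStatus", function(x) standardGeneric("caseStatus"))

#' @rdname cohort-accessors
#' @export
setMethod("caseStatus", "SnpCohort", function(x) {
    s <- colData(x)$status
    stats::setNames(as.integer(s), colnames(x))
})

#' @rdname cohort-accessors
#' @export
callRate <- function(x) {
    g <- genotypes(x)
    rowMeans(!is.na(g))
}

#' @rdname cohort-accessors
#' @export
controlMaf <- function(x) {
    g <- genotypes(x)[, caseStatus(x) == 0L, drop = FALSE]
    rowSums(g, na.rm = TRUE) / (2 * rowSums(!is.na(g)))
}

# internal: subjects x SNPs orientation used by the model code
.gt <- function(x) t(genotypes(x))

# internal: fetch one SNP's dosage vector by rsid
.snpVec <- function(x, rsid) {
    i <- match(rsid, rowData(x)$rsid)
    if (is.na(i)) stop("unknown rsid: ", rsid)
    as.integer(genotypes(x)[i, ])
}
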