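# Fast internal trend-test p-value: Wald test on the dosage coefficient
# of a maximum-likelihood logistic fit (lean IRLS, deviance tolerance
# 1e-8 as in fitLogistic, but without the bookkeeping the permutation
# loop does not need). X is the fixed design (dosage first, then
# covariates, no intercept column - one is added here). Returns NA on a
# singular or divergent fit so the caller can drop the SNP.
.trendPFast <- function(y, X) {
    Xi <- cbind(1, X)
    p <- ncol(Xi)
    beta <- numeric(p)
    devOld <- Inf
    XtWX <- NULL
    for (it in 1:100) {
        eta <- drop(Xi %*% beta)
        mu <- 1 / (1 + exp(-eta))
        w <- mu * (1 - mu)
        w[w < 1e-10] <- 1e-10
        z <- eta + (y - mu) / w
        wX <- Xi * w
        XtWX <- crossprod(Xi, wX)
        beta <- tryCatch(drop(solve(XtWX, crossprod(wX, z))),
                         error = function(e) NULL)
        if (is.null(beta)) return(NA_real_)
        dev <- -2 * sum(ifelse(y == 1, log(mu + 1e-300),
                               log(1 - mu + 1e-300)))
        if (abs(dev - devOld) < 1e-8) break
        devOld <- dev
    }
    V <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(V)) return(NA_real_)
    se <- sqrt(V[2, 2])
    if (!is.finite(se) || (abs(beta[2]) > 10 && se > 10))
        return(NA_real_)
    2 * stats::pnorm(-abs(beta[2] / se))
}

#' Gene-level minimum-p permutation (min-P) test
#'
#' The gene's statistic is the minimum per-SNP additive-trend p-value.
#' Its null distribution is obtained by shuffling case/control labels
#' within permutation strata (default: study center, preserving the
#' frequency-matched design margins) while genotypes and covariates stay
#' attached to their subjects, and recomputing the minimum identically.
#' The empirical p-value is (count + 1) / (B + 1) where count is the
#' number of permutations whose minimum is at most the observed one;
#' this accounts for the LD correlation between the gene's SNPs without
#' any independence assumption.
#'
#' @param x a \code{\linkS4class{SnpCohort}}
#' @param gene gene-region name (SNP set taken from the cohort metadata)
#' @param covariates adjustment covariates for the per-SNP trend model
#' @param B number of permutations (>= 99)
#' @param seed integer seed for the permutation stream
#' @param strata subject column defining permutation strata, or NULL for
#'   unstratified shuffling
#' @return list of class \code{"minPResult"}: gene, snps, observedMinP,
#'   B, count, empiricalP, seed
#' @export
minPTest <- function(x, gene, covariates = c("age", "sex", "center"),
                     B = 9999L, seed = 1L, strata = "center") {
    if (B < 99) stop("B must be at least 99")
    rsids <- geneRegions(x)[[gene]]
    if (is.null(rsids)) stop("unknown gene region: ", gene)
    su <- as.data.frame(colData(x))
    Z <- .covariateDesign(su, covariates)
    okCov <- if (ncol(Z)) stats::complete.cases(Z) else
        rep(TRUE, nrow(su))
    y <- su$status
    G <- sapply(rsids, function(r) .snpVec(x, r))
    if (is.null(dim(G))) G <- matrix(G, ncol = 1,
                                     dimnames = list(NULL, rsids))
    poly <- apply(G, 2, function(g) {
        v <- g[!is.na(g) & okCov & !is.na(y)]
        length(unique(v)) > 1
    })
    if (!any(poly)) stop("gene ", gene, " has no polymorphic SNP")
    G <- G[, poly, drop = FALSE]
    rsids <- rsids[poly]

    keepList <- lapply(seq_along(rsids), function(j)
        which(!is.na(G[, j]) & okCov & !is.na(y)))
    designs <- lapply(seq_along(rsids), function(j) {
        k <- keepList[[j]]
        cbind(G[k, j], Z[k, , drop = FALSE])
    })

    minPOf <- function(yy) {
        ps <- vapply(seq_along(rsids), function(j)
            .trendPFast(yy[keepList[[j]]], designs[[j]]), numeric(1))
        suppressWarnings(min(ps, na.rm = TRUE))
    }
    obs <- minPOf(y)

    if (is.null(strata)) {
        stratIdx <- list(which(!is.na(y)))
    } else {
        sv <- su[[strata]]
        stratIdx <- split(which(!is.na(y)), sv[!is.na(y)])
        single <- lengths(stratIdx) < 2
        if (any(single)) {
            warning("skipping ", sum(single),
                    " permutation stratum/strata with a single subject")
            stratIdx <- stratIdx[!single]
        }
    }

    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
        assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(seed)

    count <- 0L
    yPerm <- y
    for (b in seq_len(B)) {
        for (idx in stratIdx) yPerm[idx] <- y[sample(idx)]
        if (minPOf(yPerm) <= obs) count <- count + 1L
    }
    structure(list(gene = gene, snps = rsids, observedMinP = obs,
                   B = as.integer(B), count = count,
                   empiricalP = (count + 1) / (B + 1),
                   seed = as.integer(seed)),
              class = "minPResult")
}

#' @export
print.minPResult <- function(x, ...) {
    cat(sprintf(
        "min-P test for %s (%d SNPs): observed min p = %.4g, empirical p = %.4g (B = %d, seed = %d)\n",
        x$gene, length(x$snps), x$observedMinP, x$empiricalP, x$B, x$seed))
    invisible(x)
}

#' BH adjustment of min-P empirical p-values across genes
#'
#' @param results list of \code{minPTest} results
#' @return data.frame: gene, nSnps, observedMinP, empiricalP, fdrMinP
#' @export
minPFdr <- function(results) {
    if (!length(results)) stop("no min-P results supplied")
    emp <- vapply(results, function(r) r$empiricalP, numeric(1))
    data.frame(gene = vapply(results, function(r) r$gene, character(1)),
               nSnps = vapply(results, function(r) length(r$snps),
                              integer(1)),
               observedMinP = vapply(results, function(r) r$observedMinP,
                                     numeric(1)),
               empiricalP = emp, fdrMinP = bhFdr(emp),
               stringsAsFactors = FALSE)
}

#' Gene-level summary table (min trend p, FDR, min-P test)
#'
#' One row per gene region: SNP count, minimum trend p across its SNPs,
#' the within-gene FDR-adjusted minimum, the min-P empirical p and its
#' BH adjustment across genes.
#'
#' @param scan data.frame from \code{\link{snpScan}} (within-gene FDR)
#' @param minp data.frame from \code{\link{minPFdr}}
#' @return data.frame in gene order of \code{minp}
#' @export
geneSummaryTable <- function(scan, minp) {
    rows <- lapply(minp$gene, function(g) {
        sg <- scan[scan$gene == g & !is.na(scan$pTrend), , drop = FALSE]
        data.frame(gene = g, nSnps = minp$nSnps[minp$gene == g],
                   minPTrend = if (nrow(sg)) min(sg$pTrend) else NA_real_,
                   fdrMinPTrend = if (nrow(sg)) min(sg$fdrTrend) else NA_real_,
                   minPEmpirical = minp$empiricalP[minp$gene == g],
                   minPFdr = minp$fdrMinP[minp$gene == g],
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
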