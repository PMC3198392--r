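#' Single-SNP codominant and trend logistic models
#'
#' Fits, for one SNP, (i) the codominant model with heterozygote and
#' rare-homozygote indicator terms against the common-homozygote
#' reference and (ii) the additive trend model with the 0/1/2 minor-allele
#' count as a single term, both adjusted for the given covariates.
#' Subjects with a missing genotype or any missing covariate are excluded
#' listwise. Odds ratios carry Wald 95% intervals (exp(b +/- 1.96 se));
#' the trend p is the two-sided Wald test on the dosage coefficient.
#'
#' @param x a \code{\linkS4class{SnpCohort}}
#' @param rsid SNP identifier
#' @param covariates character vector of subject columns to adjust for
#'   (default age continuous, sex, center)
#' @return data.frame with rows \code{het}, \code{hom} (codominant; hom
#'   omitted when no rare homozygotes) and \code{trend}; columns rsid,
#'   model, term, or, lo, hi, p, n
#' @export
snpModels <- function(x, rsid, covariates = c("age", "sex", "center")) {
    g <- .snpVec(x, rsid)
    su <- as.data.frame(colData(x))
    Z <- .covariateDesign(su, covariates)
    keep <- !is.na(g) & !is.na(su$status) &
        (if (ncol(Z)) stats::complete.cases(Z) else TRUE)
    g <- g[keep]; y <- su$status[keep]
    Z <- Z[keep, , drop = FALSE]
    if (length(unique(g)) < 2)
        stop("SNP ", rsid, " is monomorphic among analyzable subjects")

    rows <- list()
    hasHom <- any(g == 2L)
    het <- as.numeric(g == 1L)
    if (hasHom) {
        hom <- as.numeric(g == 2L)
        Xc <- cbind(het = het, hom = hom, Z)
    } else Xc <- cbind(het = het, Z)
    fc <- fitLogistic(y, Xc)
    rows$het <- c(.waldRow(fc, "het"))
    if (hasHom) rows$hom <- c(.waldRow(fc, "hom"))
    ft <- fitLogistic(y, cbind(trend = g, Z))
    rows$trend <- c(.waldRow(ft, "trend"))

    out <- do.call(rbind, rows)
    data.frame(rsid = rsid,
               model = c(if (hasHom) c("codominant", "codominant")
                         else "codominant", "trend"),
               term = rownames(out), or = out[, "or"], lo = out[, "lo"],
               hi = out[, "hi"], p = out[, "p"], n = length(y),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Joint model with several SNPs as trend terms
#'
#' One logistic model containing every listed SNP as a 0/1/2 dosage term
#' plus covariates, used to judge whether correlated SNPs carry
#' independent signal (a SNP's joint OR attenuates toward 1 when its
#' marginal association is driven by LD with another included SNP).
#' Perfectly collinear SNPs trigger an aliasing warning and one term is
#' dropped.
#'
#' @inheritParams snpModels
#' @param rsids two or more SNP identifiers
#' @return data.frame with one row per retained SNP term: rsid, or, lo,
#'   hi, p, n
#' @export
jointSnpModel <- function(x, rsids, covariates = c("age", "sex", "center")) {
    if (length(rsids) < 2) stop("need at least two SNPs for a joint model")
    G <- sapply(rsids, function(r) .snpVec(x, r))
    su <- as.data.frame(colData(x))
    Z <- .covariateDesign(su, covariates)
    keep <- stats::complete.cases(G) & !is.na(su$status) &
        (if (ncol(Z)) stats::complete.cases(Z) else TRUE)
    G <- G[keep, , drop = FALSE]; y <- su$status[keep]
    Z <- Z[keep, , drop = FALSE]
    fit <- fitLogistic(y, cbind(G, Z))
    kept <- intersect(rsids, names(fit$coef))
    out <- t(sapply(kept, function(r) .waldRow(fit, r)))
    data.frame(rsid = kept, or = out[, "or"], lo = out[, "lo"],
               hi = out[, "hi"], p = out[, "p"], n = length(y),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (sort ascending, adj(k) = min over j >= k of
#' p(j) m / j, capped at 1), returned in input order. Wraps
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric p-values in (0, 1]
#' @return adjusted p-values, same order and length
#' @examples
#' bhFdr(c(0.01, 0.01, 0.30, 0.35, 0.40, 0.45))[1]  # 0.03
#' @export
bhFdr <- function(p) {
    if (any(!is.na(p) & (p <= 0 | p > 1)))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Trend-model FDR across the SNPs of each gene
#'
#' Runs the trend model for every SNP and BH-adjusts the trend p-values,
#' by default within each gene region (each gene's SNP set is its own
#' family); set \code{withinGene = FALSE} to adjust across all SNPs.
#'
#' @inheritParams snpModels
#' @param withinGene logical, adjust within gene (default) or study-wide
#' @return data.frame: rsid, gene, or, lo, hi, pTrend, fdrTrend, n
#' @export
snpScan <- function(x, covariates = c("age", "sex", "center"),
                    withinGene = TRUE) {
    rd <- rowData(x)
    res <- lapply(as.character(rd$rsid), function(r) {
        tr <- tryCatch(snpModels(x, r, covariates),
                       error = function(e) NULL)
        if (is.null(tr)) return(data.frame(
            rsid = r, or = NA_real_, lo = NA_real_, hi = NA_real_,
            p = NA_real_, n = NA_integer_, stringsAsFactors = FALSE))
        tr[tr$model == "trend", c("rsid", "or", "lo", "hi", "p", "n")]
    })
    out <- do.call(rbind, res)
    out$gene <- as.character(rd$gene)[match(out$rsid, rd$rsid)]
    names(out)[names(out) == "p"] <- "pTrend"
    out$fdrTrend <- NA_real_
    ok <- !is.na(out$pTrend)
    if (withinGene) {
        for (g in unique(out$gene)) {
            i <- ok & out$gene == g
            out$fdrTrend[i] <- bhFdr(out$pTrend[i])
        }
    } else out$fdrTrend[ok] <- bhFdr(out$pTrend[ok])
    out[, c("rsid", "gene", "or", "lo", "hi", "pTrend", "fdrTrend", "n")]
}

#' Confounder sensitivity of the trend log-odds-ratio
#'
#' Percent change in the per-allele log-OR when one extra covariate is
#' added to the base adjustment set: 100 |b_adj - b_base| / |b_base|.
#' Changes of at least 5% are flagged. When the base coefficient is
#' exactly zero the relative change is undefined and the absolute
#' difference is reported instead.
#'
#' @inheritParams snpModels
#' @param extra name of the additional covariate (e.g. smoking,
#'   hypertension, bmiClass)
#' @param threshold flag level on the percent change (default 5)
#' @return data.frame: rsid, betaBase, betaAdj, pctChange, absChange,
#'   flagged, relativeDefined
#' @export
confounderSensitivity <- function(x, rsid, extra,
                                  covariates = c("age", "sex", "center"),
                                  threshold = 5) {
    g <- .snpVec(x, rsid)
    su <- as.data.frame(colData(x))
    Z0 <- .covariateDesign(su, covariates)
    Z1 <- .covariateDesign(su, c(covariates, extra))
    keep <- !is.na(g) & !is.na(su$status) & stats::complete.cases(Z1)
    y <- su$status[keep]
    f0 <- fitLogistic(y, cbind(trend = g[keep], Z0[keep, , drop = FALSE]))
    f1 <- fitLogistic(y, cbind(trend = g[keep], Z1[keep, , drop = FALSE]))
    b0 <- unname(f0$coef["trend"]); b1 <- unname(f1$coef["trend"])
    if (b0 == 0) {
        data.frame(rsid = rsid, betaBase = b0, betaAdj = b1,
                   pctChange = NA_real_, absChange = abs(b1 - b0),
                   flagged = TRUE, relativeDefined = FALSE,
                   stringsAsFactors = FALSE)
    } else {
        pct <- 100 * abs(b1 - b0) / abs(b0)
        data.frame(rsid = rsid, betaBase = b0, betaAdj = b1,
                   pctChange = pct, absChange = abs(b1 - b0),
                   flagged = pct >= threshold, relativeDefined = TRUE,
                   stringsAsFactors = FALSE)
    }
}

#' SNP x factor interaction likelihood-ratio test
#'
#' Compares the logistic model \{trend + factor + covariates\} against
#' the same model plus trend-by-factor product terms; the statistic is
#' twice the log-likelihood difference on (levels - 1) degrees of
#' freedom.
#'
#' @inheritParams snpModels
#' @param factorName subject column holding the categorical modifier
#' @return named numeric: \code{statistic}, \code{df}, \code{p}
#' @export
snpFactorInteractionLrt <- function(x, rsid, factorName,
                                    covariates = c("age", "sex", "center")) {
    g <- .snpVec(x, rsid)
    su <- as.data.frame(colData(x))
    f <- factor(su[[factorName]])
    Z <- .covariateDesign(su, covariates)
    keep <- !is.na(g) & !is.na(su$status) & !is.na(f) &
        (if (ncol(Z)) stats::complete.cases(Z) else TRUE)
    g <- g[keep]; y <- su$status[keep]; f <- droplevels(f[keep])
    Z <- Z[keep, , drop = FALSE]
    if (nlevels(f) < 2) stop("factor ", factorName, " has fewer than 2 levels")
    Fm <- sapply(levels(f)[-1], function(L) as.numeric(f == L))
    colnames(Fm) <- paste0(factorName, levels(f)[-1])
    X0 <- cbind(trend = g, Fm, Z)
    XI <- g * Fm
    colnames(XI) <- paste0("trend:", colnames(Fm))
    f0 <- fitLogistic(y, X0)
    f1 <- fitLogistic(y, cbind(X0, XI))
    df <- length(f1$coef) - length(f0$coef)
    stat <- max(0, 2 * (f1$logLik - f0$logLik))
    c(statistic = stat, df = df,
      p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
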