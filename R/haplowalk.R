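#' Sliding-window haplotype scan (haplowalk)
#'
#' Runs \code{\link{haplotypeGlm}} on every consecutive window of
#' \code{width} SNPs within each gene region and BH-adjusts the global
#' Wald p-values (within gene by default); windows with adjusted p below
#' \code{fdrThreshold} are flagged as regions of interest. Genes with
#' fewer than \code{width} SNPs are skipped with a message. A window
#' whose EM or model fails contributes \code{NA} and is excluded from
#' the FDR family size.
#'
#' @param x a \code{\linkS4class{SnpCohort}}
#' @param genes gene-region names (default: all in the cohort)
#' @param width window width in SNPs (default 3)
#' @param fdrThreshold region-of-interest flag level (default 0.1)
#' @param covariates adjustment set for the window models
#' @param withinGene BH within gene (default) or across all windows
#' @param poolThreshold rare-haplotype pooling threshold per window
#' @return data.frame: gene, start (1-based SNP offset), window
#'   (comma-joined rsids), globalP, fdrP, flag
#' @export
haplowalk <- function(x, genes = NULL, width = 3L, fdrThreshold = 0.1,
                      covariates = c("ageClass", "sex", "center"),
                      withinGene = TRUE, poolThreshold = 0.05) {
    gr <- geneRegions(x)
    if (is.null(genes)) genes <- names(gr)
    rows <- list()
    for (g in genes) {
        rsids <- gr[[g]]
        if (is.null(rsids)) stop("unknown gene region: ", g)
        if (length(rsids) < width) {
            message("skipping gene ", g, ": fewer than ", width, " SNPs")
            next
        }
        for (s in seq_len(length(rsids) - width + 1L)) {
            win <- rsids[s:(s + width - 1L)]
            p <- tryCatch(
                haplotypeGlm(x, win, covariates = covariates,
                             poolThreshold = poolThreshold)@globalP,
                error = function(e) NA_real_)
            rows[[length(rows) + 1L]] <- data.frame(
                gene = g, start = s,
                window = paste(win, collapse = ","), globalP = p,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) return(data.frame(
        gene = character(), start = integer(), window = character(),
        globalP = numeric(), fdrP = numeric(), flag = logical()))
    out$fdrP <- NA_real_
    ok <- !is.na(out$globalP)
    if (withinGene) {
        for (g in unique(out$gene)) {
            i <- ok & out$gene == g
            out$fdrP[i] <- bhFdr(out$globalP[i])
        }
    } else out$fdrP[ok] <- bhFdr(out$globalP[ok])
    out$flag <- !is.na(out$fdrP) & out$fdrP < fdrThreshold
    out
}

#' Haplotype block analysis
#'
#' \code{\link{haplotypeGlm}} on an analyst-chosen ordered SNP block
#' (block choice is driven by flagged haplowalk windows and the LD
#' structure; it is not automated). Conventions: the most frequent
#' haplotype is the reference and haplotypes under 5% frequency are
#' pooled as "Rare".
#'
#' @param x a \code{\linkS4class{SnpCohort}}
#' @param block ordered rsids forming the block
#' @param covariates adjustment set
#' @param poolThreshold pooling threshold (default 0.05)
#' @return a \code{\linkS4class{HapGlmFit}}
#' @export
blockAnalysis <- function(x, block,
                          covariates = c("ageClass", "sex", "center"),
                          poolThreshold = 0.05) {
    haplotypeGlm(x, block, covariates = covariates,
                 poolThreshold = poolThreshold)
}

#' Haplotype associations within strata of an intake variable
#'
#' The haplotype dictionary, reference and rare pooling are frozen from
#' a phenotype-blind EM on the full analyzable sample (so every stratum
#' reports the same haplotype rows), then the dosage logistic model is
#' refit within each stratum. A per-haplotype interaction
#' likelihood-ratio test compares full-sample models with and without
#' that haplotype's dosage-by-stratum product terms (stratum treated as
#' categorical; df = number of strata - 1).
#'
#' @param x a \code{\linkS4class{SnpCohort}} with the stratifying column
#'   present (see \code{\link{assignTertiles}})
#' @param block ordered rsids
#' @param stratifyBy subject column, e.g. \code{"vegetableTertile"} or
#'   \code{"alcoholTertile"}
#' @param covariates adjustment set; the stratifying variable must not
#'   be among them
#' @param poolThreshold pooling threshold
#' @param minPerArm strata with fewer cases or controls than this are
#'   reported as NA (default 25)
#' @return list of class \code{"stratifiedResult"}: \code{strata} (named
#'   list of per-stratum tables with global p), \code{interaction}
#'   (data.frame haplotype, lrt, df, pInt), \code{reference},
#'   \code{block}, \code{stratifyBy}, \code{n} (per-stratum subject
#'   counts)
#' @export
stratifiedBlocks <- function(x, block, stratifyBy = "vegetableTertile",
                             covariates = c("ageClass", "sex", "center"),
                             poolThreshold = 0.05, minPerArm = 25L) {
    su <- as.data.frame(colData(x))
    if (!stratifyBy %in% names(su))
        stop("stratifying column ", stratifyBy,
             " absent; run assignTertiles() first")
    sv <- factor(su[[stratifyBy]])
    Z <- .covariateDesign(su, covariates)
    ok <- !is.na(su$status) & !is.na(sv) &
        (if (ncol(Z)) stats::complete.cases(Z) else TRUE)

    ht <- emHaplotypes(x, block, subset = which(ok))
    D <- hapDosage(ht)
    built <- .hapDesign(ht, D, poolThreshold)
    ids <- ht@subjectIds
    ri <- match(ids, as.character(su$id))
    y <- su$status[ri]
    Zk <- Z[ri, , drop = FALSE]
    sk <- droplevels(sv[ri])
    lab <- built$labels
    hapCols <- colnames(built$X)

    strata <- list(); ns <- integer(0)
    for (L in levels(sk)) {
        i <- which(sk == L)
        ns[L] <- length(i)
        if (sum(y[i] == 1) < minPerArm || sum(y[i] == 0) < minPerArm) {
            strata[L] <- list(NULL)
            next
        }
        fitS <- fitLogistic(y[i], cbind(built$X[i, , drop = FALSE],
                                        Zk[i, , drop = FALSE]))
        res <- .hapGlmResult(ht, built,
                             D[i, , drop = FALSE], y[i], fitS, block,
                             paste(covariates, collapse = "+"))
        strata[[L]] <- res
    }

    # interaction LRTs on the full sample
    Sm <- sapply(levels(sk)[-1], function(L) as.numeric(sk == L))
    colnames(Sm) <- paste0(stratifyBy, levels(sk)[-1])
    X0 <- cbind(built$X, Sm, Zk)
    f0 <- fitLogistic(y, X0)
    inter <- lapply(hapCols, function(h) {
        XI <- built$X[, h] * Sm
        colnames(XI) <- paste0(h, ":", colnames(Sm))
        f1 <- fitLogistic(y, cbind(X0, XI))
        df <- length(f1$coef) - length(f0$coef)
        stat <- max(0, 2 * (f1$logLik - f0$logLik))
        data.frame(haplotype = h, lrt = stat, df = df,
                   pInt = stats::pchisq(stat, df, lower.tail = FALSE),
                   stringsAsFactors = FALSE)
    })
    structure(list(strata = strata, interaction = do.call(rbind, inter),
                   reference = lab[built$refI], block = block,
                   stratifyBy = stratifyBy, n = ns),
              class = "stratifiedResult")
}

#' @export
print.stratifiedResult <- function(x, ...) {
    cat("Stratified haplotype analysis of block",
        paste(x$block, collapse = ", "), "by", x$stratifyBy, "\n")
    for (L in names(x$strata)) {
        cat("-- stratum", L, "(n =", x$n[[L]], ")\n")
        if (is.null(x$strata[[L]])) cat("   too small to fit (NA)\n")
        else show(x$strata[[L]])
    }
    cat("Interaction LRT per haplotype:\n")
    print(x$interaction, row.names = FALSE)
    invisible(x)
}

#' Single-SNP associations within strata
#'
#' Per-stratum trend (or dominant) odds ratio for one SNP, plus the
#' SNP-by-stratum interaction likelihood-ratio p-value from the full
#' sample.
#'
#' @inheritParams stratifiedBlocks
#' @param rsid SNP identifier
#' @param coding \code{"trend"} (0/1/2 dosage, default) or
#'   \code{"dominant"} (carrier indicator)
#' @return data.frame: stratum, or, lo, hi, p, n, plus attribute
#'   \code{pInt}
#' @export
stratifiedSnp <- function(x, rsid, stratifyBy = "vegetableTertile",
                          covariates = c("ageClass", "sex", "center"),
                          coding = c("trend", "dominant"),
                          minPerArm = 25L) {
    coding <- match.arg(coding)
    g <- .snpVec(x, rsid)
    if (coding == "dominant") g <- as.integer(g >= 1L)
    su <- as.data.frame(colData(x))
    sv <- factor(su[[stratifyBy]])
    Z <- .covariateDesign(su, covariates)
    ok <- !is.na(g) & !is.na(su$status) & !is.na(sv) &
        (if (ncol(Z)) stats::complete.cases(Z) else TRUE)
    g <- g[ok]; y <- su$status[ok]; sv <- droplevels(sv[ok])
    Z <- Z[ok, , drop = FALSE]
    rows <- lapply(levels(sv), function(L) {
        i <- sv == L
        if (sum(y[i] == 1) < minPerArm || sum(y[i] == 0) < minPerArm ||
            length(unique(g[i])) < 2)
            return(data.frame(stratum = L, or = NA_real_, lo = NA_real_,
                              hi = NA_real_, p = NA_real_, n = sum(i)))
        fit <- fitLogistic(y[i], cbind(snp = g[i], Z[i, , drop = FALSE]))
        wr <- unname(.waldRow(fit, "snp"))
        data.frame(stratum = L, or = wr[1], lo = wr[2], hi = wr[3],
                   p = wr[4], n = sum(i))
    })
    out <- do.call(rbind, rows)
    Sm <- sapply(levels(sv)[-1], function(L) as.numeric(sv == L))
    f0 <- fitLogistic(y, cbind(snp = g, Sm, Z))
    XI <- g * Sm
    colnames(XI) <- paste0("snp:", levels(sv)[-1])
    f1 <- fitLogistic(y, cbind(snp = g, Sm, Z, XI))
    df <- length(f1$coef) - length(f0$coef)
    stat <- max(0, 2 * (f1$logLik - f0$logLik))
    attr(out, "pInt") <- stats::pchisq(stat, df, lower.tail = FALSE)
    out
}

#' Likelihood-ratio test for effect heterogeneity among countries
#'
#' Compares logistic models with and without genotype-by-country (or
#' haplotype-dosage-by-country) product terms. Countries contributing no
#' usable contrast have their products dropped by the aliasing rules,
#' reducing the degrees of freedom accordingly.
#'
#' @param x a \code{\linkS4class{SnpCohort}} with a \code{country}
#'   subject column holding at least two countries
#' @param rsid single SNP (trend coding); exactly one of \code{rsid} and
#'   \code{block} must be given
#' @param block ordered rsids; haplotype dosages from a phenotype-blind
#'   EM enter as the terms
#' @param covariates adjustment set (should not include country/center)
#' @param poolThreshold pooling threshold for block mode
#' @return named numeric: \code{statistic}, \code{df}, \code{p}
#' @export
countryHeterogeneityLrt <- function(x, rsid = NULL, block = NULL,
                                    covariates = c("age", "sex"),
                                    poolThreshold = 0.05) {
    if (is.null(rsid) == is.null(block))
        stop("give exactly one of rsid or block")
    su <- as.data.frame(colData(x))
    if (!"country" %in% names(su)) stop("no country column")
    Z <- .covariateDesign(su, covariates)

    if (!is.null(rsid)) {
        g <- .snpVec(x, rsid)
        ok <- !is.na(g) & !is.na(su$status) & !is.na(su$country) &
            (if (ncol(Z)) stats::complete.cases(Z) else TRUE)
        Tm <- matrix(g[ok], ncol = 1, dimnames = list(NULL, rsid))
        y <- su$status[ok]
        co <- droplevels(factor(su$country[ok]))
        Zk <- Z[ok, , drop = FALSE]
    } else {
        ok <- !is.na(su$status) & !is.na(su$country) &
            (if (ncol(Z)) stats::complete.cases(Z) else TRUE)
        ht <- emHaplotypes(x, block, subset = which(ok))
        D <- hapDosage(ht)
        built <- .hapDesign(ht, D, poolThreshold)
        ri <- match(ht@subjectIds, as.character(su$id))
        Tm <- built$X
        y <- su$status[ri]
        co <- droplevels(factor(su$country[ri]))
        Zk <- Z[ri, , drop = FALSE]
    }
    if (nlevels(co) < 2) stop("need at least two countries")
    Cm <- sapply(levels(co)[-1], function(L) as.numeric(co == L))
    colnames(Cm) <- paste0("country", levels(co)[-1])
    X0 <- cbind(Tm, Cm, Zk)
    XI <- do.call(cbind, lapply(colnames(Tm), function(tn) {
        M <- Tm[, tn] * Cm
        colnames(M) <- paste0(tn, ":", colnames(Cm))
        M
    }))
    f0 <- suppressWarnings(fitLogistic(y, X0))
    f1 <- suppressWarnings(fitLogistic(y, cbind(X0, XI)))
    df <- length(f1$coef) - length(f0$coef)
    if (df < ncol(XI))
        message("country-heterogeneity LRT: ", ncol(XI) - df,
                " aliased product term(s) dropped; df reduced")
    stat <- max(0, 2 * (f1$logLik - f0$logLik))
    c(statistic = stat, df = df,
      p = stats::pchisq(stat, df, lower.tail = FALSE))
}
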