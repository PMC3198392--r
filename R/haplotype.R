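# Enumerate the haplotype pairs compatible with one multi-locus genotype.
# g: integer vector of minor-allele counts over the window (no NA).
# Returns list of two integer matrices (h1, h2) of 0/1 rows; for a
# genotype with k heterozygous sites there are max(1, 2^(k-1)) distinct
# unordered pairs (the first het site's minor allele is anchored to h1).
.phasePairs <- function(g) {
    m <- length(g)
    base <- as.integer(g == 2L)
    hets <- which(g == 1L)
    k <- length(hets)
    if (k == 0L)
        return(list(h1 = matrix(base, 1), h2 = matrix(base, 1)))
    nPair <- 2L^(k - 1L)
    h1 <- matrix(rep(base, each = nPair), nrow = nPair)
    h2 <- h1
    h1[, hets[1]] <- 1L; h2[, hets[1]] <- 0L
    if (k > 1L) {
        for (j in seq_len(k - 1L)) {
            bit <- bitwAnd(seq_len(nPair) - 1L, bitwShiftL(1L, j - 1L)) > 0L
            h1[, hets[j + 1L]] <- as.integer(bit)
            h2[, hets[j + 1L]] <- as.integer(!bit)
        }
    }
    list(h1 = h1, h2 = h2)
}

.hapCode <- function(h) as.integer(h %*% 2L^(seq_along(h) - 1L))

#' Haplotype allele-string labels, 5' to 3'
#'
#' Renders each estimated haplotype as its allele string in SNP order,
#' e.g. \code{"A-C-C-C"}.
#'
#' @param ht a \code{\linkS4class{HaploTable}}
#' @return character vector, one label per haplotype
#' @export
hapLabels <- function(ht) {
    apply(ht@hap, 1, function(row)
        paste(ifelse(row == 1L, ht@alleles["minor", ],
                     ht@alleles["major", ]), collapse = "-"))
}

#' EM haplotype-frequency estimation over a SNP window
#'
#' Maximum-likelihood haplotype frequencies from unphased genotypes by
#' the classic expectation-maximization scheme: the E-step distributes
#' each subject over its compatible haplotype pairs with posterior
#' probability proportional to f(h1) f(h2) (doubled for heterozygous
#' pairs); the M-step sets frequencies to expected haplotype counts over
#' 2n. Initialization is the linkage-equilibrium product of single-SNP
#' allele frequencies (deterministic); iteration stops when the
#' log-likelihood improves by less than \code{tol}. The log-likelihood is
#' checked to be non-decreasing at every step. Haplotypes ending below
#' frequency 1e-6 are dropped and the remainder renormalized.
#'
#' Subjects with any missing genotype in the window are excluded (the
#' default and only implemented missing-data policy).
#'
#' @param x a \code{\linkS4class{SnpCohort}}
#' @param window character vector of 1-8 rsids, 5' to 3'
#' @param subset optional logical/integer subject selector (e.g. controls
#'   only for LD estimation)
#' @param tol log-likelihood convergence tolerance
#' @param maxIter iteration cap
#' @return a \code{\linkS4class{HaploTable}}
#' @export
emHaplotypes <- function(x, window, subset = NULL, tol = 1e-8,
                         maxIter = 500L) {
    if (length(window) < 1 || length(window) > 8)
        stop("window must contain 1 to 8 SNPs")
    rd <- rowData(x)
    ri <- match(window, rd$rsid)
    if (anyNA(ri)) stop("unknown rsid in window: ",
                        window[which(is.na(ri))[1]])
    G <- t(genotypes(x)[ri, , drop = FALSE])
    ids <- rownames(G)
    if (!is.null(subset)) { G <- G[subset, , drop = FALSE]
                            ids <- ids[subset] }
    cc <- stats::complete.cases(G)
    G <- G[cc, , drop = FALSE]; ids <- ids[cc]
    n <- nrow(G)
    if (n == 0) stop("no subjects with complete genotypes in window")
    m <- length(window)
    alleles <- rbind(major = as.character(rd$majorAllele[ri]),
                     minor = as.character(rd$minorAllele[ri]))
    colnames(alleles) <- window

    key <- apply(G, 1, paste, collapse = "")
    uk <- unique(key)
    patternOf <- match(key, uk)
    patCount <- tabulate(patternOf, nbins = length(uk))
    patG <- G[match(uk, key), , drop = FALSE]

    pairsRaw <- lapply(seq_along(uk), function(i) .phasePairs(patG[i, ]))
    codes <- sort(unique(unlist(lapply(pairsRaw, function(pp)
        c(apply(pp$h1, 1, .hapCode), apply(pp$h2, 1, .hapCode))))))
    H <- length(codes)
    hap <- t(vapply(codes, function(cd)
        as.integer(bitwAnd(bitwShiftR(cd, seq_len(m) - 1L), 1L)),
        integer(m)))
    hap <- matrix(hap, nrow = H, ncol = m)
    pairs <- lapply(pairsRaw, function(pp) {
        list(h1 = match(apply(pp$h1, 1, .hapCode), codes),
             h2 = match(apply(pp$h2, 1, .hapCode), codes))
    })

    pj <- colMeans(G) / 2
    f <- apply(hap, 1, function(row)
        prod(ifelse(row == 1L, pj, 1 - pj)))
    if (sum(f) <= 0) f <- rep(1 / H, H)
    f <- f / sum(f)
    f[f == 0] <- 1e-12
    f <- f / sum(f)

    llOld <- -Inf; it <- 0L; converged <- FALSE
    post <- vector("list", length(uk))
    repeat {
        it <- it + 1L
        ll <- 0
        expCount <- numeric(H)
        for (i in seq_along(uk)) {
            p1 <- pairs[[i]]$h1; p2 <- pairs[[i]]$h2
            terms <- f[p1] * f[p2] * ifelse(p1 == p2, 1, 2)
            Li <- sum(terms)
            w <- terms / Li
            post[[i]] <- w
            ll <- ll + patCount[i] * log(Li)
            cw <- patCount[i] * w
            for (t in seq_along(w)) {
                expCount[p1[t]] <- expCount[p1[t]] + cw[t]
                expCount[p2[t]] <- expCount[p2[t]] + cw[t]
            }
        }
        if (ll < llOld - 1e-9)
            stop("EM log-likelihood decreased (", llOld, " -> ", ll, ")")
        if (abs(ll - llOld) < tol) { converged <- TRUE; break }
        if (it >= maxIter) break
        llOld <- ll
        f <- expCount / (2 * n)
    }

    # drop vanishing haplotypes (keeping every pattern explainable)
    dropable <- f < 1e-6
    if (any(dropable)) {
        for (i in seq_along(uk)) {
            live <- !(dropable[pairs[[i]]$h1] | dropable[pairs[[i]]$h2])
            if (!any(live))
                dropable[c(pairs[[i]]$h1, pairs[[i]]$h2)] <- FALSE
        }
    }
    if (any(dropable)) {
        keep <- which(!dropable)
        remap <- match(seq_len(H), keep)
        f <- f[keep] / sum(f[keep])
        hap <- hap[keep, , drop = FALSE]
        for (i in seq_along(uk)) {
            live <- !is.na(remap[pairs[[i]]$h1]) &
                !is.na(remap[pairs[[i]]$h2])
            pairs[[i]] <- list(h1 = remap[pairs[[i]]$h1[live]],
                               h2 = remap[pairs[[i]]$h2[live]])
            w <- post[[i]][live]
            post[[i]] <- w / sum(w)
        }
    }

    pairList <- lapply(seq_along(uk), function(i)
        list(h1 = pairs[[i]]$h1, h2 = pairs[[i]]$h2, post = post[[i]]))

    new("HaploTable", rsids = window, alleles = alleles, hap = hap,
        freq = unname(f), subjectIds = ids,
        patternOf = as.integer(patternOf), pairs = pairList,
        logLik = ll, iterations = it, converged = converged)
}

#' Posterior-expected haplotype dosages
#'
#' Per-subject expected copy number of each haplotype (in [0, 2]) under
#' the EM phase posteriors. Rows sum to 2 (conservation of chromosome
#' copies).
#'
#' @param ht a \code{\linkS4class{HaploTable}}
#' @return numeric matrix, subjects x haplotypes, with haplotype labels
#'   as column names
#' @export
hapDosage <- function(ht) {
    H <- nrow(ht@hap)
    nPat <- length(ht@pairs)
    patDose <- matrix(0, nPat, H)
    for (i in seq_len(nPat)) {
        pp <- ht@pairs[[i]]
        for (t in seq_along(pp$post)) {
            patDose[i, pp$h1[t]] <- patDose[i, pp$h1[t]] + pp$post[t]
            patDose[i, pp$h2[t]] <- patDose[i, pp$h2[t]] + pp$post[t]
        }
    }
    D <- patDose[ht@patternOf, , drop = FALSE]
    rownames(D) <- ht@subjectIds
    colnames(D) <- hapLabels(ht)
    D
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Two-locus haplotype frequencies are estimated by
#' \code{\link{emHaplotypes}} (controls only, by default, as is standard
#' for describing background LD), then r2 = D^2 / (pA qA pB qB) with
#' D = f(minor, minor) - pA pB.
#'
#' @param x a \code{\linkS4class{SnpCohort}}
#' @param rsidA,rsidB the SNP pair
#' @param controlsOnly use control subjects only (default TRUE)
#' @return list: rsids, r2, D, hapFreq (the 2-locus solution)
#' @export
ldR2 <- function(x, rsidA, rsidB, controlsOnly = TRUE) {
    subset <- if (controlsOnly) caseStatus(x) == 0L else NULL
    ht <- emHaplotypes(x, c(rsidA, rsidB), subset = subset)
    fullHap <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
    f4 <- numeric(4)
    idx <- match(apply(ht@hap, 1, paste, collapse = ""),
                 apply(fullHap, 1, paste, collapse = ""))
    f4[idx] <- ht@freq
    pA <- f4[2] + f4[4]; pB <- f4[3] + f4[4]
    if (pA %in% c(0, 1) || pB %in% c(0, 1))
        stop("LD undefined: monomorphic SNP in subset (",
             rsidA, ", ", rsidB, ")")
    D <- f4[4] - pA * pB
    r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
    list(rsids = c(rsidA, rsidB), r2 = min(max(r2, 0), 1), D = D,
         hapFreq = stats::setNames(
             f4, apply(fullHap, 1, paste, collapse = "/")))
}

#' LD r-squared matrix for a gene region
#'
#' @param x a \code{\linkS4class{SnpCohort}}
#' @param gene gene-region name
#' @param controlsOnly controls only (default TRUE)
#' @return symmetric numeric matrix of r2 values with rsid dimnames
#' @export
ldMatrix <- function(x, gene, controlsOnly = TRUE) {
    rsids <- geneRegions(x)[[gene]]
    if (is.null(rsids)) stop("unknown gene region: ", gene)
    m <- length(rsids)
    R <- matrix(1, m, m, dimnames = list(rsids, rsids))
    if (m < 2) return(R)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
        r2 <- tryCatch(ldR2(x, rsids[i], rsids[j],
                            controlsOnly = controlsOnly)$r2,
                       error = function(e) NA_real_)
        R[i, j] <- R[j, i] <- r2
    }
    R
}

#' Haplotype association by posterior-dosage logistic regression
#'
#' Estimates haplotype odds ratios for a SNP window: phase posteriors are
#' taken from a phenotype-blind EM on the pooled case-control sample, each
#' subject's expected copy number of each haplotype forms a dosage column,
#' haplotypes rarer than \code{poolThreshold} are summed into one "Rare"
#' column, and the dosages (all but the most frequent, reference,
#' haplotype) enter a covariate-adjusted logistic model. Per-haplotype
#' Wald odds ratios and a global Wald chi-square across all haplotype
#' terms are reported. Case/control frequency columns are posterior
#' expected counts split by group.
#'
#' An optional refinement mode re-weights each subject's phase posterior
#' by the fitted disease model and alternates posterior update and GLM
#' fit until the coefficients move less than 1e-6 (off by default; the
#' two-stage expectation-substitution estimate is deterministic and is
#' the documented behavior).
#'
#' @param x a \code{\linkS4class{SnpCohort}}
#' @param window ordered rsids (1-8 SNPs)
#' @param covariates adjustment covariates (default age class, sex,
#'   center — the haplotype-model adjustment set)
#' @param poolThreshold pool haplotypes below this frequency (default
#'   0.05)
#' @param refine logical, alternate posterior/GLM refinement
#' @return a \code{\linkS4class{HapGlmFit}}
#' @export
haplotypeGlm <- function(x, window,
                         covariates = c("ageClass", "sex", "center"),
                         poolThreshold = 0.05, refine = FALSE) {
    su <- as.data.frame(colData(x))
    Z <- .covariateDesign(su, covariates)
    okCov <- if (ncol(Z)) stats::complete.cases(Z) else rep(TRUE, nrow(su))
    ok <- okCov & !is.na(su$status)
    ht <- emHaplotypes(x, window, subset = which(ok))
    D <- hapDosage(ht)
    ids <- ht@subjectIds
    rowIdx <- match(ids, as.character(su$id))
    y <- su$status[rowIdx]
    Zk <- Z[rowIdx, , drop = FALSE]

    built <- .hapDesign(ht, D, poolThreshold)
    fit <- fitLogistic(y, cbind(built$X, Zk))
    if (refine)
        fit <- .refineHapFit(ht, built, y, Zk, fit)

    .hapGlmResult(ht, built, D, y, fit, window,
                  paste(covariates, collapse = "+"))
}

# Shared: build haplotype dosage design with reference + rare pooling.
.hapDesign <- function(ht, D, poolThreshold) {
    lab <- hapLabels(ht)
    refI <- which.max(ht@freq)
    if (ht@freq[refI] < poolThreshold)
        stop("reference haplotype frequency (", round(ht@freq[refI], 4),
             ") below pooling threshold ", poolThreshold,
             "; threshold too high")
    rare <- ht@freq < poolThreshold
    rare[refI] <- FALSE
    keep <- which(!rare & seq_along(lab) != refI)
    X <- D[, keep, drop = FALSE]
    colnames(X) <- lab[keep]
    if (any(rare)) {
        X <- cbind(X, Rare = rowSums(D[, rare, drop = FALSE]))
    }
    list(X = X, refI = refI, rare = rare, keep = keep, labels = lab)
}

.hapGlmResult <- function(ht, built, D, y, fit, window, covDesc) {
    lab <- built$labels
    hapTerms <- colnames(built$X)
    refLab <- lab[built$refI]
    nCase <- sum(y == 1); nCtrl <- sum(y == 0)
    fAll <- ht@freq
    fCase <- colSums(D[y == 1, , drop = FALSE]) / (2 * nCase)
    fCtrl <- colSums(D[y == 0, , drop = FALSE]) / (2 * nCtrl)

    ord <- c(built$refI, built$keep)
    rows <- lapply(ord, function(i) {
        if (i == built$refI)
            data.frame(haplotype = lab[i], freq = fAll[i],
                       freqCases = unname(fCase[i]),
                       freqControls = unname(fCtrl[i]),
                       or = 1, lo = NA_real_, hi = NA_real_, p = NA_real_,
                       stringsAsFactors = FALSE)
        else {
            wr <- unname(.waldRow(fit, lab[i]))
            data.frame(haplotype = lab[i], freq = fAll[i],
                       freqCases = unname(fCase[i]),
                       freqControls = unname(fCtrl[i]),
                       or = wr[1], lo = wr[2], hi = wr[3],
                       p = wr[4], stringsAsFactors = FALSE)
        }
    })
    tab <- do.call(rbind, rows)
    if (any(built$rare)) {
        wr <- unname(.waldRow(fit, "Rare"))
        tab <- rbind(tab, data.frame(
            haplotype = "Rare", freq = sum(fAll[built$rare]),
            freqCases = sum(fCase[built$rare]),
            freqControls = sum(fCtrl[built$rare]),
            or = wr[1], lo = wr[2], hi = wr[3], p = wr[4],
            stringsAsFactors = FALSE))
    }
    rownames(tab) <- NULL

    terms <- intersect(hapTerms, names(fit$coef))
    b <- fit$coef[terms]
    V <- fit$vcov[terms, terms, drop = FALSE]
    gl <- tryCatch({
        stat <- drop(t(b) %*% solve(V, b))
        c(stat = stat, df = length(b),
          p = stats::pchisq(stat, df = length(b), lower.tail = FALSE))
    }, error = function(e) c(stat = NA_real_, df = length(b),
                             p = NA_real_))

    new("HapGlmFit", window = window, table = tab, reference = refLab,
        globalStat = unname(gl["stat"]), globalDf = as.integer(gl["df"]),
        globalP = unname(gl["p"]), fit = unclass(fit),
        covariates = covDesc)
}

# Optional refinement: re-weight phase posteriors by the fitted disease
# model and alternate with the GLM until coefficients stabilize.
.refineHapFit <- function(ht, built, y, Zk, fit, tol = 1e-6,
                          maxIter = 20L) {
    lab <- built$labels
    hapCols <- colnames(built$X)
    for (iter in seq_len(maxIter)) {
        old <- fit$coef
        H <- nrow(ht@hap)
        nPat <- length(ht@pairs)
        # per-subject dosage under disease-model-weighted posteriors
        D <- matrix(0, length(y), H)
        etaCov <- drop(cbind(1, Zk) %*%
                       fit$coef[c("(Intercept)",
                                  setdiff(names(fit$coef),
                                          c("(Intercept)", hapCols)))])
        bHap <- numeric(H)
        for (h in seq_len(H)) {
            nm <- if (built$rare[h]) "Rare" else lab[h]
            if (nm %in% names(fit$coef) && h != built$refI)
                bHap[h] <- fit$coef[nm]
        }
        for (i in seq_along(y)) {
            pp <- ht@pairs[[ht@patternOf[i]]]
            dose <- bHap[pp$h1] + bHap[pp$h2]
            eta <- etaCov[i] + dose
            mu <- stats::plogis(eta)
            lik <- ifelse(y[i] == 1, mu, 1 - mu)
            w <- pp$post * lik
            w <- w / sum(w)
            for (t in seq_along(w)) {
                D[i, pp$h1[t]] <- D[i, pp$h1[t]] + w[t]
                D[i, pp$h2[t]] <- D[i, pp$h2[t]] + w[t]
            }
        }
        X <- D[, built$keep, drop = FALSE]
        colnames(X) <- lab[built$keep]
        if (any(built$rare))
            X <- cbind(X, Rare = rowSums(D[, built$rare, drop = FALSE]))
        fit <- fitLogistic(y, cbind(X, Zk))
        common <- intersect(names(old), names(fit$coef))
        if (max(abs(fit$coef[common] - old[common])) < tol) break
    }
    fit
}
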