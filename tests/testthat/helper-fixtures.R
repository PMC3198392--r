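# shared fixtures: small cohorts built in code, plus independent oracles

# cohort from a SNPs x subjects genotype matrix; covariates filled with
# reproducible draws unless supplied
toyCohort <- function(G, gene = "G1", status = NULL, seed = 99,
                      subjects = NULL) {
    G <- as.matrix(G)
    m <- nrow(G); n <- ncol(G)
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
        assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(seed)
    pairs <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
    gene <- rep(gene, length.out = m)
    posIdx <- as.integer(stats::ave(seq_len(m), gene, FUN = seq_along) - 1)
    si <- data.frame(
        rsid = paste0("rs", seq_len(m)), gene = gene,
        positionIndex = posIdx,
        majorAllele = vapply(seq_len(m), function(j)
            pairs[[(j - 1) %% 4 + 1]][1], ""),
        minorAllele = vapply(seq_len(m), function(j)
            pairs[[(j - 1) %% 4 + 1]][2], ""),
        stringsAsFactors = FALSE)
    if (is.null(status)) status <- rep_len(c(1L, 0L), n)
    if (is.null(subjects))
        subjects <- data.frame(
            id = sprintf("s%04d", seq_len(n)), status = status,
            age = runif(n, 30, 75),
            sex = sample(c("male", "female"), n, TRUE),
            center = sample(c("C1", "C2", "C3"), n, TRUE),
            stringsAsFactors = FALSE)
    if (!is.null(subjects$age))
        subjects$ageClass <- ageClassOf(subjects$age)
    SnpCohort(G, si, subjects)
}

# independent brute-force HWE chi-square: expected multinomial counts
# computed directly from the allele frequency
bruteHwe <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    p <- (2 * nAA + nAa) / (2 * n)
    if (p == 0 || p == 1) return(c(chi2 = 0, p = 1))
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    x <- sum((c(nAA, nAa, naa) - e)^2 / e)
    c(chi2 = x, p = pchisq(x, 1, lower.tail = FALSE))
}

# brute-force maximum of the 2-SNP haplotype likelihood over the
# 3-simplex: coarse grid then Nelder-Mead polish on softmax coordinates.
# G: subjects x 2 genotype matrix (0/1/2, complete).
# Returns the maximized log-likelihood.
bruteForce2SnpLogLik <- function(G) {
    haps <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
    classes <- paste(G[, 1], G[, 2])
    cnt <- table(classes)
    gKeys <- names(cnt)
    loglik <- function(f) {
        ll <- 0
        for (k in seq_along(gKeys)) {
            g <- as.integer(strsplit(gKeys[k], " ")[[1]])
            P <- 0
            for (a in 1:4) for (b in 1:4)
                if (all(haps[a, ] + haps[b, ] == g))
                    P <- P + f[a] * f[b]
            if (P <= 0) return(-Inf)
            ll <- ll + cnt[[k]] * log(P)
        }
        ll
    }
    best <- -Inf
    step <- 0.05
    grid <- seq(0, 1, by = step)
    startsTried <- list()
    for (f1 in grid) for (f2 in grid) for (f3 in grid) {
        f4 <- 1 - f1 - f2 - f3
        if (f4 < -1e-9) next
        f <- pmax(c(f1, f2, f3, max(f4, 0)), 0)
        if (sum(f) == 0) next
        f <- f / sum(f)
        ll <- loglik(f)
        if (ll > best) { best <- ll; bestF <- f }
    }
    # polish: softmax parameterization, Nelder-Mead
    obj <- function(theta) {
        f <- exp(c(theta, 0)); f <- f / sum(f)
        -loglik(f)
    }
    th0 <- log(pmax(bestF[1:3], 1e-6) / max(bestF[4], 1e-6))
    op <- optim(th0, obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
    max(best, -op$value)
}

# tiny simulation config: one gene with explicit pool
onePoolConfig <- function(pool, nCases = 250L, nControls = 250L,
                          hapEffects = list(), interaction = NULL,
                          missingness = 0, prevalence = 0.1) {
    cfg <- defaultStudyConfig(genes = "SLC19A1", nCases = nCases,
                              nControls = nControls,
                              missingness = missingness)
    cfg$pools <- stats::setNames(list(pool), pool$gene)
    cfg$model$hapEffects <- hapEffects
    cfg$model$interaction <- interaction
    cfg$model$prevalence <- prevalence
    cfg$model$ageBeta <- 0; cfg$model$sexMaleBeta <- 0
    cfg$model$vegetableBeta <- 0
    cfg
}

# 2-SNP pool in complete LD unless swap frequencies provided
twoSnpPool <- function(freq = c(0.5, 0.5),
                       haps = c("A-C", "G-T"), gene = "GX") {
    haplotypePool(gene, c("rsA", "rsB"), haps, freq,
                  major = c("A", "C"), minor = c("G", "T"))
}
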