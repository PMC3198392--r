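# run code with a private, seeded RNG stream, restoring the caller's state
.withSeed <- function(seed, code) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    force(code)
}

#' Haplotype pool for one gene region
#'
#' A population of haplotypes over a gene's SNPs with their frequencies;
#' the generator induces all linkage disequilibrium through this pool
#' (diplotypes are drawn by random mating, no recombination model).
#'
#' @param gene gene-region name
#' @param rsids ordered SNP identifiers (5' to 3')
#' @param hap 0/1 integer matrix, haplotypes x SNPs (1 = minor allele),
#'   or a character vector of allele strings like \code{"A-C-C-C"}
#' @param freq positive frequencies summing to 1 (tolerance 1e-9)
#' @param major,minor per-SNP allele characters (required when \code{hap}
#'   is a 0/1 matrix; inferred when allele strings are given only if
#'   supplied)
#' @return object of class \code{"haplotypePool"}
#' @export
haplotypePool <- function(gene, rsids, hap, freq, major, minor) {
    if (is.character(hap)) {
        rows <- strsplit(hap, "-", fixed = TRUE)
        if (any(lengths(rows) != length(rsids)))
            stop("haplotype strings must have one allele per SNP")
        S <- do.call(rbind, rows)
        hap <- t(apply(S, 1, function(r) as.integer(r == minor)))
        bad <- vapply(seq_along(rsids), function(j)
            any(!S[, j] %in% c(major[j], minor[j])), logical(1))
        if (any(bad)) stop("allele string disagrees with major/minor at ",
                           rsids[which(bad)[1]])
    }
    hap <- matrix(as.integer(hap), nrow = length(freq))
    if (length(freq) != nrow(hap)) stop("freq length != haplotype count")
    if (any(freq <= 0)) stop("haplotype frequencies must be positive")
    if (abs(sum(freq) - 1) > 1e-9) stop("frequencies must sum to 1")
    if (any(major == minor)) stop("major and minor allele must differ")
    structure(list(gene = gene, rsids = rsids, hap = hap,
                   freq = freq / sum(freq), major = major, minor = minor),
              class = "haplotypePool")
}

#' @export
print.haplotypePool <- function(x, ...) {
    cat("haplotypePool for", x$gene, "(", length(x$rsids), "SNPs,",
        nrow(x$hap), "haplotypes )\n")
    lab <- apply(x$hap, 1, function(r)
        paste(ifelse(r == 1, x$minor, x$major), collapse = "-"))
    for (i in order(x$freq, decreasing = TRUE))
        cat(sprintf("  %-20s %.4f\n", lab[i], x$freq[i]))
    invisible(x)
}

# minor-allele frequency implied by a pool, per SNP
.poolMaf <- function(pool) drop(crossprod(pool$hap, pool$freq))

# label strings for a pool's haplotypes
.poolLabels <- function(pool)
    apply(pool$hap, 1, function(r)
        paste(ifelse(r == 1, pool$minor, pool$major), collapse = "-"))

#' Draw diplotypes from a haplotype pool
#'
#' Ordered haplotype pairs drawn independently with replacement
#' proportional to pool frequency (Hardy-Weinberg random mating).
#'
#' @param pool a \code{\link{haplotypePool}}
#' @param n number of subjects
#' @param seed optional integer; when given, sampling uses a private
#'   seeded stream
#' @return integer matrix n x 2 of haplotype row indices into
#'   \code{pool$hap}
#' @export
sampleDiplotypes <- function(pool, n, seed = NULL) {
    if (!inherits(pool, "haplotypePool")) stop("not a haplotypePool")
    if (n <= 0) stop("n must be positive")
    if (!nrow(pool$hap)) stop("empty haplotype pool")
    draw <- function() matrix(sample.int(nrow(pool$hap), 2 * n,
                                         replace = TRUE,
                                         prob = pool$freq), ncol = 2)
    if (is.null(seed)) draw() else .withSeed(seed, draw())
}

# deterministic synthetic pool for a gene without published structure:
# founder haplotypes with Dirichlet-like weights, alleles flipped until
# every SNP's pool-implied MAF is at least minMaf
.makePool <- function(gene, rsids, m, minMaf = 0.06) {
    K <- max(4L, min(12L, m + 2L))
    hap <- matrix(rbinom(K * m, 1L, 0.35), K, m)
    freq <- rgamma(K, shape = 1.2)
    freq <- freq / sum(freq)
    pairs <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
    major <- minor <- character(m)
    for (j in seq_len(m)) {
        pr <- pairs[[(j - 1L) %% 4L + 1L]]
        major[j] <- pr[1]; minor[j] <- pr[2]
    }
    for (rep in 1:200) {
        maf <- drop(crossprod(hap, freq))
        bad <- which(maf < minMaf | maf > 1 - minMaf)
        if (!length(bad)) break
        j <- bad[1]
        want <- if (maf[j] < minMaf) 0L else 1L  # flip a hap with this state
        cand <- which(hap[, j] == want)
        k <- cand[which.max(freq[cand])]
        hap[k, j] <- 1L - want
    }
    # merge duplicated haplotypes created by flipping
    key <- apply(hap, 1, paste, collapse = "")
    if (anyDuplicated(key)) {
        agg <- rowsum(freq, key)
        uhap <- hap[match(rownames(agg), key), , drop = FALSE]
        hap <- uhap; freq <- drop(agg)
    }
    # orient coding so the "minor" allele is the rarer one
    maf <- drop(crossprod(hap, freq))
    for (j in which(maf > 0.5)) {
        hap[, j] <- 1L - hap[, j]
        tmp <- major[j]; major[j] <- minor[j]; minor[j] <- tmp
    }
    haplotypePool(gene, rsids, hap, freq / sum(freq), major, minor)
}

.studyCenters <- data.frame(
    center = c("Bucharest", "Lodz", "Moscow", "Prague", "Olomouc",
               "CeskeBudejovice", "Brno"),
    country = c("Romania", "Poland", "Russia", "CzechRepublic",
                "CzechRepublic", "CzechRepublic", "CzechRepublic"),
    prob = c(0.091, 0.183, 0.302, 0.150, 0.110, 0.084, 0.080),
    stringsAsFactors = FALSE)

# SLC19A1: published 4-SNP block haplotype frequencies (controls) with
# two synthetic flanking tag SNPs keeping every SNP above 5% MAF
.slc19a1Pool <- function() {
    rsids <- c("rs1051296", "rs12483553", "rs2838950", "rs2838951",
               "rs17004785", "rs3788200")
    # at rs2838951 the C allele runs just above 50% overall, so the
    # rarer (counted) allele is G even though haplotype strings carry C
    major <- c("T", "G", "C", "C", "G", "G")
    minor <- c("G", "A", "T", "G", "C", "A")
    haps <- c("T-G-C-G-G-G", "G-G-C-G-G-A",  # reference block split on flanks
              "T-A-C-C-C-G",                  # risk haplotype
              "T-G-C-C-G-G", "G-G-C-C-G-G",
              "T-G-T-C-G-G", "G-G-T-C-G-A",
              "T-A-C-G-G-G", "T-G-T-G-G-G")
    freq <- c(0.288, 0.150, 0.064, 0.140, 0.070, 0.175, 0.067,
              0.026, 0.020)
    haplotypePool("SLC19A1", rsids, haps, freq, major, minor)
}

# MTHFR: published 5-SNP block frequencies (controls) plus three
# synthetic tags
.mthfrPool <- function() {
    rsids <- c("rs4846052", "rs12121543", "rs1801133", "rs17421511",
               "rs11121832", "rs9651118", "rs1476413", "rs1801131")
    major <- c("C", "G", "C", "C", "G", "A", "C", "A")
    minor <- c("T", "T", "T", "T", "A", "G", "T", "C")
    haps <- c("C-G-T-C-G-A-T-A", "T-G-T-C-G-A-C-A",
              "C-T-C-T-A-A-C-C", "T-T-C-T-A-A-C-A",
              "C-T-C-C-G-A-C-C",
              "C-G-C-C-G-G-C-A", "T-G-C-C-G-G-C-C",
              "C-G-C-C-G-A-C-A",
              "C-G-C-C-A-A-C-C", "T-G-C-C-A-A-C-A",
              "C-T-C-C-A-G-T-C")
    freq <- c(0.182, 0.120, 0.106, 0.070, 0.101, 0.160, 0.084, 0.070,
              0.056, 0.038, 0.013)
    haplotypePool("MTHFR", rsids, haps, freq, major, minor)
}

.geneSizes <- c(ALDH1L1 = 25L, BHMT = 13L, CBS = 18L, CTH = 8L,
                FOLR1 = 4L, GGH = 6L, GSS = 10L, MTHFR = 8L, MTR = 9L,
                MTRR = 23L, SHMT1 = 8L, SLC19A1 = 6L, TYMS = 25L)

.geneBands <- c(ALDH1L1 = "3q21.3", BHMT = "5q14.1", CBS = "21q22.3",
                CTH = "1p31.1", FOLR1 = "11q13.4", GGH = "8q12.3",
                GSS = "20q11.22", MTHFR = "1p36.3", MTR = "1q43",
                MTRR = "5p15.31", SHMT1 = "17p11.2", SLC19A1 = "21q22.3",
                TYMS = "18p11.32")

#' Default synthetic study configuration
#'
#' A ready-to-run \code{SimulationConfig} emulating a multi-center
#' case-control study: 777 cases and 1,035 controls recruited across 7
#' centers in 4 countries, 13 candidate gene regions totalling 163 tag
#' SNPs (all pool-implied minor-allele frequencies at least 5%), 2%
#' completely-at-random genotype missingness, and a disease model
#' carrying one 4-SNP risk haplotype in SLC19A1 (A-C-C-C at 6.4% control
#' frequency, per-copy odds ratio 1.37) whose effect is amplified to an
#' odds ratio of about 1.9 among subjects in the lowest vegetable-intake
#' tertile. Haplotype pools for the two genes with published block
#' structure embed those haplotype frequencies; pools for the other
#' genes are generated deterministically (fixed internal stream) and are
#' synthetic.
#'
#' @param genes optional character vector restricting the config to a
#'   subset of gene regions (e.g. only the risk gene, for focused
#'   simulation experiments)
#' @param nCases,nControls target sample sizes
#' @param missingness per-call missing probability
#' @return object of class \code{"simConfig"}
#' @export
defaultStudyConfig <- function(genes = NULL, nCases = 777L,
                               nControls = 1035L, missingness = 0.02) {
    pools <- .withSeed(20111019, {
        out <- list()
        counter <- 0L
        for (g in names(.geneSizes)) {
            if (g == "SLC19A1") out[[g]] <- .slc19a1Pool()
            else if (g == "MTHFR") out[[g]] <- .mthfrPool()
            else {
                m <- .geneSizes[[g]]
                rs <- paste0("rs9", sprintf("%05d", counter + seq_len(m)))
                counter <- counter + m
                out[[g]] <- .makePool(g, rs, m)
            }
        }
        out
    })
    if (!is.null(genes)) {
        unknown <- setdiff(genes, names(pools))
        if (length(unknown)) stop("unknown gene(s): ",
                                  paste(unknown, collapse = ", "))
        pools <- pools[genes]
    }
    cfg <- list(
        nCases = as.integer(nCases), nControls = as.integer(nControls),
        centers = .studyCenters,
        age = list(mean = 59, sd = 10.2, min = 20, max = 79),
        sexMaleProb = 0.626,
        bmiProb = c("<25" = 0.363, "25-30" = 0.419, ">30" = 0.218),
        smokingProb = c(never = 0.407, former = 0.238, current = 0.355),
        hypertensionProb = 0.383,
        familyHistoryProb = 0.280,
        vegetable = list(shape = 4, scale = 2, max = 24, lowCut = 6),
        alcohol = list(zeroProb = 0.24, shape = 2, scale = 2, max = 20),
        missingness = missingness,
        pools = pools,
        model = list(
            prevalence = 0.06,
            hapEffects = if ("SLC19A1" %in% names(pools))
                list(SLC19A1 = c("T-A-C-C-C-G" = log(1.37))) else list(),
            ageBeta = 0.005, sexMaleBeta = 0.10, vegetableBeta = -0.02,
            interaction = if ("SLC19A1" %in% names(pools))
                list(gene = "SLC19A1", haplotype = "T-A-C-C-C-G",
                     stratum = "low",
                     extraLogOr = log(1.9) - log(1.37)) else NULL),
        seed = 1L)
    class(cfg) <- "simConfig"
    cfg
}

#' @export
print.simConfig <- function(x, ...) {
    cat("simConfig:", x$nCases, "cases /", x$nControls, "controls,",
        length(x$pools), "gene regions,",
        sum(vapply(x$pools, function(p) length(p$rsids), integer(1))),
        "SNPs\n")
    invisible(x)
}

# subject-level covariate draw (n rows); vegetable low stratum is defined
# generatively by the fixed score cut in cfg$vegetable$lowCut
.drawCovariates <- function(cfg, n) {
    ci <- sample.int(nrow(cfg$centers), n, replace = TRUE,
                     prob = cfg$centers$prob)
    age <- pmin(pmax(rnorm(n, cfg$age$mean, cfg$age$sd), cfg$age$min),
                cfg$age$max)
    veg <- pmin(round(rgamma(n, shape = cfg$vegetable$shape,
                             scale = cfg$vegetable$scale)),
                cfg$vegetable$max)
    alcRaw <- pmin(round(rgamma(n, shape = cfg$alcohol$shape,
                                scale = cfg$alcohol$scale)) + 1,
                   cfg$alcohol$max)
    alc <- ifelse(runif(n) < cfg$alcohol$zeroProb, 0, alcRaw)
    data.frame(
        center = cfg$centers$center[ci],
        country = cfg$centers$country[ci],
        age = age,
        sex = ifelse(runif(n) < cfg$sexMaleProb, "male", "female"),
        bmiClass = sample(names(cfg$bmiProb), n, TRUE, cfg$bmiProb),
        smoking = sample(names(cfg$smokingProb), n, TRUE,
                         cfg$smokingProb),
        hypertension = as.integer(runif(n) < cfg$hypertensionProb),
        familyHistory = as.integer(runif(n) < cfg$familyHistoryProb),
        vegetableFreq = veg, alcoholFreq = alc,
        stringsAsFactors = FALSE)
}

# linear predictor (without intercept) for a batch
.riskScore <- function(cfg, cov, dips) {
    eta <- cfg$model$ageBeta * (cov$age - cfg$age$mean) +
        cfg$model$sexMaleBeta * (cov$sex == "male") +
        cfg$model$vegetableBeta * cov$vegetableFreq
    for (g in names(cfg$model$hapEffects)) {
        ef <- cfg$model$hapEffects[[g]]
        lab <- .poolLabels(cfg$pools[[g]])
        perHap <- stats::setNames(numeric(length(lab)), lab)
        perHap[names(ef)] <- ef
        copies <- perHap[lab[dips[[g]][, 1]]] + perHap[lab[dips[[g]][, 2]]]
        eta <- eta + unname(copies)
    }
    ia <- cfg$model$interaction
    if (!is.null(ia)) {
        lab <- .poolLabels(cfg$pools[[ia$gene]])
        cp <- (lab[dips[[ia$gene]][, 1]] == ia$haplotype) +
            (lab[dips[[ia$gene]][, 2]] == ia$haplotype)
        inLow <- cov$vegetableFreq <= cfg$vegetable$lowCut
        eta <- eta + ia$extraLogOr * cp * inLow
    }
    eta
}

#' Simulate a case-control cohort
#'
#' Draws subjects (covariates and per-gene diplotypes), assigns disease
#' by a Bernoulli draw from the logistic model (the intercept is
#' calibrated numerically so that the population prevalence matches the
#' configured value), collects cases up to \code{nCases}, and selects
#' controls from the non-case pool frequency-matched to the realized
#' case distribution over age-class x sex x center cells. Genotypes are
#' the per-SNP sums of the two haplotype alleles, coded as minor-allele
#' counts, with completely-at-random missingness applied at the
#' configured rate.
#'
#' @param cfg a \code{\link{defaultStudyConfig}}-style configuration
#' @param seed integer seed fixing the whole stream (defaults to
#'   \code{cfg$seed})
#' @return list: \code{cohort} (a \code{\linkS4class{SnpCohort}}),
#'   \code{truth} (list with seed, model coefficients, per-subject risk
#'   haplotype copy numbers and per-gene diplotype indices)
#' @export
simulateCohort <- function(cfg, seed = cfg$seed) {
    stopifnot(inherits(cfg, "simConfig"))
    .withSeed(seed, .simulateCohortInner(cfg, seed))
}

.simulateCohortInner <- function(cfg, seed) {
    batch <- max(4000L, 4L * (cfg$nCases + cfg$nControls))
    alpha <- NULL
    cases <- list(); pool <- list()
    nCase <- 0L; nPool <- 0L
    maxPool <- 8L * cfg$nControls
    for (attempt in 1:60) {
        cov <- .drawCovariates(cfg, batch)
        dips <- lapply(cfg$pools, function(p)
            matrix(sample.int(nrow(p$hap), 2L * batch, replace = TRUE,
                              prob = p$freq), ncol = 2))
        eta <- .riskScore(cfg, cov, dips)
        if (is.null(alpha)) {
            f <- function(a) mean(stats::plogis(a + eta)) -
                cfg$model$prevalence
            if (!is.finite(f(-30)) || f(-30) * f(10) > 0)
                stop("cannot calibrate intercept: case count unreachable")
            alpha <- stats::uniroot(f, c(-30, 10))$root
        }
        y <- rbinom(batch, 1L, stats::plogis(alpha + eta))
        rec <- list(cov = cov, dips = dips, eta = eta)
        ci <- which(y == 1L); pi <- which(y == 0L)
        take <- function(rec, idx) list(
            cov = rec$cov[idx, , drop = FALSE],
            dips = lapply(rec$dips, function(d) d[idx, , drop = FALSE]))
        if (length(ci)) { cases[[length(cases) + 1L]] <- take(rec, ci)
                          nCase <- nCase + length(ci) }
        if (nPool < maxPool && length(pi)) {
            pool[[length(pool) + 1L]] <- take(rec, pi)
            nPool <- nPool + length(pi)
        }
        if (nCase >= cfg$nCases && nPool >= 3L * cfg$nControls) break
    }
    if (nCase < cfg$nCases)
        stop("simulation could not reach ", cfg$nCases, " cases in ",
             attempt, " batches (", nCase, " found)")

    bindRec <- function(lst) list(
        cov = do.call(rbind, lapply(lst, `[[`, "cov")),
        dips = stats::setNames(lapply(names(cfg$pools), function(g)
            do.call(rbind, lapply(lst, function(e) e$dips[[g]]))),
            names(cfg$pools)))
    caseRec <- bindRec(cases)
    poolRec <- bindRec(pool)
    caseRec$cov <- caseRec$cov[seq_len(cfg$nCases), , drop = FALSE]
    caseRec$dips <- lapply(caseRec$dips, function(d)
        d[seq_len(cfg$nCases), , drop = FALSE])

    # frequency-matched control selection over ageClass x sex x center
    cellOf <- function(cov) paste(ageClassOf(cov$age), cov$sex,
                                  cov$center, sep = "|")
    caseCells <- cellOf(caseRec$cov)
    poolCells <- cellOf(poolRec$cov)
    want <- table(caseCells) / length(caseCells) * cfg$nControls
    target <- floor(want)
    rem <- want - target
    short <- cfg$nControls - sum(target)
    if (short > 0) {
        up <- names(sort(rem, decreasing = TRUE))[seq_len(short)]
        target[up] <- target[up] + 1
    }
    chosen <- integer(0)
    for (cell in names(target)) {
        avail <- which(poolCells == cell)
        k <- min(length(avail), target[[cell]])
        if (k > 0) chosen <- c(chosen, sample(avail, k))
    }
    deficit <- cfg$nControls - length(chosen)
    if (deficit > 0) {
        left <- setdiff(seq_along(poolCells), chosen)
        chosen <- c(chosen, sample(left, deficit))
    }
    ctrlRec <- list(cov = poolRec$cov[chosen, , drop = FALSE],
                    dips = lapply(poolRec$dips, function(d)
                        d[chosen, , drop = FALSE]))

    n <- cfg$nCases + cfg$nControls
    cov <- rbind(caseRec$cov, ctrlRec$cov)
    dips <- stats::setNames(lapply(names(cfg$pools), function(g)
        rbind(caseRec$dips[[g]], ctrlRec$dips[[g]])), names(cfg$pools))
    status <- c(rep(1L, cfg$nCases), rep(0L, cfg$nControls))

    # genotypes: SNPs x subjects
    gBlocks <- lapply(names(cfg$pools), function(g) {
        p <- cfg$pools[[g]]
        t(p$hap[dips[[g]][, 1], , drop = FALSE] +
          p$hap[dips[[g]][, 2], , drop = FALSE])
    })
    G <- do.call(rbind, gBlocks)
    if (cfg$missingness > 0) {
        drop <- matrix(runif(length(G)) < cfg$missingness, nrow(G))
        G[drop] <- NA_integer_
    }

    si <- do.call(rbind, lapply(names(cfg$pools), function(g) {
        p <- cfg$pools[[g]]
        data.frame(rsid = p$rsids, gene = g,
                   chromBand = if (g %in% names(.geneBands))
                       .geneBands[[g]] else NA_character_,
                   positionIndex = seq_along(p$rsids) - 1L,
                   majorAllele = p$major, minorAllele = p$minor,
                   stringsAsFactors = FALSE)
    }))
    su <- data.frame(id = sprintf("subj%05d", seq_len(n)),
                     status = status, cov, stringsAsFactors = FALSE)
    su$ageClass <- ageClassOf(su$age)
    cohort <- SnpCohort(G, si, su)

    riskCopies <- rep(0L, n)
    if (length(cfg$model$hapEffects)) {
        g <- names(cfg$model$hapEffects)[1]
        hlab <- names(cfg$model$hapEffects[[g]])[1]
        lab <- .poolLabels(cfg$pools[[g]])
        riskCopies <- (lab[dips[[g]][, 1]] == hlab) +
            (lab[dips[[g]][, 2]] == hlab)
    }
    truth <- list(seed = seed, intercept = alpha, model = cfg$model,
                  riskCopies = stats::setNames(riskCopies, su$id),
                  diplotypes = dips)
    list(cohort = cohort, truth = truth)
}

#' Write the simulation truth record as a delimited file
#'
#' Subject-level truth (status and planted risk-haplotype copy number)
#' as tab-separated text, with the model coefficients in '#'-prefixed
#' header lines.
#'
#' @param truth the \code{truth} element of \code{\link{simulateCohort}}
#' @param cohort the matching cohort
#' @param path output path
#' @export
writeTruthRecord <- function(truth, cohort, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# seed\t", truth$seed),
                 paste0("# intercept\t", format(truth$intercept))), con)
    for (g in names(truth$model$hapEffects)) {
        ef <- truth$model$hapEffects[[g]]
        writeLines(paste0("# hapEffect\t", g, "\t", names(ef), "\t",
                          format(ef)), con)
    }
    df <- data.frame(id = names(truth$riskCopies),
                     status = caseStatus(cohort)[names(truth$riskCopies)],
                     riskCopies = unname(truth$riskCopies))
    utils::write.table(df, con, quote = FALSE, sep = "\t",
                       row.names = FALSE)
    invisible(path)
}
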