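test_that("window counts follow the sliding rule and conservation", {
    set.seed(81)
    G <- matrix(rbinom(11 * 300, 2, .3), nrow = 11)
    x <- toyCohort(G, gene = rep(c("A", "B", "C"), c(6, 3, 2)))
    expect_message(hw <- haplowalk(x, covariates = character(0)),
                   "skipping gene C")
    expect_equal(sum(hw$gene == "A"), 4)  # 6 SNPs -> 4 windows
    expect_equal(sum(hw$gene == "B"), 1)
    # conservation: sum over genes of max(m - 2, 0)
    expect_equal(nrow(hw), 4 + 1 + 0)
    expect_true(all(hw$fdrP >= hw$globalP - 1e-12))
})

test_that("haplowalk flags windows overlapping a planted risk block", {
    cfg <- defaultStudyConfig(genes = "SLC19A1")
    cfg$model$interaction <- NULL
    sim <- simulateCohort(cfg, seed = 82)
    hw <- haplowalk(sim$cohort, covariates = c("ageClass", "sex",
                                               "center"))
    # block spans SNPs 2-5; windows starting 1..4 overlap SNPs 2-5
    overlapping <- hw$flag[hw$start %in% 1:4]
    expect_true(any(overlapping))
})

test_that("min-P test: single-SNP gene agrees with the asymptotic trend p", {
    set.seed(83)
    n <- 2000
    g <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, plogis(-0.3 + 0.25 * g))
    x <- toyCohort(matrix(g, 1), status = y)
    res <- snpModels(x, "rs1", covariates = character(0))
    asym <- res$p[res$term == "trend"]
    mp <- minPTest(x, "G1", covariates = character(0), B = 999,
                   seed = 84, strata = NULL)
    mcSe <- 2 * sqrt(asym * (1 - asym) / 999)
    expect_lt(abs(mp$empiricalP - asym), mcSe + 0.02)
})

test_that("min-P empirical p is seed-reproducible, SNP-order invariant,
           and bounded below by 1/(B+1)", {
    set.seed(85)
    G <- rbind(rbinom(300, 2, .3), rbinom(300, 2, .4))
    x <- toyCohort(G)
    a <- minPTest(x, "G1", covariates = character(0), B = 199,
                  seed = 86, strata = NULL)
    b <- minPTest(x, "G1", covariates = character(0), B = 199,
                  seed = 86, strata = NULL)
    expect_identical(a$empiricalP, b$empiricalP)
    xr <- toyCohort(G[2:1, ], status = unname(caseStatus(x)))
    c2 <- minPTest(xr, "G1", covariates = character(0), B = 199,
                   seed = 86, strata = NULL)
    expect_identical(a$empiricalP, c2$empiricalP)
    expect_gte(a$empiricalP, 1 / 200)
    expect_equal(a$empiricalP, (a$count + 1) / (a$B + 1))
})

test_that("stratified label permutation preserves each stratum's case count", {
    # strong genotype-status association only through center imbalance:
    # within-center permutation must keep per-center case totals fixed
    set.seed(87)
    n <- 400
    center <- rep(c("C1", "C2"), each = n / 2)
    y <- c(rbinom(n / 2, 1, 0.8), rbinom(n / 2, 1, 0.2))
    su <- data.frame(id = sprintf("s%03d", 1:n), status = y,
                     center = center)
    x <- toyCohort(matrix(rbinom(n, 2, .3), 1), status = y,
                   subjects = su)
    # direct check on the permutation machinery via a 1-permutation run
    mp <- minPTest(x, "G1", covariates = character(0), B = 99,
                   seed = 88, strata = "center")
    expect_s3_class(mp, "minPResult")
    # independent verification of the invariant itself
    idx <- split(seq_len(n), center)
    set.seed(88)
    yp <- y
    for (i in idx) yp[i] <- y[sample(i)]
    expect_equal(tapply(yp, center, sum), tapply(y, center, sum))
})

test_that("Sidak closed form approximates min-P on independent null SNPs", {
    set.seed(89)
    n <- 1500; k <- 3
    G <- matrix(rbinom(k * n, 2, .3), nrow = k)
    y <- rbinom(n, 1, 0.5)
    x <- toyCohort(G, status = y)
    mp <- minPTest(x, "G1", covariates = character(0), B = 1999,
                   seed = 90, strata = NULL)
    sidak <- 1 - (1 - mp$observedMinP)^k
    expect_lt(abs(mp$empiricalP - sidak),
              3 * sqrt(sidak * (1 - sidak) / 1999) + 0.02)
})

test_that("min-P FDR across genes follows BH closed forms", {
    mk <- function(g, p) structure(list(gene = g, snps = "rs",
                                        observedMinP = p, B = 999L,
                                        count = as.integer(p * 1000 - 1),
                                        empiricalP = p, seed = 1L),
                                   class = "minPResult")
    all1 <- lapply(1:13, function(i) mk(paste0("g", i), 1))
    expect_true(all(minPFdr(all1)$fdrMinP == 1))
    mixed <- c(list(mk("hit", 0.002)),
               lapply(1:12, function(i) mk(paste0("g", i), 0.5)))
    tab <- minPFdr(mixed)
    expect_equal(tab$fdrMinP[tab$gene == "hit"], 0.026)
    expect_true(all(tab$fdrMinP >= tab$empiricalP))
})

test_that("block analysis has one reference row and survives a
           monomorphic SNP", {
    cfg <- defaultStudyConfig(genes = "SLC19A1", nCases = 250,
                              nControls = 250)
    cfg$model$interaction <- NULL
    sim <- simulateCohort(cfg, seed = 91)
    block <- c("rs12483553", "rs2838950", "rs2838951", "rs17004785")
    hg <- blockAnalysis(sim$cohort, block)
    tb <- hg@table
    expect_equal(sum(tb$or == 1 & is.na(tb$p)), 1)
    expect_equal(tb$haplotype[1], hg@reference)

    # block containing a monomorphic SNP still yields a simplex
    G <- rbind(rep(0L, 200), rbinom(200, 2, .3), rbinom(200, 2, .4))
    x <- toyCohort(G)
    hg2 <- haplotypeGlm(x, c("rs1", "rs2", "rs3"),
                        covariates = character(0))
    expect_equal(sum(hg2@table$freq), 1, tolerance = 1e-8)
})

test_that("identical strata give identical stratified ORs", {
    set.seed(92)
    G <- rbind(rbinom(600, 2, .35), rbinom(600, 2, .3))
    y <- rbinom(600, 1, .5)
    su <- data.frame(id = sprintf("s%03d", 1:600), status = y,
                     stratum = rep(c("a", "b"), 300))
    # duplicate the data across two strata labels
    su2 <- su; su2$id <- paste0(su$id, "x"); su2$stratum <-
        ifelse(su$stratum == "a", "b", "a")
    G2 <- cbind(G, G)
    sub <- rbind(su, su2)
    x <- toyCohort(G2, status = c(y, y), subjects = sub)
    sres <- stratifiedBlocks(x, c("rs1", "rs2"), stratifyBy = "stratum",
                             covariates = character(0))
    ta <- sres$strata$a@table; tb <- sres$strata$b@table
    expect_equal(ta$or, tb$or, tolerance = 1e-6)
    # interaction LRT must be ~0 on identical strata
    expect_true(all(sres$interaction$lrt < 1e-4))
    # stratum subject counts partition the analyzable sample
    expect_equal(sum(sres$n), 1200)
})

test_that("small strata are reported as NA rather than fit", {
    set.seed(93)
    n <- 300
    G <- rbind(rbinom(n, 2, .35), rbinom(n, 2, .3))
    su <- data.frame(id = sprintf("s%03d", 1:n),
                     status = rep_len(0:1, n),
                     stratum = c(rep("tiny", 10),
                                 rep("big", n - 10)))
    x <- toyCohort(G, subjects = su)
    sres <- stratifiedBlocks(x, c("rs1", "rs2"), stratifyBy = "stratum",
                             covariates = character(0))
    expect_null(sres$strata$tiny)
    expect_false(is.null(sres$strata$big))
})

test_that("country heterogeneity LRT is null-calibrated and requires
           two countries", {
    set.seed(94)
    ps <- replicate(150, {
        n <- 400
        g <- rbinom(n, 2, .3)
        country <- sample(c("P", "Q", "R"), n, TRUE)
        y <- rbinom(n, 1, plogis(-0.2 + 0.2 * g))
        su <- data.frame(id = sprintf("s%03d", 1:n), status = y,
                         country = country)
        x <- toyCohort(matrix(g, 1), status = y, subjects = su)
        countryHeterogeneityLrt(x, rsid = "rs1",
                                covariates = character(0))["p"]
    })
    expect_gt(ks.test(ps, "punif")$p.value, 0.01)

    su1 <- data.frame(id = sprintf("s%02d", 1:60),
                      status = rep_len(0:1, 60), country = "P")
    x1 <- toyCohort(matrix(rbinom(60, 2, .4), 1), subjects = su1)
    expect_error(countryHeterogeneityLrt(x1, rsid = "rs1",
                                         covariates = character(0)),
                 "two countries")
})

test_that("country-specific effects are detected at scale", {
    set.seed(95)
    hits <- replicate(10, {
        n <- 10000
        g <- rbinom(n, 2, .3)
        country <- sample(c("P", "Q"), n, TRUE)
        y <- rbinom(n, 1, plogis(-0.3 + 0.5 * g * (country == "Q")))
        su <- data.frame(id = sprintf("s%05d", 1:n), status = y,
                         country = country)
        x <- toyCohort(matrix(g, 1), status = y, subjects = su)
        countryHeterogeneityLrt(x, rsid = "rs1",
                                covariates = character(0))["p"] < 0.05
    })
    expect_gt(mean(hits), 0.5)
})
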