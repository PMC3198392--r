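test_that("trend model recovers a per-allele effect and the null", {
    set.seed(21)
    n <- 10000
    g <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, plogis(-0.5 + log(1.5) * g))
    x <- toyCohort(matrix(g, 1), status = y)
    res <- snpModels(x, "rs1", covariates = character(0))
    tr <- res[res$model == "trend", ]
    expect_gt(tr$or, 1.4); expect_lt(tr$or, 1.6)

    # null SNP: CI covers 1
    g0 <- rbinom(2000, 2, 0.3)
    y0 <- rbinom(2000, 1, 0.5)
    x0 <- toyCohort(matrix(g0, 1), status = y0)
    tr0 <- snpModels(x0, "rs1", covariates = character(0))
    tr0 <- tr0[tr0$model == "trend", ]
    expect_true(tr0$lo <= 1 && 1 <= tr0$hi)
})

test_that("codominant ORs of exactly (1, r, r^2) give trend OR r", {
    # genotype counts engineered so het OR = 2 and hom OR = 4 exactly
    r <- 2
    nCtrl <- c(400, 200, 100)
    nCase <- round(nCtrl * c(1, r, r^2))
    g <- rep(c(0, 1, 2, 0, 1, 2), c(nCase, nCtrl))
    y <- rep(c(1, 0), c(sum(nCase), sum(nCtrl)))
    x <- toyCohort(matrix(as.integer(g), 1), status = y)
    res <- snpModels(x, "rs1", covariates = character(0))
    expect_equal(res$or[res$term == "trend"], r, tolerance = 1e-6)
    expect_equal(res$or[res$term == "het"], r, tolerance = 1e-6)
    expect_equal(res$or[res$term == "hom"], r^2, tolerance = 1e-6)
})

test_that("monomorphic SNP raises an error naming it", {
    x <- toyCohort(matrix(0L, 1, 50))
    expect_error(snpModels(x, "rs1", covariates = character(0)),
                 "rs1.*monomorphic")
})

test_that("zero rare-homozygote count omits the hom term, trend still fits", {
    set.seed(22)
    g <- c(rep(0L, 150), rep(1L, 50))[sample(200)]
    x <- toyCohort(matrix(g, 1))
    res <- snpModels(x, "rs1", covariates = character(0))
    expect_false("hom" %in% res$term)
    expect_true("trend" %in% res$term)
})

test_that("joint model attenuates the non-causal SNP of an LD pair", {
    set.seed(23)
    n <- 6000
    # two SNPs on a common haplotype background (strong LD), SNP 1 causal
    h <- matrix(rbinom(2 * n, 1, 0.3), ncol = 1)
    h2 <- ifelse(runif(2 * n) < 0.9, h, rbinom(2 * n, 1, 0.3))
    g1 <- h[seq(1, 2 * n, 2)] + h[seq(2, 2 * n, 2)]
    g2 <- h2[seq(1, 2 * n, 2)] + h2[seq(2, 2 * n, 2)]
    y <- rbinom(n, 1, plogis(-0.6 + 0.5 * g1))
    x <- toyCohort(rbind(g1, g2), status = y)
    marg2 <- snpModels(x, "rs2", covariates = character(0))
    marg2 <- marg2$or[marg2$term == "trend"]
    joint <- jointSnpModel(x, c("rs1", "rs2"),
                           covariates = character(0))
    expect_lt(abs(log(joint$or[joint$rsid == "rs2"])),
              abs(log(marg2)))
    # duplicate SNP columns: one dropped with warning
    xdup <- toyCohort(rbind(g1, g1), status = y)
    expect_warning(jd <- jointSnpModel(xdup, c("rs1", "rs2"),
                                       covariates = character(0)),
                   "aliased")
    expect_equal(nrow(jd), 1)
})

test_that("BH step-up reproduces closed-form adjustments", {
    expect_equal(bhFdr(c(0.01, 0.01, 0.30, 0.35, 0.40, 0.45))[1:2],
                 c(0.03, 0.03))
    expect_equal(bhFdr(c(0.02, 0.30, 0.35, 0.40, 0.45, 0.50, 0.55,
                         0.60))[1], 0.16)
    expect_equal(bhFdr(0.37), 0.37)  # single p unchanged
})

test_that("BH output is monotone in sorted order, capped, >= raw", {
    set.seed(24)
    for (i in 1:30) {
        p <- runif(sample(2:40, 1))
        adj <- bhFdr(p)
        expect_true(all(adj >= p - 1e-12))
        expect_true(all(adj <= 1))
        o <- order(p)
        expect_true(all(diff(adj[o]) >= -1e-12))
        # matches the independent reference implementation
        expect_equal(adj, p.adjust(p, "BH"))
    }
    expect_error(bhFdr(c(0.5, 0)), "0, 1")
})

test_that("confounder sensitivity flags only real confounding", {
    set.seed(25)
    n <- 3000
    g <- rbinom(n, 2, 0.3)
    conf <- rbinom(n, 1, plogis(-1 + 1.2 * g))  # tied to genotype
    y <- rbinom(n, 1, plogis(-1 + 0.3 * g + 1.5 * conf))
    su <- data.frame(id = sprintf("s%04d", 1:n), status = y,
                     hypertension = conf,
                     noise = rbinom(n, 1, 0.4))
    x <- toyCohort(matrix(g, 1), status = y, subjects = su)
    strong <- confounderSensitivity(x, "rs1", "hypertension",
                                    covariates = character(0))
    expect_true(strong$flagged)
    weak <- confounderSensitivity(x, "rs1", "noise",
                                  covariates = character(0))
    expect_lt(weak$pctChange, 5)
})

test_that("interaction LRT is calibrated under the null and powered", {
    set.seed(26)
    # null: factor has no modifying effect
    ps <- replicate(200, {
        n <- 400
        g <- rbinom(n, 2, 0.3)
        f <- sample(c("a", "b", "c"), n, TRUE)
        y <- rbinom(n, 1, plogis(-0.2 + 0.2 * g))
        su <- data.frame(id = sprintf("s%03d", 1:n), status = y,
                         grp = f)
        x <- toyCohort(matrix(g, 1), status = y, subjects = su)
        snpFactorInteractionLrt(x, "rs1", "grp",
                                covariates = character(0))["p"]
    })
    expect_gt(ks.test(ps, "punif")$p.value, 0.01)

    # strong interaction is detected
    set.seed(27)
    hits <- replicate(30, {
        n <- 3000
        g <- rbinom(n, 2, 0.3)
        f <- sample(c("a", "b"), n, TRUE)
        y <- rbinom(n, 1, plogis(-0.3 + 0.7 * g * (f == "b")))
        su <- data.frame(id = sprintf("s%04d", 1:n), status = y,
                         grp = f)
        x <- toyCohort(matrix(g, 1), status = y, subjects = su)
        snpFactorInteractionLrt(x, "rs1", "grp",
                                covariates = character(0))["p"] < 0.05
    })
    expect_gt(mean(hits), 0.8)

    x1 <- toyCohort(matrix(rbinom(50, 2, .4), 1),
                    subjects = data.frame(id = sprintf("s%02d", 1:50),
                                          status = rep_len(0:1, 50),
                                          grp = "only"))
    expect_error(snpFactorInteractionLrt(x1, "rs1", "grp",
                                         covariates = character(0)),
                 "fewer than 2")
})

test_that("snpScan applies within-gene FDR families", {
    set.seed(28)
    G <- rbind(rbinom(300, 2, .3), rbinom(300, 2, .4),
               rbinom(300, 2, .2))
    x <- toyCohort(G, gene = c("A", "A", "B"))
    sc <- snpScan(x, covariates = character(0))
    a <- sc[sc$gene == "A", ]
    expect_equal(a$fdrTrend, bhFdr(a$pTrend))
    b <- sc[sc$gene == "B", ]
    expect_equal(b$fdrTrend, b$pTrend)  # family of one
    scAll <- snpScan(x, covariates = character(0), withinGene = FALSE)
    expect_equal(scAll$fdrTrend, bhFdr(scAll$pTrend))
})
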