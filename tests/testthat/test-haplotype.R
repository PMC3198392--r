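test_that("single-SNP window frequencies equal allele frequencies", {
    g <- c(rep(0L, 10), rep(1L, 8), rep(2L, 2))
    x <- toyCohort(matrix(g, 1))
    ht <- emHaplotypes(x, "rs1")
    n <- 20
    expect_equal(sort(ht@freq),
                 sort(c((2 * 10 + 8) / (2 * n), (8 + 2 * 2) / (2 * n))))
    expect_equal(ht@iterations <= 3, TRUE)  # no ambiguity to resolve
})

test_that("unambiguous two-SNP data gives direct haplotype counts", {
    # no double heterozygotes: phase is observed
    G <- rbind(c(0, 1, 2, 0, 1), c(0, 0, 2, 2, 2))
    x <- toyCohort(G)
    ht <- emHaplotypes(x, c("rs1", "rs2"))
    lab <- hapLabels(ht)
    # enumerate chromosomes by hand: subjects (0,0)(1,0)(2,2)(0,2)(1,2)
    # -> A-C:2+1+0+0+0 =3? count: s1: A-C,A-C; s2: G-C,A-C; s3: G-T,G-T;
    # s4: A-T,A-T; s5: G-T,A-T
    want <- c("A-C" = 3, "G-C" = 1, "G-T" = 3, "A-T" = 3) / 10
    expect_equal(ht@freq[match(names(want), lab)], unname(want),
                 tolerance = 1e-9)
})

test_that("EM matches the brute-force simplex maximizer on toy data", {
    set.seed(51)
    for (rep in 1:5) {
        n <- sample(10:30, 1)
        # draw genotypes with double heterozygotes present
        repeat {
            G <- cbind(rbinom(n, 2, runif(1, .25, .6)),
                       rbinom(n, 2, runif(1, .25, .6)))
            if (any(G[, 1] == 1 & G[, 2] == 1)) break
        }
        x <- toyCohort(t(G))
        ht <- emHaplotypes(x, c("rs1", "rs2"), tol = 1e-12)
        oracle <- bruteForce2SnpLogLik(G)
        expect_equal(ht@logLik, oracle, tolerance = 1e-6)
    }
})

test_that("EM respects invariants: monotone likelihood path, sums, order", {
    set.seed(52)
    G <- rbind(rbinom(80, 2, .4), rbinom(80, 2, .35), rbinom(80, 2, .3))
    x <- toyCohort(G)
    ht <- emHaplotypes(x, c("rs1", "rs2", "rs3"))
    expect_true(ht@converged)
    expect_equal(sum(ht@freq), 1, tolerance = 1e-8)
    for (pp in ht@pairs) expect_equal(sum(pp$post), 1, tolerance = 1e-8)
    # dosage conservation: every subject carries exactly 2 copies
    D <- hapDosage(ht)
    expect_equal(unname(rowSums(D)), rep(2, nrow(D)), tolerance = 1e-8)
    # frequencies invariant to subject order
    perm <- sample(ncol(G))
    xp <- toyCohort(G[, perm], status = unname(caseStatus(x))[perm])
    htp <- emHaplotypes(xp, c("rs1", "rs2", "rs3"))
    o <- order(hapLabels(ht)); op <- order(hapLabels(htp))
    expect_equal(hapLabels(ht)[o], hapLabels(htp)[op])
    expect_equal(ht@freq[o], htp@freq[op], tolerance = 1e-6)
})

test_that("phase-pair enumeration covers exactly the compatible pairs", {
    pp <- SnpHapScan:::.phasePairs(c(1L, 1L, 1L))
    expect_equal(nrow(pp$h1), 4)  # 2^(3-1) unordered pairs
    expect_true(all(pp$h1 + pp$h2 == 1L))
    pp0 <- SnpHapScan:::.phasePairs(c(0L, 2L))
    expect_equal(nrow(pp0$h1), 1)
    expect_equal(pp0$h1[1, ], c(0L, 1L))
})

test_that("r2 closed forms: perfect LD, equilibrium, symmetry", {
    g <- rbinom(200, 2, 0.4)
    x <- toyCohort(rbind(g, g))
    expect_equal(ldR2(x, "rs1", "rs2", controlsOnly = FALSE)$r2, 1,
                 tolerance = 1e-6)

    # four haplotypes at 1/4 each: D = 0
    pool <- haplotypePool("GX", c("r1", "r2"),
                          c("A-C", "A-T", "G-C", "G-T"), rep(0.25, 4),
                          major = c("A", "C"), minor = c("G", "T"))
    d <- sampleDiplotypes(pool, 5000, seed = 61)
    G <- t(pool$hap[d[, 1], ] + pool$hap[d[, 2], ])
    x2 <- toyCohort(G)
    expect_lt(ldR2(x2, "rs1", "rs2", controlsOnly = FALSE)$r2, 0.01)

    # independent SNPs at n = 10,000
    set.seed(62)
    G3 <- rbind(rbinom(10000, 2, .3), rbinom(10000, 2, .4))
    x3 <- toyCohort(G3)
    est <- ldR2(x3, "rs1", "rs2", controlsOnly = FALSE)
    expect_lt(est$r2, 0.01)
    swapped <- ldR2(x3, "rs2", "rs1", controlsOnly = FALSE)
    expect_equal(est$r2, swapped$r2, tolerance = 1e-9)

    xm <- toyCohort(rbind(rep(0L, 50), rbinom(50, 2, .3)))
    expect_error(ldR2(xm, "rs1", "rs2", controlsOnly = FALSE),
                 "monomorphic")
})

test_that("haplotype GLM equals logistic regression on true counts when
           phase is unambiguous", {
    # haplotypes confined to SNP-disjoint patterns: A-C, G-C, A-T never
    # create double heterozygotes ambiguity only with G-T present; use
    # 3 haplotypes so phase is always resolvable
    pool <- haplotypePool("GX", c("r1", "r2"),
                          c("A-C", "G-C", "A-T"), c(0.5, 0.3, 0.2),
                          major = c("A", "C"), minor = c("G", "T"))
    d <- sampleDiplotypes(pool, 400, seed = 71)
    G <- t(pool$hap[d[, 1], ] + pool$hap[d[, 2], ])
    set.seed(72)
    y <- rbinom(400, 1, 0.45)
    x <- toyCohort(G, status = y)
    hg <- haplotypeGlm(x, c("rs1", "rs2"), covariates = character(0),
                       poolThreshold = 0.05)
    # true per-subject haplotype counts
    lab <- c("A-C", "G-C", "A-T")
    cnt <- sapply(1:3, function(h) (d[, 1] == h) + (d[, 2] == h))
    ref <- glm(y ~ cnt[, 2] + cnt[, 3], binomial)
    tb <- hg@table
    expect_equal(hg@reference, "A-C")
    expect_equal(log(tb$or[tb$haplotype == "G-C"]),
                 unname(coef(ref)[2]), tolerance = 1e-8)
    expect_equal(log(tb$or[tb$haplotype == "A-T"]),
                 unname(coef(ref)[3]), tolerance = 1e-8)
})

test_that("haplotype GLM pools sub-threshold haplotypes and errors when the
           reference would be pooled", {
    pool <- haplotypePool("GX", c("r1", "r2"),
                          c("A-C", "G-C", "A-T"), c(0.9, 0.07, 0.03),
                          major = c("A", "C"), minor = c("G", "T"))
    d <- sampleDiplotypes(pool, 600, seed = 73)
    G <- t(pool$hap[d[, 1], ] + pool$hap[d[, 2], ])
    x <- toyCohort(G)
    hg <- haplotypeGlm(x, c("rs1", "rs2"), covariates = character(0),
                       poolThreshold = 0.06)
    tb <- hg@table
    expect_true("Rare" %in% tb$haplotype)
    # exactly the haplotypes under the threshold are pooled: G-C (7%)
    # keeps its own row, A-T (3%) goes to Rare, frequencies still total 1
    expect_true("G-C" %in% tb$haplotype)
    expect_false("A-T" %in% tb$haplotype)
    expect_lt(tb$freq[tb$haplotype == "Rare"], 0.06)
    expect_equal(sum(tb$freq), 1, tolerance = 1e-8)
    expect_error(haplotypeGlm(x, c("rs1", "rs2"),
                              covariates = character(0),
                              poolThreshold = 0.95),
                 "threshold too high")
})

test_that("global Wald p is uniform on null windows", {
    set.seed(74)
    ps <- replicate(200, {
        G <- rbind(rbinom(300, 2, .35), rbinom(300, 2, .3))
        y <- rbinom(300, 1, 0.5)
        x <- toyCohort(G, status = y)
        tryCatch(haplotypeGlm(x, c("rs1", "rs2"),
                              covariates = character(0))@globalP,
                 error = function(e) NA_real_)
    })
    ps <- ps[!is.na(ps)]
    expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("refinement mode stays at the two-stage answer when phase is
           certain", {
    pool <- haplotypePool("GX", c("r1", "r2"),
                          c("A-C", "G-C", "A-T"), c(0.5, 0.3, 0.2),
                          major = c("A", "C"), minor = c("G", "T"))
    d <- sampleDiplotypes(pool, 300, seed = 75)
    G <- t(pool$hap[d[, 1], ] + pool$hap[d[, 2], ])
    set.seed(76)
    y <- rbinom(300, 1, 0.5)
    x <- toyCohort(G, status = y)
    a <- haplotypeGlm(x, c("rs1", "rs2"), covariates = character(0))
    b <- haplotypeGlm(x, c("rs1", "rs2"), covariates = character(0),
                      refine = TRUE)
    expect_equal(a@table$or, b@table$or, tolerance = 1e-6)
})
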