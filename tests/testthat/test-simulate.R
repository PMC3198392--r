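test_that("diplotype sampling respects pool frequencies", {
    p1 <- twoSnpPool(freq = 1, haps = "A-C")
    d <- sampleDiplotypes(p1, 5, seed = 1)
    expect_true(all(d == 1L))  # degenerate pool: always the same pair

    p2 <- twoSnpPool()
    d <- sampleDiplotypes(p2, 10000, seed = 2)
    hetFrac <- mean(d[, 1] != d[, 2])
    se <- sqrt(0.5 * 0.5 / 10000)
    expect_lt(abs(hetFrac - 0.5), 3 * 2 * se)  # 2p(1-p) = 0.5

    # complementary haplotypes: every subject double-het or double-hom
    pc <- haplotypePool("GX", c("r1", "r2"), c("A-T", "G-C"),
                        c(0.5, 0.5), major = c("A", "C"),
                        minor = c("G", "T"))
    d <- sampleDiplotypes(pc, 500, seed = 3)
    g <- pc$hap[d[, 1], ] + pc$hap[d[, 2], ]
    dhet <- g[, 1] == 1 & g[, 2] == 1
    dhom <- g[, 1] != 1 & g[, 2] != 1
    expect_true(all(dhet | dhom))

    expect_error(sampleDiplotypes(p1, 0), "positive")
})

test_that("default study config matches the emulated study scale", {
    cfg <- defaultStudyConfig()
    expect_equal(cfg$nCases, 777L)
    expect_equal(cfg$nControls, 1035L)
    expect_equal(length(cfg$pools), 13L)
    expect_equal(sum(vapply(cfg$pools, function(p) length(p$rsids),
                            integer(1))), 163L)
    # pool-implied MAF >= 5% everywhere
    mafs <- unlist(lapply(cfg$pools, SnpHapScan:::.poolMaf))
    expect_true(all(mafs >= 0.05 & mafs <= 0.5))
    # risk haplotype planted at 6.4% with OR 1.37
    ef <- cfg$model$hapEffects$SLC19A1
    expect_equal(unname(ef), log(1.37))
    pool <- cfg$pools$SLC19A1
    expect_equal(pool$freq[match(names(ef), SnpHapScan:::.poolLabels(pool))],
                 0.064)
    # config construction is deterministic and does not touch the RNG
    set.seed(5); before <- runif(1)
    cfg2 <- defaultStudyConfig()
    set.seed(5); after <- runif(1)
    expect_identical(before, after)
    expect_identical(cfg2$pools$MTRR$hap, cfg$pools$MTRR$hap)
})

test_that("a fixed seed reproduces the cohort bit for bit", {
    cfg <- defaultStudyConfig(genes = "GGH", nCases = 120,
                              nControls = 150)
    a <- simulateCohort(cfg, seed = 7)
    b <- simulateCohort(cfg, seed = 7)
    expect_identical(genotypes(a$cohort), genotypes(b$cohort))
    expect_identical(as.data.frame(subjectData(a$cohort)),
                     as.data.frame(subjectData(b$cohort)))
    expect_identical(a$truth$riskCopies, b$truth$riskCopies)
    c <- simulateCohort(cfg, seed = 8)
    expect_false(identical(genotypes(a$cohort), genotypes(c$cohort)))
})

test_that("simulated cohort hits target sizes, missingness and MAF floor", {
    cfg <- defaultStudyConfig()
    sim <- simulateCohort(cfg, seed = 31)
    x <- sim$cohort
    st <- caseStatus(x)
    expect_equal(sum(st == 1L), 777L)
    expect_equal(sum(st == 0L), 1035L)
    frac <- mean(!is.na(genotypes(x)))
    expect_lt(abs(frac - 0.98), 0.005)
    expect_true(all(controlMaf(x) >= 0.03))  # sampling noise around 5%
})

test_that("null disease model leaves case/control allele freqs equal", {
    pool <- twoSnpPool(freq = c(0.3, 0.3, 0.4),
                       haps = c("A-C", "G-T", "G-C"))
    cfg <- onePoolConfig(pool, nCases = 400, nControls = 400)
    diffs <- sapply(1:20, function(s) {
        sim <- simulateCohort(cfg, seed = s)
        g <- genotypes(sim$cohort)
        st <- caseStatus(sim$cohort)
        fCase <- rowMeans(g[, st == 1], na.rm = TRUE) / 2
        fCtrl <- rowMeans(g[, st == 0], na.rm = TRUE) / 2
        fCase - fCtrl
    })
    se <- sqrt(0.3 * 0.7 / (2 * 400) * 2)
    expect_lt(abs(mean(diffs)), 3 * se / sqrt(20))
})

test_that("genotype frequencies converge to pool-implied values", {
    pool <- defaultStudyConfig(genes = "SLC19A1")$pools$SLC19A1
    d <- sampleDiplotypes(pool, 50000, seed = 41)
    g <- pool$hap[d[, 1], ] + pool$hap[d[, 2], ]
    emp <- colMeans(g) / 2
    expect_equal(unname(emp), unname(SnpHapScan:::.poolMaf(pool)),
                 tolerance = 0.01)
})

test_that("truth record writer round-trips the planted copies", {
    cfg <- defaultStudyConfig(genes = "SLC19A1", nCases = 100,
                              nControls = 100)
    sim <- simulateCohort(cfg, seed = 13)
    f <- tempfile()
    writeTruthRecord(sim$truth, sim$cohort, f)
    hdr <- readLines(f, n = 3)
    expect_match(hdr[1], "seed\t13")
    tab <- read.delim(f, comment.char = "#")
    expect_equal(nrow(tab), 200)
    expect_equal(tab$riskCopies,
                 unname(sim$truth$riskCopies[as.character(tab$id)]))
})
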