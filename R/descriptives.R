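#' Pearson chi-square test on a categories x case/control table
#'
#' Uncorrected (no continuity correction) Pearson chi-square for equality
#' of category proportions between cases and controls — the test behind
#' the descriptive-table p-values.
#'
#' @param counts integer matrix, categories in rows, two columns
#'   (cases, controls); at least 2 rows
#' @return named numeric: \code{statistic}, \code{df}, \code{p}
#' @examples
#' pearsonChi2(cbind(cases = c(472, 305), controls = c(648, 387)))
#' @export
pearsonChi2 <- function(counts) {
    counts <- as.matrix(counts)
    if (nrow(counts) < 2 || ncol(counts) < 2)
        stop("need at least a 2x2 table")
    if (any(counts < 0)) stop("counts must be non-negative")
    if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
        stop("degenerate table: zero row or column sum")
    ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    c(statistic = unname(ht$statistic), df = unname(ht$parameter),
      p = unname(ht$p.value))
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' @param mean1,sd1,n1 summary statistics of group 1
#' @param mean2,sd2,n2 summary statistics of group 2
#' @return named numeric: \code{t}, \code{df}, \code{p} (two-sided)
#' @examples
#' twoSampleT(59.5, 10.4, 777, 59.0, 10.2, 1035)
#' @export
twoSampleT <- function(mean1, sd1, n1, mean2, sd2, n2) {
    if (n1 < 2 || n2 < 2) stop("need n >= 2 in each group")
    if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    c(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Control-based tertile stratification
#'
#' Cut-points are the 1/3 and 2/3 empirical quantiles of the control
#' values (type-7 quantiles); every subject, cases included, is then
#' labeled low/medium/high. Values equal to a cut-point fall in the lower
#' stratum.
#'
#' @param controlValues numeric, intake scores among controls
#' @param allValues numeric, scores for every subject to be labeled
#' @return list: \code{cutpoints} (length 2), \code{labels} (factor
#'   low/medium/high aligned with \code{allValues})
#' @examples
#' controlTertiles(1:9, c(2, 6, 7))$labels  # low, medium, high
#' @export
controlTertiles <- function(controlValues, allValues = controlValues) {
    controlValues <- controlValues[!is.na(controlValues)]
    if (!length(controlValues)) stop("no non-missing control values")
    if (length(unique(controlValues)) < 3)
        warning("fewer than 3 distinct control values; tertiles degenerate")
    cp <- unname(stats::quantile(controlValues, c(1 / 3, 2 / 3), type = 7))
    lab <- ifelse(is.na(allValues), NA_character_,
                  ifelse(allValues <= cp[1], "low",
                         ifelse(allValues <= cp[2], "medium", "high")))
    list(cutpoints = cp,
         labels = factor(lab, levels = c("low", "medium", "high")))
}

#' Assign vegetable and alcohol tertiles on a cohort
#'
#' Derives \code{vegetableTertile} and \code{alcoholTertile} subject
#' columns from the intake frequency scores using control-based tertiles
#' (\code{\link{controlTertiles}}). For alcohol, non-drinkers (score 0)
#' form their own \code{"none"} class and tertiles are computed among
#' drinking controls only.
#'
#' @param x a \code{\linkS4class{SnpCohort}} with \code{vegetableFreq}
#'   and/or \code{alcoholFreq} subject columns
#' @return the cohort with tertile columns filled in
#' @export
assignTertiles <- function(x) {
    cd <- colData(x)
    ctrl <- cd$status == 0L
    if ("vegetableFreq" %in% colnames(cd)) {
        tt <- controlTertiles(cd$vegetableFreq[ctrl], cd$vegetableFreq)
        cd$vegetableTertile <- tt$labels
    }
    if ("alcoholFreq" %in% colnames(cd)) {
        drink <- !is.na(cd$alcoholFreq) & cd$alcoholFreq > 0
        tt <- controlTertiles(cd$alcoholFreq[ctrl & drink],
                              cd$alcoholFreq)
        lab <- as.character(tt$labels)
        lab[!is.na(cd$alcoholFreq) & cd$alcoholFreq == 0] <- "none"
        cd$alcoholTertile <- factor(lab,
                                    levels = c("none", "low", "medium", "high"))
    }
    colData(x) <- cd
    x
}

#' Case/control descriptive table with tests
#'
#' Builds the demographic-characteristics report: for each categorical
#' subject field, per-category case and control counts and percentages
#' with an uncorrected Pearson chi-square p-value; for \code{age}, means,
#' SDs and a pooled t-test.
#'
#' @param subjects data.frame/DataFrame with \code{status} plus the fields
#' @param fields character, which subject columns to tabulate
#' @return data.frame in report layout (one row per category plus one per
#'   continuous field)
#' @export
descriptivesTable <- function(subjects,
                              fields = c("center", "sex", "age", "bmiClass",
                                         "smoking", "hypertension",
                                         "familyHistory", "vegetableTertile",
                                         "alcoholTertile")) {
    su <- as.data.frame(subjects)
    fields <- intersect(fields, names(su))
    cases <- su[su$status == 1L, , drop = FALSE]
    ctrls <- su[su$status == 0L, , drop = FALSE]
    rows <- list()
    for (f in fields) {
        if (is.numeric(su[[f]]) && length(unique(stats::na.omit(su[[f]]))) > 4) {
            m1 <- mean(cases[[f]], na.rm = TRUE); s1 <- stats::sd(cases[[f]], na.rm = TRUE)
            m2 <- mean(ctrls[[f]], na.rm = TRUE); s2 <- stats::sd(ctrls[[f]], na.rm = TRUE)
            tt <- twoSampleT(m1, s1, sum(!is.na(cases[[f]])),
                             m2, s2, sum(!is.na(ctrls[[f]])))
            rows[[length(rows) + 1L]] <- data.frame(
                field = f, category = "mean ± sd",
                cases = sprintf("%.1f±%.1f", m1, s1), casesPct = NA,
                controls = sprintf("%.1f±%.1f", m2, s2),
                controlsPct = NA, p = unname(tt["p"]))
        } else {
            v <- factor(su[[f]])
            tabC <- table(factor(cases[[f]], levels = levels(v)))
            tabK <- table(factor(ctrls[[f]], levels = levels(v)))
            keep <- tabC + tabK > 0
            tabC <- tabC[keep]; tabK <- tabK[keep]
            p <- if (length(tabC) >= 2)
                unname(pearsonChi2(cbind(tabC, tabK))["p"]) else NA_real_
            rows[[length(rows) + 1L]] <- data.frame(
                field = f, category = names(tabC),
                cases = as.character(as.integer(tabC)),
                casesPct = round(100 * as.integer(tabC) / sum(tabC), 1),
                controls = as.character(as.integer(tabK)),
                controlsPct = round(100 * as.integer(tabK) / sum(tabK), 1),
                p = c(p, rep(NA, length(tabC) - 1L)))
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
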