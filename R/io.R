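#' Read a PLINK text ped/map pair into a SnpCohort
#'
#' Parses the white-space delimited PLINK text dialect: six leading ped
#' columns (family, individual, paternal, maternal ids, sex 1=male/2=female,
#' phenotype 2=case/1=control/0 or -9=missing) followed by two allele
#' columns per SNP; "0 0" marks a missing call. Allele pairs are converted
#' to minor-allele counts.
#'
#' @param pedPath,mapPath file paths
#' @param minorAllelePolicy how the minor allele of each SNP is decided:
#'   \code{"control_freq"} (default) takes the rarer allele among control
#'   subjects, ties broken lexicographically (so coding is reproducible);
#'   alternatively a named character vector rsid -> minor allele.
#' @param geneMap optional named list mapping gene-region names to ordered
#'   rsid vectors (5' to 3'). When omitted, the map file's chromosome field
#'   is used as the region name and SNPs keep file order within it.
#' @return a \code{\linkS4class{SnpCohort}}; subject data hold only
#'   \code{id}, \code{status} and \code{sex} (a ped file carries no more).
#' @export
readPedMap <- function(pedPath, mapPath, minorAllelePolicy = "control_freq",
                       geneMap = NULL) {
    map <- utils::read.table(mapPath, header = FALSE,
                             colClasses = "character")
    if (ncol(map) < 4) stop("map file must have 4 columns")
    names(map)[1:4] <- c("chrom", "rsid", "cm", "bp")
    m <- nrow(map)

    lines <- readLines(pedPath)
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "[ \t]+")
    nTok <- lengths(toks)
    expected <- 6L + 2L * m
    bad <- which(nTok != expected)
    if (length(bad))
        stop("ragged ped line ", bad[1], ": ", nTok[bad[1]],
             " fields, expected ", expected)
    tok <- do.call(rbind, toks)

    ids <- tok[, 2]
    sexCode <- tok[, 5]
    sex <- ifelse(sexCode == "1", "male", ifelse(sexCode == "2", "female", NA))
    ph <- tok[, 6]
    status <- ifelse(ph == "2", 1L, ifelse(ph == "1", 0L, NA_integer_))

    n <- nrow(tok)
    a1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
    a2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]

    counts <- matrix(NA_integer_, nrow = m, ncol = n)
    major <- minor <- character(m)
    for (j in seq_len(m)) {
        x1 <- a1[, j]; x2 <- a2[, j]
        missing <- x1 == "0" | x2 == "0"
        if (any(xor(x1 == "0", x2 == "0")))
            stop("half-missing genotype at ", map$rsid[j])
        alleles <- sort(unique(c(x1[!missing], x2[!missing])))
        if (length(alleles) > 2)
            stop("triallelic site at ", map$rsid[j], ": ",
                 paste(alleles, collapse = "/"))
        if (length(alleles) == 0) alleles <- c("A", "B")  # all missing
        if (is.character(minorAllelePolicy) &&
            length(minorAllelePolicy) == 1 &&
            minorAllelePolicy == "control_freq") {
            keep <- !missing & !is.na(status) & status == 0L
            pool <- c(x1[keep], x2[keep])
            if (!length(pool)) pool <- c(x1[!missing], x2[!missing])
            cnt <- table(factor(pool, levels = alleles))
            # rarer allele is minor; lexicographic tie-break
            if (length(alleles) == 1) {
                minor[j] <- setdiff(c("A", "C", "G", "T", "B"), alleles)[1]
                major[j] <- alleles
            } else if (cnt[1] == cnt[2]) {
                minor[j] <- alleles[1]; major[j] <- alleles[2]
            } else {
                minor[j] <- alleles[which.min(cnt)]
                major[j] <- alleles[which.max(cnt)]
            }
        } else {
            mi <- minorAllelePolicy[[map$rsid[j]]]
            if (is.null(mi) || is.na(mi))
                stop("no declared minor allele for ", map$rsid[j])
            minor[j] <- mi
            major[j] <- if (length(alleles) == 2) setdiff(alleles, mi)
                        else if (alleles != mi) alleles else "N"
        }
        cj <- (x1 == minor[j]) + (x2 == minor[j])
        cj[missing] <- NA_integer_
        counts[j, ] <- as.integer(cj)
    }

    if (is.null(geneMap)) {
        gene <- map$chrom
        posIdx <- stats::ave(seq_len(m), gene, FUN = seq_along) - 1L
    } else {
        gene <- rep(NA_character_, m)
        posIdx <- rep(NA_integer_, m)
        for (g in names(geneMap)) {
            i <- match(geneMap[[g]], map$rsid)
            if (anyNA(i)) stop("geneMap rsid absent from map file: ",
                               geneMap[[g]][which(is.na(i))[1]])
            gene[i] <- g
            posIdx[i] <- seq_along(i) - 1L
        }
        if (anyNA(gene)) stop("map rsid not covered by geneMap: ",
                              map$rsid[which(is.na(gene))[1]])
    }

    si <- data.frame(rsid = map$rsid, gene = gene,
                     positionIndex = as.integer(posIdx),
                     majorAllele = major, minorAllele = minor,
                     stringsAsFactors = FALSE)
    su <- data.frame(id = ids, status = status, sex = sex,
                     stringsAsFactors = FALSE)
    SnpCohort(counts, si, su)
}

#' Write a SnpCohort as a PLINK text ped/map pair
#'
#' Inverse of \code{\link{readPedMap}}: reading the written files back
#' (with the written minor alleles declared) reproduces the genotype
#' counts exactly.
#'
#' @param x a \code{\linkS4class{SnpCohort}}
#' @param pedPath,mapPath output paths
#' @export
writePedMap <- function(x, pedPath, mapPath) {
    rd <- rowData(x)
    map <- data.frame(chrom = as.character(rd$gene), rsid = rd$rsid,
                      cm = 0, bp = seq_len(nrow(rd)))
    utils::write.table(map, mapPath, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    g <- genotypes(x)
    cd <- colData(x)
    n <- ncol(g); m <- nrow(g)
    sexCode <- ifelse(is.na(cd$sex), "0",
                      ifelse(cd$sex %in% c("male", "1", 1), "1", "2"))
    phCode <- ifelse(is.na(cd$status), "0",
                     ifelse(cd$status == 1L, "2", "1"))
    alleleCols <- matrix("0", nrow = n, ncol = 2 * m)
    for (j in seq_len(m)) {
        cj <- g[j, ]
        A <- rd$majorAllele[j]; a <- rd$minorAllele[j]
        a1 <- ifelse(is.na(cj), "0", ifelse(cj >= 1, a, A))
        a2 <- ifelse(is.na(cj), "0", ifelse(cj == 2, a, A))
        alleleCols[, 2 * j - 1] <- a1
        alleleCols[, 2 * j] <- a2
    }
    ped <- cbind(as.character(cd$id), as.character(cd$id), "0", "0",
                 sexCode, phCode, alleleCols)
    utils::write.table(ped, pedPath, quote = FALSE, sep = " ",
                       row.names = FALSE, col.names = FALSE)
    invisible(c(ped = pedPath, map = mapPath))
}

#' Bucket continuous age into the analysis age classes
#'
#' Classes are \code{<50}, \code{50-<60}, \code{60-<70}, \code{70+},
#' the adjustment categories used in the haplotype models.
#'
#' @param age numeric years
#' @return factor with the four levels above
#' @export
ageClassOf <- function(age) {
    cut(age, breaks = c(-Inf, 50, 60, 70, Inf),
        labels = c("<50", "50-<60", "60-<70", "70+"), right = FALSE)
}

.subjectCats <- list(
    sex = c("male", "female"),
    bmiClass = c("<25", "25-30", ">30"),
    smoking = c("never", "former", "current"))

#' Read a delimited subject table
#'
#' Expects a comma- or tab-delimited file with a header naming subject
#' fields; \code{id} and \code{status} are required. \code{status} accepts
#' 0/1 or the words case/control. Continuous \code{age} is bucketed into
#' \code{ageClass}. Unknown category labels are rejected; empty cells
#' become missing values and the record is retained.
#'
#' @param path file path
#' @param sep field separator; default guesses comma vs tab from the header
#' @return data.frame of typed subject records
#' @export
readSubjectTable <- function(path, sep = NULL) {
    if (is.null(sep)) {
        h <- readLines(path, n = 1)
        sep <- if (grepl("\t", h)) "\t" else ","
    }
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, na.strings = c("", "NA"))
    if (!all(c("id", "status") %in% names(df)))
        stop("subject table must have 'id' and 'status' columns")
    st <- as.character(df$status)
    ok <- st %in% c("0", "1", "case", "control") | is.na(st)
    if (!all(ok))
        stop("invalid status value(s): ",
             paste(unique(st[!ok]), collapse = ", "),
             " (expected 0/1/case/control)")
    df$status <- ifelse(st %in% c("1", "case"), 1L,
                        ifelse(st %in% c("0", "control"), 0L, NA_integer_))
    if ("age" %in% names(df)) df$ageClass <- ageClassOf(df$age)
    for (fld in names(.subjectCats)) {
        if (!fld %in% names(df)) next
        v <- as.character(df[[fld]])
        bad <- !is.na(v) & !v %in% .subjectCats[[fld]]
        if (any(bad))
            stop("unknown ", fld, " category: ", unique(v[bad])[1])
        df[[fld]] <- factor(v, levels = .subjectCats[[fld]])
    }
    for (fld in c("hypertension", "familyHistory"))
        if (fld %in% names(df)) df[[fld]] <- as.integer(df[[fld]])
    df
}

#' Write subject records as a tab-separated table
#' @param subjects data.frame or DataFrame of subject records
#' @param path output path
#' @export
writeSubjectTable <- function(subjects, path) {
    utils::write.table(as.data.frame(subjects), path, quote = FALSE,
                       sep = "\t", row.names = FALSE)
    invisible(path)
}
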