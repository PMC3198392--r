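#' Maximum-likelihood logistic regression on a design matrix
#'
#' Thin, fast wrapper around \code{stats::glm.fit} (iteratively reweighted
#' least squares) used by every model in the package. Convergence follows
#' the usual deviance criterion (change < 1e-8, at most 100 iterations).
#' Aliased (rank-deficient) columns are dropped with a warning and the
#' model refit on the reduced design. Complete or quasi-complete
#' separation is flagged through the convergence flag and inflated
#' standard errors; estimates for terms with unbounded likelihood are
#' reported as \code{NA}.
#'
#' @param y binary 0/1 outcome vector
#' @param X design matrix with named columns (no intercept column; one is
#'   prepended unless \code{intercept = FALSE})
#' @param intercept logical, prepend an intercept column
#' @return object of class \code{"logisticFit"}: list with \code{coef},
#'   \code{se}, \code{vcov}, \code{logLik}, \code{converged}, \code{n},
#'   \code{dropped} (names of aliased columns), \code{fitted}
#' @examples
#' set.seed(1)
#' x <- rbinom(200, 1, 0.5); y <- rbinom(200, 1, plogis(-0.3 + 0.8 * x))
#' fitLogistic(y, cbind(exposed = x))
#' @export
fitLogistic <- function(y, X, intercept = TRUE) {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
    if (is.null(dim(X))) X <- matrix(X, ncol = 1,
                                     dimnames = list(NULL, "x"))
    X <- as.matrix(X)
    if (ncol(X) && is.null(colnames(X)))
        colnames(X) <- paste0("x", seq_len(ncol(X)))
    if (intercept)
        X <- cbind("(Intercept)" = 1, X)
    if (nrow(X) != length(y)) stop("design rows != outcome length")
    if (all(y == 0) || all(y == 1)) stop("outcome has a single class")

    ctl <- stats::glm.control(epsilon = 1e-8, maxit = 100L)
    fit <- suppressWarnings(
        stats::glm.fit(X, y, family = stats::binomial(), control = ctl))

    dropped <- character()
    if (anyNA(fit$coefficients)) {
        dropped <- names(fit$coefficients)[is.na(fit$coefficients)]
        warning("aliased column(s) dropped: ",
                paste(dropped, collapse = ", "))
        X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
        fit <- suppressWarnings(
            stats::glm.fit(X, y, family = stats::binomial(), control = ctl))
    }

    beta <- fit$coefficients
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) {
        MASSlike <- tryCatch(solve(XtWX), error = function(e2) NULL)
        MASSlike
    })
    if (is.null(V)) {
        se <- rep(NA_real_, length(beta))
        V <- matrix(NA_real_, length(beta), length(beta))
    } else se <- sqrt(pmax(diag(V), 0))
    names(se) <- names(beta)
    dimnames(V) <- list(names(beta), names(beta))

    mu <- fit$fitted.values
    eps <- 1e-12
    ll <- sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))

    converged <- isTRUE(fit$converged)
    # separation: divergent estimates with exploding SEs
    sep <- !is.na(beta) & !is.na(se) & abs(beta) > 10 & se > 10
    if (any(sep)) {
        converged <- FALSE
        beta[sep] <- NA_real_
        se[sep] <- NA_real_
    }

    structure(list(coef = beta, se = se, vcov = V, logLik = ll,
                   converged = converged, n = length(y),
                   dropped = dropped, fitted = mu),
              class = "logisticFit")
}

#' @export
print.logisticFit <- function(x, ...) {
    cat("Logistic fit (n =", x$n,
        if (x$converged) ", converged" else ", NOT converged", ")\n")
    tab <- cbind(coef = x$coef, se = x$se, OR = exp(x$coef))
    print(round(tab, 4))
    cat("logLik:", format(x$logLik), "\n")
    invisible(x)
}

# Wald summary for a single coefficient: OR, 95% CI, two-sided p
.waldRow <- function(fit, term) {
    b <- unname(fit$coef[term]); s <- unname(fit$se[term])
    if (is.na(b) || is.na(s))
        return(c(or = NA, lo = NA, hi = NA, p = NA))
    z <- b / s
    c(or = exp(b), lo = exp(b - 1.96 * s), hi = exp(b + 1.96 * s),
      p = 2 * stats::pnorm(-abs(z)))
}

# Build a covariate design matrix from subject records.
# Numeric fields enter as-is; factors/characters are expanded to
# treatment-coded indicator columns (first level = reference).
.covariateDesign <- function(subjects, covariates) {
    su <- as.data.frame(subjects)
    if (!length(covariates))
        return(matrix(numeric(0), nrow = nrow(su), ncol = 0))
    cols <- list()
    for (cv in covariates) {
        if (!cv %in% names(su)) stop("unknown covariate: ", cv)
        v <- su[[cv]]
        if (is.numeric(v) || is.integer(v)) {
            cols[[cv]] <- matrix(as.numeric(v), ncol = 1,
                                 dimnames = list(NULL, cv))
        } else {
            f <- factor(v)
            lev <- levels(droplevels(f))
            f <- factor(f, levels = lev)
            if (length(lev) < 2) next  # constant factor carries nothing
            mm <- sapply(lev[-1], function(L) as.numeric(f == L))
            colnames(mm) <- paste0(cv, lev[-1])
            cols[[cv]] <- mm
        }
    }
    if (!length(cols))
        return(matrix(numeric(0), nrow = nrow(su), ncol = 0))
    do.call(cbind, cols)
}
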