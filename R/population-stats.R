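#' @include AllClasses.R
NULL

#' Summarize a group of measurements
#'
#' Sample mean, standard deviation (n - 1 denominator) and standard error of
#' the mean, as used for "mean +/- SD" and "mean +/- SEM" reporting of
#' granule, cell and embryo measurements.
#'
#' @param values numeric vector, non-empty.
#' @param errorKind which error to expose in the \code{error} column:
#'   \code{"sem"} or \code{"sd"}.
#' @param label group label.
#' @return A one-row data.frame: \code{n, mean, sd, sem, error, error_kind,
#'   label}. A single value yields sd = 0 with a warning.
#' @examples
#' summarizeGroup(c(1, 2, 3))
#' @export
summarizeGroup <- function(values, errorKind = c("sem", "sd"), label = "") {
    errorKind <- match.arg(errorKind)
    if (!length(values)) stop("empty input")
    n <- length(values)
    s <- if (n > 1) stats::sd(values) else {
        warning("sd undefined for a single value; reported as 0")
        0
    }
    sem <- s / sqrt(n)
    data.frame(n = n, mean = mean(values), sd = s, sem = sem,
               error = if (errorKind == "sem") sem else s,
               error_kind = errorKind, label = label)
}

#' Percent decrease from a control mean to a test mean
#'
#' @param controlMean control group mean, non-zero.
#' @param testMean test group mean.
#' @return Percent decrease, 100 (control - test) / control, full precision
#'   (round to 1 decimal place for display).
#' @examples
#' round(percentChange(36.9, 22.4), 1)   # 39.3
#' @export
percentChange <- function(controlMean, testMean) {
    if (controlMean == 0) stop("controlMean must be non-zero")
    100 * (controlMean - testMean) / controlMean
}

#' Two-sample two-tailed t-test
#'
#' Classical unpaired two-tailed t-test; Welch's unequal-variance variant is
#' the default, the equal-variance (Student) variant is selectable. The
#' degenerate case of two zero-variance groups with equal means returns
#' t = 0, p = 1 by convention.
#'
#' @param groupA,groupB numeric vectors with at least 2 values each.
#' @param kind \code{"welch"} or \code{"equal_var"}.
#' @return A list: \code{statistic} (t), \code{p.value}, \code{df},
#'   \code{kind}.
#' @export
twoSampleTest <- function(groupA, groupB, kind = c("welch", "equal_var")) {
    kind <- match.arg(kind)
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("both groups need at least 2 values")
    if (stats::var(groupA) == 0 && stats::var(groupB) == 0) {
        if (mean(groupA) == mean(groupB))
            return(list(statistic = 0, p.value = 1,
                        df = length(groupA) + length(groupB) - 2L,
                        kind = kind))
        stop("both groups have zero variance but unequal means; t undefined")
    }
    ht <- stats::t.test(groupA, groupB, var.equal = (kind == "equal_var"),
                        alternative = "two.sided")
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         df = unname(ht$parameter), kind = kind)
}

#' One-way analysis of variance
#'
#' Classical one-way fixed-effects ANOVA across two or more groups.
#'
#' @param groups named or unnamed list of numeric vectors, each with at
#'   least 2 values.
#' @return A list: \code{statistic} (F), \code{p.value}, \code{df} (between,
#'   within).
#' @export
oneWayAnova <- function(groups) {
    if (length(groups) < 2L) stop("need at least two groups")
    if (any(vapply(groups, length, integer(1)) < 2L))
        stop("every group needs at least 2 values (degenerate group)")
    value <- unlist(groups, use.names = FALSE)
    grp <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
    gm <- tapply(value, grp, mean)
    df1 <- nlevels(grp) - 1L
    df2 <- length(value) - nlevels(grp)
    if (all(gm == gm[1]) && stats::var(value) > 0)
        return(list(statistic = 0, p.value = 1, df = c(df1, df2)))
    if (sum((value - gm[grp])^2) == 0)
        stop("zero within-group variance; F undefined")
    ht <- stats::oneway.test(value ~ grp, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         df = unname(ht$parameter))
}
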