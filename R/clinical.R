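#' @include methods.R
NULL

#' Seizure-frequency categories, in clinical order
#'
#' From no seizure history through rare (one or two seizures ever),
#' monthly (>= 1/month), weekly (>= 1/week), to daily (>= 1/day), graded
#' over the three months before surgery.
#' @export
frequencyLevels <- c("none", "rare_1_2", "monthly", "weekly", "daily")

#' Seizure-type categories
#' @export
seizureTypes <- c("focal_aware", "focal_impaired_awareness",
                  "focal_to_bilateral_tonic_clonic", "none")

#' Ordinal seizure-frequency score
#'
#' Maps the graded frequency category to the 0-4 score used as the symptom
#' column of the VLSM design matrix: 0 no seizure history, 1 only one or
#' two seizures ever, 2 more than once per month, 3 more than once per
#' week, 4 more than once per day.
#'
#' @param category character vector of categories (see
#'   \code{\link{frequencyLevels}}).
#' @return integer vector of scores in 0..4.
#' @examples
#' scoreFrequency(c("none", "rare_1_2", "monthly", "weekly", "daily"))
#' @export
scoreFrequency <- function(category) {
    i <- match(category, frequencyLevels)
    if (anyNA(i))
        stop("unknown frequency category: ",
             paste(unique(category[is.na(i)]), collapse = ", "))
    as.integer(i - 1L)
}

#' Frequent-seizure dichotomy
#'
#' Seizures occurring at least once per month (score >= 2) count as
#' frequent; rarer seizures, or no seizure history, as non-frequent.
#'
#' @param score integer vector of ordinal scores in 0..4.
#' @return logical vector, TRUE for frequent.
#' @export
isFrequent <- function(score) {
    score <- as.integer(score)
    if (anyNA(score) || any(score < 0L | score > 4L))
        stop("scores must be integers in 0..4")
    score >= 2L
}

#' Dichotomize the Engel surgical seizure outcome
#'
#' Engel Class I is seizure free; Classes II-IV are grouped as uncontrolled
#' seizures. A missing class yields NA, signalling that the subject is
#' excluded from outcome analyses rather than raising an error.
#'
#' @param engel character vector in \{"I","II","III","IV"\} or NA.
#' @return character vector, "seizure_free", "uncontrolled" or NA.
#' @export
dichotomizeEngel <- function(engel) {
    out <- rep(NA_character_, length(engel))
    known <- !is.na(engel) & engel != ""
    bad <- known & !engel %in% c("I", "II", "III", "IV")
    if (any(bad))
        stop("unknown Engel class: ", paste(unique(engel[bad]), collapse = ", "))
    out[known & engel == "I"] <- "seizure_free"
    out[known & engel %in% c("II", "III", "IV")] <- "uncontrolled"
    out
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson's chi-square without continuity correction (the uncorrected
#' statistic is the one clinical cohort tables in this literature report),
#' df = (r-1)(c-1), p from the upper tail of the chi-square distribution.
#'
#' @param table r x c matrix of non-negative integer counts, at least 2x2,
#'   with strictly positive row and column margins.
#' @return A \linkS4class{ContingencyResult}.
#' @examples
#' ## extent of resection (gross total / partial) by seizure frequency
#' chiSquareTest(matrix(c(46, 64, 80, 56), 2, byrow = TRUE))
#' @export
chiSquareTest <- function(table) {
    table <- as.matrix(table)
    if (any(table < 0) || any(table != round(table)))
        stop("counts must be non-negative integers")
    if (nrow(table) < 2L || ncol(table) < 2L)
        stop("table must be at least 2x2")
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        stop("degenerate table: a row or column margin is zero")
    ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    new("ContingencyResult", statistic = unname(ht$statistic),
        df = as.integer(ht$parameter), pValue = unname(ht$p.value),
        table = table)
}

#' Mann-Whitney U test (two-sided, tie-corrected normal approximation)
#'
#' U counts, over all cross-group pairs, wins for the first group plus half
#' the ties (equivalently it is derived from midrank sums). The two-sided
#' p-value uses the normal approximation with tie-corrected variance and no
#' continuity correction — appropriate for the heavily tied ordinal scores
#' this package compares.
#'
#' @param groupA,groupB non-empty numeric vectors.
#' @return A \linkS4class{RankTestResult} (U reported for \code{groupA}).
#' @export
mannWhitney <- function(groupA, groupB) {
    groupA <- as.numeric(groupA); groupB <- as.numeric(groupB)
    if (!length(groupA) || !length(groupB))
        stop("both groups must be non-empty")
    ht <- suppressWarnings(
        stats::wilcox.test(groupA, groupB, exact = FALSE, correct = FALSE))
    p <- ht$p.value
    if (is.nan(p)) p <- 1  # zero-variance case: identical tied samples
    new("RankTestResult", uStatistic = unname(ht$statistic), pValue = p,
        n1 = length(groupA), n2 = length(groupB))
}

#' Multivariate logistic regression with Wald inference
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares)
#' of a binary outcome on a predictor matrix, reporting coefficients,
#' standard errors, Wald p-values and odds ratios with 95\% confidence
#' intervals. Non-convergence or (quasi-)separation is flagged and the
#' coefficient table withheld, since Wald inference is meaningless there.
#'
#' @param outcome binary (0/1 or logical) vector, not constant.
#' @param predictors numeric matrix or data.frame, one column per
#'   predictor (no intercept column; one is added).
#' @return A \linkS4class{LogisticResult}.
#' @export
logisticRegression <- function(outcome, predictors) {
    y <- as.numeric(outcome)
    X <- as.matrix(as.data.frame(predictors))
    if (length(unique(y[!is.na(y)])) < 2L)
        stop("outcome is constant")
    if (length(y) <= ncol(X) + 1L)
        stop("need more subjects than predictors + 1")
    if (is.null(colnames(X)))
        colnames(X) <- paste0("x", seq_len(ncol(X)))
    dat <- data.frame(.y = y, X, check.names = FALSE)
    sepFlag <- FALSE
    fit <- withCallingHandlers(
        stats::glm(.y ~ ., data = dat, family = stats::binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
                sepFlag <<- TRUE
            invokeRestart("muffleWarning")
        })
    conv <- isTRUE(fit$converged)
    ## quasi-separation also shows up as exploding coefficients
    if (any(abs(stats::coef(fit)[-1L]) > 15)) sepFlag <- TRUE
    if (!conv || sepFlag) {
        return(new("LogisticResult", coefficients = data.frame(),
                   converged = conv, separation = sepFlag,
                   n = length(y)))
    }
    cf <- summary(fit)$coefficients
    z975 <- stats::qnorm(0.975)
    tab <- data.frame(
        term = rownames(cf),
        estimate = cf[, 1L], se = cf[, 2L], z = cf[, 3L], p_value = cf[, 4L],
        odds_ratio = exp(cf[, 1L]),
        or_low = exp(cf[, 1L] - z975 * cf[, 2L]),
        or_high = exp(cf[, 1L] + z975 * cf[, 2L]),
        row.names = NULL)
    new("LogisticResult", coefficients = tab, converged = TRUE,
        separation = FALSE, n = length(y))
}

## -- clinical table I/O ------------------------------------------------------

.clinicalColumns <- c("subject_id", "age", "sex", "tumor_volume_cm3",
                      "has_seizure", "seizure_type", "frequency_category",
                      "asm_use", "resection", "pathology", "hemisphere",
                      "lobes", "engel_class")

#' Validate a clinical table
#'
#' Checks the documented schema: one row per subject with columns
#' subject_id, age (years), sex ("male"/"female"), tumor_volume_cm3,
#' has_seizure (logical), seizure_type, frequency_category, asm_use
#' (logical), resection ("gross_total"/"partial"), pathology, hemisphere
#' ("left"/"right"), lobes (semicolon-separated set), engel_class
#' ("I".."IV" or empty). Enforces the consistency invariant that
#' has_seizure is FALSE exactly when the frequency category and seizure
#' type are "none".
#'
#' @param clinical a data.frame.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validateClinicalTable <- function(clinical) {
    miss <- setdiff(.clinicalColumns, names(clinical))
    if (length(miss))
        stop("clinical table is missing required column(s): ",
             paste(miss, collapse = ", "))
    if (any(clinical$age <= 0, na.rm = TRUE)) stop("ages must be > 0")
    if (any(clinical$tumor_volume_cm3 < 0, na.rm = TRUE))
        stop("tumor volumes must be >= 0")
    sc <- scoreFrequency(clinical$frequency_category)
    hz <- as.logical(clinical$has_seizure)
    if (any(hz != (sc > 0L)))
        stop("inconsistent records: has_seizure must match frequency_category != 'none' for subject(s) ",
             paste(clinical$subject_id[hz != (sc > 0L)], collapse = ", "))
    if (any(hz != (clinical$seizure_type != "none")))
        stop("inconsistent records: seizure_type must be 'none' exactly for seizure-free subjects")
    clinical
}

#' Read a clinical table from CSV
#'
#' @param path CSV file with the schema of
#'   \code{\link{validateClinicalTable}}.
#' @return validated data.frame.
#' @export
readClinicalTable <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character"))
    df$has_seizure <- as.logical(df$has_seizure)
    df$asm_use <- as.logical(df$asm_use)
    if (!"engel_class" %in% names(df)) df$engel_class <- NA_character_
    df$engel_class[df$engel_class %in% c("", "NA")] <- NA_character_
    validateClinicalTable(df)
}

#' Write a clinical table to CSV
#' @param clinical validated clinical data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeClinicalTable <- function(clinical, path) {
    validateClinicalTable(clinical)
    utils::write.csv(clinical, path, row.names = FALSE, quote = TRUE,
                     na = "")
    invisible(path)
}

## -- cohort summary ----------------------------------------------------------

.twoByTwo <- function(flagVar, flagGroup) {
    m <- matrix(c(sum(flagVar & flagGroup), sum(flagVar & !flagGroup),
                  sum(!flagVar & flagGroup), sum(!flagVar & !flagGroup)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("yes", "no"), c("group1", "group2")))
    m
}

.summaryRow <- function(variable, level, flagVar, flagGroup) {
    tab <- .twoByTwo(flagVar, flagGroup)
    p <- tryCatch(chiSquareTest(tab)@pValue, error = function(e) NA_real_)
    data.frame(variable = variable, level = level,
               group1 = sum(flagVar & flagGroup),
               group2 = sum(flagVar & !flagGroup),
               test = "chi_square", p_value = p,
               stringsAsFactors = FALSE)
}

.rankRow <- function(variable, values, flagGroup) {
    p <- tryCatch(mannWhitney(values[flagGroup], values[!flagGroup])@pValue,
                  error = function(e) NA_real_)
    data.frame(variable = variable, level = "median",
               group1 = stats::median(values[flagGroup]),
               group2 = stats::median(values[!flagGroup]),
               test = "mann_whitney", p_value = p, stringsAsFactors = FALSE)
}

#' Cohort characteristics table with per-variable group comparisons
#'
#' Reproduces the layout of a clinical characteristics table: per-variable
#' counts (or medians) in two groups, with a Pearson chi-square p-value for
#' categorical rows and a Mann-Whitney p-value for age and tumor volume.
#' Grouping \code{"seizure_vs_none"} compares subjects with any seizure
#' history to seizure-free subjects; \code{"frequent_vs_nonfrequent"}
#' compares, among subjects with seizures, frequent (>= 1/month) to
#' non-frequent ones. Degenerate rows (zero margins) carry an NA p-value
#' rather than failing.
#'
#' @param clinical validated clinical data.frame.
#' @param grouping one of \code{"seizure_vs_none"},
#'   \code{"frequent_vs_nonfrequent"}.
#' @return data.frame with columns variable, level, group1, group2, test,
#'   p_value (group1 = seizure or frequent group).
#' @export
cohortSummary <- function(clinical,
                          grouping = c("frequent_vs_nonfrequent",
                                       "seizure_vs_none")) {
    grouping <- match.arg(grouping)
    clinical <- validateClinicalTable(clinical)
    score <- scoreFrequency(clinical$frequency_category)
    if (grouping == "frequent_vs_nonfrequent") {
        clinical <- clinical[clinical$has_seizure, , drop = FALSE]
        score <- score[score > 0L]
        grp <- isFrequent(score)
    } else {
        grp <- as.logical(clinical$has_seizure)
    }
    if (!any(grp) || all(grp))
        stop("one of the comparison groups is empty")
    lobeSets <- strsplit(ifelse(is.na(clinical$lobes), "", clinical$lobes), ";")
    inLobe <- function(lb) vapply(lobeSets, function(s) lb %in% s, logical(1L))
    rows <- list(
        data.frame(variable = "n", level = "subjects", group1 = sum(grp),
                   group2 = sum(!grp), test = "", p_value = NA_real_,
                   stringsAsFactors = FALSE),
        .rankRow("age", clinical$age, grp),
        .summaryRow("age_gt_40", "yes", clinical$age > 40, grp),
        .summaryRow("sex", "male", clinical$sex == "male", grp),
        .summaryRow("hemisphere", "left", clinical$hemisphere == "left", grp))
    for (lb in c("frontal", "temporal", "insula", "parietal", "occipital"))
        rows <- c(rows, list(.summaryRow("lobe", lb, inLobe(lb), grp)))
    rows <- c(rows, list(.rankRow("tumor_volume_cm3",
                                  clinical$tumor_volume_cm3, grp)))
    if (grouping == "frequent_vs_nonfrequent") {
        for (st in setdiff(seizureTypes, "none"))
            rows <- c(rows, list(
                .summaryRow("seizure_type", st, clinical$seizure_type == st, grp)))
    }
    rows <- c(rows,
        list(.summaryRow("asm_use", "yes", as.logical(clinical$asm_use), grp),
             .summaryRow("resection", "gross_total",
                         clinical$resection == "gross_total", grp)))
    for (pt in c("oligodendroglioma", "astrocytoma", "oligoastrocytoma"))
        rows <- c(rows, list(.summaryRow("pathology", pt,
                                         clinical$pathology == pt, grp)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
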