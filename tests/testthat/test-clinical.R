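test_that("frequency scoring and the frequent dichotomy follow the grading rules", {
    expect_identical(scoreFrequency(c("none", "rare_1_2", "monthly",
                                      "weekly", "daily")),
                     c(0L, 1L, 2L, 3L, 4L))
    expect_error(scoreFrequency("biweekly"), "unknown")

    expect_true(isFrequent(2L))
    expect_false(isFrequent(1L))
    expect_error(isFrequent(5L), "0..4")

    ## applied to the reference category counts: 126 frequent, 120 not
    cnt <- referenceCohortTables()$frequency_counts
    scores <- scoreFrequency(rep(names(cnt), cnt))
    expect_equal(sum(isFrequent(scores)), 126L)
    expect_equal(sum(!isFrequent(scores) & scores > 0L), 120L)
    expect_equal(sum(scores == 0L), 106L)

    ## monotone in the clinical ordering; frequent exactly for monthly+
    expect_true(all(diff(scoreFrequency(frequencyLevels)) > 0))
    expect_identical(isFrequent(scoreFrequency(frequencyLevels)),
                     frequencyLevels %in% c("monthly", "weekly", "daily"))
})

test_that("Engel dichotomization maps I to seizure free and II-IV to uncontrolled", {
    expect_equal(dichotomizeEngel(c("I", "II", "III", "IV")),
                 c("seizure_free", rep("uncontrolled", 3)))
    expect_true(is.na(dichotomizeEngel(NA_character_)))  # excluded, no error
    expect_error(dichotomizeEngel("V"), "unknown")
})

test_that("chi-square is Pearson without continuity correction", {
    ## perfect homogeneity
    r <- chiSquareTest(matrix(10, 2, 2))
    expect_equal(r@statistic, 0)
    expect_equal(r@pValue, 1)

    ## diagonal 2x2: direct Pearson formula oracle, all expected = 2.5
    tab <- matrix(c(5, 0, 0, 5), 2)
    exp25 <- matrix(2.5, 2, 2)
    stat0 <- sum((tab - exp25)^2 / exp25)
    r <- chiSquareTest(tab)
    expect_equal(r@statistic, stat0)          # = 10
    expect_equal(r@pValue, pchisq(stat0, 1, lower.tail = FALSE),
                 tolerance = 1e-12)

    ## invariance under simultaneous row and column permutation
    set.seed(61)
    tab <- matrix(rpois(12, 20) + 1, 3, 4)
    r1 <- chiSquareTest(tab)
    r2 <- chiSquareTest(tab[c(2, 3, 1), c(4, 1, 3, 2)])
    expect_equal(r2@statistic, r1@statistic, tolerance = 1e-12)
    expect_equal(r2@df, r1@df)

    ## degenerate margins are refused
    expect_error(chiSquareTest(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "degenerate")
    expect_error(chiSquareTest(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("chi-square reproduces the reference cohort's printed p-values", {
    tabs <- referenceCohortTables()
    expect_equal(round(chiSquareTest(tabs$resection_by_frequency)@pValue, 3), 0.008)
    expect_equal(round(chiSquareTest(tabs$hemisphere_by_seizure)@pValue, 3), 0.004)
    expect_equal(round(chiSquareTest(tabs$frontal_by_seizure)@pValue, 3), 0.004)
    expect_equal(round(chiSquareTest(tabs$asm_by_frequency)@pValue, 3), 0.006)
    expect_lt(chiSquareTest(tabs$seizure_type_by_frequency)@pValue, 0.001)
    expect_equal(formatPValue(chiSquareTest(tabs$seizure_type_by_frequency)@pValue),
                 "<0.001")
})

test_that("Mann-Whitney U matches the exhaustive pairwise-comparison count", {
    ## identical multisets: U = n1*n2/2 and p ~ 1
    r <- mannWhitney(c(1, 2, 2, 3), c(1, 2, 2, 3))
    expect_equal(r@uStatistic, 8)
    expect_equal(r@pValue, 1, tolerance = 1e-9)

    ## complete separation
    r <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
    expect_equal(r@uStatistic, 0)

    ## random tied small samples vs pair-count oracle; U_A + U_B = n1*n2
    set.seed(71)
    for (rep in 1:25) {
        a <- sample(0:4, sample(2:8, 1), replace = TRUE)
        b <- sample(0:4, sample(2:8, 1), replace = TRUE)
        wins <- 0
        for (x in a) for (y in b) wins <- wins + (x > y) + 0.5 * (x == y)
        rA <- mannWhitney(a, b)
        rB <- mannWhitney(b, a)
        expect_equal(rA@uStatistic, wins)
        expect_equal(rA@uStatistic + rB@uStatistic, length(a) * length(b))
        expect_equal(rB@pValue, rA@pValue, tolerance = 1e-9)
    }
    expect_error(mannWhitney(numeric(0), 1:3), "non-empty")
})

test_that("logistic regression recovers the closed-form 2x2 odds ratio and flags separation", {
    ## no-effect case
    set.seed(81)
    y <- rep(c(0, 1), 50)
    x <- rep(c(0, 1), each = 50)
    r <- logisticRegression(y, cbind(grp = x))
    expect_true(r@converged)
    expect_lt(abs(r@coefficients$estimate[2]), 0.5)
    expect_equal(r@coefficients$odds_ratio[2], 1, tolerance = 0.6)

    ## saturated 2x2: OR equals the cross-product ratio to 1e-6 relative
    tab <- referenceCohortTables()$hemisphere_by_seizure
    y2 <- c(rep(1, 145), rep(0, 45), rep(1, 101), rep(0, 61))
    x2 <- c(rep(1, 145 + 45), rep(0, 101 + 61))  # left hemisphere
    r2 <- logisticRegression(y2, cbind(left = x2))
    orHat <- r2@coefficients$odds_ratio[r2@coefficients$term == "left"]
    orRef <- (145 * 61) / (45 * 101)
    expect_equal(orHat, orRef, tolerance = 1e-6)
    expect_equal(log(orHat), log(orRef), tolerance = 1e-6)

    ## perfect separation is flagged and coefficients withheld
    r3 <- logisticRegression(c(0, 0, 0, 1, 1, 1), cbind(x = c(0, 0, 0, 1, 1, 1)))
    expect_true(r3@separation)
    expect_equal(nrow(r3@coefficients), 0L)

    expect_error(logisticRegression(rep(1, 10), cbind(x = rnorm(10))), "constant")
})

test_that("cohort summary reproduces the reference margins and printed tests", {
    cohort <- referenceCohort()
    expect_equal(nrow(cohort), 352L)

    fr <- cohortSummary(cohort, "frequent_vs_nonfrequent")
    nrow_ <- fr[fr$variable == "n", ]
    expect_equal(nrow_$group1, 126)
    expect_equal(nrow_$group2, 120)
    expect_equal(round(fr$p_value[fr$variable == "resection"], 3), 0.008)
    expect_equal(round(fr$p_value[fr$variable == "asm_use"], 3), 0.006)
    expect_equal(round(fr$p_value[fr$variable == "sex"], 3), 0.277)
    fa <- fr[fr$variable == "seizure_type" & fr$level == "focal_aware", ]
    expect_lt(fa$p_value, 0.001)
    expect_equal(c(fa$group1, fa$group2), c(40, 12))

    sz <- cohortSummary(cohort, "seizure_vs_none")
    expect_equal(sz[sz$variable == "n", "group1"], 246)
    expect_equal(sz[sz$variable == "n", "group2"], 106)
    expect_equal(round(sz$p_value[sz$variable == "hemisphere"], 3), 0.004)
    expect_equal(round(sz$p_value[sz$variable == "lobe" & sz$level == "frontal"], 3),
                 0.004)

    ## constant variables degrade to NA p-values, not errors
    set.seed(91)
    dup <- makeClinical(rep(c("monthly", "rare_1_2"), each = 6))
    dup$sex <- "male"; dup$hemisphere <- "left"; dup$resection <- "partial"
    dup$pathology <- "astrocytoma"; dup$age <- 30; dup$tumor_volume_cm3 <- 50
    dup$asm_use <- TRUE
    dup$seizure_type <- "focal_aware"
    s <- cohortSummary(dup, "frequent_vs_nonfrequent")
    expect_true(is.na(s$p_value[s$variable == "sex"]))
    expect_true(is.na(s$p_value[s$variable == "resection"]))

    ## an empty comparison group is an error
    allf <- makeClinical(rep("daily", 10))
    expect_error(cohortSummary(allf, "frequent_vs_nonfrequent"), "empty")
})

test_that("clinical table round-trips through CSV with validation", {
    set.seed(101)
    cl <- makeClinical(c("none", "rare_1_2", "monthly", "daily", "none",
                         "weekly"))
    cl$engel_class[3] <- "II"
    f <- tempfile(fileext = ".csv")
    writeClinicalTable(cl, f)
    back <- readClinicalTable(f)
    expect_equal(back$subject_id, cl$subject_id)
    expect_equal(back$frequency_category, cl$frequency_category)
    expect_identical(back$has_seizure, cl$has_seizure)
    expect_identical(is.na(back$engel_class), is.na(cl$engel_class))

    ## inconsistent seizure flags are rejected
    bad <- cl; bad$has_seizure[1] <- TRUE
    expect_error(validateClinicalTable(bad), "inconsistent")
    expect_error(validateClinicalTable(cl[, -3]), "missing required")
})
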