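test_that("design matrix has the score first, centered nuisance, intercept last", {
    set.seed(111)
    cl <- makeClinical(c("none", "rare_1_2", "monthly", "daily", "weekly",
                         "none"))
    cl$sex <- rep(c("male", "female"), 3)
    d <- buildDesign(cl)
    X <- designMatrix(d)
    expect_identical(colnames(X)[1], "freq_score")
    expect_equal(unname(X[, 1]), c(0, 1, 2, 4, 3, 0))
    expect_identical(colnames(X)[ncol(X)], "intercept")
    nuis <- setdiff(colnames(X), c("freq_score", "intercept"))
    expect_true(all(abs(colMeans(X[, nuis, drop = FALSE])) < 1e-12))

    ## single-sex cohort: sex column dropped with a warning, not an error
    cl2 <- cl; cl2$sex <- "female"
    expect_warning(d2 <- buildDesign(cl2), "sex")
    expect_false("sex" %in% colnames(designMatrix(d2)))

    cl3 <- cl; cl3$age[2] <- NA
    expect_error(buildDesign(cl3), "s02")
})

test_that("voxel-wise GLM matches an independent normal-equations solver", {
    set.seed(121)
    g <- tinyGrid(c(5L, 5L, 4L), c(2, 2, 2))   # 100 voxels
    n <- 30L
    cl <- makeClinical(sample(frequencyLevels, n, replace = TRUE))
    masks <- lapply(seq_len(n), function(i) randomMask(g, runif(1, .2, .6),
                                                       cl$subject_id[i]))
    d <- buildDesign(cl)
    sm <- voxelwiseGLM(masks, d)
    X <- designMatrix(d)
    idx <- which(eligibleVoxels(sm))
    expect_gt(length(idx), 50)
    for (v in idx) {
        y <- vapply(masks, function(m) as.numeric(mapData(m)[v]), numeric(1))
        ## independent oracle: explicit (X'X)^{-1} X'y and the classical SE
        XtXi <- solve(t(X) %*% X)
        bhat <- XtXi %*% t(X) %*% y
        res <- y - X %*% bhat
        s2 <- sum(res^2) / (n - ncol(X))
        tstar <- bhat[1] / sqrt(s2 * XtXi[1, 1])
        expect_equal(sm@beta[v], bhat[1], tolerance = 1e-8)
        expect_equal(sm@tstat[v], tstar, tolerance = 1e-8)
    }
    expect_equal(sm@dfResidual, n - ncol(X))

    ## and against R's own lm at a handful of voxels
    for (v in idx[1:5]) {
        y <- vapply(masks, function(m) as.numeric(mapData(m)[v]), numeric(1))
        fit <- summary(lm(y ~ X[, 1] + X[, 2] + X[, 3] + X[, 4]))
        expect_equal(sm@tstat[v], fit$coefficients["X[, 1]", "t value"],
                     tolerance = 1e-8)
    }
})

test_that("constant-lesion voxels are ineligible and symmetric patterns give t = 0", {
    g <- tinyGrid(c(3L, 3L, 3L), c(2, 2, 2))
    ## 4 subjects; voxel 1 lesioned in all, voxel 2 in none, voxel 3 mixed
    pats <- list(c(1L, 3L), c(1L, 14L), c(1L, 14L), c(1L, 3L))
    cl <- makeClinical(c("none", "rare_1_2", "monthly", "weekly"))
    cl$age <- c(20, 30, 40, 50); cl$sex <- c("male", "male", "female", "female")
    cl$tumor_volume_cm3 <- c(10, 20, 30, 40)
    masks <- Map(function(p, id) maskAt(p, g, id), pats, cl$subject_id)
    ## n = 4 subjects cannot support a 5-column design
    expect_error(buildDesign(cl), "rank deficient")

    ## reduce to score + intercept by making nuisance constant
    cl$age <- 30; cl$sex <- "male"; cl$tumor_volume_cm3 <- 25
    d <- suppressWarnings(buildDesign(cl))
    expect_equal(ncol(designMatrix(d)), 2L)
    sm <- voxelwiseGLM(masks, d)
    expect_false(eligibleVoxels(sm)[1])          # lesioned in all -> constant
    expect_false(eligibleVoxels(sm)[2])          # lesioned in none
    ## voxel 3 (linear index 3): lesion [1,0,0,1] against scores [0,1,2,3]
    expect_true(eligibleVoxels(sm)[3])
    expect_equal(sm@beta[3], 0, tolerance = 1e-12)
    expect_equal(sm@tstat[3], 0, tolerance = 1e-12)
})

test_that("a deterministic lesion-score relationship is flagged with capped t", {
    g <- tinyGrid(c(3L, 3L, 3L), c(2, 2, 2))
    set.seed(131)
    cl <- makeClinical(c("none", "none", "daily", "daily", "none", "daily"))
    cl$age <- 30; cl$sex <- "male"; cl$tumor_volume_cm3 <- 25
    sc <- scoreFrequency(cl$frequency_category)
    masks <- lapply(seq_along(sc), function(i)
        maskAt(if (sc[i] >= 2) c(5L, 6L) else 6L, g, cl$subject_id[i]))
    ## voxel 5 is exactly the indicator of score >= 2; voxel 6 constant
    d <- suppressWarnings(buildDesign(cl))
    sm <- voxelwiseGLM(masks, d)
    expect_true(sm@deterministic[5])
    expect_true(is.finite(sm@tstat[5]))
    expect_gt(sm@tstat[5], 1e100)
})

test_that("nuisance centering, shifting and rescaling leave the frequency t unchanged", {
    set.seed(141)
    g <- tinyGrid(c(4L, 4L, 3L), c(2, 2, 2))
    n <- 25L
    cl <- makeClinical(sample(frequencyLevels, n, replace = TRUE))
    masks <- lapply(seq_len(n), function(i) randomMask(g, 0.4, cl$subject_id[i]))
    d <- buildDesign(cl)
    sm <- voxelwiseGLM(masks, d)
    ## uncentered-refit oracle via lm on the raw covariates
    idx <- which(eligibleVoxels(sm))
    sex <- as.numeric(cl$sex == "male")
    for (v in idx[seq(1, length(idx), length.out = 10)]) {
        y <- vapply(masks, function(m) as.numeric(mapData(m)[v]), numeric(1))
        fit <- summary(lm(y ~ scoreFrequency(cl$frequency_category) + sex +
                              cl$age + cl$tumor_volume_cm3))
        expect_equal(sm@tstat[v], fit$coefficients[2, "t value"],
                     tolerance = 1e-8)
    }
    ## shifted and rescaled nuisance covariates: identical t map
    cl2 <- cl
    cl2$age <- cl$age * 12 + 1000          # months since some epoch
    cl2$tumor_volume_cm3 <- cl$tumor_volume_cm3 * 1000  # mm^3-scale units
    sm2 <- voxelwiseGLM(masks, buildDesign(cl2))
    expect_equal(sm2@tstat[eligibleVoxels(sm2)], sm@tstat[eligibleVoxels(sm)],
                 tolerance = 1e-8)
})

test_that("power map follows the two-sample normal approximation", {
    g <- tinyGrid(c(4L, 4L, 4L), c(2, 2, 2))
    n <- 100L
    counts <- array(0L, gridDims(g))
    counts[1:64] <- rep(c(0L, 25L, 50L, 100L), 16)
    ov <- new("OverlapMap", counts = counts, nSubjects = n, grid = g)
    pm <- powerMap(ov, effectSize = 1.0, alpha = 0.05)
    expect_equal(mapData(pm)[1], 0)                      # k = 0
    expect_equal(mapData(pm)[4], 0)                      # k = n
    expect_equal(mapData(pm)[3],
                 pnorm(1.0 * sqrt(50 * 50 / 100) - qnorm(0.975)),
                 tolerance = 1e-12)                      # Phi(5 - 1.96)
    expect_gt(mapData(pm)[3], mapData(pm)[2])            # maximal at n/2
    ## cross-check against power.t.test at large n (normal limit)
    ptt <- power.t.test(n = 50, delta = 1, sd = 1, sig.level = 0.05)$power
    expect_equal(mapData(pm)[3], ptt, tolerance = 5e-3)

    em <- eligibleMask(pm, 0.8)
    expect_false(any(em[counts == 0L]))
    ## strict inequality at the threshold
    pv <- array(0, gridDims(g)); pv[1:3] <- c(0.79, 0.80, 0.81)
    pm2 <- new("PowerMap", power = pv, effectSize = 1, alpha = 0.05, grid = g)
    em2 <- eligibleMask(pm2, 0.8)
    expect_identical(which(em2), 3L)
    ## monotone: raising the threshold never adds voxels
    expect_true(all(which(eligibleMask(pm, 0.9)) %in% which(eligibleMask(pm, 0.8))))
})
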