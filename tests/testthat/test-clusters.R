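## Build matching StatMap / PermutationNull pairs by hand for threshold tests.
statNullPair <- function(tvals, thr, grid) {
    elig <- array(!is.na(tvals), gridDims(grid))
    tv <- tvals; tv[!elig] <- NA_real_
    sm <- new("StatMap", beta = tv, tstat = tv, eligible = elig,
              deterministic = array(FALSE, gridDims(grid)),
              nSubjects = 20L, dfResidual = 15L, grid = grid)
    nl <- new("PermutationNull", threshold = thr, eligible = elig,
              nPermutations = 100L, alpha = 0.05, seed = 1L,
              mode = "voxelwise", scheme = "score", grid = grid)
    list(stat = sm, null = nl)
}

test_that("thresholding is strict and restricted to eligible voxels", {
    g <- tinyGrid(c(3L, 3L, 3L), c(2, 2, 2))
    tv <- array(NA_real_, gridDims(g))
    tv[1:4] <- c(2.0, 3.0, 3.0, 5.0)
    thr <- array(NA_real_, gridDims(g))
    thr[1:4] <- c(3.0, 3.0, 2.5, 2.5)
    p <- statNullPair(tv, thr, g)
    ret <- applyThreshold(p$stat, p$null)
    expect_identical(which(ret), c(3L, 4L))    # t == threshold not retained
    ## observed below threshold everywhere -> empty mask
    thr2 <- thr; thr2[1:4] <- 10
    p2 <- statNullPair(tv, thr2, g)
    expect_equal(sum(applyThreshold(p2$stat, p2$null)), 0L)
    ## mismatched eligible masks are refused
    nlBad <- p$null; nlBad@eligible[9] <- TRUE; nlBad@threshold[9] <- 1
    expect_error(applyThreshold(p$stat, nlBad), "different eligible")
})

test_that("cluster extraction respects connectivity and reports sorted peaks", {
    g <- tinyGrid(c(5L, 5L, 5L), c(2, 2, 2))
    tv <- array(0, gridDims(g))

    ## single retained voxel
    ret <- array(FALSE, gridDims(g)); ret[2, 2, 2] <- TRUE
    tv[2, 2, 2] <- 4
    cr <- extractClusters(ret, tv, 26L, grid = g)
    expect_equal(nrow(clusterTable(cr)), 1L)
    expect_equal(clusterTable(cr)$n_voxels, 1L)
    expect_equal(unlist(clusterTable(cr)[1, c("peak_x", "peak_y", "peak_z")],
                        use.names = FALSE), c(1L, 1L, 1L))
    expect_equal(unlist(clusterTable(cr)[1, c("peak_x1", "peak_y1", "peak_z1")],
                        use.names = FALSE), c(2L, 2L, 2L))

    ## face-adjacent pair: one cluster even under 6-connectivity
    ret <- array(FALSE, gridDims(g)); ret[2, 2, 2] <- ret[3, 2, 2] <- TRUE
    expect_equal(nrow(clusterTable(extractClusters(ret, tv, 6L, grid = g))), 1L)

    ## diagonal-only pair: two clusters under 6, one under 26
    ret <- array(FALSE, gridDims(g)); ret[2, 2, 2] <- ret[3, 3, 3] <- TRUE
    expect_equal(nrow(clusterTable(extractClusters(ret, tv, 6L, grid = g))), 2L)
    expect_equal(nrow(clusterTable(extractClusters(ret, tv, 26L, grid = g))), 1L)

    ## empty retained mask: empty result, not an error
    ret <- array(FALSE, gridDims(g))
    cr0 <- extractClusters(ret, tv, 26L, grid = g)
    expect_equal(nrow(clusterTable(cr0)), 0L)
    expect_equal(max(mapData(cr0)), 0L)

    ## two clusters sorted by peak t descending; within-cluster peak-t ties
    ## break to the lexicographically smallest coordinate
    ret <- array(FALSE, gridDims(g))
    ret[1:2, 1, 1] <- TRUE          # cluster A, peak t 3 at two voxels
    ret[5, 5, 5] <- TRUE            # cluster B, t 7
    tv2 <- array(0, gridDims(g))
    tv2[1:2, 1, 1] <- 3; tv2[5, 5, 5] <- 7
    cr2 <- extractClusters(ret, tv2, 26L, grid = g)
    tab <- clusterTable(cr2)
    expect_equal(tab$peak_t, c(7, 3))
    expect_equal(tab$cluster, c(1L, 2L))
    expect_equal(unlist(tab[2, c("peak_x", "peak_y", "peak_z")],
                        use.names = FALSE), c(0L, 0L, 0L))
    expect_equal(mapData(cr2)[5, 5, 5], 1L)     # relabeled in sorted order
    expect_equal(mapData(cr2)[1, 1, 1], 2L)
})

test_that("component labeling matches a flood-fill oracle on random masks", {
    set.seed(171)
    g <- tinyGrid(c(10L, 10L, 10L), c(2, 2, 2))
    tv <- array(0, gridDims(g))
    for (conn in c(6L, 18L, 26L)) {
        ret <- array(runif(1000) < 0.25, gridDims(g))
        cr <- extractClusters(ret, tv, conn, grid = g)
        oracle <- floodFillLabels(ret, conn)
        expect_true(samePartition(mapData(cr), oracle))
        ## sizes agree as multisets
        expect_equal(sort(clusterTable(cr)$n_voxels),
                     sort(as.integer(table(oracle[oracle > 0L]))))
    }
})

test_that("involvement labeling agrees with the overlap map at the peak", {
    set.seed(181)
    g <- tinyGrid(c(6L, 6L, 6L), c(2, 2, 2))
    masks <- lapply(1:15, function(i) randomMask(g, 0.3, sprintf("s%02d", i)))
    peak <- c(2L, 3L, 4L)
    inv <- labelInvolvement(masks, peak)
    expect_equal(sum(inv),
                 mapData(overlapMap(masks))[peak[1] + 1, peak[2] + 1, peak[3] + 1])
    expect_named(inv, sprintf("s%02d", 1:15))
    empty <- lesionVolume("e", array(0L, gridDims(g)), g)
    expect_false(labelInvolvement(list(empty), peak)[[1]])
    expect_error(labelInvolvement(masks, c(6L, 0L, 0L)), "outside")
})

test_that("involvement-frequency comparison behaves at the extremes", {
    inv <- c(rep(TRUE, 6), rep(FALSE, 8))
    ## complete separation: involved all daily, spared all none
    r <- involvementVsFrequency(inv, c(rep(4L, 6), rep(0L, 8)))
    expect_equal(r@uStatistic, 48)  # involved win every pair
    expect_lt(r@pValue, 0.01)
    ## identical score distributions: p ~ 1
    r2 <- involvementVsFrequency(c(TRUE, TRUE, FALSE, FALSE),
                                 c(2L, 3L, 2L, 3L))
    expect_equal(r2@pValue, 1, tolerance = 1e-9)
    ## subset restriction and empty-group error
    expect_error(involvementVsFrequency(rep(TRUE, 5), rep(1L, 5)), "non-empty")
    r3 <- involvementVsFrequency(c(TRUE, FALSE, TRUE, FALSE),
                                 c(4L, 0L, 2L, 4L),
                                 subset = c(TRUE, TRUE, TRUE, FALSE))
    expect_equal(r3@n1 + r3@n2, 3L)
})
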