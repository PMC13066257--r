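## Shared fixtures, all built in code at test time.

tinyGrid <- function(dims = c(6L, 6L, 6L), vs = c(2, 2, 2)) {
    templateGrid(dims, vs)
}

## A mask with 1s at the given 1-based linear indices.
maskAt <- function(idx, grid, id = "s") {
    a <- array(0L, gridDims(grid))
    a[idx] <- 1L
    lesionVolume(id, a, grid)
}

## Bernoulli(p) random mask (uses the caller's RNG state).
randomMask <- function(grid, p = 0.3, id = "s") {
    a <- array(rbinom(prod(gridDims(grid)), 1L, p), gridDims(grid))
    lesionVolume(id, a, grid)
}

## Minimal valid clinical table for n subjects with given frequency
## categories; continuous covariates drawn from the caller's RNG.
makeClinical <- function(categories, ids = sprintf("s%02d", seq_along(categories))) {
    n <- length(categories)
    data.frame(
        subject_id = ids,
        age = runif(n, 16, 68),
        sex = sample(c("male", "female"), n, replace = TRUE, prob = c(.6, .4)),
        tumor_volume_cm3 = runif(n, 5, 200),
        has_seizure = categories != "none",
        seizure_type = ifelse(categories != "none",
                              "focal_to_bilateral_tonic_clonic", "none"),
        frequency_category = categories,
        asm_use = categories != "none",
        resection = sample(c("gross_total", "partial"), n, replace = TRUE),
        pathology = sample(c("oligodendroglioma", "astrocytoma",
                             "oligoastrocytoma"), n, replace = TRUE),
        hemisphere = sample(c("left", "right"), n, replace = TRUE),
        lobes = "frontal",
        engel_class = NA_character_,
        stringsAsFactors = FALSE)
}

## Independent flood-fill connected-component oracle: seeded set growth
## over an explicit neighbor set, no shared code with the implementation.
floodFillLabels <- function(mask, connectivity) {
    dims <- dim(mask)
    off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
    off <- switch(as.character(connectivity),
                  "6"  = off[rowSums(abs(off)) == 1, , drop = FALSE],
                  "18" = off[rowSums(abs(off)) <= 2, , drop = FALSE],
                  "26" = off)
    lab <- array(0L, dims)
    nxt <- 0L
    fg <- which(mask)
    for (start in fg) {
        if (lab[start] > 0L) next
        nxt <- nxt + 1L
        frontier <- start
        lab[start] <- nxt
        while (length(frontier)) {
            newFrontier <- integer()
            for (v in frontier) {
                c0 <- arrayInd(v, dims)
                for (r in seq_len(nrow(off))) {
                    cc <- c0 + off[r, ]
                    if (any(cc < 1L) || any(cc > dims)) next
                    li <- cc[1] + dims[1] * (cc[2] - 1L + dims[2] * (cc[3] - 1L))
                    if (mask[li] && lab[li] == 0L) {
                        lab[li] <- nxt
                        newFrontier <- c(newFrontier, li)
                    }
                }
            }
            frontier <- newFrontier
        }
    }
    lab
}

## Compare two labelings up to relabeling: same partition of foreground.
samePartition <- function(a, b) {
    if (!identical(which(a > 0L), which(b > 0L))) return(FALSE)
    fg <- which(a > 0L)
    key <- paste(a[fg], b[fg])
    length(unique(key)) == length(unique(a[fg])) &&
        length(unique(a[fg])) == length(unique(b[fg]))
}
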