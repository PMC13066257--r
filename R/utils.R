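#' @include AllClasses.R
NULL

#' Format a p-value for reporting
#'
#' Three decimals, with values below 0.001 rendered \code{"<0.001"} — the
#' convention used in clinical tables.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @examples
#' formatPValue(c(0.0079771, 2e-5))
#' @export
formatPValue <- function(p) {
    ifelse(p < 0.001, "<0.001", sprintf("= %.3f", p))
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG state afterwards. All stochastic entry points funnel through
## this so results are pure functions of their seed argument.
withSeed <- function(seed, expr) {
    if (is.null(seed) || is.na(seed))
        stop("an explicit integer seed is required")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

sameGrid <- function(a, b) {
    ga <- templateGridOf(a); gb <- templateGridOf(b)
    all(ga@dims == gb@dims) && all(abs(ga@voxelSize - gb@voxelSize) < 1e-9)
}

stopIfGridMismatch <- function(a, b, what = "objects") {
    if (!sameGrid(a, b))
        stop(sprintf("%s live on different template grids", what))
    invisible(TRUE)
}

## 0-based (x,y,z) coordinates of TRUE voxels of a logical/binary array.
voxelCoords <- function(arr) {
    which(arr != 0, arr.ind = TRUE) - 1L
}

## Linear index (1-based, column-major) of a 0-based voxel coordinate.
coordToLinear <- function(coord, dims) {
    1L + coord[1L] + dims[1L] * (coord[2L] + dims[2L] * coord[3L])
}

checkInsideGrid <- function(coord, grid) {
    if (length(coord) != 3L || any(coord < 0L) || any(coord >= grid@dims))
        stop(sprintf("voxel coordinate (%s) lies outside the %s grid",
                     paste(coord, collapse = ","),
                     paste(grid@dims, collapse = "x")))
    invisible(TRUE)
}
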