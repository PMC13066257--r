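#' @include methods.R
NULL

.stripNiftiExt <- function(path) {
    sub("\\.nii(\\.gz)?$", "", basename(path))
}

#' Read a binary lesion mask from a NIfTI file
#'
#' Reads a 3D NIfTI volume, binarizes it at 0.5 (masks resampled with
#' interpolation may carry fractional values), and validates it against the
#' target grid. A mask for an enrolled subject must contain at least one
#' lesioned voxel.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param grid optional \linkS4class{TemplateGrid} the mask must live on. If
#'   omitted, the grid is taken from the file header. If supplied and the
#'   file grid differs, the call fails unless \code{resample = TRUE}.
#' @param resample logical; nearest-neighbor resample onto \code{grid} when
#'   the file grid differs (default FALSE).
#' @param subjectId subject identifier; defaults to the filename stem.
#' @return A \linkS4class{LesionVolume}.
#' @seealso \code{\link{writeMap}}, \code{\link{resampleNearest}}
#' @export
readMask <- function(path, grid = NULL, resample = FALSE,
                     subjectId = .stripNiftiExt(path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    pd <- RNifti::pixdim(img)
    d <- dim(arr)
    ## tolerate a trailing singleton volume dimension, nothing more
    while (length(d) > 3L && d[length(d)] == 1L) {
        dim(arr) <- d[-length(d)]
        d <- dim(arr)
    }
    if (length(d) != 3L)
        stop(sprintf("'%s' is not a 3D volume (found %d non-singleton dimensions)",
                     path, length(d)))
    fileGrid <- templateGrid(d, pd[seq_len(3L)])
    bin <- array(as.integer(arr >= 0.5), dim = d)
    vol <- lesionVolume(subjectId, bin, fileGrid)
    if (!is.null(grid) && !sameGrid(vol, grid)) {
        if (!resample)
            stop(sprintf("mask '%s' grid (%s) does not match target grid (%s); set resample = TRUE to resample",
                         subjectId, paste(d, collapse = "x"),
                         paste(grid@dims, collapse = "x")))
        vol <- resampleNearest(vol, grid)
    }
    if (sum(vol@data) == 0L)
        stop(sprintf("mask '%s' is empty: an enrolled subject must have at least one lesioned voxel",
                     subjectId))
    vol
}

.writeNiftiArray <- function(arr, path, grid) {
    arr[is.na(arr)] <- 0
    nim <- RNifti::asNifti(arr)
    RNifti::pixdim(nim) <- grid@voxelSize
    RNifti::writeNifti(nim, path)
    invisible(path)
}

#' @rdname writeMap
#' @export
setMethod("writeMap", "array", function(x, path, grid) {
    .writeNiftiArray(x, path, templateGridOf(grid))
})
#' @rdname writeMap
#' @export
setMethod("writeMap", "LesionVolume", function(x, path) {
    .writeNiftiArray(x@data, path, x@grid)
})
#' @rdname writeMap
#' @export
setMethod("writeMap", "OverlapMap", function(x, path) {
    .writeNiftiArray(x@counts, path, x@grid)
})
#' @rdname writeMap
#' @export
setMethod("writeMap", "StatMap", function(x, path) {
    .writeNiftiArray(x@tstat, path, x@grid)
})
#' @rdname writeMap
#' @export
setMethod("writeMap", "PowerMap", function(x, path) {
    .writeNiftiArray(x@power, path, x@grid)
})
#' @rdname writeMap
#' @export
setMethod("writeMap", "PermutationNull", function(x, path) {
    .writeNiftiArray(x@threshold, path, x@grid)
})
#' @rdname writeMap
#' @export
setMethod("writeMap", "ClusterResult", function(x, path) {
    .writeNiftiArray(x@labels, path, x@grid)
})

#' Nearest-neighbor resampling of a binary mask onto another grid
#'
#' Maps each target voxel centre to physical (mm) space, assuming both
#' grids share orientation and a common corner origin, and copies the value
#' of the nearest source voxel. Binarity is preserved exactly; no
#' interpolation is performed.
#'
#' @param mask a \linkS4class{LesionVolume}.
#' @param target a \linkS4class{TemplateGrid}.
#' @return A \linkS4class{LesionVolume} on \code{target}.
#' @export
resampleNearest <- function(mask, target) {
    stopifnot(is(mask, "LesionVolume"), is(target, "TemplateGrid"))
    if (sameGrid(mask, target)) {
        return(lesionVolume(mask@subjectId, mask@data, target))
    }
    src <- mask@grid
    idx <- lapply(seq_len(3L), function(a) {
        centres <- (seq_len(target@dims[a]) - 0.5) * target@voxelSize[a]
        i <- floor(centres / src@voxelSize[a]) + 1
        pmin(pmax(as.integer(i), 1L), src@dims[a])
    })
    out <- mask@data[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
    dim(out) <- target@dims
    lesionVolume(mask@subjectId, out, target)
}

#' Lesion-overlap map of a cohort
#'
#' Per-voxel count of subjects whose lesion covers the voxel. The overlap
#' map determines where the cohort supports lesion-symptom inference at
#' all, and feeds the statistical power map.
#'
#' @param masks non-empty list of \linkS4class{LesionVolume}s on one grid.
#' @return An \linkS4class{OverlapMap}.
#' @seealso \code{\link{powerMap}}
#' @export
overlapMap <- function(masks) {
    if (!length(masks)) stop("'masks' must be a non-empty list")
    grid <- templateGridOf(masks[[1L]])
    for (m in masks) stopIfGridMismatch(m, grid, "lesion masks")
    counts <- Reduce(`+`, lapply(masks, function(m) m@data))
    storage.mode(counts) <- "integer"
    new("OverlapMap", counts = counts, nSubjects = length(masks), grid = grid)
}

#' Lesion volume in cubic centimetres
#'
#' @param mask a \linkS4class{LesionVolume}.
#' @return lesioned-voxel count times voxel volume, in cm^3.
#' @examples
#' g <- templateGrid(c(10L, 10L, 10L), c(1, 1, 1))
#' a <- array(0L, dim = c(10, 10, 10)); a[1:10, 1:10, 1:10] <- 1L
#' maskVolumeCm3(lesionVolume("s1", a, g))  # 1000 mm^3 = 1 cm^3
#' @export
maskVolumeCm3 <- function(mask) {
    stopifnot(is(mask, "LesionVolume"))
    sum(mask@data) * prod(mask@grid@voxelSize) / 1000
}
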