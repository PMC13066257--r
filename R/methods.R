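#' @include AllGenerics.R
NULL

## -- accessors ---------------------------------------------------------------

#' @rdname gridDims
#' @export
setMethod("gridDims", "TemplateGrid", function(x) x@dims)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "TemplateGrid", function(x) x@voxelSize)

.gridded <- c("LesionVolume", "OverlapMap", "StatMap", "PermutationNull",
              "PowerMap", "ClusterResult", "GroundTruth", "SimulationConfig")
for (.cl in .gridded) {
    setMethod("templateGridOf", .cl, function(x) x@grid)
    setMethod("gridDims", .cl, function(x) x@grid@dims)
    setMethod("voxelSize", .cl, function(x) x@grid@voxelSize)
}
setMethod("templateGridOf", "TemplateGrid", function(x) x)

#' @rdname subjectId
#' @export
setMethod("subjectId", "LesionVolume", function(x) x@subjectId)

#' @rdname mapData
#' @export
setMethod("mapData", "LesionVolume", function(x) x@data)
#' @rdname mapData
#' @export
setMethod("mapData", "OverlapMap", function(x) x@counts)
#' @rdname mapData
#' @export
setMethod("mapData", "StatMap", function(x) x@tstat)
#' @rdname mapData
#' @export
setMethod("mapData", "PowerMap", function(x) x@power)
#' @rdname mapData
#' @export
setMethod("mapData", "PermutationNull", function(x) x@threshold)
#' @rdname mapData
#' @export
setMethod("mapData", "ClusterResult", function(x) x@labels)

#' @rdname eligibleVoxels
#' @export
setMethod("eligibleVoxels", "StatMap", function(x) x@eligible)
#' @rdname eligibleVoxels
#' @export
setMethod("eligibleVoxels", "PermutationNull", function(x) x@eligible)

#' @rdname clusterTable
#' @export
setMethod("clusterTable", "ClusterResult", function(x) x@table)

#' @rdname designMatrix
#' @export
setMethod("designMatrix", "SymptomDesign", function(x) x@design)

## -- show --------------------------------------------------------------------

setMethod("show", "TemplateGrid", function(object) {
    cat(sprintf("TemplateGrid: %s voxels at %s mm\n",
                paste(object@dims, collapse = " x "),
                paste(format(object@voxelSize), collapse = " x ")))
})

setMethod("show", "LesionVolume", function(object) {
    cat(sprintf("LesionVolume '%s': %d lesioned voxel(s) (%.2f cm^3) on %s\n",
                object@subjectId, sum(object@data),
                maskVolumeCm3(object),
                paste(object@grid@dims, collapse = "x")))
})

setMethod("show", "OverlapMap", function(object) {
    cat(sprintf("OverlapMap of %d subjects on %s; max overlap %d, covered voxels %d\n",
                object@nSubjects, paste(object@grid@dims, collapse = "x"),
                max(object@counts), sum(object@counts > 0L)))
})

setMethod("show", "SymptomDesign", function(object) {
    cat(sprintf("SymptomDesign: %d subjects x %d columns [%s]\n",
                nrow(object@design), ncol(object@design),
                paste(colnames(object@design), collapse = ", ")))
    if (length(object@dropped))
        cat("  dropped constant nuisance column(s):",
            paste(object@dropped, collapse = ", "), "\n")
})

setMethod("show", "StatMap", function(object) {
    ne <- sum(object@eligible)
    tmax <- if (ne) max(object@tstat[object@eligible]) else NA_real_
    cat(sprintf("StatMap: %d eligible voxel(s), n = %d, df = %d, max t = %s\n",
                ne, object@nSubjects, object@dfResidual,
                ifelse(is.na(tmax), "NA", sprintf("%.3f", tmax))))
})

setMethod("show", "PermutationNull", function(object) {
    cat(sprintf("PermutationNull: %d permutations, alpha = %g, %s/%s, seed = %d\n",
                object@nPermutations, object@alpha, object@mode,
                object@scheme, object@seed))
})

setMethod("show", "PowerMap", function(object) {
    cat(sprintf("PowerMap (d = %g, alpha = %g): %d voxel(s) with power > 0.8\n",
                object@effectSize, object@alpha, sum(object@power > 0.8)))
})

setMethod("show", "ClusterResult", function(object) {
    cat(sprintf("ClusterResult: %d cluster(s), connectivity %d\n",
                nrow(object@table), object@connectivity))
    if (nrow(object@table)) print(utils::head(object@table, 5L))
})

setMethod("show", "ContingencyResult", function(object) {
    cat(sprintf("Pearson chi-square = %.4f, df = %d, p %s\n",
                object@statistic, object@df, formatPValue(object@pValue)))
})

setMethod("show", "RankTestResult", function(object) {
    cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), p %s\n",
                object@uStatistic, object@n1, object@n2,
                formatPValue(object@pValue)))
})

setMethod("show", "LogisticResult", function(object) {
    if (!object@converged || object@separation) {
        cat("LogisticResult: fit flagged (non-convergence or separation); coefficients withheld\n")
    } else {
        cat(sprintf("LogisticResult (n = %d):\n", object@n))
        print(object@coefficients, digits = 4L)
    }
})

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: n = %d on %s; ROI centre (%s) r = %g; gamma = %g, noise sd = %g, seed = %d\n",
        object@nSubjects, paste(object@grid@dims, collapse = "x"),
        paste(object@roiCenter, collapse = ","), object@roiRadius,
        object@effectGamma, object@noiseSd, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: ROI of %d voxel(s); %d/%d subjects with involvement > 0\n",
                sum(object@roi), sum(object@involvement > 0),
                length(object@involvement)))
})
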