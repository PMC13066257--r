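#' @include AllClasses.R
NULL

#' Grid dimensions accessor
#' @param x an object carrying a \linkS4class{TemplateGrid}.
#' @return integer triple of voxels per axis.
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' Voxel size accessor
#' @param x an object carrying a \linkS4class{TemplateGrid}.
#' @return numeric triple of voxel edge lengths in mm.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Template grid accessor
#' @param x an object carrying a grid.
#' @return the \linkS4class{TemplateGrid}.
#' @export
setGeneric("templateGridOf", function(x) standardGeneric("templateGridOf"))

#' Subject identifier accessor
#' @param x a \linkS4class{LesionVolume}.
#' @return character scalar.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' Raw volumetric data accessor
#' @param x a volume-like object.
#' @return the underlying 3D array.
#' @export
setGeneric("mapData", function(x) standardGeneric("mapData"))

#' Eligible-voxel mask accessor
#' @param x a \linkS4class{StatMap} or \linkS4class{PermutationNull}.
#' @return 3D logical array of tested voxels.
#' @export
setGeneric("eligibleVoxels", function(x) standardGeneric("eligibleVoxels"))

#' Cluster table accessor
#' @param x a \linkS4class{ClusterResult}.
#' @return data.frame of clusters (size, peak coordinates, peak t).
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' Design matrix accessor
#' @param x a \linkS4class{SymptomDesign}.
#' @return the numeric design matrix.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' Write a volume to a NIfTI file
#'
#' @param x the object to write (a \linkS4class{LesionVolume}, a bare 3D
#'   array, or a map-carrying object such as a \linkS4class{StatMap},
#'   \linkS4class{PowerMap}, \linkS4class{OverlapMap},
#'   \linkS4class{PermutationNull} or \linkS4class{ClusterResult}).
#' @param path output filename (.nii or .nii.gz).
#' @param grid the \linkS4class{TemplateGrid}, required only for bare
#'   arrays.
#' @param ... passed on to methods.
#' @return the path, invisibly.
#' @export
setGeneric("writeMap", function(x, path, ...) standardGeneric("writeMap"))
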