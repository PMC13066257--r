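#' @import methods
NULL

## Central S4 containers. Voxel indices are 0-based (x, y, z) internally;
## reporting functions additionally print 1-based coordinates.

#' TemplateGrid: the common voxel grid of the template space
#'
#' Describes the regular 3D grid shared by all lesion masks and statistical
#' maps: the number of voxels along each axis and the voxel edge lengths in
#' millimetres. All masks entering an analysis must live on one grid; the
#' grid abstracts the stereotactic template space the masks were registered
#' to, at whatever resolution is convenient.
#'
#' @slot dims integer(3), voxels per axis (x, y, z); all >= 1.
#' @slot voxelSize numeric(3), voxel edge lengths in mm; all > 0.
#' @export
setClass("TemplateGrid",
    representation(dims = "integer", voxelSize = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(object@dims) != 3L || any(is.na(object@dims)))
            msg <- c(msg, "'dims' must be an integer triple")
        else if (any(object@dims < 1L))
            msg <- c(msg, "all grid dims must be >= 1")
        if (length(object@voxelSize) != 3L || any(is.na(object@voxelSize)))
            msg <- c(msg, "'voxelSize' must be a numeric triple")
        else if (any(object@voxelSize <= 0))
            msg <- c(msg, "all voxel sizes must be > 0")
        if (is.null(msg)) TRUE else msg
    })

#' Construct a TemplateGrid
#'
#' @param dims voxels per axis, integer triple (x, y, z).
#' @param voxelSize voxel edge lengths in mm, numeric triple (default
#'   isotropic 4 mm, a convenient desk-scale resolution; the method itself
#'   is resolution-agnostic).
#' @return A \linkS4class{TemplateGrid}.
#' @examples
#' templateGrid(c(24L, 28L, 24L), c(4, 4, 4))
#' @export
templateGrid <- function(dims, voxelSize = c(4, 4, 4)) {
    new("TemplateGrid", dims = as.integer(dims),
        voxelSize = as.numeric(voxelSize))
}

#' LesionVolume: one subject's binary tumor mask
#'
#' A binary (0/1) 3D array on a \linkS4class{TemplateGrid}, with 1 marking
#' voxels the segmented tumor occupies. Masks read from disk must contain at
#' least one lesioned voxel; in-memory volumes may be empty (useful for
#' edge-case handling).
#'
#' @slot subjectId character scalar identifier.
#' @slot data 3D integer array with values in \{0, 1\}.
#' @slot grid the \linkS4class{TemplateGrid} the data lives on.
#' @export
setClass("LesionVolume",
    representation(subjectId = "character", data = "array",
                   grid = "TemplateGrid"),
    validity = function(object) {
        msg <- NULL
        if (length(object@subjectId) != 1L)
            msg <- c(msg, "'subjectId' must be a single string")
        d <- dim(object@data)
        if (length(d) != 3L)
            msg <- c(msg, "'data' must be a 3D array")
        else if (!all(d == object@grid@dims))
            msg <- c(msg, sprintf("mask shape (%s) does not match grid dims (%s)",
                                  paste(d, collapse = "x"),
                                  paste(object@grid@dims, collapse = "x")))
        if (!all(object@data %in% c(0L, 1L)))
            msg <- c(msg, "mask values must be exactly {0, 1}")
        if (is.null(msg)) TRUE else msg
    })

#' Construct a LesionVolume
#'
#' @param subjectId subject identifier.
#' @param data 3D array; coerced to integer 0/1 (values must already be
#'   binary — use \code{\link{readMask}} for thresholding of float inputs).
#' @param grid a \linkS4class{TemplateGrid}.
#' @return A \linkS4class{LesionVolume}.
#' @export
lesionVolume <- function(subjectId, data, grid) {
    storage.mode(data) <- "integer"
    new("LesionVolume", subjectId = as.character(subjectId), data = data,
        grid = grid)
}

#' OverlapMap: per-voxel lesion counts across a cohort
#'
#' @slot counts 3D non-negative integer array: number of subjects whose
#'   lesion covers each voxel.
#' @slot nSubjects number of masks summed.
#' @slot grid the shared \linkS4class{TemplateGrid}.
#' @export
setClass("OverlapMap",
    representation(counts = "array", nSubjects = "integer",
                   grid = "TemplateGrid"),
    validity = function(object) {
        msg <- NULL
        if (!all(dim(object@counts) == object@grid@dims))
            msg <- c(msg, "counts shape does not match grid dims")
        if (any(object@counts < 0L) || any(object@counts > object@nSubjects))
            msg <- c(msg, "counts must lie in [0, nSubjects]")
        if (is.null(msg)) TRUE else msg
    })

#' SymptomDesign: the per-subject regression design matrix
#'
#' Column 1 is the ordinal seizure-frequency score (0-4); the remaining
#' columns are mean-centered nuisance covariates (sex, age, tumor volume)
#' and a trailing intercept. One row per subject, aligned with the lesion
#' masks by \code{subjectIds}.
#'
#' @slot design numeric matrix with labelled columns.
#' @slot subjectIds character vector, one id per row.
#' @slot scoreColumn index of the symptom (frequency score) column.
#' @slot dropped character vector of nuisance columns removed because they
#'   were constant in the cohort.
#' @export
setClass("SymptomDesign",
    representation(design = "matrix", subjectIds = "character",
                   scoreColumn = "integer", dropped = "character"),
    validity = function(object) {
        msg <- NULL
        if (nrow(object@design) != length(object@subjectIds))
            msg <- c(msg, "one subject id per design row required")
        if (qr(object@design)$rank < ncol(object@design))
            msg <- c(msg, "design matrix is rank deficient")
        sc <- object@design[, object@scoreColumn]
        if (any(sc < 0 | sc > 4 | sc != round(sc)))
            msg <- c(msg, "frequency scores must be integers in 0..4")
        if (is.null(msg)) TRUE else msg
    })

#' StatMap: per-voxel regression coefficient and t-statistic volumes
#'
#' Result of the mass-univariate GLM: at every eligible voxel, binary lesion
#' status was regressed on the symptom design, and the frequency-score
#' coefficient and its t-statistic stored. Voxels where lesion status is
#' constant across subjects are marked ineligible. Voxels fit with zero
#' residual (deterministic association) carry a capped, machine-finite t and
#' are flagged.
#'
#' @slot beta 3D numeric array, frequency coefficient (NA off-eligible).
#' @slot tstat 3D numeric array, t-statistic (NA off-eligible).
#' @slot eligible 3D logical array of tested voxels.
#' @slot deterministic 3D logical array flagging zero-residual fits.
#' @slot nSubjects number of subjects.
#' @slot dfResidual residual degrees of freedom (n - p).
#' @slot grid the \linkS4class{TemplateGrid}.
#' @export
setClass("StatMap",
    representation(beta = "array", tstat = "array", eligible = "array",
                   deterministic = "array", nSubjects = "integer",
                   dfResidual = "integer", grid = "TemplateGrid"),
    validity = function(object) {
        msg <- NULL
        dims <- object@grid@dims
        for (nm in c("beta", "tstat", "eligible", "deterministic"))
            if (!all(dim(slot(object, nm)) == dims))
                msg <- c(msg, sprintf("'%s' shape does not match grid", nm))
        if (any(!is.na(object@tstat) & !object@eligible))
            msg <- c(msg, "t defined outside the eligible mask")
        if (object@dfResidual < 1L)
            msg <- c(msg, "residual degrees of freedom must be >= 1")
        if (is.null(msg)) TRUE else msg
    })

#' PermutationNull: per-voxel permutation thresholds
#'
#' Empirical null thresholds obtained by permuting the frequency-score
#' column of the design across subjects and recomputing the voxel-wise t.
#' In \code{"voxelwise"} mode each voxel carries the ceiling((1-alpha)*B)-th
#' order statistic of its own B permuted t-values; in \code{"max_stat"} mode
#' every eligible voxel carries the same familywise threshold taken from the
#' permutation distribution of the image-wide maximum t.
#'
#' @slot threshold 3D numeric array (NA off-eligible).
#' @slot eligible 3D logical array the null was built on.
#' @slot nPermutations number of permutations.
#' @slot alpha level.
#' @slot seed RNG seed used.
#' @slot mode "voxelwise" or "max_stat".
#' @slot scheme "score" (permute the score column only) or "freedman_lane".
#' @slot grid the \linkS4class{TemplateGrid}.
#' @export
setClass("PermutationNull",
    representation(threshold = "array", eligible = "array",
                   nPermutations = "integer", alpha = "numeric",
                   seed = "integer", mode = "character", scheme = "character",
                   grid = "TemplateGrid"),
    validity = function(object) {
        msg <- NULL
        if (object@nPermutations < 1L)
            msg <- c(msg, "nPermutations must be >= 1")
        if (object@alpha <= 0 || object@alpha >= 1)
            msg <- c(msg, "alpha must lie in (0, 1)")
        if (any(!is.na(object@threshold) & !object@eligible))
            msg <- c(msg, "thresholds defined outside the eligible mask")
        if (is.null(msg)) TRUE else msg
    })

#' PowerMap: per-voxel statistical power for a fixed effect size
#'
#' Two-sample power of detecting a standardized mean difference d between
#' lesioned and non-lesioned subjects at each voxel, given the observed
#' lesioned/spared split there. Power is 0 where the split is degenerate
#' (no lesioned, or no spared, subject).
#'
#' @slot power 3D numeric array in [0, 1].
#' @slot effectSize assumed standardized difference d.
#' @slot alpha two-sided level.
#' @slot grid the \linkS4class{TemplateGrid}.
#' @export
setClass("PowerMap",
    representation(power = "array", effectSize = "numeric", alpha = "numeric",
                   grid = "TemplateGrid"),
    validity = function(object) {
        msg <- NULL
        if (any(object@power < 0 | object@power > 1, na.rm = TRUE))
            msg <- c(msg, "power values must lie in [0, 1]")
        if (object@effectSize <= 0)
            msg <- c(msg, "effect size must be > 0")
        if (is.null(msg)) TRUE else msg
    })

#' ClusterResult: supra-threshold connected components
#'
#' Connected components of the retained (supra-threshold) mask under 6-, 18-
#' or 26-neighborhood connectivity, with per-cluster size, peak voxel and
#' peak t. Clusters are sorted by peak t descending; ties are broken by the
#' lexicographically smallest peak coordinate.
#'
#' @slot labels 3D integer array, 0 = background, k = cluster k.
#' @slot table data.frame: cluster, n_voxels, peak coordinates (0- and
#'   1-based) and peak_t.
#' @slot connectivity 6, 18 or 26.
#' @slot grid the \linkS4class{TemplateGrid}.
#' @export
setClass("ClusterResult",
    representation(labels = "array", table = "data.frame",
                   connectivity = "integer", grid = "TemplateGrid"),
    validity = function(object) {
        msg <- NULL
        if (!object@connectivity %in% c(6L, 18L, 26L))
            msg <- c(msg, "connectivity must be 6, 18 or 26")
        if (is.null(msg)) TRUE else msg
    })

#' ContingencyResult: Pearson chi-square test of a contingency table
#'
#' @slot statistic chi-square statistic (no continuity correction).
#' @slot df degrees of freedom, (r-1)(c-1).
#' @slot pValue upper-tail p-value.
#' @slot table the observed counts.
#' @export
setClass("ContingencyResult",
    representation(statistic = "numeric", df = "integer", pValue = "numeric",
                   table = "matrix"),
    validity = function(object) {
        msg <- NULL
        if (object@statistic < 0) msg <- c(msg, "statistic must be >= 0")
        if (object@pValue < 0 || object@pValue > 1)
            msg <- c(msg, "p-value must lie in [0, 1]")
        if (is.null(msg)) TRUE else msg
    })

#' RankTestResult: Mann-Whitney U test
#'
#' @slot uStatistic U for the first group (pairs won + half the ties).
#' @slot pValue two-sided p from the tie-corrected normal approximation.
#' @slot n1,n2 group sizes.
#' @export
setClass("RankTestResult",
    representation(uStatistic = "numeric", pValue = "numeric",
                   n1 = "integer", n2 = "integer"),
    validity = function(object) {
        msg <- NULL
        nn <- as.numeric(object@n1) * as.numeric(object@n2)
        if (object@uStatistic < 0 || object@uStatistic > nn)
            msg <- c(msg, "U must lie in [0, n1*n2]")
        if (object@pValue < 0 || object@pValue > 1)
            msg <- c(msg, "p-value must lie in [0, 1]")
        if (is.null(msg)) TRUE else msg
    })

#' LogisticResult: multivariate logistic regression fit
#'
#' Maximum-likelihood logistic fit with Wald inference. When the fit does
#' not converge or the data are (quasi-)separated, the result is flagged and
#' the coefficient table is withheld.
#'
#' @slot coefficients data.frame: term, estimate, se, z, p_value, odds_ratio,
#'   or_low, or_high (95\% Wald CI); empty when not converged.
#' @slot converged logical.
#' @slot separation logical, TRUE when (quasi-)separation was detected.
#' @slot n number of observations.
#' @export
setClass("LogisticResult",
    representation(coefficients = "data.frame", converged = "logical",
                   separation = "logical", n = "integer"))

#' SimulationConfig: parameters of the synthetic lesion-symptom cohort
#'
#' Defines the generative model used for validation: blob-shaped lesions of
#' realistic volume on a template grid, a hidden spherical epileptogenic
#' region of interest (ROI), and an ordinal seizure-frequency category
#' produced by thresholding a latent score
#' \deqn{latent = \gamma \cdot frac + \beta_{sex}(sex-\bar{sex}) +
#'   \beta_{age}(age-\bar{age}) + \beta_{vol}(vol-\bar{vol}) + \epsilon,}
#' where \code{frac} is the fraction of the ROI the lesion covers and
#' \eqn{\epsilon \sim N(0, noiseSd^2)}. The four ascending cut points map
#' the latent score to the categories none / rare / monthly / weekly /
#' daily.
#'
#' @slot grid \linkS4class{TemplateGrid}.
#' @slot nSubjects cohort size (>= 10).
#' @slot roiCenter 0-based voxel coordinate of the ROI centre.
#' @slot roiRadius ROI radius in voxels.
#' @slot lesionVolumeMean,lesionVolumeSd lesion volume distribution (cm^3),
#'   normal clamped below at \code{lesionVolumeMin}.
#' @slot lesionVolumeMin lower clamp (cm^3).
#' @slot effectGamma latent-scale coefficient of ROI-involvement fraction.
#' @slot covariateBetas named numeric (sex, age, volume) latent-scale
#'   coefficients of the centered covariates.
#' @slot noiseSd latent noise standard deviation.
#' @slot cutPoints 4 strictly ascending latent thresholds.
#' @slot centerMargin lesion centres are sampled uniformly at least this
#'   many voxels from the grid faces.
#' @slot seed RNG seed; the whole cohort is a pure function of the config.
#' @export
setClass("SimulationConfig",
    representation(grid = "TemplateGrid", nSubjects = "integer",
                   roiCenter = "integer", roiRadius = "numeric",
                   lesionVolumeMean = "numeric", lesionVolumeSd = "numeric",
                   lesionVolumeMin = "numeric", effectGamma = "numeric",
                   covariateBetas = "numeric", noiseSd = "numeric",
                   cutPoints = "numeric", centerMargin = "integer",
                   seed = "integer"),
    validity = function(object) {
        msg <- NULL
        if (object@nSubjects < 10L)
            msg <- c(msg, "nSubjects must be >= 10")
        if (length(object@cutPoints) != 4L ||
            any(diff(object@cutPoints) <= 0))
            msg <- c(msg, "cutPoints must be 4 strictly ascending values")
        if (any(object@roiCenter < 0L) ||
            any(object@roiCenter >= object@grid@dims))
            msg <- c(msg, "roiCenter must lie inside the grid")
        if (object@roiRadius <= 0)
            msg <- c(msg, "roiRadius must be > 0")
        if (!all(c("sex", "age", "volume") %in% names(object@covariateBetas)))
            msg <- c(msg, "covariateBetas needs named entries sex, age, volume")
        if (length(object@seed) != 1L || is.na(object@seed))
            msg <- c(msg, "an explicit integer seed is required")
        if (is.null(msg)) TRUE else msg
    })

#' GroundTruth: the hidden generative state of a simulated cohort
#'
#' @slot roi 3D logical array, the planted epileptogenic region.
#' @slot involvement per-subject ROI-involvement fraction in [0, 1].
#' @slot latent per-subject latent symptom score.
#' @slot categories realized frequency categories.
#' @slot grid the \linkS4class{TemplateGrid}.
#' @export
setClass("GroundTruth",
    representation(roi = "array", involvement = "numeric", latent = "numeric",
                   categories = "character", grid = "TemplateGrid"),
    validity = function(object) {
        msg <- NULL
        if (any(object@involvement < 0 | object@involvement > 1))
            msg <- c(msg, "involvement fractions must lie in [0, 1]")
        if (length(object@latent) != length(object@categories))
            msg <- c(msg, "latent and categories lengths differ")
        if (is.null(msg)) TRUE else msg
    })
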