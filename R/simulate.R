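#' @include vlsm.R
NULL

#' Construct a SimulationConfig
#'
#' Defaults describe a desk-scale validation cohort: a 24 x 28 x 24 grid
#' at 4 mm (small enough that a 1,000-permutation run takes seconds, while
#' the grid-to-lesion size ratio matches a whole-brain template), lesion
#' volumes drawn from a normal with mean 80.8 and sd 60.0 cm^3 clamped
#' below at 1 cm^3 (the scale reported for surgical low-grade-glioma
#' cohorts), age uniform on 16-68 years, 60\% male, and cut points
#' calibrated so that an unlesioned (null) cohort reproduces the reference
#' category mix of roughly 30\% no seizure, 34\% rare, 21\% monthly, 7\%
#' weekly, 7\% daily. The planted effect defaults to effectGamma = 5 with
#' unit latent noise: a subject whose lesion fully covers the hidden ROI
#' is pushed about five noise standard deviations up the latent scale, a
#' strong effect under which involvement essentially determines a high
#' frequency category and the mapping should recover the ROI reliably.
#'
#' @param grid \linkS4class{TemplateGrid}.
#' @param nSubjects cohort size.
#' @param roiCenter 0-based ROI centre; default the grid centre.
#' @param roiRadius ROI radius in voxels (default 3).
#' @param lesionVolumeMean,lesionVolumeSd,lesionVolumeMin lesion-volume
#'   distribution in cm^3.
#' @param effectGamma latent coefficient of the ROI-involvement fraction.
#' @param covariateBetas named numeric: latent coefficients of the centered
#'   sex, age (per year) and volume (per cm^3) covariates. Small non-zero
#'   defaults so the nuisance regression has something to remove.
#' @param noiseSd latent noise sd.
#' @param cutPoints 4 ascending latent thresholds.
#' @param centerMargin minimum distance (voxels) of lesion centres from the
#'   grid faces.
#' @param seed explicit RNG seed (required).
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(grid = templateGrid(c(24L, 28L, 24L), c(4, 4, 4)),
                             nSubjects = 60L,
                             roiCenter = gridDims(grid) %/% 2L,
                             roiRadius = 3,
                             lesionVolumeMean = 80.8, lesionVolumeSd = 60.0,
                             lesionVolumeMin = 1,
                             effectGamma = 5,
                             covariateBetas = c(sex = 0.1, age = 0.005,
                                                volume = 0.002),
                             noiseSd = 1,
                             cutPoints = stats::qnorm(c(0.301, 0.642,
                                                        0.855, 0.926)),
                             centerMargin = 4L, seed) {
    if (missing(seed)) stop("an explicit integer seed is required")
    new("SimulationConfig", grid = grid, nSubjects = as.integer(nSubjects),
        roiCenter = as.integer(roiCenter), roiRadius = as.numeric(roiRadius),
        lesionVolumeMean = lesionVolumeMean, lesionVolumeSd = lesionVolumeSd,
        lesionVolumeMin = lesionVolumeMin, effectGamma = effectGamma,
        covariateBetas = covariateBetas, noiseSd = noiseSd,
        cutPoints = cutPoints, centerMargin = as.integer(centerMargin),
        seed = as.integer(seed))
}

## Spherical ROI mask around a 0-based centre.
.sphereMask <- function(grid, center, radius) {
    d <- grid@dims
    ax <- (seq_len(d[1L]) - 1L - center[1L])^2
    ay <- (seq_len(d[2L]) - 1L - center[2L])^2
    az <- (seq_len(d[3L]) - 1L - center[3L])^2
    outer(outer(ax, ay, `+`), az, `+`) <= radius^2
}

## Deterministic blob given centre (0-based), voxel count and per-axis
## anisotropy: the k voxels nearest the centre under an ellipsoidal metric
## (an ellipsoid ball, hence connected by construction). Ties broken by
## array order, so the result is a pure function of its arguments.
.makeBlob <- function(grid, center, nVoxels, aniso = c(1, 1, 1)) {
    d <- grid@dims
    if (nVoxels > prod(d))
        stop("target lesion volume exceeds the grid volume")
    ax <- ((seq_len(d[1L]) - 1L - center[1L]) / aniso[1L])^2
    ay <- ((seq_len(d[2L]) - 1L - center[2L]) / aniso[2L])^2
    az <- ((seq_len(d[3L]) - 1L - center[3L]) / aniso[3L])^2
    d2 <- outer(outer(ax, ay, `+`), az, `+`)
    sel <- order(d2)[seq_len(nVoxels)]
    out <- array(0L, d)
    out[sel] <- 1L
    out
}

.sampleCenter <- function(grid, margin) {
    d <- grid@dims
    lo <- pmin(margin, (d - 1L) %/% 2L)
    hi <- pmax(d - 1L - margin, lo)
    vapply(seq_len(3L), function(a)
        if (hi[a] > lo[a]) sample(lo[a]:hi[a], 1L) else lo[a], integer(1L))
}

#' Simulate one blob-shaped lesion
#'
#' A connected binary blob: the target number of voxels nearest a sampled
#' (or given) centre under a randomly anisotropic ellipsoidal metric. The
#' voxel count equals the target volume rounded to the grid's voxel
#' volume.
#'
#' @param grid \linkS4class{TemplateGrid}.
#' @param targetVolumeCm3 desired lesion volume (cm^3).
#' @param center optional 0-based centre; sampled uniformly (with a 4-voxel
#'   face margin) when NULL.
#' @param seed explicit RNG seed (required).
#' @param subjectId identifier for the returned volume.
#' @return A \linkS4class{LesionVolume}.
#' @export
simulateLesion <- function(grid, targetVolumeCm3, center = NULL, seed,
                           subjectId = "sim") {
    if (missing(seed)) stop("an explicit integer seed is required")
    withSeed(seed, {
        if (is.null(center)) center <- .sampleCenter(grid, 4L)
        checkInsideGrid(as.integer(center), grid)
        k <- max(1L, as.integer(round(targetVolumeCm3 * 1000 /
                                      prod(grid@voxelSize))))
        aniso <- stats::runif(3L, 0.7, 1.4)
        lesionVolume(subjectId, .makeBlob(grid, center, k, aniso), grid)
    })
}

#' Simulate a full lesion-symptom cohort
#'
#' Generates, per subject: a blob lesion with volume ~ Normal(mean, sd)
#' clamped at the minimum; age ~ Uniform(16, 68); sex ~ Bernoulli(0.6
#' male); the ROI-involvement fraction |lesion intersect ROI| / |ROI|; a
#' latent symptom score gamma * fraction + covariate effects (centered) +
#' Gaussian noise; and the frequency category obtained by cutting the
#' latent score at the config's cut points. Categorical clinical
#' covariates (seizure type, ASM use, resection, pathology, Engel class)
#' are drawn with marginals typical of surgical low-grade-glioma cohorts;
#' hemisphere and a coarse lobe label are derived from the lesion
#' geometry. The whole cohort is a pure function of the config, seed
#' included.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{masks} (list of
#'   \linkS4class{LesionVolume}), \code{clinical} (validated clinical
#'   data.frame) and \code{truth} (a \linkS4class{GroundTruth}).
#' @export
simulateCohort <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    grid <- config@grid
    roi <- .sphereMask(grid, config@roiCenter, config@roiRadius)
    nroi <- sum(roi)
    n <- config@nSubjects
    b <- config@covariateBetas
    withSeed(config@seed, {
        vols <- pmax(config@lesionVolumeMin,
                     stats::rnorm(n, config@lesionVolumeMean,
                                  config@lesionVolumeSd))
        age <- stats::runif(n, 16, 68)
        sexMale <- stats::rbinom(n, 1L, 0.6)
        masks <- vector("list", n)
        frac <- numeric(n)
        centers <- matrix(0L, n, 3L)
        for (i in seq_len(n)) {
            ctr <- .sampleCenter(grid, config@centerMargin)
            centers[i, ] <- ctr
            k <- max(1L, as.integer(round(vols[i] * 1000 /
                                          prod(grid@voxelSize))))
            aniso <- stats::runif(3L, 0.7, 1.4)
            masks[[i]] <- lesionVolume(sprintf("sim%03d", i),
                                       .makeBlob(grid, ctr, k, aniso), grid)
            frac[i] <- sum(masks[[i]]@data[roi]) / nroi
        }
        realVol <- vapply(masks, maskVolumeCm3, numeric(1L))
        latent <- config@effectGamma * frac +
            b[["sex"]] * (sexMale - 0.6) +
            b[["age"]] * (age - 42) +
            b[["volume"]] * (realVol - config@lesionVolumeMean) +
            stats::rnorm(n, 0, config@noiseSd)
        cat5 <- frequencyLevels[findInterval(latent, config@cutPoints) + 1L]
        hasSz <- cat5 != "none"
        freq <- isFrequent(scoreFrequency(cat5))
        stype <- ifelse(hasSz,
                        sample(seizureTypes[1:3], n, replace = TRUE,
                               prob = c(52, 26, 168)),
                        "none")
        asm <- ifelse(hasSz, stats::rbinom(n, 1L, 239 / 246),
                      stats::rbinom(n, 1L, 31 / 106)) == 1L
        resec <- ifelse(stats::rbinom(n, 1L, 165 / 352) == 1L,
                        "gross_total", "partial")
        patho <- sample(c("oligodendroglioma", "astrocytoma",
                          "oligoastrocytoma"), n, replace = TRUE,
                        prob = c(66, 123, 163))
        engel <- rep(NA_character_, n)
        unc <- stats::rbinom(n, 1L, stats::plogis(-1.1 + 1.0 * freq)) == 1L
        engel[hasSz & !unc] <- "I"
        engel[hasSz & unc] <- sample(c("II", "III", "IV"), sum(hasSz & unc),
                                     replace = TRUE, prob = c(5, 3, 2))
        d <- grid@dims
        hemi <- ifelse(centers[, 1L] < d[1L] / 2, "left", "right")
        lobe <- ifelse(centers[, 2L] >= 2 * d[2L] / 3, "frontal",
                ifelse(centers[, 2L] >= d[2L] / 3,
                       ifelse(abs(centers[, 1L] - d[1L] / 2) < d[1L] / 4,
                              "insula", "temporal"),
                       ifelse(centers[, 3L] >= d[3L] / 2,
                              "parietal", "occipital")))
        clinical <- data.frame(
            subject_id = vapply(masks, subjectId, character(1L)),
            age = age,
            sex = ifelse(sexMale == 1L, "male", "female"),
            tumor_volume_cm3 = realVol,
            has_seizure = hasSz,
            seizure_type = stype,
            frequency_category = cat5,
            asm_use = asm,
            resection = resec,
            pathology = patho,
            hemisphere = hemi,
            lobes = lobe,
            engel_class = engel,
            stringsAsFactors = FALSE)
        truth <- new("GroundTruth", roi = roi, involvement = frac,
                     latent = latent, categories = cat5, grid = grid)
        list(masks = masks, clinical = validateClinicalTable(clinical),
             truth = truth)
    })
}

#' Voxel-level recovery metrics against the planted ROI
#'
#' Confusion counts of the retained mask versus the ground-truth ROI,
#' restricted to the eligible voxels (only there could the method have
#' spoken at all).
#'
#' @param retained 3D logical array from \code{\link{applyThreshold}}.
#' @param truth a \linkS4class{GroundTruth}.
#' @param eligible 3D logical array of tested voxels.
#' @return named list: sensitivity, specificity, dice, and the raw counts
#'   tp, fp, fn, tn.
#' @export
recoveryMetrics <- function(retained, truth, eligible) {
    stopifnot(is(truth, "GroundTruth"))
    if (!all(dim(retained) == truth@grid@dims) ||
        !all(dim(eligible) == truth@grid@dims))
        stop("masks must share the ground-truth grid")
    if (!any(eligible)) stop("eligible set is empty")
    e <- which(eligible)
    roi <- truth@roi[e]
    ret <- retained[e]
    tp <- sum(ret & roi); fp <- sum(ret & !roi)
    fn <- sum(!ret & roi); tn <- sum(!ret & !roi)
    list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn)
                else NA_real_,
         tp = tp, fp = fp, fn = fn, tn = tn)
}
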