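#' @include clusters.R simulate.R reference-cohort.R
NULL

.pkgVersion <- function() {
    as.character(utils::packageVersion("glioVLSM"))
}

## Write a run manifest: config snapshot, seed, package version, input
## checksums, timestamp. Every output directory gets exactly one.
.writeManifest <- function(dir, command, params, inputs = character()) {
    checks <- if (length(inputs))
        as.list(tools::md5sum(inputs)) else list()
    manifest <- list(command = command,
                     package = "glioVLSM",
                     version = .pkgVersion(),
                     parameters = params,
                     input_md5 = checks,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
}

.configSnapshot <- function(config) {
    list(grid_dims = config@grid@dims, voxel_size = config@grid@voxelSize,
         n_subjects = config@nSubjects, roi_center = config@roiCenter,
         roi_radius = config@roiRadius,
         lesion_volume_mean = config@lesionVolumeMean,
         lesion_volume_sd = config@lesionVolumeSd,
         lesion_volume_min = config@lesionVolumeMin,
         effect_gamma = config@effectGamma,
         covariate_betas = as.list(config@covariateBetas),
         noise_sd = config@noiseSd, cut_points = config@cutPoints,
         center_margin = config@centerMargin, seed = config@seed)
}

#' Write a simulated cohort to disk
#'
#' Materializes a simulated cohort in the layout the analysis pipeline
#' consumes: one uncompressed NIfTI mask per subject named
#' \code{masks/<subject_id>.nii}, \code{clinical.csv}, the ground-truth
#' ROI as \code{roi.nii}, the full ground truth as
#' \code{ground_truth.json}, and a \code{manifest.json} echoing every
#' generation parameter. Rerunning with an identical config reproduces
#' byte-identical masks and CSV.
#'
#' @param config a \linkS4class{SimulationConfig} (carries its own seed).
#' @param dir output directory (created if needed).
#' @return the simulated cohort (as \code{\link{simulateCohort}}),
#'   invisibly.
#' @export
writeSimulatedCohort <- function(config, dir) {
    stopifnot(is(config, "SimulationConfig"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
    cohort <- simulateCohort(config)
    maskDir <- file.path(dir, "masks")
    dir.create(maskDir, showWarnings = FALSE)
    for (m in cohort$masks)
        writeMap(m, file.path(maskDir, paste0(subjectId(m), ".nii")))
    writeClinicalTable(cohort$clinical, file.path(dir, "clinical.csv"))
    .writeNiftiArray(array(as.integer(cohort$truth@roi), gridDims(config)),
                     file.path(dir, "roi.nii"), config@grid)
    jsonlite::write_json(
        list(roi_center = config@roiCenter, roi_radius = config@roiRadius,
             involvement = cohort$truth@involvement,
             latent = cohort$truth@latent,
             categories = cohort$truth@categories),
        file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    .writeManifest(dir, "simulate", .configSnapshot(config))
    invisible(cohort)
}

.readMaskDir <- function(masksDir, ids) {
    files <- list.files(masksDir, pattern = "\\.nii(\\.gz)?$",
                        full.names = TRUE)
    stems <- .stripNiftiExt(files)
    missing <- setdiff(ids, stems)
    extra <- setdiff(stems, ids)
    if (length(missing) || length(extra))
        stop("mask files and clinical subject_ids do not match.",
             if (length(missing)) paste0(" Missing mask(s): ",
                 paste(missing, collapse = ", ")) else "",
             if (length(extra)) paste0(" Unmatched mask file(s): ",
                 paste(extra, collapse = ", ")) else "")
    files <- files[match(ids, stems)]
    lapply(files, readMask)
}

#' Run the full lesion-symptom mapping pipeline
#'
#' Orchestrates the analysis end to end: align masks with the clinical
#' table, build the symptom design, compute the lesion-overlap and power
#' maps, screen voxels at power > powerThreshold, fit the voxel-wise GLM,
#' build the permutation null, threshold, extract clusters, and test
#' frequency scores by involvement of the top peak. With an output
#' directory, all maps (t, power, permutation threshold, retained mask,
#' cluster labels, overlap counts) are written as NIfTI alongside the
#' cluster table, the involvement vector and a run manifest.
#'
#' @param masks list of \linkS4class{LesionVolume}s, or a directory of
#'   NIfTI masks whose filename stems (case-sensitive) are the clinical
#'   subject_ids.
#' @param clinical validated clinical data.frame, or a CSV path.
#' @param seed explicit RNG seed for the permutations (required).
#' @param alpha voxel-wise level (default 0.05).
#' @param nPermutations permutations (default 1000).
#' @param connectivity cluster connectivity 6/18/26 (default 26).
#' @param powerD assumed effect size of the power screen (default 1.0).
#' @param powerThreshold power cutoff (default 0.8, strict).
#' @param scheme permutation scheme, \code{"score"} (default) or
#'   \code{"freedman_lane"}.
#' @param mode thresholding mode, \code{"voxelwise"} (default) or
#'   \code{"max_stat"}.
#' @param includeNoSeizure keep seizure-free subjects (score 0) in the
#'   model (default TRUE; the score scale explicitly includes 0 = no
#'   seizure history).
#' @param outputDir optional output directory.
#' @return list: design, overlap, power, stat, null, retained, clusters,
#'   involvement (logical vector or NULL when no cluster), rankTest (a
#'   \linkS4class{RankTestResult} or NULL), clinical (the analyzed table).
#' @export
vlsmPipeline <- function(masks, clinical, seed,
                         alpha = 0.05, nPermutations = 1000L,
                         connectivity = 26L, powerD = 1.0,
                         powerThreshold = 0.8,
                         scheme = c("score", "freedman_lane"),
                         mode = c("voxelwise", "max_stat"),
                         includeNoSeizure = TRUE, outputDir = NULL) {
    scheme <- match.arg(scheme)
    mode <- match.arg(mode)
    if (missing(seed)) stop("an explicit integer seed is required")
    inputPaths <- character()
    if (is.character(clinical)) {
        inputPaths <- clinical
        clinical <- readClinicalTable(clinical)
    } else clinical <- validateClinicalTable(clinical)
    if (is.character(masks)) {
        masks <- .readMaskDir(masks, clinical$subject_id)
    } else {
        ids <- vapply(masks, subjectId, character(1L))
        if (!identical(sort(ids), sort(as.character(clinical$subject_id))))
            stop("mask subject ids and clinical subject_ids do not match: ",
                 paste(union(setdiff(ids, clinical$subject_id),
                             setdiff(clinical$subject_id, ids)),
                       collapse = ", "))
        masks <- masks[match(clinical$subject_id, ids)]
    }
    if (!includeNoSeizure) {
        keep <- clinical$has_seizure
        clinical <- clinical[keep, , drop = FALSE]
        masks <- masks[keep]
    }
    design <- buildDesign(clinical)
    ov <- overlapMap(masks)
    pw <- powerMap(ov, effectSize = powerD, alpha = alpha)
    elig <- eligibleMask(pw, powerThreshold)
    if (!any(elig))
        stop("no voxel passes the power screen; the cohort's lesion overlap is too sparse")
    stat <- voxelwiseGLM(masks, design, elig)
    null <- permutationNull(masks, design, eligibleVoxels(stat),
                            nPermutations = nPermutations, alpha = alpha,
                            seed = seed, scheme = scheme, mode = mode)
    retained <- applyThreshold(stat, null)
    clusters <- extractClusters(retained, stat, connectivity)
    involvement <- NULL
    rankTest <- NULL
    ctab <- clusterTable(clusters)
    if (nrow(ctab)) {
        peak <- as.integer(ctab[1L, c("peak_x", "peak_y", "peak_z")])
        involvement <- labelInvolvement(masks, peak)
        scores <- scoreFrequency(clinical$frequency_category)
        rankTest <- tryCatch(involvementVsFrequency(involvement, scores),
                             error = function(e) NULL)
    }
    res <- list(design = design, overlap = ov, power = pw, stat = stat,
                null = null, retained = retained, clusters = clusters,
                involvement = involvement, rankTest = rankTest,
                clinical = clinical)
    if (!is.null(outputDir)) {
        dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
        writeMap(stat, file.path(outputDir, "t_map.nii"))
        writeMap(pw, file.path(outputDir, "power_map.nii"))
        writeMap(null, file.path(outputDir, "threshold_map.nii"))
        writeMap(ov, file.path(outputDir, "overlap_map.nii"))
        .writeNiftiArray(array(as.integer(retained), gridDims(stat)),
                         file.path(outputDir, "retained_mask.nii"), stat@grid)
        writeMap(clusters, file.path(outputDir, "cluster_labels.nii"))
        utils::write.csv(ctab, file.path(outputDir, "clusters.csv"),
                         row.names = FALSE)
        if (!is.null(involvement))
            utils::write.csv(
                data.frame(subject_id = names(involvement),
                           involved = involvement, row.names = NULL),
                file.path(outputDir, "involvement.csv"), row.names = FALSE)
        .writeManifest(outputDir, "vlsm",
                       list(alpha = alpha, n_permutations = nPermutations,
                            seed = as.integer(seed),
                            connectivity = as.integer(connectivity),
                            power_d = powerD,
                            power_threshold = powerThreshold,
                            scheme = scheme, mode = mode,
                            include_no_seizure = includeNoSeizure,
                            n_subjects = nrow(clinical)),
                       inputs = inputPaths)
    }
    res
}

#' Univariate screen and multivariate model of the surgical seizure outcome
#'
#' Restricted to subjects with preoperative seizures and a recorded Engel
#' class, dichotomized as Class I (seizure free) versus Classes II-IV
#' (uncontrolled). Candidate predictors are screened univariately with the
#' chi-square test; those with p strictly below \code{enterP} enter a
#' multivariate logistic regression.
#'
#' @param clinical validated clinical data.frame.
#' @param enterP entry cutoff for the multivariate model (default 0.05,
#'   strict inequality).
#' @return list: \code{n} subjects analyzed, \code{univariate} data.frame
#'   (predictor, p_value, entered), \code{multivariate} a
#'   \linkS4class{LogisticResult} or NULL when nothing entered.
#' @export
engelOutcomeAnalysis <- function(clinical, enterP = 0.05) {
    clinical <- validateClinicalTable(clinical)
    keep <- clinical$has_seizure & !is.na(dichotomizeEngel(clinical$engel_class))
    cl <- clinical[keep, , drop = FALSE]
    if (nrow(cl) < 10L)
        stop("too few subjects with a recorded Engel outcome")
    y <- dichotomizeEngel(cl$engel_class) == "uncontrolled"
    score <- scoreFrequency(cl$frequency_category)
    preds <- list(
        frequent_seizures = isFrequent(score),
        focal_aware = cl$seizure_type == "focal_aware",
        oligodendroglioma = cl$pathology == "oligodendroglioma",
        partial_resection = cl$resection == "partial",
        male = cl$sex == "male",
        age_gt_40 = cl$age > 40,
        left_hemisphere = cl$hemisphere == "left")
    pvals <- vapply(preds, function(x) {
        tryCatch(chiSquareTest(.twoByTwo(x, y))@pValue,
                 error = function(e) NA_real_)
    }, numeric(1L))
    entered <- !is.na(pvals) & pvals < enterP
    uni <- data.frame(predictor = names(preds), p_value = unname(pvals),
                      entered = unname(entered), stringsAsFactors = FALSE)
    multi <- NULL
    if (any(entered)) {
        Xm <- vapply(preds[entered], as.numeric, numeric(nrow(cl)))
        multi <- tryCatch(logisticRegression(y, Xm), error = function(e) NULL)
    }
    list(n = nrow(cl), univariate = uni, multivariate = multi)
}

#' Clinical characteristics report
#'
#' Computes the grouped cohort summaries (seizure vs none, frequent vs
#' non-frequent) and, when Engel outcomes are present, the outcome screen
#' with its multivariate logistic model. With an output directory the
#' summaries are written as CSV and the whole report as JSON.
#'
#' @param clinical validated clinical data.frame or CSV path.
#' @param outputDir optional output directory.
#' @return list: seizure_vs_none, frequent_vs_nonfrequent (data.frames),
#'   outcome (list or NULL).
#' @export
clinicalReport <- function(clinical, outputDir = NULL) {
    inputPaths <- character()
    if (is.character(clinical)) {
        inputPaths <- clinical
        clinical <- readClinicalTable(clinical)
    } else clinical <- validateClinicalTable(clinical)
    res <- list(
        seizure_vs_none = tryCatch(
            cohortSummary(clinical, "seizure_vs_none"),
            error = function(e) NULL),
        frequent_vs_nonfrequent = tryCatch(
            cohortSummary(clinical, "frequent_vs_nonfrequent"),
            error = function(e) NULL),
        outcome = tryCatch(engelOutcomeAnalysis(clinical),
                           error = function(e) NULL))
    if (!is.null(outputDir)) {
        dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
        for (nm in c("seizure_vs_none", "frequent_vs_nonfrequent"))
            if (!is.null(res[[nm]]))
                utils::write.csv(res[[nm]],
                                 file.path(outputDir, paste0(nm, ".csv")),
                                 row.names = FALSE)
        out <- res
        if (!is.null(out$outcome$multivariate))
            out$outcome$multivariate <- list(
                converged = out$outcome$multivariate@converged,
                separation = out$outcome$multivariate@separation,
                coefficients = out$outcome$multivariate@coefficients)
        jsonlite::write_json(out, file.path(outputDir, "clinical_report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        .writeManifest(outputDir, "clinical",
                       list(n_subjects = nrow(clinical)),
                       inputs = inputPaths)
    }
    res
}

#' Read a pipeline configuration from YAML
#'
#' Reads the YAML configuration consumed by the command-line interface and
#' fills package defaults for absent keys. Recognized keys: alpha, n_perm,
#' seed, connectivity, threshold_mode, permutation_scheme, power_d,
#' power_threshold, include_no_seizure, and for simulation grid_dims,
#' voxel_size, n_subjects, roi_center, roi_radius, lesion_volume_mean/sd,
#' effect_gamma, noise_sd. Stochastic commands refuse to run without an
#' explicit seed.
#'
#' @param path YAML file.
#' @return named list of settings.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    defaults <- list(alpha = 0.05, n_perm = 1000L, connectivity = 26L,
                     threshold_mode = "voxelwise",
                     permutation_scheme = "score", power_d = 1.0,
                     power_threshold = 0.8, include_no_seizure = TRUE)
    for (nm in names(defaults))
        if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    cfg
}
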