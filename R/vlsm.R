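#' @include clinical.R imaging-io.R
NULL

#' Build the symptom design matrix
#'
#' One row per subject with columns [freq_score, sex, age, tumor_volume,
#' intercept]: the ordinal seizure-frequency score of interest, then the
#' nuisance covariates whose effect is regressed out of the voxel-wise
#' model. Nuisance columns are mean-centered (which leaves the
#' frequency-score t-statistic unchanged but keeps the intercept
#' interpretable); a nuisance column that is constant in the cohort (e.g.
#' sex in a single-sex cohort) is dropped with a warning, since it would
#' make the design rank deficient.
#'
#' @param clinical validated clinical data.frame (see
#'   \code{\link{validateClinicalTable}}); sex is coded male = 1,
#'   female = 0.
#' @return A \linkS4class{SymptomDesign}.
#' @export
buildDesign <- function(clinical) {
    clinical <- validateClinicalTable(clinical)
    needed <- c("age", "sex", "tumor_volume_cm3", "frequency_category")
    for (col in needed) {
        bad <- is.na(clinical[[col]]) | clinical[[col]] == ""
        if (any(bad))
            stop(sprintf("missing %s for subject(s): %s", col,
                         paste(clinical$subject_id[bad], collapse = ", ")))
    }
    score <- scoreFrequency(clinical$frequency_category)
    nuis <- cbind(sex = as.numeric(clinical$sex == "male"),
                  age = as.numeric(clinical$age),
                  tumor_volume = as.numeric(clinical$tumor_volume_cm3))
    keep <- apply(nuis, 2L, function(v) length(unique(v)) > 1L)
    if (!all(keep))
        warning("dropping constant nuisance column(s): ",
                paste(colnames(nuis)[!keep], collapse = ", "))
    dropped <- colnames(nuis)[!keep]
    nuis <- nuis[, keep, drop = FALSE]
    nuis <- scale(nuis, center = TRUE, scale = FALSE)
    X <- cbind(freq_score = as.numeric(score), nuis,
               intercept = rep(1, nrow(clinical)))
    new("SymptomDesign", design = X,
        subjectIds = as.character(clinical$subject_id),
        scoreColumn = 1L, dropped = as.character(dropped))
}

## Stack lesion masks into an n-subjects x n-voxels matrix restricted to
## the linear indices `which`.
.lesionMatrix <- function(masks, which) {
    out <- vapply(masks, function(m) as.numeric(m@data[which]),
                  numeric(length(which)))
    if (is.null(dim(out))) out <- matrix(out, nrow = 1L)  # single voxel
    t(out)
}

## Voxel-wise OLS of Y (n x V) on X (n x p); returns the coefficient,
## standard-error-based t and residual sum of squares of column `col`.
## Zero-residual (deterministic) fits get a machine-finite capped t.
.fitScoreT <- function(X, Y, col = 1L, ysq = colSums(Y * Y)) {
    n <- nrow(X); p <- ncol(X)
    XtXinv <- chol2inv(chol(crossprod(X)))
    XtY <- crossprod(X, Y)
    B <- XtXinv %*% XtY
    rss <- pmax(ysq - colSums(B * XtY), 0)
    df <- n - p
    sigma2 <- rss / df
    beta <- B[col, ]
    se <- sqrt(sigma2 * XtXinv[col, col])
    tt <- beta / se
    det <- rss < 1e-10 * n
    if (any(det)) {
        tt[det] <- sign(beta[det]) * .Machine$double.xmax
        tt[det & beta == 0] <- 0
    }
    list(t = tt, beta = beta, rss = rss, deterministic = det, df = df)
}

#' Mass-univariate voxel-wise general linear model
#'
#' At every eligible voxel, fits ordinary least squares with the binary
#' lesion indicator across subjects as the response and the symptom design
#' as predictors (a linear-probability model per voxel), and reports the
#' frequency-score coefficient and its t-statistic with n - p residual
#' degrees of freedom. Voxels where the lesion indicator is constant across
#' subjects carry no information and are marked ineligible. Voxels fit with
#' zero residual are flagged deterministic and their t capped at the
#' largest finite double.
#'
#' @param masks list of \linkS4class{LesionVolume}s on one grid, aligned
#'   with the design rows.
#' @param design a \linkS4class{SymptomDesign}.
#' @param eligible optional 3D logical array of voxels to test (e.g. from
#'   \code{\link{eligibleMask}}); default all voxels.
#' @return A \linkS4class{StatMap}.
#' @export
voxelwiseGLM <- function(masks, design, eligible = NULL) {
    stopifnot(is(design, "SymptomDesign"))
    grid <- templateGridOf(masks[[1L]])
    for (m in masks) stopIfGridMismatch(m, grid, "lesion masks")
    X <- design@design
    n <- nrow(X); p <- ncol(X)
    if (length(masks) != n)
        stop("number of masks does not match design rows")
    if (n <= p)
        stop("need more subjects than design columns")
    if (qr(X)$rank < p) stop("design matrix is rank deficient")
    dims <- grid@dims
    if (is.null(eligible)) eligible <- array(TRUE, dims)
    if (!all(dim(eligible) == dims))
        stop("eligible mask shape does not match the grid")
    idx <- which(eligible)
    Y <- .lesionMatrix(masks, idx)
    k <- colSums(Y)
    nonconst <- k > 0 & k < n  # lesion indicator varies across subjects
    elig <- array(FALSE, dims)
    beta <- array(NA_real_, dims)
    tstat <- array(NA_real_, dims)
    determ <- array(FALSE, dims)
    keep <- idx[nonconst]
    if (length(keep)) {
        fit <- .fitScoreT(X, Y[, nonconst, drop = FALSE])
        elig[keep] <- TRUE
        beta[keep] <- fit$beta
        tstat[keep] <- fit$t
        determ[keep] <- fit$deterministic
    }
    new("StatMap", beta = beta, tstat = tstat, eligible = elig,
        deterministic = determ, nSubjects = as.integer(n),
        dfResidual = as.integer(n - p), grid = grid)
}

#' Per-voxel statistical power map
#'
#' Power to detect a standardized two-sample difference d between lesioned
#' and spared subjects at each voxel, given the observed split of k
#' lesioned out of n subjects there, via the normal approximation
#' \deqn{power = \Phi\big(d\sqrt{k(n-k)/n} - z_{1-\alpha/2}\big).}
#' Power is defined as 0 where k = 0 or k = n (no contrast). The map
#' identifies the brain regions with enough lesion coverage for the
#' voxel-wise test to be trustworthy.
#'
#' @param overlap an \linkS4class{OverlapMap}.
#' @param effectSize assumed standardized difference d > 0 (default 1.0, a
#'   large single-voxel effect appropriate for screening).
#' @param alpha two-sided level in (0, 1), default 0.05.
#' @return A \linkS4class{PowerMap}.
#' @export
powerMap <- function(overlap, effectSize = 1.0, alpha = 0.05) {
    stopifnot(is(overlap, "OverlapMap"))
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    if (effectSize <= 0) stop("effect size must be > 0")
    k <- overlap@counts
    n <- overlap@nSubjects
    pw <- stats::pnorm(effectSize * sqrt(k * (n - k) / n) -
                       stats::qnorm(1 - alpha / 2))
    pw[k == 0L | k == n] <- 0
    new("PowerMap", power = pw, effectSize = effectSize, alpha = alpha,
        grid = overlap@grid)
}

#' Eligibility mask from a power map
#'
#' Voxels with power strictly greater than the threshold are retained for
#' testing; the inequality is strict, so a voxel at exactly the threshold
#' is excluded.
#'
#' @param power a \linkS4class{PowerMap}.
#' @param threshold power cutoff in (0, 1), default 0.8.
#' @return 3D logical array.
#' @export
eligibleMask <- function(power, threshold = 0.8) {
    stopifnot(is(power, "PowerMap"))
    if (threshold <= 0 || threshold >= 1)
        stop("threshold must lie in (0, 1)")
    power@power > threshold
}

#' Permutation null distribution of the voxel-wise t-statistic
#'
#' Builds the empirical null by repeatedly permuting the symptom of
#' interest across subjects and recomputing every eligible voxel's t. In
#' the default \code{"score"} scheme only the frequency-score column is
#' permuted while sex, age and tumor volume stay attached to their
#' subject's lesion, preserving the lesion-covariate dependence; the
#' \code{"freedman_lane"} scheme instead permutes the residuals of the
#' lesion indicator after regressing out the nuisance covariates. The
#' per-voxel threshold is the ceiling((1-alpha) * B)-th order statistic of
#' the B permuted t-values at that voxel (\code{mode = "voxelwise"}), or
#' the same order statistic of the permutation distribution of the
#' image-wide maximum t applied to every voxel (\code{mode = "max_stat"},
#' a familywise-error-controlling alternative).
#'
#' @param masks list of \linkS4class{LesionVolume}s aligned with the
#'   design.
#' @param design a \linkS4class{SymptomDesign}.
#' @param eligible 3D logical array of voxels to test, normally
#'   \code{eligibleVoxels(statMap)}.
#' @param nPermutations number of permutations (default 1000).
#' @param alpha level (default 0.05); a warning is raised when
#'   \code{nPermutations < 1/alpha}, where the threshold is unattainable.
#' @param seed explicit RNG seed (required; there is no default).
#' @param scheme \code{"score"} or \code{"freedman_lane"}.
#' @param mode \code{"voxelwise"} or \code{"max_stat"}.
#' @return A \linkS4class{PermutationNull}. Identical inputs (including
#'   seed) give bit-identical thresholds.
#' @export
permutationNull <- function(masks, design, eligible, nPermutations = 1000L,
                            alpha = 0.05, seed, scheme = c("score",
                            "freedman_lane"), mode = c("voxelwise",
                            "max_stat")) {
    scheme <- match.arg(scheme)
    mode <- match.arg(mode)
    stopifnot(is(design, "SymptomDesign"))
    if (missing(seed)) stop("an explicit integer seed is required")
    nPermutations <- as.integer(nPermutations)
    if (nPermutations < 1L) stop("nPermutations must be >= 1")
    if (nPermutations < 1 / alpha)
        warning(sprintf("nPermutations = %d cannot resolve the %g quantile (need >= %d)",
                        nPermutations, 1 - alpha, ceiling(1 / alpha)))
    grid <- templateGridOf(masks[[1L]])
    X <- design@design
    n <- nrow(X)
    idx <- which(eligible)
    if (!length(idx)) stop("eligible mask is empty")
    Y <- .lesionMatrix(masks, idx)
    ysq <- colSums(Y * Y)
    V <- length(idx)
    Tperm <- matrix(NA_real_, nPermutations, V)
    if (scheme == "freedman_lane") {
        Z <- X[, -design@scoreColumn, drop = FALSE]
        Hz <- Z %*% chol2inv(chol(crossprod(Z))) %*% t(Z)
        Yfit <- Hz %*% Y
        Yres <- Y - Yfit
    }
    withSeed(seed, {
        for (b in seq_len(nPermutations)) {
            perm <- sample.int(n)
            if (scheme == "score") {
                Xb <- X
                Xb[, design@scoreColumn] <- X[perm, design@scoreColumn]
                Tperm[b, ] <- .fitScoreT(Xb, Y, design@scoreColumn, ysq)$t
            } else {
                Yb <- Yfit + Yres[perm, , drop = FALSE]
                Tperm[b, ] <- .fitScoreT(X, Yb, design@scoreColumn)$t
            }
        }
    })
    kth <- as.integer(ceiling((1 - alpha) * nPermutations))
    thr <- array(NA_real_, grid@dims)
    if (mode == "voxelwise") {
        thr[idx] <- apply(Tperm, 2L, function(x) sort.int(x, partial = kth)[kth])
    } else {
        maxima <- apply(Tperm, 1L, max)
        thr[idx] <- sort.int(maxima, partial = kth)[kth]
    }
    new("PermutationNull", threshold = thr, eligible = eligible,
        nPermutations = nPermutations, alpha = alpha,
        seed = as.integer(seed), mode = mode, scheme = scheme, grid = grid)
}

#' Apply the permutation threshold to an observed statistical map
#'
#' A voxel is retained exactly when it is eligible and its observed t is
#' strictly greater than its permutation threshold — i.e. it beats more
#' than a (1-alpha) fraction of the permuted statistics. The test is
#' one-sided: only positive lesion-frequency associations are retained.
#'
#' @param stat a \linkS4class{StatMap}.
#' @param null a \linkS4class{PermutationNull} built on the same grid and
#'   eligible mask.
#' @return 3D logical array of retained voxels.
#' @export
applyThreshold <- function(stat, null) {
    stopifnot(is(stat, "StatMap"), is(null, "PermutationNull"))
    stopIfGridMismatch(stat, null, "statistical map and permutation null")
    if (!identical(stat@eligible, null@eligible))
        stop("permutation null was built on a different eligible mask")
    retained <- array(FALSE, stat@grid@dims)
    e <- stat@eligible
    retained[e] <- stat@tstat[e] > null@threshold[e]
    retained
}

#' Label subjects by tumor involvement of a peak voxel
#'
#' Involvement is defined as the subject's segmented tumor mask containing
#' the given voxel — normally the voxel with the highest t-value in a
#' VLSM-identified cluster.
#'
#' @param masks list of \linkS4class{LesionVolume}s.
#' @param peak 0-based voxel coordinate (x, y, z).
#' @return named logical vector, one entry per subject.
#' @export
labelInvolvement <- function(masks, peak) {
    grid <- templateGridOf(masks[[1L]])
    peak <- as.integer(peak)
    checkInsideGrid(peak, grid)
    out <- vapply(masks,
                  function(m) m@data[peak[1L] + 1L, peak[2L] + 1L,
                                     peak[3L] + 1L] == 1L,
                  logical(1L))
    names(out) <- vapply(masks, subjectId, character(1L))
    out
}

#' Compare seizure-frequency scores by peak involvement
#'
#' Mann-Whitney U test of the ordinal frequency scores between subjects
#' whose tumor does and does not contain the peak voxel, optionally
#' restricted to a subset (e.g. one hemisphere).
#'
#' @param involvement logical vector from \code{\link{labelInvolvement}}.
#' @param scores integer vector of frequency scores (0-4), aligned.
#' @param subset optional logical vector restricting the comparison.
#' @return A \linkS4class{RankTestResult} (U reported for the involved
#'   group).
#' @export
involvementVsFrequency <- function(involvement, scores, subset = NULL) {
    if (length(involvement) != length(scores))
        stop("involvement and scores must be aligned")
    if (!is.null(subset)) {
        involvement <- involvement[subset]
        scores <- scores[subset]
    }
    if (!any(involvement) || all(involvement))
        stop("both involved and non-involved groups must be non-empty")
    mannWhitney(scores[involvement], scores[!involvement])
}
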