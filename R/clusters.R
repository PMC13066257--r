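#' @include vlsm.R
NULL

## Neighbor offsets (rows of dx, dy, dz) for a 3D connectivity class:
## 6 = faces, 18 = faces + edges, 26 = full neighborhood.
.connectivityOffsets <- function(connectivity) {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    ord <- rowSums(abs(g))
    keep <- switch(as.character(connectivity),
                   "6" = ord == 1L,
                   "18" = ord >= 1L & ord <= 2L,
                   "26" = ord >= 1L,
                   stop("connectivity must be 6, 18 or 26"))
    g[keep, , drop = FALSE]
}

## Connected-component labeling of a logical 3D array by breadth-first
## search over compacted foreground voxels. Returns an integer array with
## arbitrary (discovery-order) labels.
.labelComponents <- function(mask, connectivity) {
    dims <- dim(mask)
    idx <- which(mask)
    labels <- array(0L, dims)
    if (!length(idx)) return(labels)
    compact <- array(0L, dims)
    compact[idx] <- seq_along(idx)
    coords <- arrayInd(idx, dims)           # 1-based
    off <- .connectivityOffsets(connectivity)
    lab <- integer(length(idx))
    queue <- integer(length(idx))
    cur <- 0L
    for (s in seq_along(idx)) {
        if (lab[s] != 0L) next
        cur <- cur + 1L
        lab[s] <- cur
        queue[1L] <- s
        head <- 1L; tail <- 1L
        while (head <= tail) {
            v <- queue[head]; head <- head + 1L
            nb <- sweep(off, 2L, coords[v, ], `+`)
            ok <- nb[, 1L] >= 1L & nb[, 1L] <= dims[1L] &
                  nb[, 2L] >= 1L & nb[, 2L] <= dims[2L] &
                  nb[, 3L] >= 1L & nb[, 3L] <= dims[3L]
            nb <- nb[ok, , drop = FALSE]
            lin <- nb[, 1L] + dims[1L] * (nb[, 2L] - 1L +
                   dims[2L] * (nb[, 3L] - 1L))
            cid <- compact[lin]
            cid <- cid[cid > 0L]
            cid <- cid[lab[cid] == 0L]
            if (length(cid)) {
                lab[cid] <- cur
                queue[(tail + 1L):(tail + length(cid))] <- cid
                tail <- tail + length(cid)
            }
        }
    }
    labels[idx] <- lab
    labels
}

#' Extract supra-threshold clusters and their peaks
#'
#' Labels the maximal connected components of the retained mask under 6-,
#' 18- or 26-neighborhood connectivity and reports, per cluster, its size
#' and the peak voxel (highest t; ties broken by the lexicographically
#' smallest 0-based coordinate). Clusters are sorted by peak t descending,
#' with the same lexicographic tie-break, and relabeled 1, 2, ... in that
#' order. An empty retained mask yields an empty result, not an error.
#'
#' @param retained 3D logical array of supra-threshold voxels (from
#'   \code{\link{applyThreshold}}).
#' @param stat the \linkS4class{StatMap} the mask came from (or a bare 3D
#'   t array, in which case \code{grid} must be given).
#' @param connectivity 6, 18 or 26 (default 26, the common choice in
#'   volumetric lesion mapping).
#' @param grid \linkS4class{TemplateGrid}, only needed with a bare array.
#' @return A \linkS4class{ClusterResult}; its table carries both 0-based
#'   (peak_x, peak_y, peak_z) and 1-based (peak_x1, ...) coordinates.
#' @export
extractClusters <- function(retained, stat, connectivity = 26L, grid = NULL) {
    if (is(stat, "StatMap")) {
        tarr <- stat@tstat
        grid <- stat@grid
        if (any(retained & !stat@eligible))
            stop("retained mask includes voxels outside the eligible set")
    } else {
        tarr <- stat
        if (is.null(grid)) stop("'grid' is required with a bare t array")
    }
    connectivity <- as.integer(connectivity)
    if (!all(dim(retained) == grid@dims))
        stop("retained mask shape does not match the grid")
    labels <- .labelComponents(retained, connectivity)
    nlab <- max(labels)
    if (nlab == 0L) {
        tab <- data.frame(cluster = integer(), n_voxels = integer(),
                          peak_x = integer(), peak_y = integer(),
                          peak_z = integer(), peak_x1 = integer(),
                          peak_y1 = integer(), peak_z1 = integer(),
                          peak_t = numeric())
        return(new("ClusterResult", labels = labels, table = tab,
                   connectivity = connectivity, grid = grid))
    }
    rows <- lapply(seq_len(nlab), function(lb) {
        lin <- which(labels == lb)
        tv <- tarr[lin]
        pk <- lin[tv == max(tv)]
        crd <- arrayInd(pk, grid@dims)          # 1-based candidates
        crd <- crd[order(crd[, 1L], crd[, 2L], crd[, 3L]), , drop = FALSE]
        data.frame(n_voxels = length(lin),
                   peak_x = crd[1L, 1L] - 1L, peak_y = crd[1L, 2L] - 1L,
                   peak_z = crd[1L, 3L] - 1L,
                   peak_x1 = crd[1L, 1L], peak_y1 = crd[1L, 2L],
                   peak_z1 = crd[1L, 3L],
                   peak_t = max(tv))
    })
    tab <- do.call(rbind, rows)
    ord <- order(-tab$peak_t, tab$peak_x, tab$peak_y, tab$peak_z)
    tab <- tab[ord, , drop = FALSE]
    tab <- cbind(cluster = seq_len(nlab), tab)
    rownames(tab) <- NULL
    ## relabel the volume so label k is the k-th sorted cluster
    relabel <- integer(nlab)
    relabel[ord] <- seq_len(nlab)
    pos <- labels > 0L
    labels[pos] <- relabel[labels[pos]]
    new("ClusterResult", labels = labels, table = tab,
        connectivity = connectivity, grid = grid)
}
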