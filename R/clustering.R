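# Jaccard similarity of snapshot contact sets, Ward.D2 substate clustering
# with the diagnostics used to choose the number of clusters, centroid
# selection, and principal-coordinate projection of the dissimilarities.

#' Jaccard index of two contact sets
#'
#' |C1 intersect C2| / |C1 union C2|: 0 when the two interfaces share no
#' contact, 1 when they are identical. Two empty sets are identical
#' interfaces and score `empty_value` (1 by default; set 0 for the
#' alternative convention).
#'
#' @param c1,c2 [ContactSet-class] objects.
#' @param empty_value value returned when both sets are empty.
#' @return numeric in [0, 1].
#' @examples
#' a <- newContactSet(data.frame(chain1 = "A", resid1 = 1,
#'                               chain2 = "B", resid2 = 1))
#' b <- newContactSet(data.frame(chain1 = "A", resid1 = 2,
#'                               chain2 = "B", resid2 = 2))
#' jaccardIndex(a, b)   # disjoint: 0
#' jaccardIndex(a, a)   # identical: 1
#' @export
jaccardIndex <- function(c1, c2, empty_value = 1) {
    k1 <- contactKeys(c1)
    k2 <- contactKeys(c2)
    u <- length(union(k1, k2))
    if (u == 0L) return(empty_value)
    length(intersect(k1, k2)) / u
}

#' Jaccard similarity matrix of a contact-set series
#'
#' Full symmetric snapshot-by-snapshot similarity matrix; the dissimilarity
#' view used for clustering is `1 - J`. Computed through a binary
#' contact-incidence matrix, so it scales to hundreds of snapshots.
#'
#' @param contact_series list of [ContactSet-class].
#' @param empty_value Jaccard value for two empty sets.
#' @return n x n numeric matrix with snapshot times in attribute `times`.
#' @export
jaccardMatrix <- function(contact_series, empty_value = 1) {
    n <- length(contact_series)
    if (n < 2L) stop("need at least 2 snapshots", call. = FALSE)
    keys <- lapply(contact_series, contactKeys)
    universe <- unique(unlist(keys))
    if (length(universe) == 0L) {
        J <- matrix(empty_value, n, n)
        diag(J) <- 1
    } else {
        M <- vapply(keys, function(k) universe %in% k,
                    logical(length(universe)))
        M <- matrix(as.numeric(M), ncol = n)
        inter <- crossprod(M)
        sz <- colSums(M)
        uni <- outer(sz, sz, "+") - inter
        J <- ifelse(uni > 0, inter / uni, empty_value)
        diag(J) <- 1
    }
    attr(J, "times") <- vapply(contact_series, slot, numeric(1),
                               name = "time")
    J
}

.relabelByAppearance <- function(labels) {
    lv <- unique(labels)
    as.integer(match(labels, lv))
}

.countChanges <- function(labels) sum(diff(labels) != 0L)

#' Cluster snapshots into interface substates
#'
#' Agglomerative hierarchical clustering (Ward.D2 Lance-Williams update, as
#' implemented in [stats::hclust()]) on the Jaccard dissimilarity `1 - J`,
#' cut at `n_clusters`. Cluster labels are renumbered in order of first
#' appearance along the trajectory. Diagnostics (smallest/largest cluster
#' size, number of label changes in time) and per-cluster centroids are
#' filled in.
#'
#' Note that `1 - J` is a metric but not Euclidean; Ward.D2 is applied to
#' it directly, as is common practice for contact-set dissimilarities.
#'
#' @param jmatrix Jaccard similarity matrix from [jaccardMatrix()].
#' @param n_clusters number of clusters (1..n).
#' @return An [InterfaceClustering-class].
#' @export
clusterInterfaces <- function(jmatrix, n_clusters) {
    n <- nrow(jmatrix)
    if (n_clusters < 1 || n_clusters > n)
        stop("n_clusters must be between 1 and ", n, call. = FALSE)
    labels <- if (n_clusters == 1L) rep(1L, n)
        else {
            hc <- stats::hclust(stats::as.dist(1 - jmatrix),
                                method = "ward.D2")
            .relabelByAppearance(stats::cutree(hc, k = n_clusters))
        }
    sizes <- tabulate(labels, nbins = max(labels))
    times <- attr(jmatrix, "times")
    if (is.null(times)) times <- seq_len(n) - 1
    cents <- vapply(seq_len(max(labels)), function(k)
        selectCentroid(jmatrix, labels, k), integer(1))
    new("InterfaceClustering", labels = labels, times = as.numeric(times),
        nClusters = as.integer(max(labels)),
        minSize = as.integer(min(sizes)), maxSize = as.integer(max(sizes)),
        nChanges = as.integer(.countChanges(labels)),
        centroids = cents)
}

#' Diagnostics for choosing the number of substates
#'
#' For each k up to `k_max`, reports the size of the smallest and largest
#' cluster, the number of cluster changes along the trajectory and the mean
#' within-cluster dissimilarity. The recommended k codifies the qualitative
#' goal of few, long-lived, well-populated substates: the largest k whose
#' smallest cluster holds at least `min_size_frac` of the snapshots and
#' whose number of changes stays within `change_budget` per extra cluster.
#'
#' @param jmatrix Jaccard similarity matrix.
#' @param k_max largest number of clusters to examine (>= 2).
#' @param min_size_frac minimal fraction of snapshots in the smallest
#'   cluster.
#' @param change_budget allowed label changes per additional cluster; k
#'   qualifies when `n_changes <= change_budget * (k - 1)`.
#' @return list with `diagnostics` (data.frame: `k`, `min_size`,
#'   `max_size`, `n_changes`, `intra_dissim`) and `recommended` (integer).
#' @export
suggestNClusters <- function(jmatrix, k_max = 6, min_size_frac = 0.05,
                             change_budget = 2) {
    n <- nrow(jmatrix)
    k_max <- min(k_max, n)
    D <- 1 - jmatrix
    rows <- lapply(seq_len(k_max), function(k) {
        cl <- clusterInterfaces(jmatrix, k)
        lab <- cl@labels
        wd <- unlist(lapply(seq_len(k), function(g) {
            idx <- which(lab == g)
            if (length(idx) < 2) return(numeric(0))
            D[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
        }))
        data.frame(k = k, min_size = cl@minSize, max_size = cl@maxSize,
                   n_changes = cl@nChanges,
                   intra_dissim = if (length(wd)) mean(wd) else 0)
    })
    diag_df <- do.call(rbind, rows)
    ok <- diag_df$min_size >= min_size_frac * n &
        diag_df$n_changes <= change_budget * (diag_df$k - 1)
    ok[1] <- TRUE   # a single substate is always admissible
    list(diagnostics = diag_df, recommended = max(diag_df$k[ok]))
}

#' Centroid snapshot of a cluster
#'
#' The member with the highest average Jaccard similarity to the other
#' members of its cluster; a singleton is its own centroid; ties resolve to
#' the earliest snapshot.
#'
#' @param jmatrix Jaccard similarity matrix.
#' @param labels integer labels per snapshot (or an
#'   [InterfaceClustering-class]).
#' @param cluster cluster number.
#' @return integer snapshot index.
#' @export
selectCentroid <- function(jmatrix, labels, cluster) {
    if (is(labels, "InterfaceClustering")) labels <- labels@labels
    idx <- which(labels == cluster)
    if (length(idx) == 0L)
        stop("cluster ", cluster, " is empty", call. = FALSE)
    if (length(idx) == 1L) return(idx)
    avg <- vapply(seq_along(idx), function(i)
        mean(jmatrix[idx[i], idx[-i]]), numeric(1))
    idx[which.max(avg)]   # which.max takes the earliest on ties
}

#' Principal-coordinate projection of interface dissimilarities
#'
#' Classical metric multidimensional scaling ([stats::cmdscale()]) of
#' `1 - J`: double-centred squared dissimilarities, top eigenvectors scaled
#' by the square root of their eigenvalues; negative eigenvalues (the
#' Jaccard distance is not Euclidean) are truncated. Degenerate axes are
#' returned as zero columns, so the result always has `n_dims` columns.
#'
#' @param jmatrix Jaccard similarity matrix.
#' @param n_dims number of output dimensions.
#' @return n x n_dims coordinate matrix.
#' @export
pcoaProjection <- function(jmatrix, n_dims = 2) {
    n <- nrow(jmatrix)
    if (n < n_dims + 1) stop("need at least n_dims + 1 snapshots",
                             call. = FALSE)
    D <- 1 - jmatrix
    out <- matrix(0, n, n_dims)
    if (all(D == 0)) return(out)
    mds <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n_dims))
    out[, seq_len(ncol(mds))] <- mds
    out[is.na(out)] <- 0
    out
}
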