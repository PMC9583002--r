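#' @name accessors
#' @title Accessors for ifdyn containers
#'
#' @description
#' `atoms()`, `waterTable()`, `snapshotTime()` read the slots of a
#' [Snapshot-class]; `snapshots()` returns the frame list of a
#' [SnapshotSeries-class]; `contactPairs()` the pair table of a
#' [ContactSet-class]; `clusterLabels()` the per-snapshot labels of an
#' [InterfaceClustering-class].
#'
#' @param x the object.
#' @param i frame index.
#' @aliases atoms waterTable snapshotTime snapshots contactPairs
#'   clusterLabels
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setMethod("atoms", "Snapshot", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("waterTable", function(x) standardGeneric("waterTable"))
#' @rdname accessors
#' @export
setMethod("waterTable", "Snapshot", function(x) x@waters)

#' @rdname accessors
#' @export
setGeneric("snapshotTime", function(x) standardGeneric("snapshotTime"))
#' @rdname accessors
#' @export
setMethod("snapshotTime", "Snapshot", function(x) x@time)

#' @rdname accessors
#' @export
setGeneric("snapshots", function(x) standardGeneric("snapshots"))
#' @rdname accessors
#' @export
setMethod("snapshots", "SnapshotSeries", function(x) x@snapshots)

#' @rdname accessors
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))
#' @rdname accessors
#' @export
setMethod("contactPairs", "ContactSet", function(x) x@pairs)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "InterfaceClustering", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("length", "SnapshotSeries", function(x) length(x@snapshots))

#' @rdname accessors
#' @export
setMethod("[[", "SnapshotSeries", function(x, i) x@snapshots[[i]])

#' @rdname accessors
#' @export
setMethod("length", "ContactSet", function(x) nrow(x@pairs))

setMethod("show", "Snapshot", function(object) {
    ch <- unique(object@atoms$chain)
    cat("Snapshot at t =", object@time, "ns\n")
    cat("  chains:", paste(ch, collapse = ", "),
        sprintf("(%d heavy atoms, %d residues)\n", nrow(object@atoms),
                nrow(unique(object@atoms[, c("chain", "resid")]))))
    cat("  waters:", nrow(object@waters),
        " hydrogens kept:", nrow(object@hydrogens), "\n")
})

setMethod("show", "SnapshotSeries", function(object) {
    n <- length(object@snapshots)
    cat(sprintf("SnapshotSeries '%s': %d frames, dt = %g ns\n",
                object@source, n, object@dt))
    if (n > 0) {
        tt <- vapply(object@snapshots, slot, numeric(1), name = "time")
        cat(sprintf("  time range: %g .. %g ns\n", min(tt), max(tt)))
    }
})

setMethod("show", "ContactSet", function(object) {
    cat(sprintf("ContactSet: %d cross-chain residue pairs (t = %g ns)\n",
                nrow(object@pairs), object@time))
    if (nrow(object@pairs) > 0)
        print(utils::head(object@pairs, 5))
})

setMethod("show", "InterfaceClustering", function(object) {
    cat(sprintf(
        "InterfaceClustering: %d snapshots in %d clusters\n",
        length(object@labels), object@nClusters))
    cat(sprintf("  min size %d, max size %d, %d changes along time\n",
                object@minSize, object@maxSize, object@nChanges))
    cat("  centroid snapshots:",
        paste(object@centroids, collapse = ", "), "\n")
})
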