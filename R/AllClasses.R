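#' @import methods
NULL

.emptyAtoms <- function() {
    data.frame(chain = character(0), resid = integer(0),
               resname = character(0), atom = character(0),
               elem = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0), stringsAsFactors = FALSE)
}

.emptyWaters <- function() {
    data.frame(water_id = integer(0), x = numeric(0), y = numeric(0),
               z = numeric(0), stringsAsFactors = FALSE)
}

.emptyPairs <- function() {
    data.frame(chain1 = character(0), resid1 = integer(0),
               resname1 = character(0), chain2 = character(0),
               resid2 = integer(0), resname2 = character(0),
               stringsAsFactors = FALSE)
}

#' Snapshot: one trajectory time point of a protein system with waters
#'
#' A `Snapshot` holds the heavy atoms of one or two protein chains at a single
#' time point, the oxygen positions of all water molecules, and (optionally)
#' hydrogen atoms kept aside for hydrogen-bond angle checks. Coordinates are
#' in Angstrom, time in nanoseconds. Residues are identified by the
#' `(chain, resid)` pair in the numbering of the source file; no renumbering
#' is performed.
#'
#' @slot time numeric(1), time of the frame in ns.
#' @slot atoms data.frame with columns `chain`, `resid`, `resname`, `atom`,
#'   `elem`, `x`, `y`, `z`; heavy atoms only.
#' @slot hydrogens data.frame with the same columns; hydrogen atoms if the
#'   source provided them (may be empty).
#' @slot waters data.frame with columns `water_id`, `x`, `y`, `z`; one row
#'   per water molecule, oxygen position only.
#'
#' @seealso [newSnapshot()], [SnapshotSeries-class]
#' @exportClass Snapshot
setClass("Snapshot",
         representation(time = "numeric", atoms = "data.frame",
                        hydrogens = "data.frame", waters = "data.frame"),
         prototype(time = 0, atoms = .emptyAtoms(),
                   hydrogens = .emptyAtoms(), waters = .emptyWaters()))

setValidity("Snapshot", function(object) {
    msg <- character(0)
    a <- object@atoms
    need <- c("chain", "resid", "resname", "atom", "elem", "x", "y", "z")
    if (!all(need %in% names(a)))
        msg <- c(msg, paste("atoms must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (nrow(a) > 0 && !all(is.finite(c(a$x, a$y, a$z))))
            msg <- c(msg, "all atom coordinates must be finite")
        if (any(toupper(a$elem) %in% c("H", "D")))
            msg <- c(msg, "atoms must contain heavy atoms only (H/D found)")
    }
    w <- object@waters
    if (!all(c("water_id", "x", "y", "z") %in% names(w)))
        msg <- c(msg, "waters must have columns water_id, x, y, z")
    else if (nrow(w) > 0) {
        if (!all(is.finite(c(w$x, w$y, w$z))))
            msg <- c(msg, "all water coordinates must be finite")
        if (anyDuplicated(w$water_id))
            msg <- c(msg, "water_id must be unique")
    }
    if (length(object@time) != 1L || !is.finite(object@time))
        msg <- c(msg, "time must be a single finite number")
    if (length(msg)) msg else TRUE
})

#' SnapshotSeries: a time-ordered collection of snapshots
#'
#' Wraps a list of [Snapshot-class] objects taken at strictly increasing
#' times with a constant atom composition (same topology in every frame).
#' The `source` label records whether the series describes the bound complex
#' or one of the unbound partners.
#'
#' @slot snapshots list of `Snapshot`.
#' @slot dt numeric(1), nominal sampling interval in ns.
#' @slot source character(1), one of `"complex"`, `"unbound_A"`,
#'   `"unbound_B"` (free-form labels are tolerated).
#'
#' @seealso [newSnapshotSeries()], [loadSeries()]
#' @exportClass SnapshotSeries
setClass("SnapshotSeries",
         representation(snapshots = "list", dt = "numeric",
                        source = "character"),
         prototype(snapshots = list(), dt = 1, source = "complex"))

setValidity("SnapshotSeries", function(object) {
    msg <- character(0)
    ok <- vapply(object@snapshots, is, logical(1), class2 = "Snapshot")
    if (!all(ok))
        msg <- c(msg, "all elements of snapshots must be Snapshot objects")
    else if (length(object@snapshots) > 1) {
        tt <- vapply(object@snapshots, slot, numeric(1), name = "time")
        if (any(diff(tt) <= 0))
            msg <- c(msg, "snapshot times must be strictly increasing")
        sig <- function(s) paste(s@atoms$chain, s@atoms$resid, s@atoms$atom,
                                 collapse = ";")
        sigs <- vapply(object@snapshots, sig, character(1))
        if (length(unique(sigs)) != 1L)
            msg <- c(msg, "atom composition must be constant across frames")
    }
    if (length(object@dt) != 1L || object@dt <= 0)
        msg <- c(msg, "dt must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' ContactSet: the cross-chain residue contacts of one snapshot
#'
#' The set of residue pairs (one residue from each chain) that are in contact
#' in a given snapshot, i.e. whose minimal heavy-atom distance does not
#' exceed the contact cutoff. Pairs are stored with chain, residue index and
#' residue name for each partner; set semantics are enforced (no duplicate
#' pairs). Residue names may be `NA` for abstract contact sets produced by
#' the synthetic contact-series generator.
#'
#' @slot pairs data.frame with columns `chain1`, `resid1`, `resname1`,
#'   `chain2`, `resid2`, `resname2`.
#' @slot time numeric(1), time of the underlying snapshot in ns.
#'
#' @seealso [computeContacts()], [jaccardIndex()]
#' @exportClass ContactSet
setClass("ContactSet",
         representation(pairs = "data.frame", time = "numeric"),
         prototype(pairs = .emptyPairs(), time = NA_real_))

setValidity("ContactSet", function(object) {
    msg <- character(0)
    p <- object@pairs
    need <- c("chain1", "resid1", "resname1", "chain2", "resid2", "resname2")
    if (!all(need %in% names(p)))
        msg <- c(msg, paste("pairs must have columns:",
                            paste(need, collapse = ", ")))
    else if (nrow(p) > 0) {
        if (any(p$chain1 == p$chain2))
            msg <- c(msg, "contacts must be cross-chain (chain1 != chain2)")
        key <- paste(p$chain1, p$resid1, p$chain2, p$resid2)
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate contact pairs are not allowed")
    }
    if (length(msg)) msg else TRUE
})

#' InterfaceClustering: substate assignment of trajectory snapshots
#'
#' Result of cutting the Ward.D2 dendrogram of Jaccard dissimilarities at a
#' chosen number of clusters. Holds the time-ordered labels together with the
#' diagnostics used to judge a clustering: size of the smallest and largest
#' cluster and the number of label changes along the trajectory, plus the
#' centroid snapshot of each cluster (highest average Jaccard similarity to
#' the other members).
#'
#' @slot labels integer vector, cluster label (1..nClusters) per snapshot in
#'   time order.
#' @slot times numeric vector of snapshot times (ns).
#' @slot nClusters integer(1).
#' @slot minSize,maxSize integer(1), smallest/largest cluster size.
#' @slot nChanges integer(1), number of t with label(t) != label(t+1).
#' @slot centroids integer vector, snapshot index of each cluster centroid.
#'
#' @seealso [clusterInterfaces()], [suggestNClusters()]
#' @exportClass InterfaceClustering
setClass("InterfaceClustering",
         representation(labels = "integer", times = "numeric",
                        nClusters = "integer", minSize = "integer",
                        maxSize = "integer", nChanges = "integer",
                        centroids = "integer"))

setValidity("InterfaceClustering", function(object) {
    msg <- character(0)
    k <- object@nClusters
    if (length(object@labels) == 0L)
        msg <- c(msg, "labels must be non-empty")
    else {
        if (!all(object@labels %in% seq_len(k)))
            msg <- c(msg, "labels must lie in 1..nClusters")
        if (length(unique(object@labels)) != k)
            msg <- c(msg, "every cluster must be non-empty")
        nc <- sum(diff(object@labels) != 0L)
        if (nc != object@nChanges)
            msg <- c(msg, "nChanges inconsistent with labels")
    }
    if (length(object@times) != length(object@labels))
        msg <- c(msg, "times and labels must have equal length")
    if (length(msg)) msg else TRUE
})
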