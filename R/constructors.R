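#' Create a Snapshot from atom and water tables
#'
#' Convenience constructor performing column completion (element inference
#' from atom names when `elem` is missing) and heavy-atom filtering:
#' hydrogens found in `atoms` are moved to the `hydrogens` slot.
#'
#' @param atoms data.frame with columns `chain`, `resid`, `resname`, `atom`,
#'   `x`, `y`, `z` and optionally `elem`.
#' @param waters data.frame with columns `x`, `y`, `z` (water oxygen
#'   positions) and optionally `water_id`; `NULL` for a dry system.
#' @param time frame time in ns.
#' @return A [Snapshot-class] object.
#' @examples
#' at <- data.frame(chain = "A", resid = 1, resname = "GLY", atom = "CA",
#'                  x = 0, y = 0, z = 0)
#' s <- newSnapshot(at, time = 0)
#' @export
newSnapshot <- function(atoms, waters = NULL, time = 0) {
    atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
    if (is.null(atoms$elem))
        atoms$elem <- inferElement(atoms$atom)
    atoms$chain <- as.character(atoms$chain)
    atoms$resid <- as.integer(atoms$resid)
    atoms$resname <- toupper(as.character(atoms$resname))
    isH <- toupper(atoms$elem) %in% c("H", "D")
    hyd <- atoms[isH, , drop = FALSE]
    atoms <- atoms[!isH, , drop = FALSE]
    rownames(atoms) <- NULL
    rownames(hyd) <- NULL
    if (is.null(waters) || nrow(as.data.frame(waters)) == 0L) {
        waters <- .emptyWaters()
    } else {
        waters <- as.data.frame(waters, stringsAsFactors = FALSE)
        if (is.null(waters$water_id))
            waters$water_id <- seq_len(nrow(waters))
        waters <- waters[, c("water_id", "x", "y", "z")]
        rownames(waters) <- NULL
    }
    new("Snapshot", time = as.numeric(time),
        atoms = atoms[, c("chain", "resid", "resname", "atom", "elem",
                          "x", "y", "z")],
        hydrogens = if (nrow(hyd)) hyd[, c("chain", "resid", "resname",
                                           "atom", "elem", "x", "y", "z")]
                    else .emptyAtoms(),
        waters = waters)
}

#' Create a SnapshotSeries from a list of snapshots
#'
#' @param snapshots list of [Snapshot-class] objects in time order.
#' @param dt nominal sampling interval in ns.
#' @param source label, typically `"complex"`, `"unbound_A"` or
#'   `"unbound_B"`.
#' @return A [SnapshotSeries-class] object.
#' @export
newSnapshotSeries <- function(snapshots, dt = 1, source = "complex") {
    new("SnapshotSeries", snapshots = snapshots, dt = as.numeric(dt),
        source = source)
}

#' Create a ContactSet from a pair table
#'
#' @param pairs data.frame with columns `chain1`, `resid1`, `chain2`,
#'   `resid2` and optionally `resname1`, `resname2`. Duplicate pairs are
#'   collapsed (set semantics).
#' @param time time of the snapshot in ns (`NA` for abstract sets).
#' @return A [ContactSet-class] object.
#' @examples
#' cs <- newContactSet(data.frame(chain1 = "A", resid1 = 1,
#'                                chain2 = "B", resid2 = 7))
#' length(cs)
#' @export
newContactSet <- function(pairs, time = NA_real_) {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    if (nrow(pairs) == 0L)
        return(new("ContactSet", pairs = .emptyPairs(),
                   time = as.numeric(time)))
    if (is.null(pairs$resname1)) pairs$resname1 <- NA_character_
    if (is.null(pairs$resname2)) pairs$resname2 <- NA_character_
    pairs$chain1 <- as.character(pairs$chain1)
    pairs$chain2 <- as.character(pairs$chain2)
    pairs$resid1 <- as.integer(pairs$resid1)
    pairs$resid2 <- as.integer(pairs$resid2)
    key <- paste(pairs$chain1, pairs$resid1, pairs$chain2, pairs$resid2)
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    ord <- order(pairs$chain1, pairs$resid1, pairs$chain2, pairs$resid2)
    pairs <- pairs[ord, c("chain1", "resid1", "resname1",
                          "chain2", "resid2", "resname2"), drop = FALSE]
    rownames(pairs) <- NULL
    new("ContactSet", pairs = pairs, time = as.numeric(time))
}
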