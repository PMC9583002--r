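# Reading structures/trajectories into SnapshotSeries and writing tables.
# Parsing of PDB and DCD is delegated to bio3d; this file only maps bio3d's
# tables onto the Snapshot representation (heavy atoms of two chains + water
# oxygens) and provides a multi-model PDB writer, which bio3d lacks.

.WATER_RESNAMES <- c("HOH", "WAT", "SOL", "TIP3", "TIP", "TIP4", "SPC")
.ION_RESNAMES <- c("NA", "CL", "K", "MG", "ZN", "CA", "SOD", "CLA", "POT",
                   "CAL", "MN", "FE", "CU", "IOD", "BR")

#' Load a snapshot series from a structure (and optional trajectory) file
#'
#' Reads a single- or multi-model PDB file, or a PDB topology paired with a
#' DCD/NetCDF trajectory, and converts the frames into a
#' [SnapshotSeries-class]: heavy atoms of the two requested protein chains,
#' hydrogens kept aside, waters reduced to their oxygen position. Waters are
#' recognised by residue name (HOH/WAT/SOL/TIP3/TIP/TIP4/SPC,
#' case-insensitive) on any chain; ions are discarded.
#'
#' Frames are assumed to be `dt` ns apart; `stride` selects the frame nearest
#' to each multiple of `stride` ns (nearest-frame selection when `dt` does
#' not divide `stride`). Periodic-boundary re-imaging is assumed done
#' upstream: each chain must already be whole.
#'
#' @param structure_path path to a PDB file (multi-model allowed).
#' @param trajectory_path optional path to a DCD or NetCDF trajectory whose
#'   atoms match `structure_path`.
#' @param chains character(2), the chain identifiers of the two partners; or
#'   character(1) for an unbound single-chain system.
#' @param stride sampling interval in ns between retained snapshots.
#' @param dt time between consecutive frames of the source, in ns.
#' @param source label stored in the series (`"complex"`, `"unbound_A"`, ...).
#' @return A [SnapshotSeries-class].
#' @examples
#' spec <- toyComplexSpec(n_residues = 4, n_waters = 5, seed = 1)
#' toy <- genToyComplex(spec)
#' f <- tempfile(fileext = ".pdb")
#' writeSnapshotSeries(newSnapshotSeries(list(toy$complex)), f)
#' ser <- loadSeries(f, chains = c("A", "B"))
#' length(ser)
#' @export
loadSeries <- function(structure_path, trajectory_path = NULL,
                       chains = c("A", "B"), stride = 1, dt = 1,
                       source = "complex") {
    if (!file.exists(structure_path))
        stop("structure file not found: ", structure_path, call. = FALSE)
    pdb <- bio3d::read.pdb(structure_path, multi = TRUE, verbose = FALSE)
    at <- pdb$atom
    resname <- toupper(trimws(at$resid))
    is_water <- resname %in% .WATER_RESNAMES
    is_ion <- resname %in% .ION_RESNAMES & !is_water
    chain_col <- ifelse(is.na(at$chain), "", as.character(at$chain))

    avail <- sort(unique(chain_col[!is_water & !is_ion]))
    missing <- setdiff(chains, avail)
    if (length(missing))
        stop("chain(s) ", paste(missing, collapse = ", "),
             " not found; available chains: ",
             paste(avail, collapse = ", "), call. = FALSE)

    prot_idx <- which(chain_col %in% chains & !is_water & !is_ion)
    elem <- if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy))))
        toupper(trimws(at$elesy)) else inferElement(at$elety)
    wat_o <- which(is_water & toupper(trimws(at$elety)) %in%
                       c("O", "OW", "OH2"))

    # stable integer water ids from (chain, resno)
    wkey <- paste(chain_col[wat_o], at$resno[wat_o])
    wid <- as.integer(factor(wkey, levels = unique(wkey)))

    xyz <- pdb$xyz
    if (!is.null(trajectory_path)) {
        ext <- tolower(tools::file_ext(trajectory_path))
        xyz <- switch(ext,
            dcd = bio3d::read.dcd(trajectory_path, verbose = FALSE),
            nc = ,
            ncdf = bio3d::read.ncdf(trajectory_path),
            stop("unsupported trajectory format '.", ext,
                 "'; use DCD or NetCDF (XTC is not supported)",
                 call. = FALSE))
    }
    xyz <- as.matrix(xyz)
    if (ncol(xyz) != 3L * nrow(at))
        stop("trajectory atom count does not match the topology",
             call. = FALSE)
    n_frames <- nrow(xyz)

    times <- (seq_len(n_frames) - 1) * dt
    wanted <- seq(0, max(times), by = stride)
    keep <- unique(vapply(wanted, function(tw)
        which.min(abs(times - tw)), integer(1)))
    if (length(keep) == 0L)
        stop("no snapshots left after striding", call. = FALSE)

    frames <- lapply(keep, function(i) {
        co <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
        adf <- data.frame(chain = chain_col[prot_idx],
                          resid = at$resno[prot_idx],
                          resname = resname[prot_idx],
                          atom = trimws(at$elety[prot_idx]),
                          elem = elem[prot_idx],
                          x = co[prot_idx, 1], y = co[prot_idx, 2],
                          z = co[prot_idx, 3], stringsAsFactors = FALSE)
        wdf <- if (length(wat_o))
            data.frame(water_id = wid, x = co[wat_o, 1], y = co[wat_o, 2],
                       z = co[wat_o, 3], stringsAsFactors = FALSE)
        else NULL
        newSnapshot(adf, wdf, time = times[i])
    })
    newSnapshotSeries(frames, dt = stride, source = source)
}

.pdbAtomLine <- function(serial, name, resname, chain, resno, x, y, z, elem) {
    name <- ifelse(nchar(name) < 4, sprintf(" %-3s", name),
                   sprintf("%-4s", name))
    sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial %% 100000L, name, substr(resname, 1, 3), chain,
            resno %% 10000L, x, y, z, 1, 0, elem)
}

#' Write a snapshot series as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per snapshot; protein heavy atoms and hydrogens on
#' their own chains, waters as single-oxygen HOH residues on chain `W`. The
#' resulting file round-trips through [loadSeries()] to 1e-3 Angstrom (the
#' PDB coordinate precision).
#'
#' @param series a [SnapshotSeries-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeSnapshotSeries <- function(series, path) {
    stopifnot(is(series, "SnapshotSeries"))
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("cannot write to ", path,
                                             call. = FALSE))
    on.exit(close(con))
    for (m in seq_along(series@snapshots)) {
        s <- series@snapshots[[m]]
        writeLines(sprintf("MODEL     %4d", m), con)
        adf <- rbind(s@atoms, s@hydrogens)
        adf <- adf[order(adf$chain, adf$resid), , drop = FALSE]
        serial <- 0L
        if (nrow(adf)) {
            serial <- seq_len(nrow(adf))
            writeLines(.pdbAtomLine(serial, adf$atom, adf$resname, adf$chain,
                                    adf$resid, adf$x, adf$y, adf$z,
                                    adf$elem), con)
            serial <- nrow(adf)
        }
        w <- s@waters
        if (nrow(w))
            writeLines(.pdbAtomLine(serial + seq_len(nrow(w)), "O", "HOH",
                                    "W", w$water_id, w$x, w$y, w$z, "O"),
                       con)
        writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    invisible(path)
}

#' Write a deterministic CSV table
#'
#' Writes records as UTF-8 CSV with a header and '.' as decimal separator.
#' Rows are ordered by the time column when one is present (`time_ns` or
#' `time`), then lexicographically by the remaining columns, so repeated runs
#' produce byte-identical files.
#'
#' @param records data.frame (zero rows allowed: header-only file).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeTable <- function(records, path) {
    records <- as.data.frame(records, stringsAsFactors = FALSE)
    if (nrow(records) > 1) {
        tcol <- intersect(c("time_ns", "time"), names(records))[1]
        keys <- c(tcol[!is.na(tcol)],
                  setdiff(names(records), tcol))
        ord <- do.call(order, lapply(records[keys], function(v)
            if (is.numeric(v)) v else as.character(v)))
        records <- records[ord, , drop = FALSE]
    }
    ok <- tryCatch({
        utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                         fileEncoding = "UTF-8")
        TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write table to ", path, call. = FALSE)
    invisible(path)
}
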