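# Hydration shells, released waters upon complexation, interfacial waters,
# water-mediated (bridging) contacts and residue-water contact statistics.
# All distances are water-oxygen to protein-heavy-atom minima.

#' Hydration-shell water counts of a snapshot
#'
#' Bins every water by its minimal distance d_m to the protein heavy atoms:
#' first shell d_m < `first` (3.4 Angstrom), second shell
#' `first` <= d_m < `second` (5.0 Angstrom); half-open intervals, so no
#' water is counted in both shells.
#'
#' @param snapshot a [Snapshot-class].
#' @param chains optional chain subset defining "the protein".
#' @param first,second shell boundaries in Angstrom.
#' @return named integer vector `n_first`, `n_second`.
#' @export
shellCounts <- function(snapshot, chains = NULL, first = 3.4,
                        second = 5.0) {
    a <- snapshot@atoms
    if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
    d <- waterMinDist(snapshot@waters, xyzMatrix(a))
    c(n_first = sum(d < first),
      n_second = sum(d >= first & d < second))
}

#' Shell counts along a snapshot series
#'
#' @param series a [SnapshotSeries-class].
#' @inheritParams shellCounts
#' @return data.frame `time_ns`, `n_first`, `n_second`.
#' @export
shellCountsSeries <- function(series, chains = NULL, first = 3.4,
                              second = 5.0) {
    rows <- lapply(snapshots(series), function(s) {
        sc <- shellCounts(s, chains, first, second)
        data.frame(time_ns = s@time, n_first = sc[["n_first"]],
                   n_second = sc[["n_second"]])
    })
    do.call(rbind, rows)
}

#' Waters released upon complexation
#'
#' Compares the time-averaged shell population of the bound complex with
#' the sum over the two unbound partners:
#' N_released = mean N_shell(free A) + mean N_shell(free B)
#' - mean N_shell(complex). A positive value means the complex sheds shell
#' waters relative to the isolated chains. The standard error combines the
#' per-series standard errors of the three means in quadrature.
#'
#' @param complex_series,freeA_series,freeB_series [SnapshotSeries-class]
#'   objects for the bound complex and the two unbound chains.
#' @param shell `"first"` or `"second"`.
#' @param first,second shell boundaries in Angstrom (must be identical
#'   across the three series).
#' @return list `released`, `se`, and the three per-series means.
#' @export
releasedWaters <- function(complex_series, freeA_series, freeB_series,
                           shell = c("first", "second"), first = 3.4,
                           second = 5.0) {
    shell <- match.arg(shell)
    col <- if (shell == "first") "n_first" else "n_second"
    grab <- function(ser) {
        if (length(ser) == 0L) stop("empty series", call. = FALSE)
        v <- shellCountsSeries(ser, first = first, second = second)[[col]]
        list(mean = mean(v),
             se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
    }
    a <- grab(freeA_series); b <- grab(freeB_series)
    cc <- grab(complex_series)
    list(released = a$mean + b$mean - cc$mean,
         se = sqrt(a$se^2 + b$se^2 + cc$se^2),
         mean_freeA = a$mean, mean_freeB = b$mean, mean_complex = cc$mean)
}

#' Interfacial waters of a snapshot
#'
#' Waters whose oxygen lies strictly within `cutoff` of at least one heavy
#' atom of each of the two chains simultaneously.
#'
#' @param snapshot a [Snapshot-class] with two chains.
#' @param cutoff distance cutoff in Angstrom.
#' @return integer vector of water ids.
#' @export
interfacialWaters <- function(snapshot, cutoff = 4.0) {
    ch <- requireTwoChains(snapshot)
    w <- snapshot@waters
    if (nrow(w) == 0L) return(integer(0))
    a <- snapshot@atoms
    d1 <- waterMinDist(w, xyzMatrix(a[a$chain == ch[1], , drop = FALSE]))
    d2 <- waterMinDist(w, xyzMatrix(a[a$chain == ch[2], , drop = FALSE]))
    w$water_id[d1 < cutoff & d2 < cutoff]
}

# Per-snapshot bridge pairs: residues r1 (chain 1) and r2 (chain 2) both
# strictly within `cutoff` of the same water oxygen.
.bridgePairs <- function(snapshot, cutoff) {
    ch <- requireTwoChains(snapshot)
    w <- snapshot@waters
    if (nrow(w) == 0L) return(character(0))
    a <- snapshot@atoms
    res_near <- function(chain) {
        sub <- a[a$chain == chain, , drop = FALSE]
        d <- crossDist(xyzMatrix(w), xyzMatrix(sub))
        lapply(seq_len(nrow(w)), function(i)
            unique(sub$resid[d[i, ] < cutoff]))
    }
    n1 <- res_near(ch[1])
    n2 <- res_near(ch[2])
    keys <- unlist(lapply(seq_len(nrow(w)), function(i) {
        if (length(n1[[i]]) == 0L || length(n2[[i]]) == 0L)
            return(character(0))
        g <- expand.grid(r1 = n1[[i]], r2 = n2[[i]])
        paste0(ch[1], ":", g$r1, "|", ch[2], ":", g$r2)
    }))
    unique(keys)   # a pair counts once per snapshot
}

#' Water-mediated contacts along a series
#'
#' A water-mediated contact between residues r1 (chain 1) and r2 (chain 2)
#' exists in a snapshot when some water is simultaneously within `cutoff`
#' of both residues (a residue-water-residue triplet). The reported
#' frequency is the fraction of snapshots containing at least one such
#' triplet; the bridging water identity is allowed to change between
#' snapshots. With cluster labels, per-cluster frequencies are added
#' (cluster `"all"` is the whole series); with a region table, each residue
#' is annotated by its interface region.
#'
#' @param series a [SnapshotSeries-class].
#' @param labels optional [InterfaceClustering-class] or integer vector.
#' @param cutoff residue-water distance cutoff in Angstrom.
#' @param regions optional data.frame from [classifyRegions()].
#' @return data.frame `chain1`, `resid1`, `chain2`, `resid2`, `cluster`,
#'   `frequency` (+ `region1`, `region2` when regions are given).
#' @export
waterMediatedContacts <- function(series, labels = NULL, cutoff = 4.0,
                                  regions = NULL) {
    per_snap <- lapply(snapshots(series), .bridgePairs, cutoff = cutoff)
    universe <- sort(unique(unlist(per_snap)))
    if (length(universe) == 0L)
        return(data.frame(chain1 = character(0), resid1 = integer(0),
                          chain2 = character(0), resid2 = integer(0),
                          cluster = character(0), frequency = numeric(0)))
    inc <- vapply(per_snap, function(k) universe %in% k,
                  logical(length(universe)))
    inc <- matrix(inc, nrow = length(universe))
    groups <- list(all = seq_along(per_snap))
    if (!is.null(labels)) {
        lab <- .labelsVector(labels)
        for (cl in sort(unique(lab)))
            groups[[as.character(cl)]] <- which(lab == cl)
    }
    parts <- do.call(rbind, strsplit(universe, "[:|]"))
    rows <- lapply(names(groups), function(g) {
        idx <- groups[[g]]
        data.frame(chain1 = parts[, 1], resid1 = as.integer(parts[, 2]),
                   chain2 = parts[, 3], resid2 = as.integer(parts[, 4]),
                   cluster = g,
                   frequency = rowMeans(inc[, idx, drop = FALSE]),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!is.null(regions)) {
        rkey <- paste(regions$chain, regions$resid)
        out$region1 <- regions$region[match(paste(out$chain1, out$resid1),
                                            rkey)]
        out$region2 <- regions$region[match(paste(out$chain2, out$resid2),
                                            rkey)]
    }
    rownames(out) <- NULL
    out
}

#' Residue-interfacial-water contact counts per cluster
#'
#' For each interface residue and snapshot, counts the interfacial waters
#' (within `cutoff` of both chains) that lie within `cutoff` of the
#' residue. Counts are summarised per cluster (quartiles and mean), and
#' residues whose count standard deviation over the whole series exceeds
#' `sd_flag` are flagged as having variable solvation.
#'
#' @param series a [SnapshotSeries-class].
#' @param labels an [InterfaceClustering-class] or integer vector.
#' @param regions optional [classifyRegions()] table restricting the
#'   residues to interface residues (all residues when `NULL`).
#' @param cutoff distance cutoff in Angstrom.
#' @param sd_flag standard-deviation threshold for the variability flag.
#' @return list `counts` (per residue and snapshot), `summary` (per
#'   residue and cluster: quartiles, mean, overall sd and `variable`
#'   flag).
#' @export
residueWaterContactCounts <- function(series, labels, regions = NULL,
                                      cutoff = 4.0, sd_flag = 2) {
    lab <- .labelsVector(labels)
    frames <- snapshots(series)
    if (length(lab) != length(frames))
        stop("labels must align with the series", call. = FALSE)
    a0 <- frames[[1]]@atoms
    resdf <- unique(a0[, c("chain", "resid")])
    if (!is.null(regions)) {
        keep <- regions$region != "non_interface"
        rkey <- paste(regions$chain[keep], regions$resid[keep])
        resdf <- resdf[paste(resdf$chain, resdf$resid) %in% rkey, ,
                       drop = FALSE]
    }
    rows <- lapply(seq_along(frames), function(t) {
        s <- frames[[t]]
        iw <- interfacialWaters(s, cutoff)
        w <- s@waters[s@waters$water_id %in% iw, , drop = FALSE]
        n <- vapply(seq_len(nrow(resdf)), function(i) {
            sub <- s@atoms[s@atoms$chain == resdf$chain[i] &
                           s@atoms$resid == resdf$resid[i], , drop = FALSE]
            if (nrow(w) == 0L) return(0L)
            d <- crossDist(xyzMatrix(w), xyzMatrix(sub))
            sum(apply(d, 1, min) < cutoff)
        }, integer(1))
        data.frame(chain = resdf$chain, resid = resdf$resid,
                   time_ns = s@time, cluster = lab[t], n_waters = n,
                   stringsAsFactors = FALSE)
    })
    counts <- do.call(rbind, rows)
    sp <- split(counts, list(counts$chain, counts$resid, counts$cluster),
                drop = TRUE)
    summ <- do.call(rbind, lapply(sp, function(d) {
        q <- stats::quantile(d$n_waters, c(0.25, 0.5, 0.75))
        data.frame(chain = d$chain[1], resid = d$resid[1],
                   cluster = d$cluster[1], q25 = q[[1]], median = q[[2]],
                   q75 = q[[3]], mean = mean(d$n_waters),
                   stringsAsFactors = FALSE)
    }))
    sds <- stats::aggregate(n_waters ~ chain + resid, data = counts,
                            FUN = stats::sd)
    names(sds)[3] <- "sd"
    summ <- merge(summ, sds, by = c("chain", "resid"))
    summ$variable <- summ$sd > sd_flag
    summ <- summ[order(summ$chain, summ$resid, summ$cluster), ,
                 drop = FALSE]
    rownames(summ) <- NULL
    rownames(counts) <- NULL
    list(counts = counts, summary = summ)
}

#' Histogram of water-protein minimal distances
#'
#' Diagnostic used to locate hydration-shell boundaries: counts of waters
#' per `binwidth` interval of the minimal water-protein heavy-atom
#' distance, pooled over the frames of a series.
#'
#' @param series a [SnapshotSeries-class] (or single [Snapshot-class]).
#' @param binwidth histogram bin width in Angstrom.
#' @param max_dist histogram upper bound in Angstrom.
#' @return data.frame `d_lo`, `d_hi`, `count`.
#' @export
waterDistanceHistogram <- function(series, binwidth = 0.1, max_dist = 8) {
    frames <- if (is(series, "Snapshot")) list(series) else
        snapshots(series)
    d <- unlist(lapply(frames, function(s)
        waterMinDist(s@waters, xyzMatrix(s@atoms))))
    d <- d[is.finite(d) & d < max_dist]
    br <- seq(0, max_dist, by = binwidth)
    h <- hist(d, breaks = br, plot = FALSE)
    data.frame(d_lo = utils::head(br, -1), d_hi = br[-1], count = h$counts)
}
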