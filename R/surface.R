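# Solvent-accessible surface areas and geometric interface descriptors.
# ASA uses a Shrake-Rupley quadrature written here (no SASA engine is
# bundled with the R stack); it agrees with the analytic sphere to ~1% at
# the default 960 points. Constants below are documented package choices.

# Protein heavy-atom vdW radii (NACCESS-like, Chothia-style set), Angstrom.
.VDW_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
                SE = 1.90, H = 1.00, D = 1.00)

# Maximal residue ASA in a Gly-X-Gly tripeptide (theoretical reference
# values), Angstrom^2; used to normalise relative ASA.
.MAX_ASA <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0,
              CYS = 167.0, GLU = 223.0, GLN = 225.0, GLY = 104.0,
              HIS = 224.0, ILE = 197.0, LEU = 201.0, LYS = 236.0,
              MET = 224.0, PHE = 240.0, PRO = 159.0, SER = 155.0,
              THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
.spherePoints <- function(n) {
    i <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * i / n)
    theta <- pi * (1 + sqrt(5)) * i
    cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.atomRadii <- function(elem) {
    r <- .VDW_RADII[toupper(elem)]
    if (anyNA(r))
        stop("no vdW radius for element(s): ",
             paste(unique(elem[is.na(r)]), collapse = ", "), call. = FALSE)
    unname(r)
}

# Per-atom solvent-accessible area by Shrake-Rupley quadrature.
.shrakeRupley <- function(coords, radii, probe = 1.4, n_points = 960) {
    n <- nrow(coords)
    pts <- .spherePoints(n_points)
    R <- radii + probe
    asa <- numeric(n)
    if (n == 1L) return(4 * pi * R^2)
    d2 <- crossDist2(coords, coords)
    for (i in seq_len(n)) {
        nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
        p <- sweep(pts * R[i], 2, coords[i, ], "+")
        acc <- rep(TRUE, n_points)
        for (j in nb) {
            blocked <- (p[, 1] - coords[j, 1])^2 +
                (p[, 2] - coords[j, 2])^2 +
                (p[, 3] - coords[j, 3])^2 < R[j]^2
            acc <- acc & !blocked
            if (!any(acc)) break
        }
        asa[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
    }
    asa
}

#' Solvent-accessible surface area of a structure
#'
#' Shrake-Rupley quadrature ASA with a water-sized probe, summed per
#' residue; relative ASA normalises by the residue's maximal exposure in a
#' Gly-X-Gly reference tripeptide (NA for non-standard residues). Waters in
#' the snapshot are ignored.
#'
#' @param snapshot a [Snapshot-class] (one or two chains).
#' @param probe probe radius in Angstrom (1.4 approximates a water).
#' @param n_points quadrature points per atom.
#' @param chains optional chain subset to compute on.
#' @return data.frame with columns `chain`, `resid`, `resname`, `asa`
#'   (Angstrom^2) and `rel_asa` (percent); total area in attribute
#'   `total`.
#' @export
computeAsa <- function(snapshot, probe = 1.4, n_points = 960,
                       chains = NULL) {
    a <- snapshot@atoms
    if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
    if (nrow(a) == 0L) stop("no atoms selected", call. = FALSE)
    asa <- .shrakeRupley(xyzMatrix(a), .atomRadii(a$elem), probe, n_points)
    key <- paste(a$chain, a$resid)
    agg <- rowsum(asa, key, reorder = FALSE)
    first <- !duplicated(key)
    out <- data.frame(chain = a$chain[first], resid = a$resid[first],
                      resname = a$resname[first],
                      asa = agg[match(unique(key), rownames(agg)), 1],
                      stringsAsFactors = FALSE)
    out$rel_asa <- 100 * out$asa / unname(.MAX_ASA[out$resname])
    out <- out[order(out$chain, out$resid), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "total") <- sum(asa)
    out
}

#' Per-residue ASA in the complex and in the isolated chains
#'
#' Computes the ASA of each residue twice: in the intact two-chain complex
#' and in its isolated chain extracted from the complex (same coordinates,
#' partner removed). These two contexts are what the buried surface,
#' interface detection and core/rim/support classification are defined on.
#'
#' @inheritParams computeAsa
#' @return list with `residues` (data.frame: `chain`, `resid`, `resname`,
#'   `asa_isolated`, `rel_isolated`, `asa_complex`, `rel_complex`,
#'   `delta_asa`) and `totals` (named numeric: `ASA_A`, `ASA_B`,
#'   `ASA_AB`).
#' @export
asaContexts <- function(snapshot, probe = 1.4, n_points = 960) {
    ch <- requireTwoChains(snapshot)
    cplx <- computeAsa(snapshot, probe, n_points)
    iso <- lapply(ch, function(c1)
        computeAsa(snapshot, probe, n_points, chains = c1))
    isodf <- rbind(iso[[1]], iso[[2]])
    m <- match(paste(cplx$chain, cplx$resid),
               paste(isodf$chain, isodf$resid))
    res <- data.frame(chain = cplx$chain, resid = cplx$resid,
                      resname = cplx$resname,
                      asa_isolated = isodf$asa[m],
                      rel_isolated = isodf$rel_asa[m],
                      asa_complex = cplx$asa,
                      rel_complex = cplx$rel_asa,
                      stringsAsFactors = FALSE)
    res$delta_asa <- res$asa_isolated - res$asa_complex
    totals <- c(ASA_A = attr(iso[[1]], "total"),
                ASA_B = attr(iso[[2]], "total"),
                ASA_AB = attr(cplx, "total"))
    list(residues = res, totals = totals)
}

#' Buried surface area of a complex
#'
#' `deltaAsa()` evaluates ASA_A + ASA_B - ASA_AB from the three total
#' areas; `deltaAsaFromSnapshot()` computes the contexts first. A result
#' that is negative beyond the quadrature tolerance signals inconsistent
#' inputs and errors; small negative values (non-touching chains) are
#' clamped to 0.
#'
#' @param asa_A,asa_B total ASA of each isolated chain (Angstrom^2).
#' @param asa_AB total ASA of the complex (Angstrom^2).
#' @param tol tolerance for the negativity check, as a fraction of
#'   `asa_AB`.
#' @return Buried area in Angstrom^2.
#' @examples
#' deltaAsa(500, 600, 900)   # 200 A^2 buried
#' @export
deltaAsa <- function(asa_A, asa_B, asa_AB, tol = 0.02) {
    stopifnot(asa_A >= 0, asa_B >= 0, asa_AB >= 0)
    d <- asa_A + asa_B - asa_AB
    if (d < -tol * max(asa_AB, 1))
        stop("negative buried area (", format(d),
             " A^2): inconsistent ASA inputs", call. = FALSE)
    max(d, 0)
}

#' @rdname deltaAsa
#' @inheritParams computeAsa
#' @export
deltaAsaFromSnapshot <- function(snapshot, probe = 1.4, n_points = 960) {
    tot <- asaContexts(snapshot, probe, n_points)$totals
    deltaAsa(tot[["ASA_A"]], tot[["ASA_B"]], tot[["ASA_AB"]])
}

#' Classify interface residues into support, core and rim
#'
#' Levy-style regions: a residue is part of the interface when its ASA
#' changes between the isolated chain and the complex (by more than
#' `min_dasa`, which suppresses quadrature noise). Interface residues are
#' *support* when their relative ASA in the isolated chain is below
#' `threshold` percent, *rim* when their relative ASA in the complex is
#' above it, and *core* when the relative ASA drops from above to below the
#' threshold upon binding. Interface residues at exactly the threshold
#' (failing all three strict rules) are labelled rim (peripheral
#' catch-all).
#'
#' @param contexts output of [asaContexts()].
#' @param threshold relative-ASA threshold in percent.
#' @param min_dasa minimal per-residue buried area (Angstrom^2) to count as
#'   interface.
#' @return data.frame `chain`, `resid`, `resname`, `region` with region in
#'   `support`, `core`, `rim`, `non_interface`.
#' @export
classifyRegions <- function(contexts, threshold = 25, min_dasa = 0.1) {
    r <- contexts$residues
    region <- rep("non_interface", nrow(r))
    iface <- r$delta_asa > min_dasa
    sup <- iface & !is.na(r$rel_isolated) & r$rel_isolated < threshold
    rim <- iface & !is.na(r$rel_complex) & r$rel_complex > threshold
    core <- iface & !is.na(r$rel_isolated) & r$rel_isolated > threshold &
        r$rel_complex < threshold
    region[iface] <- "rim"          # catch-all for threshold ties
    region[core] <- "core"
    region[rim] <- "rim"
    region[sup] <- "support"
    data.frame(chain = r$chain, resid = r$resid, resname = r$resname,
               region = region, stringsAsFactors = FALSE)
}

#' Gap volume and gap index of an interface
#'
#' Grid approximation of the empty volume enclosed between the two chains:
#' for every cross-chain atom pair closer than `pair_cutoff`, a sphere is
#' placed at the pair midpoint and shrunk until it touches no atom's vdW
#' surface; spheres with final radius in `[r_min, r_max]` are kept and the
#' volume of their union is integrated on a cubic grid of spacing `grid`.
#' The gap index is twice the gap volume divided by the buried area
#' (undefined, `NA`, when the chains bury no surface); lower values mean
#' better shape complementarity.
#'
#' @param snapshot a [Snapshot-class] with two chains.
#' @param delta_asa buried area in Angstrom^2; computed from the snapshot
#'   when `NULL`.
#' @param grid grid spacing (Angstrom).
#' @param pair_cutoff maximal cross-chain atom distance defining candidate
#'   gap spheres (Angstrom).
#' @param r_min,r_max retained sphere radius bounds (Angstrom).
#' @return list `gap_volume` (Angstrom^3), `delta_asa` (Angstrom^2),
#'   `gap_index` (Angstrom).
#' @export
gapDescriptors <- function(snapshot, delta_asa = NULL, grid = 0.8,
                           pair_cutoff = 10, r_min = 1.0, r_max = 5.0) {
    ch <- requireTwoChains(snapshot)
    a <- snapshot@atoms
    co <- xyzMatrix(a)
    rad <- .atomRadii(a$elem)
    i1 <- which(a$chain == ch[1])
    i2 <- which(a$chain == ch[2])
    d <- crossDist(co[i1, , drop = FALSE], co[i2, , drop = FALSE])
    hit <- which(d <= pair_cutoff, arr.ind = TRUE)
    if (is.null(delta_asa))
        delta_asa <- deltaAsaFromSnapshot(snapshot)
    if (nrow(hit) == 0L)
        return(list(gap_volume = 0, delta_asa = delta_asa,
                    gap_index = if (delta_asa > 0) 0 else NA_real_))
    mid <- (co[i1[hit[, 1]], , drop = FALSE] +
            co[i2[hit[, 2]], , drop = FALSE]) / 2
    # shrink: largest radius not penetrating any vdW sphere
    dc <- crossDist(mid, co)
    rsph <- apply(sweep(dc, 2, rad, "-"), 1, min)
    keep <- rsph >= r_min & rsph <= r_max
    if (!any(keep))
        return(list(gap_volume = 0, delta_asa = delta_asa,
                    gap_index = if (delta_asa > 0) 0 else NA_real_))
    ctr <- mid[keep, , drop = FALSE]
    rs <- rsph[keep]
    lo <- apply(ctr - rs, 2, min)
    hi <- apply(ctr + rs, 2, max)
    gx <- seq(lo[1], hi[1], by = grid)
    gy <- seq(lo[2], hi[2], by = grid)
    gz <- seq(lo[3], hi[3], by = grid)
    pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    inside <- rep(FALSE, nrow(pts))
    for (s in seq_along(rs)) {
        todo <- which(!inside)
        if (!length(todo)) break
        d2 <- (pts[todo, 1] - ctr[s, 1])^2 + (pts[todo, 2] - ctr[s, 2])^2 +
            (pts[todo, 3] - ctr[s, 3])^2
        inside[todo[d2 <= rs[s]^2]] <- TRUE
    }
    vol <- sum(inside) * grid^3
    list(gap_volume = vol, delta_asa = delta_asa,
         gap_index = if (delta_asa > 0) 2 * vol / delta_asa else NA_real_)
}

#' Gap index from precomputed quantities
#'
#' @param gap_volume gap volume in Angstrom^3.
#' @param delta_asa buried area in Angstrom^2.
#' @return Gap index in Angstrom (`NA` when `delta_asa` is 0).
#' @examples
#' gapIndex(700, 1000)   # 1.4 A
#' @export
gapIndex <- function(gap_volume, delta_asa) {
    stopifnot(gap_volume >= 0, delta_asa >= 0)
    if (delta_asa == 0) return(NA_real_)
    2 * gap_volume / delta_asa
}

#' Interface RMSD between two snapshots
#'
#' The interface set is defined on `snapshot_a` (CAPRI-style): residues of
#' either chain with any heavy atom within `interface_cutoff` of the other
#' chain. The backbone atoms of that set are optimally superposed
#' (least-squares) between the two snapshots and the RMSD over them is
#' returned.
#'
#' @param snapshot_a,snapshot_b two [Snapshot-class] objects with identical
#'   topology; `snapshot_a` defines the interface set.
#' @param interface_cutoff heavy-atom distance defining interface residues
#'   (Angstrom).
#' @param backbone atom names treated as backbone.
#' @return RMSD in Angstrom.
#' @export
interfaceRmsd <- function(snapshot_a, snapshot_b, interface_cutoff = 10,
                          backbone = c("N", "CA", "C", "O")) {
    ch <- requireTwoChains(snapshot_a)
    a <- snapshot_a@atoms
    b <- snapshot_b@atoms
    if (nrow(a) != nrow(b) ||
        !all(paste(a$chain, a$resid, a$atom) ==
             paste(b$chain, b$resid, b$atom)))
        stop("snapshots must share an identical topology", call. = FALSE)
    i1 <- a$chain == ch[1]
    d <- crossDist(xyzMatrix(a[i1, ]), xyzMatrix(a[!i1, ]))
    near <- d <= interface_cutoff
    res1 <- unique(a$resid[i1][apply(near, 1, any)])
    res2 <- unique(a$resid[!i1][apply(near, 2, any)])
    sel <- (a$chain == ch[1] & a$resid %in% res1 |
            a$chain == ch[2] & a$resid %in% res2) & a$atom %in% backbone
    if (!any(sel))
        stop("empty interface set at cutoff ", interface_cutoff,
             call. = FALSE)
    xa <- xyzMatrix(a[sel, ])
    xb <- xyzMatrix(b[sel, ])
    fit <- bio3d::fit.xyz(fixed = as.vector(t(xa)),
                          mobile = as.vector(t(xb)),
                          fixed.inds = seq_len(3 * nrow(xa)),
                          mobile.inds = seq_len(3 * nrow(xb)))
    xb2 <- matrix(fit, ncol = 3, byrow = TRUE)
    sqrt(mean(rowSums((xa - xb2)^2)))
}
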