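# Cross-chain residue contacts, their conservation in time, polar/apolar
# typing, and geometric interface hydrogen-bond counting.

#' Default polar residue alphabet
#'
#' The polar/apolar partition used by [contactTypeFractions()]: polar
#' residues are those with side chains capable of hydrogen bonding or
#' carrying charge; the remaining 8 standard residues are apolar. The
#' partition is a package choice (standard physico-chemical grouping) and is
#' configurable in every function that uses it.
#'
#' @return character vector of 3-letter residue codes.
#' @export
polarResidues <- function() {
    c("ARG", "LYS", "HIS", "ASP", "GLU", "ASN", "GLN", "SER", "THR",
      "TYR", "TRP", "CYS")
}

.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

#' Compute the cross-chain residue contacts of a snapshot
#'
#' A residue pair (one residue from each chain) is in contact when the
#' minimal distance between their heavy atoms is at most `cutoff` (boundary
#' inclusive); the default 5 Angstrom is the conventional residue-contact
#' cutoff for protein-protein interfaces.
#'
#' @param snapshot a [Snapshot-class] with exactly two protein chains.
#' @param cutoff contact distance cutoff in Angstrom.
#' @return A [ContactSet-class]; pairs are reported with partner 1 taken
#'   from the alphabetically first chain.
#' @examples
#' toy <- genToyComplex(toyComplexSpec(n_residues = 4, interface_gap = 4,
#'                                     n_waters = 0, seed = 2))
#' computeContacts(toy$complex)
#' @export
computeContacts <- function(snapshot, cutoff = 5.0) {
    ch <- requireTwoChains(snapshot)
    a <- snapshot@atoms
    a1 <- a[a$chain == ch[1], , drop = FALSE]
    a2 <- a[a$chain == ch[2], , drop = FALSE]
    d2 <- crossDist2(xyzMatrix(a1), xyzMatrix(a2))
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) == 0L)
        return(newContactSet(.emptyPairs(), time = snapshot@time))
    pairs <- data.frame(chain1 = ch[1], resid1 = a1$resid[hit[, 1]],
                        resname1 = a1$resname[hit[, 1]],
                        chain2 = ch[2], resid2 = a2$resid[hit[, 2]],
                        resname2 = a2$resname[hit[, 2]],
                        stringsAsFactors = FALSE)
    newContactSet(pairs, time = snapshot@time)
}

#' Conservation of contacts relative to a reference snapshot
#'
#' For each snapshot t, the fraction of the reference contact set still
#' present: |C_t intersect C_ref| / |C_ref|. Also reports the absolute
#' number of contacts and, when residue names are available, the
#' polar-polar / apolar-apolar / mixed composition of each snapshot's
#' contact set.
#'
#' @param contact_series list of [ContactSet-class] in time order.
#' @param reference_index index of the reference snapshot (default: first).
#' @param polar_set polar residue alphabet for typing; `NULL` skips typing.
#' @return data.frame with columns `time_ns`, `fraction_initial`,
#'   `n_contacts`, and (when typed) `f_polar_polar`, `f_apolar_apolar`,
#'   `f_mixed`.
#' @export
conservationSeries <- function(contact_series, reference_index = 1,
                               polar_set = polarResidues()) {
    if (length(contact_series) == 0L)
        stop("empty contact series", call. = FALSE)
    ref <- contactKeys(contact_series[[reference_index]])
    if (length(ref) == 0L)
        stop("reference contact set is empty: conservation is undefined",
             call. = FALSE)
    typed <- !is.null(polar_set) &&
        all(vapply(contact_series, function(s)
            nrow(s@pairs) == 0L || !anyNA(s@pairs$resname1), logical(1)))
    rows <- lapply(seq_along(contact_series), function(i) {
        cs <- contact_series[[i]]
        keys <- contactKeys(cs)
        out <- data.frame(
            time_ns = cs@time,
            fraction_initial = length(intersect(keys, ref)) / length(ref),
            n_contacts = length(keys))
        if (typed) {
            f <- contactTypeFractions(cs, polar_set = polar_set)
            out$f_polar_polar <- f[["polar_polar"]]
            out$f_apolar_apolar <- f[["apolar_apolar"]]
            out$f_mixed <- f[["mixed"]]
        }
        out
    })
    do.call(rbind, rows)
}

#' Polar/apolar composition of a contact set
#'
#' Classifies each contact by the nature of its two residues: both polar,
#' both apolar, or mixed. Fractions sum to 1 for a non-empty set; the empty
#' set returns (0, 0, 0) with attribute `empty = TRUE`.
#'
#' @param contact_set a [ContactSet-class] with residue names.
#' @param polar_set polar residue alphabet (3-letter codes).
#' @param fallback optional class (`"polar"` or `"apolar"`) for residue
#'   names outside the 20 standard residues; unknown names error otherwise.
#' @return named numeric(3): `polar_polar`, `apolar_apolar`, `mixed`.
#' @examples
#' cs <- newContactSet(data.frame(chain1 = "A", resid1 = 1, resname1 = "LYS",
#'                                chain2 = "B", resid2 = 2, resname2 = "ASP"))
#' contactTypeFractions(cs)
#' @export
contactTypeFractions <- function(contact_set, polar_set = polarResidues(),
                                 fallback = NULL) {
    p <- contactPairs(contact_set)
    if (nrow(p) == 0L)
        return(structure(c(polar_polar = 0, apolar_apolar = 0, mixed = 0),
                         empty = TRUE))
    classify <- function(rn) {
        known <- rn %in% .STANDARD_AA
        if (any(!known) || anyNA(rn)) {
            if (is.null(fallback))
                stop("unknown residue name(s): ",
                     paste(unique(rn[!known | is.na(rn)]), collapse = ", "),
                     "; supply `fallback` to classify them", call. = FALSE)
            out <- ifelse(known & !is.na(rn), rn %in% polar_set,
                          fallback == "polar")
            return(out)
        }
        rn %in% polar_set
    }
    p1 <- classify(p$resname1)
    p2 <- classify(p$resname2)
    n <- nrow(p)
    c(polar_polar = sum(p1 & p2) / n,
      apolar_apolar = sum(!p1 & !p2) / n,
      mixed = sum(xor(p1, p2)) / n)
}

# Hydrogen-bond donor/acceptor heavy atoms per standard residue. Backbone N
# is a donor (except proline); backbone O (and terminal OXT) an acceptor.
.HB_DONORS <- list(
    ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
    HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
    TRP = "NE1", TYR = "OH", CYS = "SG")
.HB_ACCEPTORS <- list(
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
    GLN = "OE1", HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1",
    TYR = "OH", MET = "SD")

.hbondRole <- function(a, role) {
    tbl <- if (role == "donor") .HB_DONORS else .HB_ACCEPTORS
    side <- mapply(function(rn, at) at %in% tbl[[rn]],
                   a$resname, a$atom, USE.NAMES = FALSE)
    side <- vapply(side, isTRUE, logical(1))
    bb <- if (role == "donor") a$atom == "N" & a$resname != "PRO"
          else a$atom %in% c("O", "OXT")
    side | bb
}

#' Count interface hydrogen bonds geometrically
#'
#' Counts cross-chain donor-acceptor heavy-atom pairs with donor-acceptor
#' distance at most `dist_cutoff`. When hydrogens are present in the
#' snapshot, a donor must additionally carry a hydrogen (within 1.25
#' Angstrom) whose hydrogen-donor-acceptor angle at the donor is at most
#' `angle_cutoff` degrees; donors without resolved hydrogens fall back to
#' the distance criterion. Donor/acceptor typing uses a fixed template for
#' the 20 standard residues (side chains plus backbone N/O).
#'
#' @param snapshot a [Snapshot-class] with two chains.
#' @param dist_cutoff donor-acceptor distance cutoff (Angstrom).
#' @param angle_cutoff H-donor-acceptor angle cutoff (degrees).
#' @return integer: number of cross-chain hydrogen bonds.
#' @export
countInterfaceHbonds <- function(snapshot, dist_cutoff = 3.5,
                                 angle_cutoff = 30) {
    ch <- requireTwoChains(snapshot)
    a <- snapshot@atoms
    don <- a[.hbondRole(a, "donor"), , drop = FALSE]
    acc <- a[.hbondRole(a, "acceptor"), , drop = FALSE]
    hyd <- snapshot@hydrogens
    count <- 0L
    for (ci in 1:2) {
        d <- don[don$chain == ch[ci], , drop = FALSE]
        ac <- acc[acc$chain == ch[3 - ci], , drop = FALSE]
        if (nrow(d) == 0L || nrow(ac) == 0L) next
        dd <- crossDist(xyzMatrix(d), xyzMatrix(ac))
        hit <- which(dd <= dist_cutoff, arr.ind = TRUE)
        if (nrow(hit) == 0L) next
        for (r in seq_len(nrow(hit))) {
            di <- hit[r, 1]; ai <- hit[r, 2]
            ok <- TRUE
            if (nrow(hyd) > 0) {
                hres <- hyd[hyd$chain == d$chain[di] &
                            hyd$resid == d$resid[di], , drop = FALSE]
                if (nrow(hres) > 0) {
                    dpos <- c(d$x[di], d$y[di], d$z[di])
                    hd <- crossDist(xyzMatrix(hres), matrix(dpos, 1))
                    hres <- hres[hd <= 1.25, , drop = FALSE]
                    if (nrow(hres) > 0) {
                        apos <- c(ac$x[ai], ac$y[ai], ac$z[ai])
                        va <- apos - dpos
                        ang <- apply(xyzMatrix(hres), 1, function(h) {
                            vh <- h - dpos
                            cosang <- sum(vh * va) /
                                (sqrt(sum(vh^2)) * sqrt(sum(va^2)))
                            acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
                        })
                        ok <- any(ang <= angle_cutoff)
                    }
                }
            }
            if (ok) count <- count + 1L
        }
    }
    count
}
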