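# Synthetic inputs for validation: substate-switching contact series with
# ground truth, toy pseudo-atomic complexes with explicit waters, and
# correlated sample pairs. Everything is deterministic under a fixed seed.

.POLAR_TOY <- c("LYS", "ASP", "SER", "GLN")
.APOLAR_TOY <- c("LEU", "ILE", "ALA", "VAL")

#' Specification of a substate-switching contact series
#'
#' Describes a contact-set time series with hidden long-lived substates: the
#' trajectory dwells in each substate for a prescribed number of snapshots,
#' and each snapshot's contact set is its substate's defining set with
#' independent per-contact flip noise. Flips act on the finite contact
#' universe formed by the union of all substate sets plus an optional decoy
#' pool, so absent->present flips stay within a known universe.
#'
#' @param substate_sets list of [ContactSet-class] (or pair data.frames),
#'   one per substate.
#' @param dwell_segments data.frame with columns `substate` (index into
#'   `substate_sets`) and `n` (number of consecutive snapshots).
#' @param flip_noise per-contact per-snapshot flip probability, in [0, 0.5).
#' @param decoy_pairs optional ContactSet/data.frame of extra never-true
#'   pairs added to the flip universe.
#' @param seed integer seed.
#' @return A list of class `"substateSpec"`.
#' @export
substateSpec <- function(substate_sets, dwell_segments, flip_noise = 0,
                         decoy_pairs = NULL, seed = 1) {
    substate_sets <- lapply(substate_sets, function(s)
        if (is(s, "ContactSet")) s else newContactSet(s))
    if (length(substate_sets) < 1L)
        stop("at least one substate is required", call. = FALSE)
    dwell_segments <- as.data.frame(dwell_segments)
    stopifnot(all(c("substate", "n") %in% names(dwell_segments)))
    if (any(dwell_segments$n <= 0))
        stop("dwell segment lengths must be positive", call. = FALSE)
    if (!all(dwell_segments$substate %in% seq_along(substate_sets)))
        stop("dwell segments refer to unknown substates", call. = FALSE)
    if (flip_noise < 0 || flip_noise >= 0.5)
        stop("flip_noise must be in [0, 0.5)", call. = FALSE)
    if (!is.null(decoy_pairs) && !is(decoy_pairs, "ContactSet"))
        decoy_pairs <- newContactSet(decoy_pairs)
    structure(list(substate_sets = substate_sets,
                   dwell_segments = dwell_segments,
                   flip_noise = flip_noise, decoy_pairs = decoy_pairs,
                   seed = as.integer(seed)),
              class = "substateSpec")
}

#' Generate a contact-set series with hidden substates
#'
#' @param spec a [substateSpec()].
#' @param dt time between snapshots in ns.
#' @return list with `sets` (list of [ContactSet-class], times filled in),
#'   `labels` (integer ground-truth substate per snapshot) and `universe`
#'   (character keys of the flip universe).
#' @examples
#' s1 <- newContactSet(data.frame(chain1 = "A", resid1 = 1:3,
#'                                chain2 = "B", resid2 = 1:3))
#' s2 <- newContactSet(data.frame(chain1 = "A", resid1 = 4:6,
#'                                chain2 = "B", resid2 = 4:6))
#' sp <- substateSpec(list(s1, s2),
#'                    data.frame(substate = c(1, 2), n = c(5, 5)))
#' out <- genContactSeries(sp)
#' out$labels
#' @export
genContactSeries <- function(spec, dt = 1) {
    stopifnot(inherits(spec, "substateSpec"))
    set.seed(spec$seed)
    pool <- do.call(rbind, lapply(spec$substate_sets, contactPairs))
    if (!is.null(spec$decoy_pairs))
        pool <- rbind(pool, contactPairs(spec$decoy_pairs))
    universe <- newContactSet(pool)   # de-duplicates, canonical order
    upairs <- contactPairs(universe)
    ukeys <- contactKeys(universe)
    nU <- length(ukeys)

    member <- vapply(spec$substate_sets, function(s)
        ukeys %in% contactKeys(s), logical(nU))
    member <- matrix(member, nrow = nU)

    labels <- rep(spec$dwell_segments$substate,
                  times = spec$dwell_segments$n)
    sets <- vector("list", length(labels))
    for (t in seq_along(labels)) {
        present <- member[, labels[t]]
        if (spec$flip_noise > 0) {
            flip <- stats::runif(nU) < spec$flip_noise
            present <- xor(present, flip)
        }
        sets[[t]] <- newContactSet(upairs[present, , drop = FALSE],
                                   time = (t - 1) * dt)
    }
    list(sets = sets, labels = as.integer(labels), universe = ukeys)
}

#' Specification of a toy two-chain pseudo-atomic complex
#'
#' Chains are rigid 3-atom residue triads on a jittered square lattice, the
#' two chains facing each other across a gap of `interface_gap` Angstrom
#' along z. Residue names are drawn from a polar/apolar alphabet so that
#' contact typing is exercised. Waters are placed uniformly in the box by
#' rejection sampling, excluding positions closer than `clash` (default
#' 2.4 Angstrom, roughly the sum of vdW radii minus allowed overlap) to any
#' heavy atom.
#'
#' @param n_residues residues per chain.
#' @param interface_gap closest approach of the two chains, in Angstrom.
#' @param n_waters number of waters placed around the complex.
#' @param box numeric(3), box edge lengths in Angstrom (centred on the
#'   system).
#' @param lattice spacing of the residue lattice, in Angstrom.
#' @param clash minimal water-heavy-atom distance, in Angstrom.
#' @param seed integer seed.
#' @return A list of class `"toyComplexSpec"`.
#' @export
toyComplexSpec <- function(n_residues = 9, interface_gap = 4, n_waters = 30,
                           box = c(30, 30, 30), lattice = 3.8, clash = 2.4,
                           seed = 1) {
    if (n_residues <= 0 || n_waters < 0)
        stop("counts must be positive", call. = FALSE)
    if (interface_gap < 0)
        stop("interface_gap must be >= 0", call. = FALSE)
    structure(list(n_residues = as.integer(n_residues),
                   interface_gap = interface_gap,
                   n_waters = as.integer(n_waters), box = box,
                   lattice = lattice, clash = clash,
                   seed = as.integer(seed)),
              class = "toyComplexSpec")
}

# One chain: triads on a jittered lattice; `facing` atoms sit exactly on the
# interface plane z = sign * gap/2 so the closest cross-chain approach
# equals interface_gap.
.toyChain <- function(spec, chain, sign) {
    n <- spec$n_residues
    side <- ceiling(sqrt(n))
    ix <- (seq_len(n) - 1) %% side
    iy <- (seq_len(n) - 1) %/% side
    cx <- (ix - (side - 1) / 2) * spec$lattice
    cy <- (iy - (side - 1) / 2) * spec$lattice
    jit <- function(k) stats::runif(k, -0.2, 0.2)
    z0 <- sign * spec$interface_gap / 2
    resname <- sample(c(.POLAR_TOY, .APOLAR_TOY), n, replace = TRUE)
    data.frame(
        chain = chain,
        resid = rep(seq_len(n), each = 3),
        resname = rep(resname, each = 3),
        atom = rep(c("CB", "CA", "CG"), n),
        elem = "C",
        x = as.vector(rbind(cx, cx + jit(n), cx - 0.7 + jit(n))),
        y = as.vector(rbind(cy, cy + 0.5 + jit(n), cy + jit(n))),
        z = as.vector(rbind(rep(z0, n),
                            z0 + sign * (1.5 + abs(jit(n))),
                            z0 + sign * (3.0 + abs(jit(n))))),
        stringsAsFactors = FALSE)
}

.placeWaters <- function(n, box, coords, clash, centre = c(0, 0, 0)) {
    if (n == 0L) return(NULL)
    placed <- matrix(NA_real_, n, 3)
    got <- 0L
    tries <- 0L
    max_tries <- 2000L * n
    while (got < n) {
        tries <- tries + 1L
        if (tries > max_tries)
            stop("box too small to place the requested number of waters",
                 call. = FALSE)
        p <- centre + (stats::runif(3) - 0.5) * box
        ok <- TRUE
        if (nrow(coords) > 0)
            ok <- min(crossDist2(matrix(p, 1), coords)) >= clash^2
        if (ok && got > 0)
            ok <- min(crossDist2(matrix(p, 1),
                                 placed[seq_len(got), , drop = FALSE])) >=
                clash^2
        if (ok) {
            got <- got + 1L
            placed[got, ] <- p
        }
    }
    data.frame(water_id = seq_len(n), x = placed[, 1], y = placed[, 2],
               z = placed[, 3])
}

#' Generate a toy complex and its unbound partners
#'
#' Builds the bound two-chain complex plus the two isolated chains
#' (translated far apart, each with its own independently placed waters).
#' All three share the same per-chain topology, so shell counts of bound and
#' unbound forms are directly comparable.
#'
#' @param spec a [toyComplexSpec()].
#' @return list with elements `complex`, `unbound_A`, `unbound_B`, each a
#'   [Snapshot-class].
#' @examples
#' toy <- genToyComplex(toyComplexSpec(n_residues = 4, n_waters = 10,
#'                                     seed = 7))
#' toy$complex
#' @export
genToyComplex <- function(spec) {
    stopifnot(inherits(spec, "toyComplexSpec"))
    set.seed(spec$seed)
    A <- .toyChain(spec, "A", -1)
    B <- .toyChain(spec, "B", +1)
    AB <- rbind(A, B)
    wAB <- .placeWaters(spec$n_waters, spec$box, xyzMatrix(AB), spec$clash)
    cplx <- newSnapshot(AB, wAB, time = 0)

    mkFree <- function(ch, shift) {
        free <- ch
        free$x <- free$x + shift
        w <- .placeWaters(spec$n_waters, spec$box, xyzMatrix(free),
                          spec$clash, centre = c(shift, 0, 0))
        newSnapshot(free, w, time = 0)
    }
    list(complex = cplx,
         unbound_A = mkFree(A, -500),
         unbound_B = mkFree(B, +500))
}

#' Generate a toy snapshot series by jittering a toy complex
#'
#' Replicates the toy snapshot `n_snapshots` times with small normal
#' coordinate jitter on the protein and freshly placed waters per frame
#' (emulating fast water exchange between snapshots taken 1 ns apart).
#'
#' @param spec a [toyComplexSpec()].
#' @param n_snapshots number of frames.
#' @param jitter_sd per-coordinate protein jitter (Angstrom).
#' @param dt frame spacing in ns.
#' @param which one of `"complex"`, `"unbound_A"`, `"unbound_B"`.
#' @return A [SnapshotSeries-class].
#' @export
genToySeries <- function(spec, n_snapshots = 10, jitter_sd = 0.05, dt = 1,
                         which = "complex") {
    stopifnot(inherits(spec, "toyComplexSpec"))
    base <- genToyComplex(spec)[[which]]
    a0 <- base@atoms
    set.seed(spec$seed + 1L)
    ctr <- colMeans(xyzMatrix(a0))
    frames <- lapply(seq_len(n_snapshots), function(i) {
        a <- a0
        if (jitter_sd > 0) {
            a$x <- a$x + stats::rnorm(nrow(a), 0, jitter_sd)
            a$y <- a$y + stats::rnorm(nrow(a), 0, jitter_sd)
            a$z <- a$z + stats::rnorm(nrow(a), 0, jitter_sd)
        }
        w <- .placeWaters(spec$n_waters, spec$box, xyzMatrix(a), spec$clash,
                          centre = ctr)
        newSnapshot(a, w, time = (i - 1) * dt)
    })
    newSnapshotSeries(frames, dt = dt, source = which)
}

#' Generate bivariate-normal sample pairs with a prescribed correlation
#'
#' @param n sample size (>= 3).
#' @param rho population correlation, in [-1, 1].
#' @param seed integer seed.
#' @return data.frame with columns `x` and `y`.
#' @examples
#' p <- genCorrelatedPairs(100, 0.9, seed = 1)
#' cor(p$x, p$y)
#' @export
genCorrelatedPairs <- function(n, rho, seed = 1) {
    if (abs(rho) > 1) stop("|rho| must be <= 1", call. = FALSE)
    if (n < 3) stop("n must be >= 3", call. = FALSE)
    set.seed(as.integer(seed))
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
    data.frame(x = x, y = y)
}
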