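oneAtom <- function(elem = "C", resname = "ALA") makeSnapshot(
    data.frame(chain = "A", resid = 1, resname = resname, atom = "CA",
               elem = elem, x = 0, y = 0, z = 0))

test_that("single-atom ASA matches the analytic sphere within 2%", {
    for (elem in c("C", "N", "O", "S")) {
        s <- oneAtom(elem)
        got <- attr(computeAsa(s), "total")
        r <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85)[[elem]]
        expect_lt(abs(got - 4 * pi * (r + 1.4)^2) /
                      (4 * pi * (r + 1.4)^2), 0.02)
    }
})

test_that("two-atom ASA matches the closed-form two-sphere area", {
    mk2 <- function(d) makeSnapshot(data.frame(
        chain = "A", resid = 1:2, resname = "ALA", atom = "CA",
        elem = "C", x = c(0, d), y = 0, z = 0))
    for (d in c(2.0, 3.5, 5.0)) {
        got <- attr(computeAsa(mk2(d)), "total")
        want <- twoSphereArea(1.87, 1.87, d)
        expect_lt(abs(got - want) / want, 0.02)
    }
    # far apart: each equals the isolated value
    far <- attr(computeAsa(mk2(50)), "total")
    expect_lt(abs(far - 2 * 4 * pi * 3.27^2) / far, 0.02)

    expect_error(computeAsa(oneAtom("ZZ")), "vdW radius")
})

test_that("ASA shrinks monotonically as the partner chain approaches", {
    totals <- vapply(c(6, 5, 4, 3), function(gap) {
        toy <- genToyComplex(toyComplexSpec(n_residues = 6,
                                            interface_gap = gap,
                                            n_waters = 0,
                                            box = c(40, 40, 60), seed = 2))
        ctx <- asaContexts(toy$complex, n_points = 480)
        ctx$totals[["ASA_AB"]]
    }, numeric(1))
    expect_true(all(diff(totals) < 0))
})

test_that("buried area follows the A + B - AB identity", {
    expect_equal(deltaAsa(500, 600, 900), 200)
    expect_error(deltaAsa(100, 100, 400), "inconsistent")

    # separated chains bury nothing
    far <- genToyComplex(toyComplexSpec(n_residues = 5, interface_gap = 40,
                                        n_waters = 0, box = c(40, 40, 80),
                                        seed = 3))
    expect_equal(deltaAsaFromSnapshot(far$complex), 0)

    # planted interface: equals recomputation from the two contexts
    toy <- genToyComplex(toyComplexSpec(n_residues = 6, n_waters = 0,
                                        seed = 3))
    ctx <- asaContexts(toy$complex)
    expect_gt(deltaAsaFromSnapshot(toy$complex), 0)
    expect_equal(deltaAsaFromSnapshot(toy$complex),
                 deltaAsa(ctx$totals[["ASA_A"]], ctx$totals[["ASA_B"]],
                          ctx$totals[["ASA_AB"]]))
})

test_that("interface regions follow the relative-ASA thresholds", {
    mkctx <- function(rel_iso, rel_cplx, dasa = 5) {
        list(residues = data.frame(
            chain = "A", resid = 1, resname = "ALA",
            asa_isolated = rel_iso, rel_isolated = rel_iso,
            asa_complex = rel_cplx, rel_complex = rel_cplx,
            delta_asa = dasa))
    }
    expect_equal(classifyRegions(mkctx(10, 2))$region, "support")
    expect_equal(classifyRegions(mkctx(40, 10))$region, "core")
    expect_equal(classifyRegions(mkctx(60, 40))$region, "rim")
    expect_equal(classifyRegions(mkctx(25, 25))$region, "rim")  # tie rule
    expect_equal(classifyRegions(mkctx(40, 10, dasa = 0))$region,
                 "non_interface")
})

test_that("region classes are invariant to global rigid motion", {
    toy <- genToyComplex(toyComplexSpec(n_residues = 6, n_waters = 0,
                                        seed = 4))
    s <- toy$complex
    r0 <- classifyRegions(asaContexts(s, n_points = 480))
    a <- atoms(s)
    th <- 0.7
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                byrow = TRUE)
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
    a$x <- xyz[, 1] + 11; a$y <- xyz[, 2] - 3; a$z <- xyz[, 3] + 5
    r1 <- classifyRegions(asaContexts(newSnapshot(a), n_points = 480))
    expect_equal(r1$region, r0$region)
})

test_that("gap index arithmetic and degenerate cases behave", {
    expect_equal(gapIndex(700, 1000), 1.4)
    expect_true(is.na(gapIndex(100, 0)))

    far <- genToyComplex(toyComplexSpec(n_residues = 4, interface_gap = 40,
                                        n_waters = 0, box = c(40, 40, 90),
                                        seed = 1))
    gd <- gapDescriptors(far$complex)
    expect_equal(gd$gap_volume, 0)
    expect_true(is.na(gd$gap_index))
})

test_that("a planted spherical void is recovered within 10%", {
    # atoms on a shell of radius 3 + r_C so the cavity is a ball of
    # radius 3 at the origin; upper hemisphere = chain A, lower = chain B
    n <- 400
    i <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * i / n)
    theta <- pi * (1 + sqrt(5)) * i
    R0 <- 3 + 1.87
    pts <- R0 * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                      cos(phi))
    snap <- makeSnapshot(data.frame(
        chain = ifelse(pts[, 3] >= 0, "A", "B"),
        resid = seq_len(n), resname = "ALA", atom = "CA", elem = "C",
        x = pts[, 1], y = pts[, 2], z = pts[, 3]))
    gd <- gapDescriptors(snap, delta_asa = 1, grid = 0.5)
    want <- 4 / 3 * pi * 27
    expect_lt(abs(gd$gap_volume - want) / want, 0.10)
})

test_that("interface RMSD is zero under rigid motion and matches Kabsch", {
    toy <- genToyComplex(toyComplexSpec(n_residues = 6, n_waters = 0,
                                        seed = 5))
    s <- toy$complex
    expect_equal(interfaceRmsd(s, s), 0, tolerance = 1e-9)

    a <- atoms(s)
    th <- 0.5
    R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3,
                byrow = TRUE)
    xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
    a$x <- xyz[, 1] + 3; a$y <- xyz[, 2] + 4; a$z <- xyz[, 3] - 2
    expect_lt(interfaceRmsd(s, newSnapshot(a, time = 1)), 1e-6)

    # perturbed snapshot: equals an independent SVD Kabsch on the same set
    set.seed(42)
    b <- atoms(s)
    b$x <- b$x + rnorm(nrow(b), 0, 0.4)
    b$y <- b$y + rnorm(nrow(b), 0, 0.4)
    b$z <- b$z + rnorm(nrow(b), 0, 0.4)
    sb <- newSnapshot(b, time = 1)
    # generous cutoff: the interface set is every residue, so the oracle
    # can superpose the full atom set
    got <- interfaceRmsd(s, sb, interface_cutoff = 50,
                         backbone = c("CA", "CB", "CG"))
    A <- as.matrix(atoms(s)[, c("x", "y", "z")])
    B <- as.matrix(atoms(sb)[, c("x", "y", "z")])
    expect_equal(got, bruteKabschRmsd(A, B), tolerance = 1e-6)

    expect_error(interfaceRmsd(s, sb, interface_cutoff = 0.1),
                 "empty interface")
})
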