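protAt <- function(chain, resid, x, y = 0, z = 0, resname = "ALA")
    data.frame(chain = chain, resid = resid, resname = resname,
               atom = "CA", elem = "C", x = x, y = y, z = z)

watersAt <- function(...) {
    xs <- list(...)
    do.call(rbind, lapply(seq_along(xs), function(i)
        data.frame(water_id = i, x = xs[[i]][1], y = xs[[i]][2],
                   z = xs[[i]][3])))
}

test_that("shell binning follows the half-open 3.4/5.0 intervals", {
    s <- newSnapshot(protAt("A", 1, 0),
                     watersAt(c(3.0, 0, 0), c(3.4, 0, 0), c(4.0, 0, 0),
                              c(4.999, 0, 0), c(5.0, 0, 0), c(6.0, 0, 0)))
    sc <- shellCounts(s)
    expect_equal(sc[["n_first"]], 1)    # 3.0 only
    expect_equal(sc[["n_second"]], 3)   # 3.4, 4.0, 4.999
    expect_equal(sum(sc), 4)            # never double-counted

    # matches brute force on random toy boxes
    for (seed in 1:3) {
        toy <- genToyComplex(toyComplexSpec(n_residues = 5, n_waters = 40,
                                            seed = seed))
        expect_equal(shellCounts(toy$complex),
                     bruteShellCounts(toy$complex))
    }
})

test_that("released waters recover planted occlusion counts", {
    k <- 4
    mkwat <- function(cx) watersAt(
        c(cx + 3, 0, 0), c(cx - 3, 0, 0), c(cx, 3, 0), c(cx, -3, 0))
    freeA <- newSnapshotSeries(list(
        newSnapshot(protAt("A", 1, 0), mkwat(0))), source = "unbound_A")
    freeB <- newSnapshotSeries(list(
        newSnapshot(protAt("B", 1, 100), mkwat(100))),
        source = "unbound_B")
    # bound complex: all planted first-shell waters displaced
    cplx <- newSnapshotSeries(list(
        newSnapshot(rbind(protAt("A", 1, 0), protAt("B", 1, 4)), NULL)))
    rw <- releasedWaters(cplx, freeA, freeB)
    expect_equal(rw$released, 2 * k)

    # complex identical to the disjoint union of the free forms: 0
    cplx2 <- newSnapshotSeries(list(newSnapshot(
        rbind(protAt("A", 1, 0), protAt("B", 1, 100)),
        rbind(mkwat(0), within(mkwat(100), water_id <- water_id + 4)))))
    expect_equal(releasedWaters(cplx2, freeA, freeB)$released, 0)

    # no waters anywhere: 0
    dryA <- newSnapshotSeries(list(newSnapshot(protAt("A", 1, 0), NULL)))
    dryB <- newSnapshotSeries(list(newSnapshot(protAt("B", 1, 100), NULL)))
    expect_equal(releasedWaters(cplx, dryA, dryB)$released, 0)
})

test_that("interfacial waters need both chains strictly within 4 A", {
    s <- newSnapshot(rbind(protAt("A", 1, 0), protAt("B", 1, 6)),
                     watersAt(c(3, 0, 0),      # 3 from both -> in
                              c(-3, 0, 0),     # 3 / 9 -> out
                              c(2, 0, 0),      # 2 / 4 -> out (strict)
                              c(3.99, 0, 0)))  # 3.99 / 2.01 -> in
    expect_equal(interfacialWaters(s), c(1L, 4L))

    for (seed in 4:6) {
        toy <- genToyComplex(toyComplexSpec(n_residues = 5, n_waters = 40,
                                            seed = seed))
        expect_equal(interfacialWaters(toy$complex),
                     bruteInterfacialWaters(toy$complex))
    }
})

test_that("water bridges count residue pairs once per snapshot", {
    # static bridge A:1 - w - B:1 present in all 5 frames
    mk <- function(t, with_bridge = TRUE) newSnapshot(
        rbind(protAt("A", 1, 0), protAt("B", 1, 6)),
        if (with_bridge) watersAt(c(3, 0, 0)) else watersAt(c(0, 50, 0)),
        time = t)
    ser <- newSnapshotSeries(lapply(0:4, mk))
    br <- waterMediatedContacts(ser)
    expect_equal(nrow(br), 1)
    expect_equal(br$frequency, 1.0)

    # bridge in 64 of 100 snapshots -> 0.64
    ser2 <- newSnapshotSeries(lapply(0:99, function(t)
        mk(t, with_bridge = t < 64)))
    br2 <- waterMediatedContacts(ser2)
    expect_equal(br2$frequency[br2$cluster == "all"], 0.64)

    # no waters: empty table
    dry <- newSnapshotSeries(list(newSnapshot(
        rbind(protAt("A", 1, 0), protAt("B", 1, 6)), NULL)))
    expect_equal(nrow(waterMediatedContacts(dry)), 0)

    # matches brute-force triplet scan on random toys
    for (seed in 7:9) {
        toy <- genToyComplex(toyComplexSpec(n_residues = 5, n_waters = 40,
                                            seed = seed))
        one <- newSnapshotSeries(list(toy$complex))
        got <- waterMediatedContacts(one)
        keys <- paste0(got$chain1, ":", got$resid1, "|",
                       got$chain2, ":", got$resid2)
        expect_setequal(keys[got$frequency == 1],
                        bruteBridges(toy$complex))
    }
})

test_that("interfacial waters lie in the hydration shells of both chains", {
    toy <- genToyComplex(toyComplexSpec(n_residues = 6, interface_gap = 6,
                                        n_waters = 60, box = c(16, 16, 14),
                                        seed = 10))
    s <- toy$complex
    iw <- interfacialWaters(s)
    expect_gt(length(iw), 0)
    a <- atoms(s); w <- waterTable(s)
    for (id in iw) for (ch in c("A", "B")) {
        sub <- a[a$chain == ch, ]
        wi <- w[w$water_id == id, ]
        dmin <- min(sqrt((sub$x - wi$x)^2 + (sub$y - wi$y)^2 +
                         (sub$z - wi$z)^2))
        expect_lt(dmin, 5.0)   # within first or second shell of each chain
    }
})

test_that("residue-water contact counts and variability flags work", {
    # residue A:1 surrounded by 3 interfacial waters in every frame
    mk <- function(t) newSnapshot(
        rbind(protAt("A", 1, 0), protAt("B", 1, 6)),
        watersAt(c(3, 0, 0), c(3, 1, 0), c(3, -1, 0)), time = t)
    ser <- newSnapshotSeries(lapply(0:5, mk))
    rw <- residueWaterContactCounts(ser, rep(1:2, each = 3))
    cA <- rw$counts[rw$counts$chain == "A", ]
    expect_equal(cA$n_waters, rep(3L, 6))
    sA <- rw$summary[rw$summary$chain == "A", ]
    expect_equal(sA$median, c(3, 3))
    expect_false(any(sA$variable))   # constant counts never flagged

    # residue far from all waters: all-zero distribution
    far <- newSnapshotSeries(lapply(0:3, function(t) newSnapshot(
        rbind(protAt("A", 1, 0), protAt("A", 2, -40), protAt("B", 1, 6)),
        watersAt(c(3, 0, 0)), time = t)))
    rw2 <- residueWaterContactCounts(far, rep(1L, 4))
    expect_equal(rw2$counts$n_waters[rw2$counts$resid == 2 &
                                     rw2$counts$chain == "A"],
                 rep(0L, 4))
})

test_that("the distance histogram pools per-water minima", {
    s <- newSnapshot(protAt("A", 1, 0),
                     watersAt(c(2.55, 0, 0), c(3.05, 0, 0), c(7.5, 0, 0)))
    h <- waterDistanceHistogram(s, binwidth = 0.1, max_dist = 8)
    expect_equal(sum(h$count), 3)
    expect_equal(h$count[h$d_lo == 2.5], 1)
    expect_equal(h$count[h$d_lo == 3.0], 1)
})
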