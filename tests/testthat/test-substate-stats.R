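pairAB <- function(r1, r2) data.frame(chain1 = "A", resid1 = r1,
                                      chain2 = "B", resid2 = r2)

# series realising prescribed per-cluster contact frequencies for residue
# A:1 -- cluster 1 (25 snaps): B:1 at 100%, B:2 at 4%; cluster 2 (10
# snaps): B:1 at 10%, B:3 at 60%
workedExampleSeries <- function() {
    sets <- c(
        lapply(1:25, function(t) newContactSet(
            if (t == 1) rbind(pairAB(1, 1), pairAB(1, 2))
            else pairAB(1, 1), time = t)),
        lapply(1:10, function(t) newContactSet(
            if (t == 1) rbind(pairAB(1, 1), pairAB(1, 3))
            else if (t <= 6) pairAB(1, 3)
            else pairAB(2, 9), time = 25 + t)))
    list(sets = sets, labels = c(rep(1L, 25), rep(2L, 10)))
}

test_that("contact frequencies count snapshots per cluster", {
    ex <- workedExampleSeries()
    ft <- contactFrequencies(ex$sets, ex$labels)
    getf <- function(key, cl)
        ft$frequency[ft$contact == key & ft$cluster == cl]
    expect_equal(getf("A:1|B:1", 1), 1.0)
    expect_equal(getf("A:1|B:2", 1), 0.04)
    expect_equal(getf("A:1|B:1", 2), 0.1)
    expect_equal(getf("A:1|B:3", 2), 0.6)
    expect_equal(getf("A:1|B:3", 1), 0)      # absent contact scores 0
    expect_equal(getf("A:1|B:2", 2), 0)
    expect_error(contactFrequencies(ex$sets, ex$labels[-1]), "align")
})

test_that("contact variance across clusters is the population variance", {
    ex <- workedExampleSeries()
    ft <- contactFrequencies(ex$sets, ex$labels)
    v <- contactVariance(ft)
    # frequencies {1.0, 0.1} -> population variance 0.2025
    expect_equal(v$variance[v$contact == "A:1|B:1"],
                 mean((c(1, 0.1) - 0.55)^2))
    # {0.2, 0.6} -> 0.04 (hand case via a direct table)
    tab <- rbind(
        data.frame(contact = "A:1|B:1", chain1 = "A", resid1 = 1L,
                   chain2 = "B", resid2 = 1L, cluster = 1,
                   frequency = 0.2),
        data.frame(contact = "A:1|B:1", chain1 = "A", resid1 = 1L,
                   chain2 = "B", resid2 = 1L, cluster = 2,
                   frequency = 0.6))
    expect_equal(contactVariance(tab)$variance, 0.04)
    # {0, 1} -> maximal 0.25
    tab$frequency <- c(0, 1)
    expect_equal(contactVariance(tab)$variance, 0.25)
    # identical frequencies -> 0
    tab$frequency <- c(0.3, 0.3)
    expect_equal(contactVariance(tab)$variance, 0)

    expect_error(contactVariance(tab[tab$cluster == 1, ]), "2 clusters")
})

test_that("residues inherit their maximum contact variance", {
    vtab <- data.frame(contact = c("A:1|B:1", "A:1|B:2"),
                       chain1 = "A", resid1 = 1L, chain2 = "B",
                       resid2 = c(1L, 2L), variance = c(0.1, 0.3))
    mv <- residueMaxVariance(vtab)
    expect_equal(mv$max_variance[mv$chain == "A" & mv$resid == 1], 0.3)
    # single contact: its own variance
    expect_equal(mv$max_variance[mv$chain == "B" & mv$resid == 2], 0.3)

    # random instance vs exhaustive max
    set.seed(3)
    vr <- data.frame(contact = paste0("A:", 1:5, "|B:", c(1, 1, 2, 2, 3)),
                     chain1 = "A", resid1 = 1:5, chain2 = "B",
                     resid2 = c(1L, 1L, 2L, 2L, 3L),
                     variance = runif(5, 0, 0.25))
    mv2 <- residueMaxVariance(vr)
    expect_equal(mv2$max_variance[mv2$chain == "B" & mv2$resid == 1],
                 max(vr$variance[1:2]))
    expect_equal(mv2$max_variance[mv2$chain == "B" & mv2$resid == 2],
                 max(vr$variance[3:4]))
})

test_that("recurrence index is min over clusters of the best partner", {
    ex <- workedExampleSeries()
    ft <- contactFrequencies(ex$sets, ex$labels)
    ri <- recurrenceIndex(ft)
    # worked example: max(1.0, 0.04) then max(0.1, 0.6) -> min = 0.6
    expect_equal(ri$recurrence[ri$chain == "A" & ri$resid == 1], 0.6)
    # residue B:1: cluster1 max 1.0, cluster2 max 0.1 -> 0.1
    expect_equal(ri$recurrence[ri$chain == "B" & ri$resid == 1], 0.1)
    # A:2 only contacts in cluster 2 -> recurrence 0 (absent from c1)
    expect_equal(ri$recurrence[ri$chain == "A" & ri$resid == 2], 0)

    # contact present in every snapshot: variance 0, both residues
    # recurrence 1
    ser <- lapply(1:6, function(t) newContactSet(pairAB(7, 8), time = t))
    ft2 <- contactFrequencies(ser, rep(1:2, each = 3))
    expect_equal(contactVariance(ft2)$variance, 0)
    ri2 <- recurrenceIndex(ft2)
    expect_equal(ri2$recurrence, c(1, 1))
})

test_that("recurrence and variance are invariant to cluster relabelling", {
    ex <- workedExampleSeries()
    ft1 <- contactFrequencies(ex$sets, ex$labels)
    ft2 <- contactFrequencies(ex$sets, 3L - ex$labels)   # swap 1 <-> 2
    expect_equal(recurrenceIndex(ft1)$recurrence,
                 recurrenceIndex(ft2)$recurrence)
    expect_equal(contactVariance(ft1)$variance,
                 contactVariance(ft2)$variance)
})

test_that("recurrence equals brute-force evaluation on random instances", {
    set.seed(14)
    for (rep in 1:3) {
        sets <- replicate(12, randomContactSet(5, 0.3), simplify = FALSE)
        labels <- sample(1:3, 12, replace = TRUE)
        labels <- as.integer(factor(labels))  # ensure 1..k all present
        ft <- contactFrequencies(sets, labels)
        ri <- recurrenceIndex(ft)
        keysets <- lapply(sets, contactSetKeys)
        for (r in seq_len(nrow(ri))) {
            res <- paste0(ri$chain[r], ":", ri$resid[r])
            per_cluster <- vapply(sort(unique(labels)), function(cl) {
                idx <- which(labels == cl)
                partners <- unique(unlist(keysets[idx]))
                partners <- partners[grepl(paste0("(^|\\|)", res,
                                                  "(\\||$)"), partners)]
                if (!length(partners)) return(0)
                max(vapply(partners, function(k)
                    mean(vapply(keysets[idx], function(s) k %in% s,
                                logical(1))), numeric(1)))
            }, numeric(1))
            expect_equal(ri$recurrence[r], min(per_cluster))
        }
    }
})

test_that("hotspot cross-referencing applies the ddG threshold rule", {
    scores <- data.frame(chain = c("A", "A", "B"), resid = c(1, 2, 3),
                         max_variance = 0.1, recurrence = 0.9)
    muts <- data.frame(chain = c("A", "A", "A", "B", "B", "C"),
                       resid = c(1, 1, 2, 3, 3, 9),
                       mutation = NA,
                       ddg = c(-3.1, -0.5, -1.0, -2.5, 1.0, -4))
    expect_warning(out <- hotspotCrossref(scores, muts), "C 9")
    expect_equal(out$hotspot, c(TRUE, FALSE, TRUE))

    # flipped sign convention: ddg > +2 marks hotspots
    muts2 <- data.frame(chain = "A", resid = 1, mutation = NA, ddg = 3.0)
    expect_equal(hotspotCrossref(scores, muts2,
                                 flip_sign = TRUE)$hotspot[1], TRUE)
    expect_equal(hotspotCrossref(scores, muts2)$hotspot[1], FALSE)
})

test_that("SKEMPI-style mutation tables parse and drop multiples", {
    f <- tempfile(fileext = ".csv")
    writeLines(c("complex,mutation,ddg",
                 "1ABC,KI31A,-2.5",
                 "1ABC,\"KI31A,EI33Q\",-4.0",
                 "1ABC,LB7G,0.3"), f)
    m <- readMutationTable(f)
    expect_equal(nrow(m), 2)   # the double mutant is dropped
    expect_equal(m$chain, c("I", "B"))
    expect_equal(m$resid, c(31L, 7L))
    expect_equal(m$ddg, c(-2.5, 0.3))
})
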