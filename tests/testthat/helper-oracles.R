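# Independent brute-force oracles used to cross-check the package
# implementations on small instances. Deliberately naive: explicit loops,
# no shared code with the package internals.

# O(N^2) residue contact scan with explicit loops.
bruteContacts <- function(snapshot, cutoff = 5.0) {
    a <- atoms(snapshot)
    ch <- sort(unique(a$chain))
    a1 <- a[a$chain == ch[1], ]
    a2 <- a[a$chain == ch[2], ]
    found <- character(0)
    for (i in seq_len(nrow(a1))) for (j in seq_len(nrow(a2))) {
        d <- sqrt((a1$x[i] - a2$x[j])^2 + (a1$y[i] - a2$y[j])^2 +
                  (a1$z[i] - a2$z[j])^2)
        if (d <= cutoff)
            found <- c(found, paste0(ch[1], ":", a1$resid[i], "|",
                                     ch[2], ":", a2$resid[j]))
    }
    sort(unique(found))
}

contactSetKeys <- function(cs) {
    p <- contactPairs(cs)
    if (nrow(p) == 0) return(character(0))
    sort(paste0(p$chain1, ":", p$resid1, "|", p$chain2, ":", p$resid2))
}

bruteJaccard <- function(k1, k2) {
    u <- length(unique(c(k1, k2)))
    if (u == 0) return(1)
    sum(k1 %in% k2) / u
}

# Agglomerative Ward.D2 by the Lance-Williams recurrence on squared
# dissimilarities; lowest-index pair on ties. Returns merge heights.
bruteWardD2Heights <- function(D) {
    n <- nrow(D)
    d2 <- D^2
    diag(d2) <- Inf
    sizes <- rep(1, n)
    active <- rep(TRUE, n)
    heights <- numeric(0)
    for (step in seq_len(n - 1)) {
        best <- c(NA, NA); bestv <- Inf
        for (i in which(active)) for (j in which(active)) if (i < j) {
            if (d2[i, j] < bestv - 1e-15) { bestv <- d2[i, j]; best <- c(i, j) }
        }
        i <- best[1]; j <- best[2]
        heights <- c(heights, sqrt(bestv))
        ni <- sizes[i]; nj <- sizes[j]
        for (k in which(active)) if (k != i && k != j) {
            nk <- sizes[k]
            d2[i, k] <- d2[k, i] <-
                ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] -
                 nk * d2[i, j]) / (ni + nj + nk)
        }
        sizes[i] <- ni + nj
        active[j] <- FALSE
        d2[j, ] <- d2[, j] <- Inf
    }
    heights
}

# Kabsch superposition via SVD, independent of bio3d.
bruteKabschRmsd <- function(A, B) {
    ca <- colMeans(A); cb <- colMeans(B)
    A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
    s <- svd(crossprod(B0, A0))
    d <- sign(det(s$u %*% t(s$v)))
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    Bf <- B0 %*% R
    sqrt(mean(rowSums((A0 - Bf)^2)))
}

# Naive shell count: loop waters x atoms.
bruteShellCounts <- function(snapshot, first = 3.4, second = 5.0) {
    a <- atoms(snapshot); w <- waterTable(snapshot)
    n1 <- 0; n2 <- 0
    for (i in seq_len(nrow(w))) {
        dmin <- Inf
        for (j in seq_len(nrow(a)))
            dmin <- min(dmin, sqrt((w$x[i] - a$x[j])^2 +
                                   (w$y[i] - a$y[j])^2 +
                                   (w$z[i] - a$z[j])^2))
        if (dmin < first) n1 <- n1 + 1
        else if (dmin < second) n2 <- n2 + 1
    }
    c(n_first = n1, n_second = n2)
}

bruteInterfacialWaters <- function(snapshot, cutoff = 4.0) {
    a <- atoms(snapshot); w <- waterTable(snapshot)
    ch <- sort(unique(a$chain))
    ids <- integer(0)
    for (i in seq_len(nrow(w))) {
        near <- c(FALSE, FALSE)
        for (c2 in 1:2) {
            sub <- a[a$chain == ch[c2], ]
            for (j in seq_len(nrow(sub))) {
                d <- sqrt((w$x[i] - sub$x[j])^2 + (w$y[i] - sub$y[j])^2 +
                          (w$z[i] - sub$z[j])^2)
                if (d < cutoff) { near[c2] <- TRUE; break }
            }
        }
        if (all(near)) ids <- c(ids, w$water_id[i])
    }
    ids
}

# Naive triplet scan: residue (chain1) - water - residue (chain2).
bruteBridges <- function(snapshot, cutoff = 4.0) {
    a <- atoms(snapshot); w <- waterTable(snapshot)
    ch <- sort(unique(a$chain))
    out <- character(0)
    res1 <- unique(a$resid[a$chain == ch[1]])
    res2 <- unique(a$resid[a$chain == ch[2]])
    resdist <- function(chain, resid, wx) {
        sub <- a[a$chain == chain & a$resid == resid, ]
        min(sqrt((sub$x - wx[1])^2 + (sub$y - wx[2])^2 +
                 (sub$z - wx[3])^2))
    }
    for (i in seq_len(nrow(w))) {
        wx <- c(w$x[i], w$y[i], w$z[i])
        for (r1 in res1) if (resdist(ch[1], r1, wx) < cutoff)
            for (r2 in res2) if (resdist(ch[2], r2, wx) < cutoff)
                out <- c(out, paste0(ch[1], ":", r1, "|", ch[2], ":", r2))
    }
    sort(unique(out))
}

# Closed-form accessible area of two intersecting probe-expanded spheres.
twoSphereArea <- function(r1, r2, d, probe = 1.4) {
    R1 <- r1 + probe; R2 <- r2 + probe
    if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
    x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
    h1 <- R1 - x1
    h2 <- R2 - (d - x1)
    4 * pi * (R1^2 + R2^2) - 2 * pi * (R1 * h1 + R2 * h2)
}

# Hand-built snapshot from coordinate triplets.
makeSnapshot <- function(coords, waters = NULL, time = 0) {
    # coords: data.frame chain, resid, resname, atom, x, y, z
    newSnapshot(coords, waters, time = time)
}

# Random ContactSet over a small universe.
randomContactSet <- function(n_max = 12, p = 0.4) {
    grid <- expand.grid(r1 = seq_len(n_max), r2 = seq_len(n_max))
    take <- runif(nrow(grid)) < p
    newContactSet(data.frame(chain1 = "A", resid1 = grid$r1[take],
                             chain2 = "B", resid2 = grid$r2[take]))
}
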