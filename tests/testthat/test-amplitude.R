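test_that("sphere mesh is a boundary-inclusive lattice ball", {
    m <- sphereMesh(2.0, 0.5)
    expect_identical(nrow(m), 257L)
    expect_identical(nrow(sphereMesh(0.5, 0.5)), 7L)
    expect_identical(nrow(sphereMesh(0.4, 0.5)), 1L)
    # origin present, all norms within radius, lexicographic order
    expect_true(any(rowSums(abs(m)) == 0))
    expect_true(all(sqrt(rowSums(m^2)) <= 2.0 + 1e-9))
    o <- order(m[, 1], m[, 2], m[, 3])
    expect_identical(o, seq_len(nrow(m)))
    # brute-force enumeration oracle at another radius/mesh pair
    cnt <- 0
    for (i in -6:6) for (j in -6:6) for (k in -6:6)
        if (sqrt(i^2 + j^2 + k^2) * 0.4 <= 2.5) cnt <- cnt + 1
    expect_identical(nrow(sphereMesh(2.5, 0.4)), as.integer(cnt))
})

test_that("sphere amplitude separates signs and applies a strict floor", {
    cell <- unitCell(10, 10, 10)
    zero <- densityMap(array(0, dim = c(20, 20, 20)), cell)
    a <- atomAmplitude(zero, c(5, 5, 5), extractionParams(floorAbs = 0))
    expect_identical(a, list(pos = 0, neg = 0, nPos = 0L, nNeg = 0L))
    const <- densityMap(array(5, dim = c(20, 20, 20)), cell)
    a5 <- atomAmplitude(const, c(5, 5, 5), extractionParams(floorAbs = 0))
    expect_equal(a5$pos, 5)
    expect_identical(a5$nNeg, 0L)
    expect_identical(a5$nPos, 257L)
    # |v| equal to the floor survives; strictly below is zeroed
    aKeep <- atomAmplitude(const, c(5, 5, 5), extractionParams(floorAbs = 5))
    expect_equal(aKeep$pos, 5)
    aDrop <- atomAmplitude(const, c(5, 5, 5),
                           extractionParams(floorAbs = 5 + 1e-9))
    expect_identical(aDrop$nPos, 0L)
    expect_identical(aDrop$pos, 0)
})

test_that("amplitude equals the brute-force oracle on seeded blob maps", {
    for (seed in c(1, 7, 23)) {
        set.seed(seed)
        blobs <- lapply(seq_len(2), function(i)
            blobSpec(runif(3, 4, 16), sample(c(-1, 1), 1) * runif(1, 2, 6),
                     runif(1, 0.8, 1.5)))
        m <- makeBlobMap(unitCell(20, 20, 20), 0.5, blobs,
                         noiseSd = 0.3, seed = seed)
        ctr <- runif(3, 0, 20)
        for (ns in c(0, 3)) {
            pars <- extractionParams(nSigma = ns)
            got <- atomAmplitude(m, ctr, pars)
            want <- oracleAmplitude(m, ctr, 2.0, 0.5, ns * mapRms(m))
            expect_identical(got, want)
        }
    }
})

test_that("profiles match per-atom calls and respect geometry", {
    m <- makeBlobMap(unitCell(20, 20, 20), 0.5,
                     list(blobSpec(c(5, 5, 5), 6, 1.0)), noiseSd = 0.1,
                     seed = 2)
    atoms <- fixtureAtoms(rbind(c(5, 5, 5), c(15, 15, 15)))
    pars <- extractionParams(nSigma = 3)
    p <- amplitudeProfile(m, atoms, pars)
    for (i in 1:2) {
        a <- atomAmplitude(m, c(atoms$x[i], atoms$y[i], atoms$z[i]), pars)
        expect_identical(p@pos[i], a$pos)
        expect_identical(p@neg[i], a$neg)
        expect_identical(p@nPos[i], a$nPos)
    }
    # atom 2 is far beyond radius + blob support: amplitude (0, 0)
    expect_identical(p@pos[2], 0)
    expect_identical(p@neg[2], 0)
    expect_identical(p@mapSigma, mapRms(m))
    expect_error(amplitudeProfile(m, atoms[0, ]), "empty")
})

test_that("floor monotonicity and scaling linearity hold", {
    m <- makeBlobMap(unitCell(16, 16, 16), 0.5,
                     list(blobSpec(c(8, 8, 8), 4, 1.2),
                          blobSpec(c(6, 9, 8), -3, 1.0)),
                     noiseSd = 0.4, seed = 13)
    ctr <- c(7.3, 8.4, 8.1)
    floors <- c(0, 0.5, 1, 2, 3) * mapRms(m)
    res <- lapply(floors, function(f)
        atomAmplitude(m, ctr, extractionParams(floorAbs = f)))
    nPos <- vapply(res, `[[`, integer(1), "nPos")
    pos <- vapply(res, `[[`, numeric(1), "pos")
    expect_true(all(diff(nPos) <= 0))
    surviving <- nPos > 0
    expect_true(all(diff(pos[surviving]) >= 0))
    # exact linearity under map scaling with a scaled floor
    lam <- 2.5
    m2 <- densityMap(lam * m@grid, m@cell)
    a1 <- atomAmplitude(m, ctr, extractionParams(floorAbs = floors[4]))
    a2 <- atomAmplitude(m2, ctr, extractionParams(floorAbs = lam * floors[4]))
    expect_identical(a2$nPos, a1$nPos)
    expect_equal(a2$pos, lam * a1$pos, tolerance = 1e-14)
    expect_equal(a2$neg, lam * a1$neg, tolerance = 1e-14)
})

test_that("joint translation of map and centers by grid steps is exact", {
    m <- makeBlobMap(unitCell(16, 16, 16), 0.5,
                     list(blobSpec(c(8, 8, 8), 4, 1.2)), noiseSd = 0.3,
                     seed = 6)
    shift <- c(3L, 5L, 2L)                     # whole grid steps
    g2 <- m@grid
    for (ax in 1:3) {
        idx <- (((seq_len(dim(g2)[ax]) - 1) - shift[ax]) %% dim(g2)[ax]) + 1
        g2 <- switch(ax, g2[idx, , ], g2[, idx, ], g2[, , idx])
    }
    m2 <- densityMap(g2, m@cell)
    ctr <- c(7.25, 8.5, 8.0)      # dyadic: translation is exact
    pars <- extractionParams(floorAbs = 0.5)
    expect_identical(atomAmplitude(m, ctr, pars),
                     atomAmplitude(m2, ctr + shift * 0.5, pars))
})

test_that("negating the map swaps and negates the dual channels exactly", {
    m <- makeBlobMap(unitCell(16, 16, 16), 0.5,
                     list(blobSpec(c(8, 8, 8), 4, 1.2),
                          blobSpec(c(10, 8, 8), -3, 1.0)),
                     noiseSd = 0.3, seed = 21)
    neg <- densityMap(-m@grid, m@cell)
    atoms <- fixtureAtoms(rbind(c(8, 8, 8), c(10, 8, 8), c(9, 8, 8)))
    pars <- extractionParams(nSigma = 1)
    p1 <- amplitudeProfile(m, atoms, pars)
    p2 <- amplitudeProfile(neg, atoms, pars)
    expect_equal(p2@pos, -p1@neg, tolerance = 1e-14)
    expect_equal(p2@neg, -p1@pos, tolerance = 1e-14)
    expect_identical(p2@nPos, p1@nNeg)
})

test_that("sign separation: pos ignores far-away negative features", {
    base <- list(blobSpec(c(8, 8, 8), 4, 1.0))
    m1 <- makeBlobMap(unitCell(24, 24, 24), 0.5, base)
    m2 <- makeBlobMap(unitCell(24, 24, 24), 0.5,
                      c(base, list(blobSpec(c(18, 18, 18), -5, 1.0))))
    pars <- extractionParams(floorAbs = 0.01)
    a1 <- atomAmplitude(m1, c(8, 8, 8), pars)
    a2 <- atomAmplitude(m2, c(8, 8, 8), pars)
    expect_identical(a1$pos, a2$pos)
    expect_identical(a1$nPos, a2$nPos)
})

test_that("shells reduce to spheres and conserve sums over a partition", {
    m <- makeBlobMap(unitCell(40, 40, 40), 0.5,
                     list(blobSpec(c(20, 20, 20), 5, 1.5),
                          blobSpec(c(24, 20, 20), -4, 1.2),
                          blobSpec(c(20, 27, 20), 3, 1.8)),
                     noiseSd = 0.2, seed = 17)
    ctr <- c(20, 20, 20)
    pars <- extractionParams(nSigma = 2)
    s0 <- shellAmplitude(m, ctr, 0, 2, pars)
    a0 <- atomAmplitude(m, ctr, initialize(pars, radius = 2))
    expect_identical(s0[c("pos", "neg", "nPos", "nNeg")],
                     a0[c("pos", "neg", "nPos", "nNeg")])
    # constant positive map: every shell averages to the constant
    const <- densityMap(array(2, dim = c(16, 16, 16)), unitCell(8, 8, 8))
    sc <- shellAmplitude(const, c(4, 4, 4), 1, 3,
                         extractionParams(floorAbs = 0))
    expect_equal(sc$pos, 2)
    expect_identical(sc$nNeg, 0L)
    expect_error(shellAmplitude(m, ctr, 3, 2), "rInner")
    # conservation: shell sums over edges 0,2,...,14 equal the 14 A
    # sphere sums channel by channel
    edges <- seq(0, 14, by = 2)
    shells <- lapply(seq_len(length(edges) - 1), function(i)
        shellAmplitude(m, ctr, edges[i], edges[i + 1], pars))
    full <- shellAmplitude(m, ctr, 0, 14, pars)
    expect_identical(sum(vapply(shells, `[[`, integer(1), "nPos")),
                     full$nPos)
    expect_identical(sum(vapply(shells, `[[`, integer(1), "nNeg")),
                     full$nNeg)
    posSum <- sum(vapply(shells, function(s) s$pos * s$nPos, numeric(1)))
    negSum <- sum(vapply(shells, function(s) s$neg * s$nNeg, numeric(1)))
    expect_equal(posSum, full$pos * full$nPos, tolerance = 1e-12)
    expect_equal(negSum, full$neg * full$nNeg, tolerance = 1e-12)
})

test_that("region averages normalize at a reference point or window", {
    ser <- plantedSeries()
    profs <- profilesOf(ser)
    # regions populated at the late-time reference (state C atoms)
    regions <- list(stateC = 5:6, all = 1:6, oneAtom = 5L)
    ra <- regionAverage(profs, regions, reference = length(profs))
    # normalized to unity at the last time point
    last <- ra$value[ra$index == length(profs)]
    expect_equal(last, rep(1, length(regions)), tolerance = 1e-12)
    # single-atom region equals that atom's (pos + |neg|)/2 trajectory
    one <- ra[ra$region == "oneAtom", ]
    traj <- vapply(profs, function(p) (p@pos[5] - p@neg[5]) / 2, numeric(1))
    expect_equal(one$raw, traj, tolerance = 1e-14)
    # window normalization: values divided by the window mean
    ra2 <- regionAverage(profs, list(s = 1:2), reference = c(3, 4))
    rawS <- ra2$raw
    expect_equal(ra2$value, rawS / mean(rawS[c(3, 4)]), tolerance = 1e-14)
    # zero reference is an error
    zmaps <- list(densityMap(array(0, c(8, 8, 8)), unitCell(4, 4, 4)),
                  densityMap(array(0, c(8, 8, 8)), unitCell(4, 4, 4)))
    zp <- lapply(zmaps, amplitudeProfile, atoms = fixtureAtoms(c(2, 2, 2)),
                 params = extractionParams(radius = 1, floorAbs = 0))
    expect_error(regionAverage(zp, list(r = 1L), reference = 1),
                 "reference is zero")
})
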