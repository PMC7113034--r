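test_that("blob maps are deterministic, periodic and exact at centers", {
    cell <- unitCell(20, 20, 20)
    # no blobs, no noise: identically zero
    z <- makeBlobMap(cell, 0.5)
    expect_identical(max(abs(z@grid)), 0)
    # center on a grid node: value equals the amplitude
    m <- makeBlobMap(cell, 0.5, list(blobSpec(c(10, 10, 10), 4.5, 1.0)))
    expect_equal(m@grid[21, 21, 21], 4.5, tolerance = 1e-6)
    # same seed twice: bit-identical including noise
    a <- makeBlobMap(cell, 0.5, list(blobSpec(c(5, 5, 5), 3, 1.2)),
                     noiseSd = 0.5, seed = 77)
    b <- makeBlobMap(cell, 0.5, list(blobSpec(c(5, 5, 5), 3, 1.2)),
                     noiseSd = 0.5, seed = 77)
    expect_identical(a@grid, b@grid)
    expect_false(identical(a@grid,
        makeBlobMap(cell, 0.5, list(blobSpec(c(5, 5, 5), 3, 1.2)),
                    noiseSd = 0.5, seed = 78)@grid))
    # a blob near the boundary wraps periodically
    e <- makeBlobMap(cell, 0.5, list(blobSpec(c(0.25, 10, 10), 4, 1.0)))
    expect_equal(interpolateMap(e, c(0.25, 10, 10)),
                 interpolateMap(e, c(20.25, 10, 10)), tolerance = 1e-12)
    expect_gt(e@grid[40, 21, 21], 0.1)   # density crosses x = 0
})

test_that("sequential kinetics match the closed form and an ODE oracle", {
    p0 <- kineticPopulations(c(1e6, 1e3), 0)
    expect_equal(as.vector(p0), c(1, 0, 0))
    # closed form at 1 ms, rates 1e6 and 1e3 per second
    p <- kineticPopulations(c(1e6, 1e3), 1e-3)
    k1 <- 1e6; k2 <- 1e3; t <- 1e-3
    expect_equal(unname(p[2, 1]),
                 k1 / (k2 - k1) * (exp(-k1 * t) - exp(-k2 * t)),
                 tolerance = 1e-9)
    # independent numerical integration of the rate equations
    times <- c(0, 10^seq(-7, -2, length.out = 8))
    ode <- deSolve::ode(
        y = c(A = 1, B = 0, C = 0), times = times,
        func = function(t, y, parms)
            list(c(-k1 * y[1], k1 * y[1] - k2 * y[2], k2 * y[2])),
        parms = NULL, rtol = 1e-10, atol = 1e-12)
    closed <- kineticPopulations(c(k1, k2), times)
    expect_equal(unname(t(ode[, c("A", "B", "C")])), unname(closed),
                 tolerance = 1e-6)
    # conservation and positivity across random rates
    set.seed(12)
    for (i in 1:10) {
        k <- 10^runif(2, 2, 7)
        pp <- kineticPopulations(k, 10^seq(-8, -1, length.out = 9))
        expect_true(all(pp >= 0))
        expect_true(all(colSums(pp) <= 1 + 1e-9))
    }
    expect_error(kineticPopulations(c(-1, 2), 1), "nonnegative")
})

test_that("kinetic series combine components by population", {
    blobs1 <- list(blobSpec(c(10, 10, 10), 5, 1.2),
                   blobSpec(c(12, 10, 10), -4, 1.0))
    comps <- list(blobs1, list(blobSpec(c(20, 20, 20), 4, 1.3)),
                  list(blobSpec(c(30, 28, 12), 6, 1.2)))
    tr <- kineticTruth(comps, rates = c(2e6, 2e3), times = c(0, 1e-3))
    ser <- makeKineticSeries(tr)
    # at t = 0 the populations are (1, 0, 0): the map is component 1
    expect_equal(as.vector(ser$populations[, 1]), c(1, 0, 0))
    comp1 <- makeBlobMap(unitCell(40, 40, 40), 0.5, blobs1)
    expect_equal(ser$maps[[1]]@grid, comp1@grid, tolerance = 1e-12)
    expect_equal(dim(ser$populations), c(3L, 2L))
    # the 13-point planted series has the advertised shape
    full <- plantedSeries()
    expect_equal(dim(full$populations), c(3L, 13L))
    expect_gt(full$populations[1, 1], 0.95)
})

test_that("toy structures are valid, in-cell and reproducible", {
    cell <- unitCell(40, 40, 40)
    mod <- makeToyStructure(2, 8, cell, seed = 42)
    xyz <- atomCoords(mod)
    expect_true(all(xyz > 0 & xyz < 40))
    # boundary clearance
    expect_true(all(xyz > 1.5 & xyz < 38.5))
    expect_identical(atomCoords(makeToyStructure(2, 8, cell, seed = 42)),
                     xyz)
    expect_false(identical(
        atomCoords(makeToyStructure(2, 8, cell, seed = 43)), xyz))
    # round trip through PDB at format precision
    tf <- withr::local_tempfile(fileext = ".pdb")
    writeStructure(mod, tf)
    expect_equal(atomCoords(readStructure(tf)), xyz, tolerance = 1e-3,
                 ignore_attr = TRUE)
    # bonded geometry is sane: consecutive CA ~ 3.8 A apart
    ca <- modelAtoms(mod)
    ca <- ca[ca$name == "CA" & ca$chain == "A", ]
    d <- sqrt(rowSums(diff(as.matrix(ca[, c("x", "y", "z")]))^2))
    expect_true(all(d > 3.0 & d < 4.6))
})

test_that("dense quadrature of a Gaussian matches the sphere amplitude", {
    # analytic oracle: mean of the closed-form Gaussian over a dense
    # 0.05 A lattice ball vs the 0.5 A mesh amplitude off the sampled
    # grid
    cell <- unitCell(20, 20, 20)
    off <- sphereMesh(2.0, 0.05)
    set.seed(5)
    for (i in 1:5) {
        ctr <- runif(3, 5, 15)
        amp <- runif(1, 2, 6)
        w <- runif(1, 0.9, 1.5)
        m <- makeBlobMap(cell, 0.5, list(blobSpec(ctr, amp, w)))
        got <- atomAmplitude(m, ctr, extractionParams(floorAbs = 0))$pos
        truth <- mean(amp * exp(-rowSums(off^2) / (2 * w^2)))
        expect_lt(abs(got - truth) / truth, 0.02)
    }
})

test_that("blocks on a two-state series track the majority population", {
    # A -> B only (second rate 0): well separated early/late plateaus
    comps <- list(list(blobSpec(c(10, 10, 10), 5, 1.2)),
                  list(blobSpec(c(25, 25, 25), 5, 1.2)),
                  list())
    k1 <- 1e5
    times <- c(1e-7, 2e-7, 4e-7, 1e-4, 2e-4, 4e-4)
    tr <- kineticTruth(comps, rates = c(k1, 0), times = times,
                       noiseSd = 0.05, seed = 3)
    ser <- makeKineticSeries(tr)
    atoms <- fixtureAtoms(rbind(c(10, 10, 10), c(25, 25, 25),
                                c(12, 10, 10), c(23, 25, 25)))
    profs <- lapply(seq_along(ser$maps), function(j)
        amplitudeProfile(ser$maps[[j]], atoms,
                         extractionParams(nSigma = 0),
                         delay = times[j], label = ser$labels[j]))
    bp <- findBlocks(correlationMatrix(profs), 0.85)
    majority <- apply(ser$populations, 2, which.max)
    expected <- split(seq_along(times), majority)
    expect_equal(unname(lapply(bp@blocks, as.integer)),
                 unname(lapply(expected, as.integer)))
})
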