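# Independent oracle implementations used across the suite: written as
# plain scalar loops / direct formulas, never calling the package's
# vectorized code paths.

# trilinear interpolation at one Cartesian point, scalar code path
oracleInterp <- function(map, pt) {
    n <- dim(map@grid)
    g <- map@grid
    fr <- solve(map@cell@orth) %*% matrix(pt, ncol = 1)
    u <- fr[, 1] * n - map@origin
    i0 <- floor(u)
    f1 <- u[1] - i0[1]; f2 <- u[2] - i0[2]; f3 <- u[3] - i0[3]
    a <- (i0 %% n) + 1
    b <- ((i0 + 1) %% n) + 1
    v000 <- g[a[1], a[2], a[3]]; v100 <- g[b[1], a[2], a[3]]
    v010 <- g[a[1], b[2], a[3]]; v110 <- g[b[1], b[2], a[3]]
    v001 <- g[a[1], a[2], b[3]]; v101 <- g[b[1], a[2], b[3]]
    v011 <- g[a[1], b[2], b[3]]; v111 <- g[b[1], b[2], b[3]]
    ((v000 * (1 - f1) + v100 * f1) * (1 - f2) +
     (v010 * (1 - f1) + v110 * f1) * f2) * (1 - f3) +
    ((v001 * (1 - f1) + v101 * f1) * (1 - f2) +
     (v011 * (1 - f1) + v111 * f1) * f2) * f3
}

# brute-force enumerate-interpolate-floor-average sphere amplitude
oracleAmplitude <- function(map, center, radius, mesh, floorAbs) {
    m <- floor(radius / mesh)
    vals <- numeric(0)
    for (i in -m:m) for (j in -m:m) for (k in -m:m) {
        if (sqrt(i * i + j * j + k * k) <= radius / mesh + 1e-12) {
            v <- oracleInterp(map, center + c(i, j, k) * mesh)
            if (abs(v) < floorAbs) v <- 0
            vals <- c(vals, v)
        }
    }
    pos <- vals[vals > 0]; neg <- vals[vals < 0]
    list(pos = if (length(pos)) mean(pos) else 0,
         neg = if (length(neg)) mean(neg) else 0,
         nPos = length(pos), nNeg = length(neg))
}

# textbook Pearson: covariance over product of standard deviations
oraclePearson <- function(x, y) {
    n <- length(x)
    cv <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
    cv / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
          sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# greedy maximal-interval segmentation, loop-coded with explicit
# pairwise mean computation (independent of the package's matrix code)
oracleBlocks <- function(m, thr) {
    t <- nrow(m)
    blocks <- list()
    i <- 1
    while (i <= t) {
        e <- i
        for (j in i:t) {
            idx <- i:j
            if (length(idx) < 2) { mp <- 1 }
            else {
                s <- 0; np <- 0
                for (p in 1:(length(idx) - 1))
                    for (q in (p + 1):length(idx)) {
                        s <- s + m[idx[p], idx[q]]
                        np <- np + 1
                    }
                mp <- s / np
            }
            if (mp >= thr) e <- j
        }
        blocks[[length(blocks) + 1]] <- i:e
        i <- e + 1
    }
    blocks
}

# minimum matched population correlation over all component
# permutations
matchedPopCor <- function(pop, truth) {
    k <- nrow(pop)
    perms <- if (k == 3) list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                              c(3, 1, 2), c(3, 2, 1))
             else list(seq_len(k))
    cm <- stats::cor(t(pop), t(truth))
    max(vapply(perms, function(p) min(diag(cm[p, , drop = FALSE])),
               numeric(1)))
}

# small fixture atom table at given centers
fixtureAtoms <- function(centers) {
    centers <- matrix(centers, ncol = 3)
    data.frame(serial = seq_len(nrow(centers)), name = "C",
               element = "C", altloc = "", resname = "ALA", chain = "A",
               resno = seq_len(nrow(centers)), occupancy = 1, b = 20,
               x = centers[, 1], y = centers[, 2], z = centers[, 3],
               hetero = FALSE, dummy = FALSE, stringsAsFactors = FALSE)
}

# single-atom P1 model
fixtureModel <- function(x, y, z, element = "C", b = 50,
                         cell = unitCell(20, 20, 20), occupancy = 1) {
    at <- fixtureAtoms(c(x, y, z))
    at$element <- element
    at$b <- b
    at$occupancy <- occupancy
    new("StructureModel", atoms = at, cell = cell, hasCell = TRUE,
        spacegroup = "P 1")
}

# standard planted 3-state kinetic series used by several tests
plantedSeries <- function(noiseSd = 0, seed = 5) {
    comps <- list(
        list(blobSpec(c(10, 10, 10), 5, 1.2),
             blobSpec(c(12, 10, 10), -4, 1.0)),
        list(blobSpec(c(20, 20, 20), 4, 1.3),
             blobSpec(c(22, 20, 20), -5, 1.1)),
        list(blobSpec(c(30, 28, 12), 6, 1.2),
             blobSpec(c(28, 28, 12), -3, 1.2)))
    times <- 10^seq(log10(16e-9), log10(1.725e-3), length.out = 13)
    tr <- kineticTruth(comps, rates = c(2e6, 2e3), times = times,
                       noiseSd = noiseSd, seed = seed)
    ser <- makeKineticSeries(tr)
    ctrs <- do.call(rbind, lapply(comps, function(cl)
        t(vapply(cl, `[[`, numeric(3), "center"))))
    ser$atoms <- fixtureAtoms(ctrs)
    ser
}

profilesOf <- function(ser, params = extractionParams(nSigma = 0)) {
    lapply(seq_along(ser$maps), function(j)
        amplitudeProfile(ser$maps[[j]], ser$atoms, params,
                         delay = ser$delays[j], label = ser$labels[j]))
}

# write an MRC file whose fast/medium/slow axes follow `perm` (the
# cell axis stored in each file dimension), for canonicalization tests
writePermutedMap <- function(map, path, perm) {
    arr <- aperm(map@grid, perm)
    d <- dim(arr)
    con <- file(path, "wb")
    on.exit(close(con))
    wi <- function(i) writeBin(as.integer(i), con, size = 4,
                               endian = "little")
    wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                               endian = "little")
    wi(d); wi(2L); wi(map@origin[perm]); wi(map@sampling)
    wf(c(map@cell@abc, map@cell@angles))
    wi(perm)
    wf(c(min(arr), max(arr), mean(arr)))
    wi(c(1L, 0L)); wi(integer(25)); wf(numeric(3))
    writeBin(charToRaw("MAP "), con)
    writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)
    wf(map@rms); wi(0L)
    writeBin(raw(800), con)
    wf(arr)
}
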