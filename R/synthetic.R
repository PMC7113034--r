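## Seeded synthetic maps, structures and kinetic series with known
## ground truth, standing in for experimental difference maps so every
## analysis stage is testable without deposited data.

# run expr with a locally seeded RNG, restoring global state after
withSeed <- function(seed, expr) {
    oldseed <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
        if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv())
        else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv())
    })
    force(expr)
}

#' Gaussian blob specification
#'
#' A synthetic difference-density feature: isotropic Gaussian of
#' standard deviation \code{width} Angstrom, signed peak
#' \code{amplitude}, centered at \code{center} (Cartesian Angstrom).
#'
#' @param center length-3 Cartesian position.
#' @param amplitude signed peak density.
#' @param width Gaussian standard deviation in Angstrom (> 0).
#' @return list of class "BlobSpec".
#' @export
blobSpec <- function(center, amplitude, width) {
    stopifnot(length(center) == 3L, width > 0)
    structure(list(center = as.numeric(center),
                   amplitude = as.numeric(amplitude),
                   width = as.numeric(width)), class = "BlobSpec")
}

#' Synthetic full-cell blob map
#'
#' P1 map on an orthogonal cell: v(x) = sum over blobs of
#' A exp(-||x - c||^2 / (2 w^2)), summed over periodic images within
#' 4 w of each center, plus optional i.i.d. Gaussian voxel noise.
#' Deterministic per seed.
#'
#' @param cell a \linkS4class{UnitCell} (default 40 Angstrom cube).
#' @param spacing grid spacing in Angstrom (default 0.5).
#' @param blobs list of \code{\link{blobSpec}}s (may be empty).
#' @param noiseSd standard deviation of additive Gaussian noise
#'   (default 0).
#' @param seed RNG seed for the noise.
#' @return A full-cell \linkS4class{DensityMap}.
#' @export
makeBlobMap <- function(cell = unitCell(40, 40, 40), spacing = 0.5,
                        blobs = list(), noiseSd = 0, seed = 1L) {
    stopifnot(spacing > 0)
    n <- as.integer(round(cell@abc / spacing))
    stopifnot(all(n >= 2))
    grid <- array(0, dim = n)
    step <- cell@abc / n
    for (bl in blobs) {
        stopifnot(inherits(bl, "BlobSpec"))
        ext <- 4 * bl$width
        ctr <- bl$center
        lo <- floor((ctr - ext) / step)
        hi <- ceiling((ctr + ext) / step)
        if (all(hi - lo + 1 < n)) {
            # support smaller than the cell: evaluate on the voxel box
            # around the center; wrapped indexing realizes the
            # periodic images crossing the cell boundary
            ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
            dx <- ix * step[1] - ctr[1]
            dy <- iy * step[2] - ctr[2]
            dz <- iz * step[3] - ctr[3]
            g <- bl$amplitude *
                exp(-outer(outer(dx^2, dy^2, "+"), dz^2, "+") /
                    (2 * bl$width^2))
            wx <- (ix %% n[1]) + 1L; wy <- (iy %% n[2]) + 1L
            wz <- (iz %% n[3]) + 1L
            grid[wx, wy, wz] <- grid[wx, wy, wz] + g
        } else {
            # wide blob: dense evaluation with explicit image sum
            nim <- ceiling(ext / cell@abc)
            ax <- (seq_len(n[1]) - 1) * step[1]
            ay <- (seq_len(n[2]) - 1) * step[2]
            az <- (seq_len(n[3]) - 1) * step[3]
            for (sx in -nim[1]:nim[1]) for (sy in -nim[2]:nim[2])
            for (sz in -nim[3]:nim[3]) {
                cc <- ctr + c(sx, sy, sz) * cell@abc
                g <- bl$amplitude *
                    exp(-outer(outer((ax - cc[1])^2, (ay - cc[2])^2, "+"),
                               (az - cc[3])^2, "+") / (2 * bl$width^2))
                grid <- grid + g
            }
        }
    }
    if (noiseSd > 0)
        grid <- grid + withSeed(seed,
            array(stats::rnorm(prod(n), sd = noiseSd), dim = n))
    densityMap(grid, cell, spacegroup = 1L)
}

#' Closed-form populations of sequential first-order kinetics
#'
#' Three-state scheme A -> B -> C with rate constants k1, k2 (1/s),
#' starting fully in A: standard two-exponential solution.
#'
#' @param rates numeric(2), rate constants k1, k2 in 1/s (>= 0).
#' @param times numeric vector of times in seconds.
#' @return 3 x length(times) matrix of populations (columns sum to 1).
#' @export
kineticPopulations <- function(rates, times) {
    stopifnot(length(rates) == 2L)
    if (any(rates < 0)) stop("rate constants must be nonnegative")
    k1 <- rates[1]; k2 <- rates[2]
    pA <- exp(-k1 * times)
    pB <- if (abs(k2 - k1) < 1e-12 * max(k1, k2, 1))
        k1 * times * exp(-k1 * times)
    else k1 / (k2 - k1) * (exp(-k1 * times) - exp(-k2 * times))
    pC <- 1 - pA - pB
    p <- rbind(A = pA, B = pB, C = pC)
    pmax(p, 0)
}

#' Kinetic ground truth for a synthetic map series
#'
#' @param components list of blob lists, one per kinetic state (A, B,
#'   C, ... in reaction order).
#' @param rates sequential first-order rate constants (length =
#'   number of components - 1; currently 2, i.e. 3 states).
#' @param times time delays in seconds.
#' @param noiseSd per-voxel Gaussian noise sd added to every map.
#' @param seed RNG seed.
#' @return list of class "KineticTruth" with the populations filled
#'   in.
#' @export
kineticTruth <- function(components, rates, times, noiseSd = 0,
                         seed = 1L) {
    stopifnot(is.list(components), length(components) == 3L,
              length(rates) == 2L)
    pops <- kineticPopulations(rates, times)
    structure(list(components = components, rates = rates,
                   times = times, populations = pops,
                   noiseSd = noiseSd, seed = as.integer(seed)),
              class = "KineticTruth")
}

#' Synthetic kinetic series of difference maps
#'
#' map_t = sum_k population_k(t) * blobmap_k + noise, with populations
#' from the sequential first-order scheme of the truth object.
#' Deterministic per seed (noise differs between time points but is
#' reproducible).
#'
#' @param truth a \code{\link{kineticTruth}}.
#' @param cell,spacing grid geometry (defaults 40 Angstrom cube,
#'   0.5 Angstrom).
#' @return list with \code{maps} (list of \linkS4class{DensityMap}),
#'   \code{delays}, \code{labels}, \code{populations}.
#' @export
makeKineticSeries <- function(truth, cell = unitCell(40, 40, 40),
                              spacing = 0.5) {
    stopifnot(inherits(truth, "KineticTruth"))
    base <- lapply(truth$components, function(bl)
        makeBlobMap(cell, spacing, bl, noiseSd = 0)@grid)
    nT <- length(truth$times)
    maps <- vector("list", nT)
    for (j in seq_len(nT)) {
        g <- array(0, dim = dim(base[[1]]))
        for (k in seq_along(base))
            g <- g + truth$populations[k, j] * base[[k]]
        if (truth$noiseSd > 0)
            g <- g + withSeed(truth$seed + j,
                array(stats::rnorm(length(g), sd = truth$noiseSd),
                      dim = dim(g)))
        maps[[j]] <- densityMap(g, cell, spacegroup = 1L)
    }
    list(maps = maps, delays = truth$times,
         labels = formatDelay(truth$times),
         populations = truth$populations)
}

#' Format time delays with engineering units
#'
#' @param seconds numeric vector of delays in seconds.
#' @return character vector like "760 ns", "1.725 ms".
#' @export
formatDelay <- function(seconds) {
    vapply(seconds, function(s) {
        if (!is.finite(s)) return(NA_character_)
        a <- abs(s)
        if (a >= 1) sprintf("%.3g s", s)
        else if (a >= 1e-3) sprintf("%.4g ms", s * 1e3)
        else if (a >= 1e-6) sprintf("%.4g us", s * 1e6)
        else if (a >= 1e-9) sprintf("%.4g ns", s * 1e9)
        else if (a >= 1e-12) sprintf("%.4g ps", s * 1e12)
        else sprintf("%.4g fs", s * 1e15)
    }, character(1))
}

## ideal alpha-helix internal coordinates: radius (A), phase offset
## (deg) and rise offset (A) relative to CA, ~100 deg / 1.5 A per
## residue
helixAtomGeom <- list(
    N  = c(r = 1.58, dphi = -28.0, dz = -0.90),
    CA = c(r = 2.28, dphi = 0.0,   dz = 0.00),
    C  = c(r = 1.68, dphi = 26.0,  dz = 1.10),
    O  = c(r = 2.00, dphi = 29.0,  dz = 2.30),
    CB = c(r = 3.30, dphi = -8.0,  dz = -0.25))

#' Toy poly-alanine structure in a P1 cell
#'
#' Ideal alpha-helices (5 backbone/CB atoms per residue, ~100 degrees
#' twist and 1.5 Angstrom rise) placed inside a P1 box with at least
#' 5 Angstrom clearance to the cell boundary, deterministic per seed.
#' Valid for writing as PDB and for structure-factor calculation.
#'
#' @param nHelices number of helices (>= 1).
#' @param nRes residues per helix (default 8).
#' @param cell a \linkS4class{UnitCell} (default 40 Angstrom cube).
#' @param seed RNG seed controlling helix placement.
#' @return A \linkS4class{StructureModel} (spacegroup P 1).
#' @export
makeToyStructure <- function(nHelices = 1L, nRes = 8L,
                             cell = unitCell(40, 40, 40), seed = 1L) {
    stopifnot(nHelices >= 1L, nRes >= 1L)
    margin <- 5
    zlen <- 1.5 * (nRes - 1) + 2 * 3.5     # helix length + atom extent
    lim <- cell@abc - 2 * margin
    if (zlen > lim[3]) stop("cell too small for the requested helix length")
    rows <- withSeed(seed, {
        out <- NULL
        centers <- matrix(NA_real_, nHelices, 2)
        for (h in seq_len(nHelices)) {
            # rejection-sample xy center keeping helices apart
            repeat {
                xy <- margin + 4 + stats::runif(2) * (lim[1:2] - 8)
                if (h == 1L ||
                    all(sqrt(colSums((t(centers[seq_len(h - 1), , drop = FALSE]) - xy)^2)) > 8))
                    break
            }
            centers[h, ] <- xy
            phi0 <- stats::runif(1) * 360
            z0 <- margin + 3.5 + stats::runif(1) *
                max(cell@abc[3] - 2 * (margin + 3.5) - zlen, 0)
            for (i in seq_len(nRes)) {
                for (an in names(helixAtomGeom)) {
                    g <- helixAtomGeom[[an]]
                    phi <- (phi0 + 100 * (i - 1) + g["dphi"]) * pi / 180
                    out <- rbind(out, data.frame(
                        name = an,
                        element = substr(an, 1, 1),
                        chain = LETTERS[h], resno = i,
                        x = xy[1] + g["r"] * cos(phi),
                        y = xy[2] + g["r"] * sin(phi),
                        z = z0 + 1.5 * (i - 1) + g["dz"],
                        stringsAsFactors = FALSE))
                }
            }
        }
        out
    })
    atoms <- data.frame(
        serial = seq_len(nrow(rows)), name = rows$name,
        element = rows$element, altloc = "", resname = "ALA",
        chain = rows$chain, resno = rows$resno, occupancy = 1,
        b = 20, x = round(rows$x, 3), y = round(rows$y, 3),
        z = round(rows$z, 3), hetero = FALSE, dummy = FALSE,
        stringsAsFactors = FALSE)
    rownames(atoms) <- NULL
    new("StructureModel", atoms = atoms, cell = cell, hasCell = TRUE,
        spacegroup = "P 1")
}
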