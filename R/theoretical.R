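## Cromer-Mann 4-Gaussian scattering-factor coefficients
## (International Tables for Crystallography Vol. C, neutral atoms):
## f(s) = sum_i a_i exp(-b_i (s/2)^2) + c,  s = 1/d in 1/Angstrom.
cromerMann <- list(
    H  = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
              b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
    C  = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
              b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
    N  = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
              b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
    O  = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
              b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
    NA_ = list(a = c(4.76260, 3.17360, 1.26740, 1.11280),
              b = c(3.28500, 8.84220, 0.313600, 129.424), c = 0.676000),
    MG = list(a = c(5.42040, 2.17350, 1.22690, 2.30730),
              b = c(2.82750, 79.2611, 0.380800, 7.19370), c = 0.858400),
    P  = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
              b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
    S  = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
              b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
    CL = list(a = c(11.4604, 7.19640, 6.25560, 1.64550),
              b = c(0.010400, 1.16620, 18.5194, 47.7784), c = -9.5574),
    K  = list(a = c(8.21860, 7.43980, 1.05190, 0.865900),
              b = c(12.7949, 0.774800, 213.187, 41.6841), c = 1.42280),
    CA = list(a = c(8.62660, 7.38730, 1.58990, 1.02110),
              b = c(10.4421, 0.659900, 85.7484, 178.437), c = 1.37510),
    FE = list(a = c(11.7695, 7.35730, 3.52220, 2.30450),
              b = c(4.76110, 0.307200, 15.3535, 76.8805), c = 1.03690))

#' Atomic scattering factor
#'
#' Cromer-Mann 4-Gaussian form factor of a neutral element at
#' scattering vector magnitude s = 1/d.
#'
#' @param element element symbol (H, C, N, O, NA, MG, P, S, CL, K, CA,
#'   FE).
#' @param s numeric vector, 1/d in 1/Angstrom.
#' @return numeric vector f(s) in electrons.
#' @export
formFactor <- function(element, s) {
    key <- toupper(element)
    if (key == "NA") key <- "NA_"
    cm <- cromerMann[[key]]
    if (is.null(cm)) stop("no form factor tabulated for element '",
                          element, "'")
    out <- rep(cm$c, length(s))
    q <- (s / 2)^2
    for (i in 1:4) out <- out + cm$a[i] * exp(-cm$b[i] * q)
    out
}

# Miller indices of all reflections to dmin (full Friedel sphere, P1),
# including (0,0,0). Returns hkl matrix and |s| = 1/d vector.
millerIndices <- function(cell, dmin) {
    stopifnot(dmin > 0)
    hmax <- ceiling(cell@abc / dmin)
    grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1],
                                  k = -hmax[2]:hmax[2],
                                  l = -hmax[3]:hmax[3]))
    svec <- grid %*% solve(cell@orth)     # s = h . M^-1 (rows of inverse)
    slen <- sqrt(rowSums(svec^2))
    keep <- slen <= 1 / dmin + 1e-12
    list(hkl = grid[keep, , drop = FALSE], s = slen[keep])
}

#' Structure factors of a model
#'
#' Direct summation F(h) = sum_atoms occ * f_elem(s) * exp(-B s^2 / 4)
#' * exp(2 pi i h . x_frac) with Cromer-Mann form factors, isotropic
#' B-factors, over all reflections of the full Friedel sphere to
#' \code{dmin}. Only P1 models are accepted; expand symmetry mates
#' upstream for other space groups.
#'
#' @param model a \linkS4class{StructureModel} with a CRYST1 cell.
#' @param dmin resolution limit in Angstrom.
#' @param includeHydrogens include H atoms if present (default TRUE;
#'   deposited models usually have none).
#' @return A \linkS4class{ReflectionSet}.
#' @export
structureFactors <- function(model, dmin, includeHydrogens = TRUE) {
    stopifnot(is(model, "StructureModel"))
    if (dmin <= 0) stop("dmin must be positive")
    if (!model@hasCell) stop("model has no unit cell (CRYST1 missing)")
    sg <- gsub(" ", "", model@spacegroup)
    if (nzchar(sg) && sg != "P1")
        stop("only P1 models are supported; expand '", model@spacegroup,
             "' symmetry mates to P1 upstream")
    at <- model@atoms
    if (!includeHydrogens) at <- at[!(at$element %in% c("H", "D")), ]
    if (!nrow(at)) stop("model has no atoms")
    bad <- setdiff(toupper(at$element),
                   c(names(cromerMann)[names(cromerMann) != "NA_"], "NA"))
    if (length(bad))
        stop("no form factor tabulated for element(s): ",
             paste(bad, collapse = ", "))
    mi <- millerIndices(model@cell, dmin)
    hkl <- mi$hkl
    frac <- cartToFrac(model@cell, as.matrix(at[, c("x", "y", "z")]))
    f <- complex(length.out = nrow(hkl))
    q4 <- mi$s^2 / 4
    for (el in unique(at$element)) {
        sel <- at$element == el
        fe <- formFactor(el, mi$s)                       # nrefl
        dw <- exp(-outer(q4, at$b[sel]))                 # nrefl x nat
        w <- sweep(dw, 2, at$occupancy[sel], "*") * fe
        ph <- exp(2i * pi * (hkl %*% t(frac[sel, , drop = FALSE])))
        f <- f + rowSums(w * ph)
    }
    new("ReflectionSet", hkl = hkl, f = f, dmin = dmin, cell = model@cell)
}

setMethod("show", "ReflectionSet", function(object) {
    cat(sprintf("ReflectionSet: %d reflections to %.2f A\n",
                nrow(object@hkl), object@dmin))
    show(object@cell)
})

#' Fourier synthesis of a difference map
#'
#' Inverse Fourier transform of (F_excited - F_dark) onto a full-cell
#' grid: rho(x) = (1/V) sum_h [F_exc(h) - F_dark(h)] exp(-2 pi i h.x),
#' evaluated by FFT. The two reflection sets must share the cell and
#' index set; Friedel-complete input gives a real map.
#'
#' @param reflExcited,reflDark \linkS4class{ReflectionSet}s.
#' @param gridSpacing target grid spacing in Angstrom (default
#'   dmin / 3).
#' @return A full-cell \linkS4class{DensityMap} in e/A^3, RMS computed.
#' @export
fourierMap <- function(reflExcited, reflDark = NULL,
                       gridSpacing = reflExcited@dmin / 3) {
    stopifnot(is(reflExcited, "ReflectionSet"))
    h1 <- reflExcited@hkl
    if (!is.null(reflDark)) {
        stopifnot(is(reflDark, "ReflectionSet"))
        if (!isTRUE(all.equal(reflExcited@cell@abc, reflDark@cell@abc)) ||
            nrow(h1) != nrow(reflDark@hkl) ||
            any(h1 != reflDark@hkl))
            stop("reflection sets must share the same cell and index set")
        dF <- reflExcited@f - reflDark@f
    } else dF <- reflExcited@f
    cell <- reflExcited@cell
    hmax <- apply(abs(h1), 2, max)
    n <- pmax(as.integer(ceiling(cell@abc / gridSpacing)),
              2L * hmax + 1L)
    arr <- array(complex(real = 0), dim = n)
    idx <- 1L + (h1[, 1] %% n[1]) +
        n[1] * ((h1[, 2] %% n[2]) + n[2] * (h1[, 3] %% n[3]))
    arr[idx] <- dF
    rho <- stats::fft(arr) / cellVolume(cell)
    im <- max(abs(Im(rho)))
    sc <- max(abs(Re(rho)), 1e-300)
    if (im > 1e-6 * sc)
        warning(sprintf(
            "synthesis imaginary part %.2g of real scale: input not Friedel-complete?",
            im / sc))
    densityMap(Re(rho), cell, spacegroup = 1L)
}

#' Re-extract structure factors from a map (forward transform)
#'
#' Inverse of \code{\link{fourierMap}} on the map's own grid; useful
#' for round-trip checks.
#'
#' @param map a full-cell \linkS4class{DensityMap}.
#' @param hkl integer matrix of Miller indices to extract.
#' @return complex vector of coefficients F(hkl).
#' @export
mapStructureFactors <- function(map, hkl) {
    stopifnot(is(map, "DensityMap"), map@fullCell)
    n <- dim(map@grid)
    ft <- stats::fft(map@grid, inverse = TRUE) *
        (cellVolume(map@cell) / prod(n))
    idx <- 1L + (hkl[, 1] %% n[1]) +
        n[1] * ((hkl[, 2] %% n[2]) + n[2] * (hkl[, 3] %% n[3]))
    ft[idx]
}

#' Theoretical difference map from a structure pair
#'
#' Computes model structure factors for the resting (dark) and
#' full-occupancy photo-activated (excited) models and synthesizes the
#' difference density by FFT. When dummy-water positions are given
#' they are added to the excited model only, providing a known
#' positive feature outside the protein whose sphere amplitude anchors
#' relative scaling across a series (see \code{\link{scaleMapSeries}}).
#'
#' @param dark resting-state \linkS4class{StructureModel}.
#' @param excited photo-activated full-occupancy single-conformer
#'   model (prepare with \code{\link{extractConformer}}).
#' @param dmin resolution limit in Angstrom.
#' @param dummyPositions optional n x 3 matrix of dummy-water
#'   positions.
#' @param gridSpacing map grid spacing (default dmin / 3).
#' @param dummyRadius sphere radius for the dummy amplitude
#'   (default 2.0).
#' @return list with \code{map} (a \linkS4class{DensityMap}),
#'   \code{dummyMean} (mean dummy-site positive sphere amplitude,
#'   floor 0; NA without dummies) and \code{dummyPositions}.
#' @export
theoreticalDifferenceMap <- function(dark, excited, dmin,
                                     dummyPositions = NULL,
                                     gridSpacing = dmin / 3,
                                     dummyRadius = 2.0) {
    stopifnot(is(dark, "StructureModel"), is(excited, "StructureModel"))
    if (any(excited@atoms$altloc != ""))
        stop("excited model still has alternate conformers; run extractConformer first")
    if (any(excited@atoms$occupancy != 1))
        warning("excited model has partial occupancies; expected full occupancy")
    if (!is.null(dummyPositions))
        excited <- addDummyWaters(excited, dummyPositions)
    fE <- structureFactors(excited, dmin)
    fD <- structureFactors(dark, dmin)
    map <- fourierMap(fE, fD, gridSpacing = gridSpacing)
    dummyMean <- NA_real_
    if (!is.null(dummyPositions)) {
        dp <- rbind3(dummyPositions)
        pars <- extractionParams(radius = dummyRadius, floorAbs = 0)
        amps <- vapply(seq_len(nrow(dp)), function(i)
            atomAmplitude(map, dp[i, ], pars)$pos, numeric(1))
        dummyMean <- mean(amps)
    }
    list(map = map, dummyMean = dummyMean,
         dummyPositions = dummyPositions)
}

#' Scale a theoretical map series by its dummy-water amplitudes
#'
#' Divides each map by its mean dummy-site sphere amplitude and
#' multiplies by the reference map's, so that the density predicted
#' for the shared dummy waters is equal across the series.
#'
#' @param maps list of \linkS4class{DensityMap}s (a theoretical
#'   series sharing dummy positions).
#' @param dummyPositions n x 3 matrix of the shared dummy positions.
#' @param reference index of the reference map (default 1).
#' @param radius sphere radius for the dummy amplitude (default 2.0).
#' @param labels map labels for the report.
#' @return list with \code{maps} (scaled) and \code{report}
#'   (a \linkS4class{ScalingReport}).
#' @export
scaleMapSeries <- function(maps, dummyPositions, reference = 1L,
                           radius = 2.0,
                           labels = paste0("map", seq_along(maps))) {
    stopifnot(is.list(maps), length(maps) >= 1L)
    dp <- rbind3(dummyPositions)
    pars <- extractionParams(radius = radius, floorAbs = 0)
    dummyMean <- vapply(maps, function(m) {
        mean(vapply(seq_len(nrow(dp)), function(i)
            atomAmplitude(m, dp[i, ], pars)$pos, numeric(1)))
    }, numeric(1))
    if (any(dummyMean <= 0))
        stop("a map has nonpositive dummy-site amplitude; cannot scale")
    fac <- dummyMean[reference] / dummyMean
    scaled <- lapply(seq_along(maps), function(i) {
        m <- maps[[i]]
        densityMap(m@grid * fac[i], m@cell, origin = m@origin,
                   sampling = m@sampling, spacegroup = m@spacegroup)
    })
    rep <- new("ScalingReport", labels = labels, dummyMean = dummyMean,
               scale = fac, reference = labels[reference])
    list(maps = scaled, report = rep)
}

setMethod("show", "ScalingReport", function(object) {
    cat("ScalingReport (reference ", object@reference, ")\n", sep = "")
    for (i in seq_along(object@labels))
        cat(sprintf("  %s: dummy amplitude %.4g, scale %.4g\n",
                    object@labels[i], object@dummyMean[i], object@scale[i]))
})
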