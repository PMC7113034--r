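#' Extraction parameters
#'
#' Defaults follow the pragmatic choices for experimental maps: sphere
#' radius 2.0 Angstrom (about the map resolution), 0.5 Angstrom mesh,
#' and a +/-3 sigma floor. For noise-free theoretical maps a floor of 0
#' is appropriate (sigma has a different physical meaning there) and
#' must be chosen explicitly.
#'
#' @param radius sphere radius in Angstrom.
#' @param mesh sampling spacing inside the sphere in Angstrom.
#' @param nSigma floor multiplier; the absolute floor is
#'   nSigma * RMS(map), resolved when a map is supplied.
#' @param floorAbs explicit absolute floor in map units; overrides
#'   nSigma when finite.
#' @param faithful resample the map to a 0.25 Angstrom Cartesian grid
#'   before sphere interpolation (two-step fidelity mode).
#' @return An \linkS4class{ExtractionParams}.
#' @export
extractionParams <- function(radius = 2.0, mesh = 0.5, nSigma = 3.0,
                             floorAbs = NA_real_, faithful = FALSE) {
    new("ExtractionParams", radius = radius, mesh = mesh, nSigma = nSigma,
        floorAbs = as.numeric(floorAbs), faithful = faithful)
}

setMethod("show", "ExtractionParams", function(object) {
    cat(sprintf(
        "ExtractionParams: radius %.2f A, mesh %.2f A, floor %s%s\n",
        object@radius, object@mesh,
        if (is.finite(object@floorAbs))
            sprintf("%.4g (absolute)", object@floorAbs)
        else sprintf("%.1f sigma", object@nSigma),
        if (object@faithful) ", faithful resampling" else ""))
})

# absolute floor for a given map
resolveFloor <- function(params, map) {
    if (is.finite(params@floorAbs)) params@floorAbs
    else params@nSigma * mapRms(map)
}

#' Sphere sampling mesh
#'
#' All offsets (i, j, k) * mesh with integer i, j, k whose Euclidean
#' norm is at most \code{radius} (boundary inclusive), in lexicographic
#' (i, j, k) order, origin included. With radius 2.0 and mesh 0.5 this
#' is 257 points.
#'
#' @param radius sphere radius in Angstrom.
#' @param mesh lattice spacing in Angstrom.
#' @return n x 3 matrix of Cartesian offsets.
#' @examples
#' nrow(sphereMesh(2.0, 0.5))  # 257
#' @export
sphereMesh <- function(radius, mesh) {
    stopifnot(radius > 0, mesh > 0)
    m <- floor(radius / mesh)
    r <- (-m):m
    off <- as.matrix(expand.grid(k = r, j = r, i = r))[, 3:1, drop = FALSE]
    off <- off[order(off[, 1], off[, 2], off[, 3]), , drop = FALSE]
    keep <- sqrt(rowSums(off^2)) <= radius / mesh + 1e-12
    out <- off[keep, , drop = FALSE] * mesh
    dimnames(out) <- list(NULL, c("x", "y", "z"))
    out
}

# shared worker: interpolated, floored sphere samples about one center
sphereSamples <- function(map, center, params, floorAbs) {
    off <- sphereMesh(params@radius, params@mesh)
    pts <- sweep(off, 2, as.numeric(center), "+")
    v <- interpolateMap(map, pts)
    v[abs(v) < floorAbs] <- 0
    list(v = v, norm = sqrt(rowSums(off^2)))
}

dualFromSamples <- function(v) {
    pos <- v[v > 0]; neg <- v[v < 0]
    list(pos = if (length(pos)) mean(pos) else 0,
         neg = if (length(neg)) mean(neg) else 0,
         nPos = length(pos), nNeg = length(neg))
}

#' Dual-valued sphere amplitude about one point
#'
#' The central reduction: interpolate the map on the sphere mesh
#' centered at \code{center}, zero every sample with |density| strictly
#' below the floor, then average the surviving positive and negative
#' samples separately. An empty surviving set gives amplitude 0.
#'
#' @param map a full-cell \linkS4class{DensityMap}.
#' @param center Cartesian Angstrom position (length-3).
#' @param params an \linkS4class{ExtractionParams}; the absolute floor
#'   is \code{floorAbs} if finite, else \code{nSigma * mapRms(map)}.
#' @return list with \code{pos} (>= 0), \code{neg} (<= 0, signed),
#'   \code{nPos}, \code{nNeg}.
#' @export
atomAmplitude <- function(map, center, params = extractionParams()) {
    stopifnot(is(map, "DensityMap"))
    if (!map@fullCell)
        stop("amplitude extraction requires a full-cell map")
    floorAbs <- resolveFloor(params, map)
    if (params@faithful) map <- resampleCartesian(map, 0.25)
    dualFromSamples(sphereSamples(map, center, params, floorAbs)$v)
}

#' Amplitude profile A(a_i) over an atom set
#'
#' Walks the amplitude sphere through every atom of the selection and
#' records the dual-valued amplitude per atom, in model order. The map
#' sigma is resolved once per map.
#'
#' @param map a full-cell \linkS4class{DensityMap}.
#' @param atoms atom data.frame (from \code{\link{selectAtoms}} or
#'   \code{modelAtoms}), or a \linkS4class{StructureModel} (default
#'   selection applied).
#' @param params an \linkS4class{ExtractionParams}.
#' @param delay time delay in seconds (optional).
#' @param label display label, e.g. "760 ns".
#' @return An \linkS4class{AmplitudeProfile}.
#' @export
amplitudeProfile <- function(map, atoms, params = extractionParams(),
                             delay = NA_real_, label = "") {
    stopifnot(is(map, "DensityMap"))
    if (is(atoms, "StructureModel")) atoms <- selectAtoms(atoms)
    if (!is.data.frame(atoms) || nrow(atoms) == 0L)
        stop("empty atom list")
    if (!map@fullCell)
        stop("amplitude extraction requires a full-cell map")
    sigma <- mapRms(map)
    floorAbs <- resolveFloor(params, map)
    wmap <- if (params@faithful) resampleCartesian(map, 0.25) else map
    off <- sphereMesh(params@radius, params@mesh)
    nOff <- nrow(off)
    n <- nrow(atoms)
    # interpolate all atoms x offsets in one call
    ctr <- as.matrix(atoms[, c("x", "y", "z")])
    pts <- ctr[rep(seq_len(n), each = nOff), , drop = FALSE] +
        off[rep(seq_len(nOff), times = n), , drop = FALSE]
    v <- interpolateMap(wmap, pts)
    v[abs(v) < floorAbs] <- 0
    dim(v) <- c(nOff, n)
    # reduce each atom through the same path as atomAmplitude so the
    # two agree bit-for-bit
    duals <- lapply(seq_len(n), function(i) dualFromSamples(v[, i]))
    pos <- vapply(duals, `[[`, numeric(1), "pos")
    neg <- vapply(duals, `[[`, numeric(1), "neg")
    nPos <- vapply(duals, `[[`, integer(1), "nPos")
    nNeg <- vapply(duals, `[[`, integer(1), "nNeg")
    new("AmplitudeProfile", atoms = atoms, pos = pos, neg = neg,
        nPos = nPos, nNeg = nNeg, params = params, mapSigma = sigma,
        delay = as.numeric(delay), label = as.character(label))
}

#' Shell amplitude between two radii
#'
#' Amplitude within the concentric spherical shell
#' r_inner < ||offset|| <= r_outer about \code{center}, computed as a
#' difference of sphere sums (positive sum and count at the outer
#' radius minus at the inner radius, after flooring) and then averaged,
#' so that shell contributions over a partition of [0, R] add up
#' exactly to the full-sphere sums. \code{rInner = 0} reduces exactly
#' to \code{\link{atomAmplitude}} (the origin sample belongs to the
#' innermost shell).
#'
#' @param map a full-cell \linkS4class{DensityMap}.
#' @param center Cartesian Angstrom position.
#' @param rInner,rOuter shell radii, 0 <= rInner < rOuter.
#' @param params an \linkS4class{ExtractionParams}; its radius is
#'   ignored in favour of \code{rOuter}.
#' @return list with \code{pos}, \code{neg}, \code{nPos}, \code{nNeg}.
#' @export
shellAmplitude <- function(map, center, rInner, rOuter,
                           params = extractionParams()) {
    stopifnot(is(map, "DensityMap"), rInner >= 0)
    if (rInner >= rOuter) stop("rInner must be smaller than rOuter")
    if (!map@fullCell)
        stop("amplitude extraction requires a full-cell map")
    floorAbs <- resolveFloor(params, map)
    if (params@faithful) map <- resampleCartesian(map, 0.25)
    p2 <- initialize(params, radius = rOuter)
    s <- sphereSamples(map, center, p2, floorAbs)
    inner <- if (rInner == 0) rep(FALSE, length(s$v))
             else s$norm <= rInner + 1e-12
    v <- s$v
    posO <- sum(v[v > 0]); nPosO <- sum(v > 0)
    negO <- sum(v[v < 0]); nNegO <- sum(v < 0)
    vi <- v[inner]
    posI <- sum(vi[vi > 0]); nPosI <- sum(vi > 0)
    negI <- sum(vi[vi < 0]); nNegI <- sum(vi < 0)
    nPos <- nPosO - nPosI; nNeg <- nNegO - nNegI
    list(pos = if (nPos > 0) (posO - posI) / nPos else 0,
         neg = if (nNeg > 0) (negO - negI) / nNeg else 0,
         nPos = as.integer(nPos), nNeg = as.integer(nNeg))
}

#' Region-averaged absolute amplitude time courses
#'
#' For each named region, averages the per-atom absolute amplitude
#' (pos + |neg|)/2 over the member atoms, per time point, and
#' normalizes the series by a reference time point or by the mean over
#' a reference window (e.g. unity at the last delay, or unit mean over
#' an early femtosecond window).
#'
#' @param profiles list of \linkS4class{AmplitudeProfile} sharing one
#'   atom list and parameters.
#' @param regions named list; each element selects member atoms either
#'   as an integer vector of atom indices (into the shared atom list)
#'   or as a list with optional \code{chain} and \code{resno} fields.
#' @param reference integer index (single time point) or vector of
#'   indices (window) used for normalization.
#' @param reduce "pairmean" (default, (pos+|neg|)/2 per atom) or
#'   "concat" (mean over the 2N concatenated absolute values).
#' @return data.frame with columns region, index, label, delay, raw,
#'   value (normalized).
#' @export
regionAverage <- function(profiles, regions, reference = length(profiles),
                          reduce = c("pairmean", "concat")) {
    reduce <- match.arg(reduce)
    checkProfileSeries(profiles)
    stopifnot(is.list(regions), length(names(regions)) == length(regions))
    atoms <- profiles[[1]]@atoms
    out <- NULL
    for (rg in names(regions)) {
        sel <- regions[[rg]]
        if (is.numeric(sel)) idx <- as.integer(sel)
        else {
            keep <- rep(TRUE, nrow(atoms))
            if (!is.null(sel$chain)) keep <- keep & atoms$chain %in% sel$chain
            if (!is.null(sel$resno)) keep <- keep & atoms$resno %in% sel$resno
            idx <- which(keep)
        }
        if (!length(idx)) stop("region '", rg, "' selects no atoms")
        raw <- vapply(profiles, function(p) {
            if (reduce == "pairmean") mean((p@pos[idx] - p@neg[idx]) / 2)
            else mean(c(p@pos[idx], -p@neg[idx]))
        }, numeric(1))
        ref <- mean(raw[reference])
        if (ref == 0) stop("normalization reference is zero for region '", rg, "'")
        out <- rbind(out, data.frame(
            region = rg, index = seq_along(profiles),
            label = vapply(profiles, function(p) p@label, character(1)),
            delay = vapply(profiles, function(p) p@delay, numeric(1)),
            raw = raw, value = raw / ref, stringsAsFactors = FALSE))
    }
    rownames(out) <- NULL
    out
}

# consistency checks for a series of profiles
checkProfileSeries <- function(profiles) {
    if (!is.list(profiles) || !length(profiles) ||
        !all(vapply(profiles, is, logical(1), "AmplitudeProfile")))
        stop("profiles must be a nonempty list of AmplitudeProfile objects")
    n <- length(profiles[[1]]@pos)
    ser <- profiles[[1]]@atoms$serial
    for (p in profiles[-1]) {
        if (length(p@pos) != n || !identical(p@atoms$serial, ser))
            stop("profiles must share an identical atom list")
    }
    invisible(TRUE)
}

#' @describeIn amplitudeProfile Concatenated 2N amplitude vector
#'   [pos; neg] of a profile (the vector entering correlations and
#'   decompositions).
#' @param profile an \linkS4class{AmplitudeProfile}.
#' @export
concatAmplitudes <- function(profile) c(profile@pos, profile@neg)

#' @describeIn amplitudeProfile Profile as a data.frame (one row per
#'   atom: identifiers plus A_pos, A_neg, n_pos, n_neg).
#' @export
profileTable <- function(profile) {
    at <- profile@atoms
    data.frame(atom_serial = at$serial, chain = at$chain,
               residue_number = at$resno, residue_name = at$resname,
               atom_name = at$name, A_pos = profile@pos,
               A_neg = profile@neg, n_pos = profile@nPos,
               n_neg = profile@nNeg, stringsAsFactors = FALSE)
}

#' Write a profile as CSV with a JSON parameter sidecar
#'
#' @param profile an \linkS4class{AmplitudeProfile}.
#' @param path CSV output path; the sidecar is written next to it with
#'   extension .json.
#' @return \code{path}, invisibly.
#' @export
writeProfile <- function(profile, path) {
    utils::write.csv(profileTable(profile), path, row.names = FALSE)
    side <- sub("\\.csv$", "", path)
    p <- profile@params
    jsonlite::write_json(list(
        radius = p@radius, mesh = p@mesh, n_sigma = p@nSigma,
        floor_abs = if (is.finite(p@floorAbs)) p@floorAbs else NULL,
        faithful = p@faithful, map_sigma = profile@mapSigma,
        delay = if (is.finite(profile@delay)) profile@delay else NULL,
        label = profile@label), paste0(side, ".json"),
        auto_unbox = TRUE, digits = NA)
    invisible(path)
}

setMethod("show", "AmplitudeProfile", function(object) {
    cat(sprintf(
        "AmplitudeProfile%s: %d atoms, sigma %.4g, max pos %.4g, min neg %.4g\n",
        if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
        length(object@pos), object@mapSigma,
        if (length(object@pos)) max(object@pos) else NA,
        if (length(object@neg)) min(object@neg) else NA))
    show(object@params)
})
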