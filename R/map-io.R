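#' Construct a density map from a grid in canonical axis order
#'
#' @param grid 3D numeric array; index 1, 2, 3 along cell axes a, b, c.
#' @param cell a \linkS4class{UnitCell}.
#' @param origin integer(3), 0-based start indices of the grid within
#'   the full-cell sampling (default 0).
#' @param sampling integer(3), grid divisions per full cell edge
#'   (default \code{dim(grid)}: the grid covers the whole cell).
#' @param spacegroup integer space-group number (default 1, P1).
#' @return A \linkS4class{DensityMap}; \code{fullCell} is set by
#'   comparing the grid extent to the cell sampling, and the RMS sigma
#'   is computed and cached.
#' @export
densityMap <- function(grid, cell, origin = c(0L, 0L, 0L),
                       sampling = dim(grid), spacegroup = 1L) {
    storage.mode(grid) <- "double"
    new("DensityMap", grid = grid, cell = cell,
        origin = as.integer(origin), sampling = as.integer(sampling),
        spacegroup = as.integer(spacegroup),
        fullCell = all(dim(grid) == sampling),
        rms = sqrt(mean(grid^2)))
}

#' Map sigma: root-mean-square density of the cell
#'
#' The flooring/contouring unit sigma is the literal RMS of the map,
#' \code{sqrt(mean(v^2))}, with no mean subtraction; difference maps
#' have near-zero mean so this differs negligibly from the
#' mean-subtracted convention, which \code{mapSd} exposes.
#'
#' @param map a full-cell \linkS4class{DensityMap}.
#' @return RMS density (map units).
#' @export
mapRms <- function(map) {
    stopifnot(is(map, "DensityMap"))
    if (!map@fullCell)
        stop("sigma is a cell property: map must cover the full unit cell")
    map@rms
}

#' @rdname mapRms
#' @export
mapSd <- function(map) {
    stopifnot(is(map, "DensityMap"))
    if (!map@fullCell)
        stop("sigma is a cell property: map must cover the full unit cell")
    v <- map@grid
    sqrt(mean((v - mean(v))^2))
}

#' @describeIn densityMap Grid values of a map.
#' @param map a \linkS4class{DensityMap}.
#' @export
mapGrid <- function(map) map@grid

#' @describeIn densityMap Unit cell of a map.
#' @export
mapCell <- function(map) map@cell

setMethod("show", "DensityMap", function(object) {
    d <- dim(object@grid)
    cat(sprintf("DensityMap: %d x %d x %d grid%s, spacegroup %d\n",
                d[1], d[2], d[3],
                if (object@fullCell) " (full cell)" else "",
                object@spacegroup))
    show(object@cell)
    cat(sprintf("  RMS sigma = %.6g, range [%.4g, %.4g]\n",
                object@rms, min(object@grid), max(object@grid)))
})

#' Read a CCP4/MRC density map
#'
#' Parses an MRC2014 / CCP4 volume and canonicalizes the axis order so
#' that array indices 1, 2, 3 run along cell axes a, b, c regardless of
#' the file's MAPC/MAPR/MAPS permutation. Little- and big-endian files
#' are both handled. Only mode 2 (32-bit float) data are supported,
#' which is what crystallographic difference maps use.
#'
#' A map whose extent does not cover exactly one full cell period per
#' axis is flagged \code{fullCell = FALSE}; downstream sigma and
#' amplitude operations refuse such maps rather than silently wrapping
#' (expand with e.g. CCP4 mapmask first).
#'
#' @param path file path to the map.
#' @return A \linkS4class{DensityMap} with recomputed RMS.
#' @export
readDensityMap <- function(path) {
    if (!file.exists(path)) stop("map file not found: ", path)
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- readBin(con, "raw", n = 1024L)
    if (length(hdr) < 1024L) stop("unreadable CCP4/MRC header (truncated): ", path)
    magic <- rawToChar(hdr[209:212])
    endian <- "little"
    int1 <- function(off, e) readBin(hdr[off + 1:4], "integer", size = 4, endian = e)
    if (!(substr(magic, 1, 3) == "MAP")) {
        # old-style file without magic: guess endianness from MODE word
        if (!(int1(12, "little") %in% 0:6) && int1(12, "big") %in% 0:6)
            endian <- "big"
    } else {
        # machine stamp: 0x44 little, 0x11 big
        if (as.integer(hdr[213]) == 0x11) endian <- "big"
    }
    ints <- readBin(hdr, "integer", n = 256, size = 4, endian = endian)
    flts <- readBin(hdr, "numeric", n = 256, size = 4, endian = endian)
    nc <- ints[1]; nr <- ints[2]; ns <- ints[3]; mode <- ints[4]
    starts <- ints[5:7]
    mxyz <- ints[8:10]
    cellpar <- flts[11:16]
    mapcrs <- ints[17:19]
    ispg <- ints[23]
    nsymbt <- ints[24]
    if (any(c(nc, nr, ns) <= 0) || any(!is.finite(cellpar)) ||
        any(cellpar[1:3] <= 0))
        stop("unreadable CCP4/MRC header: ", path)
    if (mode != 2L)
        stop("unsupported MRC mode ", mode, " (only mode 2, float32)")
    if (!all(sort(mapcrs) == 1:3))
        stop("non-orthogonal axis codes in MAPC/MAPR/MAPS: ",
             paste(mapcrs, collapse = ","))
    if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
    nvox <- as.double(nc) * nr * ns
    vals <- readBin(con, "numeric", n = nvox, size = 4, endian = endian)
    if (length(vals) != nvox) stop("truncated map data: ", path)
    arr <- array(vals, dim = c(nc, nr, ns))
    # canonicalize: new dim k = file dim holding cell axis k
    perm <- match(1:3, mapcrs)
    arr <- aperm(arr, perm)
    origin <- starts[perm]
    cell <- unitCell(cellpar[1], cellpar[2], cellpar[3],
                     cellpar[4], cellpar[5], cellpar[6])
    densityMap(arr, cell, origin = origin, sampling = mxyz,
               spacegroup = max(ispg, 1L))
}

#' Write a density map as CCP4/MRC (mode 2, canonical axis order)
#'
#' @param map a \linkS4class{DensityMap}.
#' @param path output file path.
#' @return \code{path}, invisibly. Values are stored as 32-bit floats
#'   (the format's precision); header cell, space-group number and
#'   sampling are preserved.
#' @export
writeDensityMap <- function(map, path) {
    stopifnot(is(map, "DensityMap"))
    d <- dim(map@grid)
    ints <- integer(256)
    flts <- numeric(256)
    ints[1:3] <- d
    ints[4] <- 2L
    ints[5:7] <- map@origin
    ints[8:10] <- map@sampling
    flts[11:16] <- c(map@cell@abc, map@cell@angles)
    ints[17:19] <- 1:3
    flts[20] <- min(map@grid); flts[21] <- max(map@grid)
    flts[22] <- mean(map@grid)
    ints[23] <- map@spacegroup
    ints[24] <- 0L
    flts[55] <- map@rms
    ints[56] <- 0L
    con <- file(path, "wb")
    on.exit(close(con))
    wi <- function(i) writeBin(as.integer(i), con, size = 4, endian = "little")
    wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
    wi(ints[1:10]); wf(flts[11:16]); wi(ints[17:19]); wf(flts[20:22])
    wi(ints[23:24]); wi(integer(25))                      # words 25-49 unused
    wf(numeric(3))                                        # ORIGIN x,y,z
    writeBin(charToRaw("MAP "), con)                      # word 53 magic
    writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)      # little-endian stamp
    wf(flts[55]); wi(ints[56])
    writeBin(raw(800), con)                               # labels
    wf(map@grid)
    invisible(path)
}

#' Trilinear interpolation with periodic unit-cell wrapping
#'
#' Interpolates a full-cell map at arbitrary Cartesian points. Points
#' are converted to fractional coordinates and wrapped, so every
#' Cartesian point is valid and the result is invariant under
#' translation by whole cell vectors. Values at grid nodes are
#' reproduced exactly (no smoothing).
#'
#' @param map a full-cell \linkS4class{DensityMap}.
#' @param points n x 3 matrix (or length-3 vector) of Cartesian
#'   Angstrom coordinates.
#' @return numeric vector of n interpolated densities.
#' @export
interpolateMap <- function(map, points) {
    stopifnot(is(map, "DensityMap"))
    if (!map@fullCell)
        stop("interpolation requires a full-cell map (periodic wrapping)")
    pts <- rbind3(points)
    n <- dim(map@grid)
    fr <- solve(map@cell@orth) %*% t(pts)      # 3 x npts fractional
    g <- map@grid
    u1 <- fr[1, ] * n[1] - map@origin[1]
    u2 <- fr[2, ] * n[2] - map@origin[2]
    u3 <- fr[3, ] * n[3] - map@origin[3]
    i1 <- floor(u1); i2 <- floor(u2); i3 <- floor(u3)
    f1 <- u1 - i1; f2 <- u2 - i2; f3 <- u3 - i3
    a1 <- as.integer(i1 %% n[1]); b1 <- as.integer((i1 + 1) %% n[1])
    a2 <- as.integer(i2 %% n[2]); b2 <- as.integer((i2 + 1) %% n[2])
    a3 <- as.integer(i3 %% n[3]); b3 <- as.integer((i3 + 1) %% n[3])
    lin <- function(x, y, z) g[1L + x + n[1] * (y + n[2] * z)]
    v000 <- lin(a1, a2, a3); v100 <- lin(b1, a2, a3)
    v010 <- lin(a1, b2, a3); v110 <- lin(b1, b2, a3)
    v001 <- lin(a1, a2, b3); v101 <- lin(b1, a2, b3)
    v011 <- lin(a1, b2, b3); v111 <- lin(b1, b2, b3)
    ((v000 * (1 - f1) + v100 * f1) * (1 - f2) +
     (v010 * (1 - f1) + v110 * f1) * f2) * (1 - f3) +
    ((v001 * (1 - f1) + v101 * f1) * (1 - f2) +
     (v011 * (1 - f1) + v111 * f1) * f2) * f3
}

#' Resample a map onto an orthogonal Cartesian grid
#'
#' Fidelity mode reproducing the classical two-step workflow (full-cell
#' expansion, then regridding to a fine Cartesian mesh before sphere
#' extraction). The default analysis path interpolates spheres straight
#' off the native grid; resampling first only adds interpolation
#' smoothing.
#'
#' The output is a full-cell P1 map on an orthogonal box enclosing one
#' cell; for non-orthogonal input cells the box is the orthogonal hull
#' and values are periodic-wrapped, which preserves amplitudes near any
#' atom inside the cell.
#'
#' @param map a full-cell \linkS4class{DensityMap}.
#' @param spacing target grid spacing in Angstrom (e.g. 0.25).
#' @return A \linkS4class{DensityMap} on an orthogonal grid.
#' @export
resampleCartesian <- function(map, spacing) {
    stopifnot(is(map, "DensityMap"), spacing > 0)
    if (spacing > min(map@cell@abc) / 2)
        stop("spacing must not exceed half the shortest cell axis")
    box <- apply(abs(map@cell@orth), 1, sum)  # orthogonal hull of the cell
    nd <- pmax(2L, as.integer(ceiling(box / spacing)))
    newcell <- unitCell(box[1], box[2], box[3])
    ax1 <- (seq_len(nd[1]) - 1) / nd[1] * box[1]
    ax2 <- (seq_len(nd[2]) - 1) / nd[2] * box[2]
    ax3 <- (seq_len(nd[3]) - 1) / nd[3] * box[3]
    pts <- as.matrix(expand.grid(x = ax1, y = ax2, z = ax3))
    vals <- interpolateMap(map, pts)
    densityMap(array(vals, dim = nd), newcell, spacegroup = 1L)
}
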