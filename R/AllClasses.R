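#' @import methods
NULL

#' Crystallographic unit cell
#'
#' Holds cell lengths (\eqn{\text{\AA}}), angles (degrees) and the
#' fractional-to-Cartesian orthogonalization matrix (PDB convention:
#' a along x, b in the xy plane).
#'
#' @slot abc numeric(3), cell edge lengths in Angstrom.
#' @slot angles numeric(3), cell angles alpha, beta, gamma in degrees.
#' @slot orth 3x3 matrix mapping fractional coordinates to Cartesian
#'   Angstrom; its determinant equals the cell volume.
#' @export
setClass("UnitCell",
    representation(abc = "numeric", angles = "numeric", orth = "matrix"),
    validity = function(object) {
        msg <- NULL
        if (length(object@abc) != 3L || any(!is.finite(object@abc)) ||
            any(object@abc <= 0))
            msg <- c(msg, "cell lengths must be three finite positive numbers")
        if (length(object@angles) != 3L || any(!is.finite(object@angles)) ||
            any(object@angles <= 0) || any(object@angles >= 180))
            msg <- c(msg, "cell angles must lie in (0, 180) degrees")
        if (!all(dim(object@orth) == c(3L, 3L)))
            msg <- c(msg, "orthogonalization matrix must be 3x3")
        else if (det(object@orth) <= 0)
            msg <- c(msg, "orthogonalization matrix must have positive determinant")
        if (is.null(msg)) TRUE else msg
    })

#' Density map on a periodic unit-cell grid
#'
#' A 3D grid of (difference) electron density in canonical axis order:
#' array indices 1, 2, 3 run along cell axes a, b, c regardless of the
#' axis permutation of any file the map was read from. \code{sampling}
#' gives the number of grid divisions per full cell edge; a map is
#' "full cell" when its grid covers exactly one period per axis with no
#' duplicated boundary plane (\code{dim(grid) == sampling}).
#'
#' @slot grid 3D numeric array of density values.
#' @slot cell a \linkS4class{UnitCell}.
#' @slot origin integer(3), grid index (0-based) of the first stored
#'   voxel along each cell axis.
#' @slot sampling integer(3), grid divisions per full cell edge.
#' @slot spacegroup integer space-group number from the file header
#'   (1 = P1; only P1 periodic semantics are implemented).
#' @slot fullCell logical, whether the grid covers the whole cell.
#' @slot rms cached root-mean-square density of the stored grid
#'   (no mean subtraction).
#' @export
setClass("DensityMap",
    representation(grid = "array", cell = "UnitCell", origin = "integer",
                   sampling = "integer", spacegroup = "integer",
                   fullCell = "logical", rms = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(dim(object@grid)) != 3L)
            msg <- c(msg, "grid must be a 3D array")
        if (any(!is.finite(object@grid)))
            msg <- c(msg, "grid values must all be finite")
        if (length(object@sampling) != 3L || any(object@sampling < 1L))
            msg <- c(msg, "sampling must be three positive integers")
        if (length(object@origin) != 3L)
            msg <- c(msg, "origin must have length 3")
        if (length(dim(object@grid)) == 3L &&
            isTRUE(object@fullCell) &&
            !all(dim(object@grid) == object@sampling))
            msg <- c(msg, "full-cell map must have dim(grid) == sampling")
        if (length(object@rms) != 1L || !is.finite(object@rms) || object@rms < 0)
            msg <- c(msg, "rms must be a single nonnegative number")
        if (is.null(msg)) TRUE else msg
    })

#' Atomic model parsed from a PDB file
#'
#' Atoms are kept in file order; that order is the canonical x axis of
#' every amplitude profile derived from the model.
#'
#' @slot atoms data.frame with one row per atom: serial, name, element,
#'   altloc, resname, chain, resno, occupancy, b, x, y, z, hetero,
#'   dummy (logical flag for dummy scaling waters).
#' @slot cell a \linkS4class{UnitCell}, or a zero-size placeholder when
#'   the file had no CRYST1 record (see \code{hasCell}).
#' @slot hasCell logical, whether a CRYST1 record was present.
#' @slot spacegroup Hermann-Mauguin symbol from CRYST1 (e.g. "P 1").
#' @export
setClass("StructureModel",
    representation(atoms = "data.frame", cell = "UnitCell",
                   hasCell = "logical", spacegroup = "character"),
    validity = function(object) {
        msg <- NULL
        need <- c("serial", "name", "element", "altloc", "resname", "chain",
                  "resno", "occupancy", "b", "x", "y", "z", "hetero", "dummy")
        if (!all(need %in% names(object@atoms)))
            msg <- c(msg, paste("atoms must have columns:",
                                paste(need, collapse = ", ")))
        else {
            if (anyDuplicated(object@atoms$serial))
                msg <- c(msg, "atom serials must be unique")
            occ <- object@atoms$occupancy
            if (any(occ < 0 | occ > 1))
                msg <- c(msg, "occupancies must lie in [0, 1]")
            if (any(object@atoms$b < 0))
                msg <- c(msg, "B-factors must be nonnegative")
        }
        if (is.null(msg)) TRUE else msg
    })

#' Parameters of the sphere-amplitude extraction
#'
#' @slot radius sphere radius in Angstrom (default 2.0, roughly the map
#'   resolution).
#' @slot mesh sampling spacing inside the sphere in Angstrom
#'   (default 0.5).
#' @slot nSigma floor multiplier: samples with |density| < nSigma * map
#'   sigma are zeroed before averaging (default 3).
#' @slot floorAbs absolute floor in map units; \code{NA} means resolve
#'   as nSigma * RMS(map) at call time.
#' @slot faithful logical; when TRUE, amplitude extraction first
#'   resamples the map onto a 0.25 Angstrom Cartesian grid and
#'   interpolates the sphere mesh from that, reproducing the two-step
#'   CCP4 workflow; default interpolates straight off the native grid.
#' @export
setClass("ExtractionParams",
    representation(radius = "numeric", mesh = "numeric", nSigma = "numeric",
                   floorAbs = "numeric", faithful = "logical"),
    validity = function(object) {
        msg <- NULL
        if (object@radius <= 0) msg <- c(msg, "radius must be positive")
        if (object@mesh <= 0) msg <- c(msg, "mesh must be positive")
        if (object@mesh > object@radius)
            msg <- c(msg, "mesh must not exceed radius (sphere would be a single point)")
        if (object@nSigma < 0) msg <- c(msg, "nSigma must be nonnegative")
        if (is.null(msg)) TRUE else msg
    })

#' Per-atom dual-valued amplitude profile A(a_i)
#'
#' One row per atom of the reference model, in model order. \code{pos}
#' is the mean of surviving positive densities in the sphere about each
#' atom (>= 0), \code{neg} the mean of surviving negative densities
#' (<= 0, stored signed so plots mirror the dual-signed curves).
#'
#' @slot atoms data.frame describing the profiled atoms (subset of a
#'   StructureModel's atoms, original order preserved).
#' @slot pos,neg numeric vectors of positive/negative amplitudes.
#' @slot nPos,nNeg integer vectors of surviving sample counts.
#' @slot params the \linkS4class{ExtractionParams} used.
#' @slot mapSigma RMS sigma of the source map.
#' @slot delay time delay in seconds (NA if not time-resolved).
#' @slot label display label, e.g. "760 ns".
#' @export
setClass("AmplitudeProfile",
    representation(atoms = "data.frame", pos = "numeric", neg = "numeric",
                   nPos = "integer", nNeg = "integer",
                   params = "ExtractionParams", mapSigma = "numeric",
                   delay = "numeric", label = "character"),
    validity = function(object) {
        msg <- NULL
        n <- nrow(object@atoms)
        if (length(object@pos) != n || length(object@neg) != n ||
            length(object@nPos) != n || length(object@nNeg) != n)
            msg <- c(msg, "pos/neg/nPos/nNeg must have one entry per atom")
        if (any(object@pos < 0)) msg <- c(msg, "pos amplitudes must be >= 0")
        if (any(object@neg > 0)) msg <- c(msg, "neg amplitudes must be <= 0")
        if (any(object@pos[object@nPos == 0L] != 0))
            msg <- c(msg, "pos must be 0 where nPos is 0")
        if (any(object@neg[object@nNeg == 0L] != 0))
            msg <- c(msg, "neg must be 0 where nNeg is 0")
        if (is.null(msg)) TRUE else msg
    })

#' Pearson correlation matrix between amplitude profiles
#'
#' Square for a single time series (symmetric, unit diagonal) or
#' rectangular for experimental-vs-theoretical comparisons (no
#' auto-correlation, hence no unit diagonal).
#'
#' @slot values matrix of Pearson coefficients in [-1, 1].
#' @slot rowLabels,colLabels time-point labels.
#' @slot rowDelays,colDelays time delays in seconds.
#' @slot square logical.
#' @export
setClass("CorrelationMatrix",
    representation(values = "matrix", rowLabels = "character",
                   colLabels = "character", rowDelays = "numeric",
                   colDelays = "numeric", square = "logical"),
    validity = function(object) {
        msg <- NULL
        v <- object@values
        if (any(v < -1 - 1e-12 | v > 1 + 1e-12))
            msg <- c(msg, "correlations must lie in [-1, 1]")
        if (nrow(v) != length(object@rowLabels) ||
            ncol(v) != length(object@colLabels))
            msg <- c(msg, "label lengths must match matrix dimensions")
        if (isTRUE(object@square)) {
            if (nrow(v) != ncol(v) || max(abs(v - t(v))) > 1e-12)
                msg <- c(msg, "square correlation matrix must be symmetric")
            else if (max(abs(diag(v) - 1)) > 1e-12)
                msg <- c(msg, "square correlation matrix must have unit diagonal")
        }
        if (is.null(msg)) TRUE else msg
    })

#' Contiguous block partition of a correlation matrix
#'
#' @slot blocks list of integer vectors, each a contiguous run of
#'   time-point indices, ordered and non-overlapping.
#' @slot threshold minimum mean off-diagonal pairwise correlation.
#' @slot excluded indices removed before segmentation (noisy points).
#' @export
setClass("BlockPartition",
    representation(blocks = "list", threshold = "numeric",
                   excluded = "integer"),
    validity = function(object) {
        msg <- NULL
        idx <- unlist(object@blocks)
        if (anyDuplicated(idx)) msg <- c(msg, "blocks must not overlap")
        for (b in object@blocks)
            if (length(b) && !identical(as.integer(b), seq(min(b), max(b))))
                msg <- c(msg, "each block must be a contiguous index run")
        if (is.null(msg)) TRUE else msg
    })

#' Linear decomposition of a profile series
#'
#' Factorization M ~ W P of the 2N x T concatenated amplitude matrix
#' (rows: positive then negative channel per atom; columns: time
#' points) with nonnegative populations P and unit-norm components W.
#'
#' @slot k number of components.
#' @slot components 2N x k matrix, unit Euclidean norm columns.
#' @slot populations k x T nonnegative matrix of state populations.
#' @slot residual relative Frobenius reconstruction error.
#' @slot seed RNG seed used for the restarts.
#' @slot converged logical.
#' @export
setClass("DecompositionResult",
    representation(k = "integer", components = "matrix",
                   populations = "matrix", residual = "numeric",
                   seed = "integer", converged = "logical"),
    validity = function(object) {
        msg <- NULL
        if (any(object@populations < 0))
            msg <- c(msg, "populations must be nonnegative")
        if (object@residual < 0) msg <- c(msg, "residual must be >= 0")
        nrm <- sqrt(colSums(object@components^2))
        if (any(abs(nrm[nrm > 0] - 1) > 1e-8))
            msg <- c(msg, "nonzero components must have unit norm")
        if (is.null(msg)) TRUE else msg
    })

#' Set of complex structure factors
#'
#' @slot hkl integer matrix (n x 3) of Miller indices.
#' @slot f complex vector of structure factors F(hkl).
#' @slot dmin resolution limit in Angstrom.
#' @slot cell the \linkS4class{UnitCell}.
#' @export
setClass("ReflectionSet",
    representation(hkl = "matrix", f = "complex", dmin = "numeric",
                   cell = "UnitCell"),
    validity = function(object) {
        msg <- NULL
        if (ncol(object@hkl) != 3L)
            msg <- c(msg, "hkl must have three columns")
        if (nrow(object@hkl) != length(object@f))
            msg <- c(msg, "one structure factor per reflection required")
        if (object@dmin <= 0) msg <- c(msg, "dmin must be positive")
        if (is.null(msg)) TRUE else msg
    })

#' Dummy-water scaling report for a theoretical map series
#'
#' @slot labels map labels.
#' @slot dummyMean per-map mean dummy-site sphere amplitude before
#'   scaling.
#' @slot scale per-map multiplicative factor applied.
#' @slot reference label of the reference map (scale 1 by convention of
#'   matching its dummy amplitude).
#' @export
setClass("ScalingReport",
    representation(labels = "character", dummyMean = "numeric",
                   scale = "numeric", reference = "character"))
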