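#' Construct a unit cell
#'
#' @param a,b,c cell edge lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees (default 90: an
#'   orthorhombic cell).
#' @return A \linkS4class{UnitCell}.
#' @examples
#' uc <- unitCell(40, 40, 40)
#' cellVolume(uc)
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
    abc <- as.numeric(c(a, b, c))
    ang <- as.numeric(c(alpha, beta, gamma))
    new("UnitCell", abc = abc, angles = ang, orth = orthMatrix(abc, ang))
}

# Fractional -> Cartesian matrix, PDB convention (a along x, b in xy).
orthMatrix <- function(abc, angles) {
    ca <- cospi(angles[1] / 180); cb <- cospi(angles[2] / 180)
    cg <- cospi(angles[3] / 180); sg <- sinpi(angles[3] / 180)
    v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
    matrix(c(abc[1], abc[2] * cg, abc[3] * cb,
             0,      abc[2] * sg, abc[3] * (ca - cb * cg) / sg,
             0,      0,           abc[3] * v / sg),
           nrow = 3, byrow = TRUE)
}

#' @describeIn unitCell Cell volume in cubic Angstrom (determinant of
#'   the orthogonalization matrix).
#' @param cell a \linkS4class{UnitCell}.
#' @export
cellVolume <- function(cell) det(cell@orth)

#' Convert between fractional and Cartesian coordinates
#'
#' @param cell a \linkS4class{UnitCell}.
#' @param xyz numeric n x 3 matrix (or length-3 vector) of coordinates.
#' @return n x 3 matrix of converted coordinates.
#' @export
fracToCart <- function(cell, xyz) {
    xyz <- rbind3(xyz)
    t(cell@orth %*% t(xyz))
}

#' @rdname fracToCart
#' @export
cartToFrac <- function(cell, xyz) {
    xyz <- rbind3(xyz)
    t(solve(cell@orth) %*% t(xyz))
}

# coerce a length-3 vector to a 1 x 3 matrix, pass matrices through
rbind3 <- function(xyz) {
    if (is.null(dim(xyz))) {
        stopifnot(length(xyz) == 3L)
        matrix(xyz, nrow = 1)
    } else {
        stopifnot(ncol(xyz) == 3L)
        as.matrix(xyz)
    }
}

setMethod("show", "UnitCell", function(object) {
    cat(sprintf("UnitCell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
                object@abc[1], object@abc[2], object@abc[3],
                object@angles[1], object@angles[2], object@angles[3],
                cellVolume(object)))
})
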