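#' Read a PDB coordinate file
#'
#' All ATOM/HETATM records are parsed (via bio3d) with alternate
#' location indicators, occupancies and B-factors retained, in file
#' order; that order is the canonical atom axis of amplitude profiles.
#' The CRYST1 record supplies the unit cell and Hermann-Mauguin
#' space-group symbol.
#'
#' @param path path to a PDB file.
#' @return A \linkS4class{StructureModel}.
#' @export
readStructure <- function(path) {
    if (!file.exists(path)) stop("PDB file not found: ", path)
    pdb <- tryCatch(
        bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE, verbose = FALSE),
        error = function(e) stop("failed to parse PDB file ", path, ": ",
                                 conditionMessage(e)))
    at <- pdb$atom
    blank <- function(x, fill = "") ifelse(is.na(x), fill, x)
    elem <- blank(at$elesy)
    # fall back to the first letter of the atom name when the element
    # column is absent (common in hand-made files)
    noel <- elem == ""
    if (any(noel))
        elem[noel] <- sub("^[0-9]*([A-Za-z]).*", "\\1", at$elety[noel])
    atoms <- data.frame(
        serial = as.integer(at$eleno),
        name = blank(at$elety),
        element = toupper(elem),
        altloc = blank(at$alt),
        resname = blank(at$resid),
        chain = blank(at$chain),
        resno = as.integer(at$resno),
        occupancy = ifelse(is.na(at$o), 1, at$o),
        b = ifelse(is.na(at$b), 0, at$b),
        x = at$x, y = at$y, z = at$z,
        hetero = at$type == "HETATM",
        dummy = FALSE,
        stringsAsFactors = FALSE)
    cr <- readCryst1(path)
    if (is.null(cr))
        new("StructureModel", atoms = atoms, cell = unitCell(1, 1, 1),
            hasCell = FALSE, spacegroup = "")
    else
        new("StructureModel", atoms = atoms,
            cell = unitCell(cr$abc[1], cr$abc[2], cr$abc[3],
                            cr$angles[1], cr$angles[2], cr$angles[3]),
            hasCell = TRUE, spacegroup = cr$spacegroup)
}

# parse the CRYST1 record (fixed columns per the PDB format)
readCryst1 <- function(path) {
    lines <- readLines(path, warn = FALSE)
    cl <- grep("^CRYST1", lines, value = TRUE)
    if (!length(cl)) return(NULL)
    l <- cl[1]
    num <- function(a, b) suppressWarnings(as.numeric(substr(l, a, b)))
    abc <- c(num(7, 15), num(16, 24), num(25, 33))
    ang <- c(num(34, 40), num(41, 47), num(48, 54))
    if (any(is.na(abc)) || any(is.na(ang)))
        stop("malformed CRYST1 record in ", path)
    list(abc = abc, angles = ang,
         spacegroup = trimws(substr(l, 56, 66)))
}

#' Write a model as a PDB file
#'
#' @param model a \linkS4class{StructureModel}.
#' @param path output path.
#' @return \code{path}, invisibly. CRYST1 is written when the model has
#'   a cell; coordinates at the format's 1e-3 Angstrom precision.
#' @export
writeStructure <- function(model, path) {
    stopifnot(is(model, "StructureModel"))
    at <- model@atoms
    bio3d::write.pdb(
        file = path,
        xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
        type = ifelse(at$hetero, "HETATM", "ATOM"),
        eleno = at$serial, elety = at$name, alt = ifelse(at$altloc == "", "", at$altloc),
        resid = at$resname, chain = ifelse(at$chain == "", " ", at$chain),
        resno = at$resno, o = at$occupancy, b = at$b, elesy = at$element)
    if (model@hasCell) {
        cr <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                      model@cell@abc[1], model@cell@abc[2], model@cell@abc[3],
                      model@cell@angles[1], model@cell@angles[2],
                      model@cell@angles[3],
                      if (nzchar(model@spacegroup)) model@spacegroup else "P 1",
                      1L)
        body <- readLines(path, warn = FALSE)
        writeLines(c(cr, body), path)
    }
    invisible(path)
}

#' Extract one alternate conformer at full occupancy
#'
#' Rewrites a dual-conformer model to a single-conformer, full
#' occupancy model: atoms carrying the requested altloc are kept with
#' occupancy 1 and the altloc cleared; atoms with no altloc (shared
#' between conformers) are kept with occupancy forced to 1; atoms of
#' any other altloc are dropped. Idempotent.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param altloc single character, e.g. "B" for a deposited
#'   photo-activated conformation.
#' @return A full-occupancy \linkS4class{StructureModel}.
#' @export
extractConformer <- function(model, altloc) {
    stopifnot(is(model, "StructureModel"),
              is.character(altloc), nchar(altloc) == 1L)
    at <- model@atoms
    if (!any(at$altloc == altloc) && any(at$altloc != ""))
        warning("altloc '", altloc,
                "' not present; returning shared atoms only")
    else if (!any(at$altloc == altloc) && all(at$altloc == ""))
        message("model has no alternate conformers; occupancies set to 1")
    keep <- at$altloc == "" | at$altloc == altloc
    at <- at[keep, , drop = FALSE]
    at$altloc <- ""
    at$occupancy <- 1
    rownames(at) <- NULL
    initialize(model, atoms = at)
}

#' Select atoms from a model
#'
#' Deterministic ordered selection preserving file order. The default
#' universe for amplitude profiles is every non-hydrogen ATOM and
#' HETATM record (cofactors, lipids and structured waters included);
#' hydrogens are excluded because deposited models lack them.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param chain optional chain identifier(s).
#' @param resno optional residue numbers (vector, e.g. \code{212:217}).
#' @param resname,name optional residue / atom name filters.
#' @param includeHetero keep HETATM records (default TRUE).
#' @param includeWaters keep water residues (HOH/WAT, default TRUE).
#' @param includeHydrogens keep hydrogens (default FALSE).
#' @param altloc keep only blank-altloc atoms plus this conformer
#'   (default "A": the resting-state conformer when profiling a
#'   dual-conformer deposition; use NULL to keep all altlocs).
#' @return data.frame of selected atoms (subsequence of
#'   \code{model@atoms}).
#' @export
selectAtoms <- function(model, chain = NULL, resno = NULL, resname = NULL,
                        name = NULL, includeHetero = TRUE,
                        includeWaters = TRUE, includeHydrogens = FALSE,
                        altloc = "A") {
    stopifnot(is(model, "StructureModel"))
    at <- model@atoms
    keep <- rep(TRUE, nrow(at))
    if (!is.null(chain)) keep <- keep & at$chain %in% chain
    if (!is.null(resno)) keep <- keep & at$resno %in% resno
    if (!is.null(resname)) keep <- keep & at$resname %in% resname
    if (!is.null(name)) keep <- keep & at$name %in% name
    if (!includeHetero) keep <- keep & !at$hetero
    if (!includeWaters) keep <- keep & !(at$resname %in% c("HOH", "WAT", "DOD"))
    if (!includeHydrogens) keep <- keep & !(at$element %in% c("H", "D"))
    if (!is.null(altloc)) keep <- keep & (at$altloc == "" | at$altloc %in% altloc)
    out <- at[keep, , drop = FALSE]
    if (nrow(out) == 0L) stop("atom selection matched nothing")
    rownames(out) <- NULL
    out
}

#' Add dummy scaling waters to a model
#'
#' Appends HETATM water oxygens at the given positions, flagged as
#' dummies, for relative scaling of theoretical difference maps. The
#' dummies must sit outside the protein: any position within
#' \code{minClearance} of an existing non-dummy atom is an error.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param positions n x 3 matrix (or length-3 vector) of Cartesian
#'   Angstrom positions.
#' @param bFactor B-factor assigned to the dummies (default 30).
#' @param minClearance minimum distance to any existing atom
#'   (default 3.5 Angstrom).
#' @return The model with dummies appended (retrievable via the
#'   \code{dummy} flag of the atom table).
#' @export
addDummyWaters <- function(model, positions, bFactor = 30,
                           minClearance = 3.5) {
    stopifnot(is(model, "StructureModel"))
    pos <- rbind3(positions)
    if (nrow(pos) == 0L) stop("positions must be nonempty")
    at <- model@atoms
    xyz <- as.matrix(at[!at$dummy, c("x", "y", "z")])
    for (i in seq_len(nrow(pos))) {
        d2 <- colSums((t(xyz) - pos[i, ])^2)
        if (any(d2 < minClearance^2))
            stop(sprintf(
                "dummy water %d is %.2f A from an existing atom (< %.1f A): must lie outside the protein",
                i, sqrt(min(d2)), minClearance))
    }
    serial0 <- max(at$serial)
    resno0 <- max(at$resno)
    dummies <- data.frame(
        serial = serial0 + seq_len(nrow(pos)),
        name = "O", element = "O", altloc = "",
        resname = "HOH", chain = "Z",
        resno = resno0 + seq_len(nrow(pos)),
        occupancy = 1, b = bFactor,
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        hetero = TRUE, dummy = TRUE,
        stringsAsFactors = FALSE)
    out <- rbind(at, dummies)
    rownames(out) <- NULL
    initialize(model, atoms = out)
}

#' @describeIn readStructure Number of atoms in a model.
#' @param model a \linkS4class{StructureModel}.
#' @export
nAtoms <- function(model) nrow(model@atoms)

#' @describeIn readStructure Atom table of a model.
#' @export
modelAtoms <- function(model) model@atoms

#' @describeIn readStructure Cartesian coordinates (n x 3 matrix).
#' @export
atomCoords <- function(model) as.matrix(model@atoms[, c("x", "y", "z")])

setMethod("show", "StructureModel", function(object) {
    at <- object@atoms
    cat(sprintf("StructureModel: %d atoms (%d HETATM, %d dummy), %d with altloc\n",
                nrow(at), sum(at$hetero), sum(at$dummy),
                sum(at$altloc != "")))
    if (object@hasCell) {
        show(object@cell)
        cat("  spacegroup: ", object@spacegroup, "\n", sep = "")
    } else cat("  no CRYST1 cell\n")
})
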