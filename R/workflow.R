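## End-to-end workflows tying maps + model to profile stacks, sweeps
## and experiment-vs-model comparisons. The thin command-line wrapper
## in inst/scripts/densamp.R calls these.

#' Extract an amplitude profile series
#'
#' One profile per map over a common atom axis; optionally writes one
#' CSV (+ JSON parameter sidecar) per time point and a stacked
#' long-format CSV.
#'
#' @param maps list of \linkS4class{DensityMap}s, or character vector
#'   of CCP4/MRC paths.
#' @param model a \linkS4class{StructureModel} or PDB path.
#' @param params an \linkS4class{ExtractionParams} (defaults: radius
#'   2.0 Angstrom, mesh 0.5 Angstrom, 3 sigma floor).
#' @param delays numeric vector of time delays in seconds (optional).
#' @param labels display labels (default from \code{delays}).
#' @param outDir output directory; NULL (default) writes nothing.
#' @param ... passed to \code{\link{selectAtoms}}.
#' @return list with \code{profiles} (list of
#'   \linkS4class{AmplitudeProfile}), \code{atoms}, \code{sigma}
#'   (per-map RMS), and \code{files} (written paths, if any).
#' @export
runProfileSeries <- function(maps, model, params = extractionParams(),
                             delays = NULL, labels = NULL,
                             outDir = NULL, ...) {
    if (is.character(maps)) {
        missing <- maps[!file.exists(maps)]
        if (length(missing))
            stop("map file(s) not found: ", paste(missing, collapse = ", "))
        maps <- lapply(maps, readDensityMap)
    }
    if (!length(maps)) stop("empty map list")
    if (is.character(model)) model <- readStructure(model)
    atoms <- selectAtoms(model, ...)
    if (is.null(delays)) delays <- rep(NA_real_, length(maps))
    if (is.null(labels))
        labels <- ifelse(is.na(delays), paste0("map", seq_along(maps)),
                         formatDelay(delays))
    if (!is.na(delays[1]) && is.unsorted(delays, strictly = TRUE))
        stop("time delays must be strictly increasing")
    profiles <- lapply(seq_along(maps), function(j)
        amplitudeProfile(maps[[j]], atoms, params,
                         delay = delays[j], label = labels[j]))
    files <- character(0)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        for (j in seq_along(profiles)) {
            f <- file.path(outDir, sprintf("profile_%02d.csv", j))
            writeProfile(profiles[[j]], f)
            files <- c(files, f)
        }
        stack <- do.call(rbind, lapply(seq_along(profiles), function(j)
            cbind(time_index = j, label = labels[j], delay = delays[j],
                  profileTable(profiles[[j]]))))
        f <- file.path(outDir, "profiles_stack.csv")
        utils::write.csv(stack, f, row.names = FALSE)
        files <- c(files, f)
    }
    list(profiles = profiles, atoms = atoms,
         sigma = vapply(maps, mapRms, numeric(1)), files = files)
}

#' Radius / floor parameter sweep
#'
#' Profiles one or more maps over a grid of sphere radii and sigma
#' floors, summarizing how the baseline level of A(a_i) responds:
#' lowering the floor raises the baseline, while overly large radii
#' lose contrast as neighbouring spheres overlap.
#'
#' @param maps list of \linkS4class{DensityMap}s (or paths).
#' @param model \linkS4class{StructureModel} or path.
#' @param radii numeric vector of sphere radii (Angstrom).
#' @param nSigmas numeric vector of floor multipliers.
#' @param mesh mesh spacing (default 0.5).
#' @param ... passed to \code{\link{selectAtoms}}.
#' @return list with \code{profiles} (nested list indexed
#'   [[radius]][[floor]] by name) and \code{summary} data.frame
#'   (radius, n_sigma, per-map mean/median absolute amplitude and
#'   nonzero-atom count).
#' @export
runParameterSweep <- function(maps, model, radii = c(1.5, 2, 3),
                              nSigmas = c(0, 2, 3), mesh = 0.5, ...) {
    stopifnot(length(radii) >= 1, length(nSigmas) >= 1)
    if (is.character(maps)) maps <- lapply(maps, readDensityMap)
    if (is.character(model)) model <- readStructure(model)
    atoms <- selectAtoms(model, ...)
    profiles <- list()
    summary <- NULL
    for (r in radii) {
        rkey <- sprintf("r%.2f", r)
        profiles[[rkey]] <- list()
        for (ns in nSigmas) {
            skey <- sprintf("s%.1f", ns)
            pars <- extractionParams(radius = r, mesh = mesh, nSigma = ns)
            ps <- lapply(maps, amplitudeProfile, atoms = atoms,
                         params = pars)
            profiles[[rkey]][[skey]] <- ps
            absAmp <- unlist(lapply(ps, function(p) (p@pos - p@neg) / 2))
            nz <- mean(vapply(ps, function(p)
                sum(p@nPos + p@nNeg > 0L), numeric(1)))
            summary <- rbind(summary, data.frame(
                radius = r, n_sigma = ns,
                mean_abs_amplitude = mean(absAmp),
                median_abs_amplitude = stats::median(absAmp),
                mean_nonzero_atoms = nz))
        }
    }
    list(profiles = profiles, summary = summary)
}

#' Compare experimental and theoretical profile series
#'
#' Cross-correlates two profile series sharing the model's atom axis
#' and computes region time courses for both under a common
#' normalization.
#'
#' @param expProfiles,theoProfiles lists of
#'   \linkS4class{AmplitudeProfile} on one atom axis.
#' @param regions optional named region list (see
#'   \code{\link{regionAverage}}).
#' @param reference normalization reference passed to
#'   \code{regionAverage}.
#' @return list with \code{cross} (rectangular
#'   \linkS4class{CorrelationMatrix}), \code{regions} (data.frame or
#'   NULL) and \code{summary} (min/max/span of the correlations and
#'   the argmax column per row).
#' @export
runCompare <- function(expProfiles, theoProfiles, regions = NULL,
                       reference = length(expProfiles)) {
    n1 <- length(expProfiles[[1]]@pos)
    n2 <- length(theoProfiles[[1]]@pos)
    if (n1 != n2)
        stop("atom-axis mismatch: ", n1, " vs ", n2, " atoms")
    s1 <- expProfiles[[1]]@atoms$serial
    s2 <- theoProfiles[[1]]@atoms$serial
    if (!identical(s1, s2))
        stop("atom-axis mismatch: first differing atom serial ",
             s1[which(s1 != s2)[1]])
    cross <- crossCorrelationMatrix(expProfiles, theoProfiles)
    reg <- NULL
    if (!is.null(regions)) {
        reg <- rbind(cbind(series = "experimental",
                           regionAverage(expProfiles, regions, reference)),
                     cbind(series = "theoretical",
                           regionAverage(theoProfiles, regions, reference)))
    }
    v <- cross@values
    list(cross = cross, regions = reg,
         summary = list(min_correlation = min(v),
                        max_correlation = max(v),
                        span = max(v) - min(v),
                        row_argmax = apply(v, 1, which.max)))
}

#' Export a correlation matrix and block partition
#'
#' @param cmat a \linkS4class{CorrelationMatrix}.
#' @param blocks optional \linkS4class{BlockPartition}.
#' @param prefix output path prefix; writes <prefix>.csv and
#'   <prefix>.json.
#' @return written paths, invisibly.
#' @export
writeCorrelation <- function(cmat, blocks = NULL, prefix) {
    csv <- paste0(prefix, ".csv")
    utils::write.csv(corValues(cmat), csv, row.names = TRUE)
    js <- paste0(prefix, ".json")
    jsonlite::write_json(list(
        row_labels = cmat@rowLabels, col_labels = cmat@colLabels,
        square = cmat@square,
        blocks = if (!is.null(blocks))
            lapply(blocks@blocks, function(b) c(min(b), max(b))),
        threshold = if (!is.null(blocks)) blocks@threshold,
        excluded = if (!is.null(blocks)) blocks@excluded),
        js, auto_unbox = TRUE, digits = NA)
    invisible(c(csv, js))
}
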