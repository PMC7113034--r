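#' Pearson correlation between two amplitude profiles
#'
#' Computed on the concatenated dual-valued vector [pos; neg] of
#' length 2N, so both channels contribute and signs stay meaningful.
#' Single-channel modes are available for sensitivity checks.
#'
#' @param p1,p2 \linkS4class{AmplitudeProfile}s sharing one atom list
#'   and parameters.
#' @param channel "both" (default), "pos" or "neg".
#' @return Pearson coefficient in [-1, 1].
#' @export
profileCor <- function(p1, p2, channel = c("both", "pos", "neg")) {
    channel <- match.arg(channel)
    checkProfileSeries(list(p1, p2))
    v1 <- switch(channel, both = concatAmplitudes(p1), pos = p1@pos,
                 neg = p1@neg)
    v2 <- switch(channel, both = concatAmplitudes(p2), pos = p2@pos,
                 neg = p2@neg)
    if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
        stop("undefined correlation: a profile has zero variance")
    stats::cor(v1, v2)
}

#' Pairwise correlation matrix of a profile series
#'
#' Square symmetric matrix with unit diagonal; entry (j, k) is the
#' Pearson correlation between profiles j and k.
#'
#' @param profiles ordered list of \linkS4class{AmplitudeProfile}s
#'   (at least 2).
#' @param channel passed to \code{\link{profileCor}}.
#' @return A \linkS4class{CorrelationMatrix} with \code{square = TRUE}.
#' @export
correlationMatrix <- function(profiles, channel = "both") {
    checkProfileSeries(profiles)
    t <- length(profiles)
    if (t < 2L) stop("need at least two profiles")
    m <- diag(1, t)
    for (j in seq_len(t - 1)) for (k in (j + 1):t) {
        r <- tryCatch(profileCor(profiles[[j]], profiles[[k]], channel),
                      error = function(e)
                          stop("undefined correlation between profiles ",
                               j, " and ", k, ": ", conditionMessage(e)))
        m[j, k] <- r
        m[k, j] <- r
    }
    labs <- vapply(profiles, function(p) p@label, character(1))
    dels <- vapply(profiles, function(p) p@delay, numeric(1))
    new("CorrelationMatrix", values = m, rowLabels = labs,
        colLabels = labs, rowDelays = dels, colDelays = dels,
        square = TRUE)
}

#' Cross-correlation matrix between two profile series
#'
#' Rectangular matrix, entry (j, k) = correlation between
#' \code{experimental[[j]]} and \code{theoretical[[k]]}. There is no
#' auto-correlation in this calculation, so the diagonal is not unity.
#'
#' @param experimental,theoretical profile lists sharing one atom list
#'   and parameters across both series.
#' @param channel passed to \code{\link{profileCor}}.
#' @return A \linkS4class{CorrelationMatrix} with \code{square = FALSE}.
#' @export
crossCorrelationMatrix <- function(experimental, theoretical,
                                   channel = "both") {
    checkProfileSeries(c(experimental, theoretical))
    m <- matrix(NA_real_, length(experimental), length(theoretical))
    for (j in seq_along(experimental)) for (k in seq_along(theoretical))
        m[j, k] <- profileCor(experimental[[j]], theoretical[[k]], channel)
    new("CorrelationMatrix", values = m,
        rowLabels = vapply(experimental, function(p) p@label, character(1)),
        colLabels = vapply(theoretical, function(p) p@label, character(1)),
        rowDelays = vapply(experimental, function(p) p@delay, numeric(1)),
        colDelays = vapply(theoretical, function(p) p@delay, numeric(1)),
        square = FALSE)
}

#' @describeIn correlationMatrix Correlation values as a plain matrix.
#' @param x a \linkS4class{CorrelationMatrix}.
#' @export
corValues <- function(x) {
    v <- x@values
    dimnames(v) <- list(x@rowLabels, x@colLabels)
    v
}

setMethod("show", "CorrelationMatrix", function(object) {
    cat(sprintf("CorrelationMatrix: %d x %d%s, range [%.3f, %.3f]\n",
                nrow(object@values), ncol(object@values),
                if (object@square) " (square)" else " (cross)",
                min(object@values), max(object@values)))
})

# mean off-diagonal pairwise correlation over a set of indices
meanPairCor <- function(m, idx) {
    if (length(idx) < 2L) return(1)
    sub <- m[idx, idx, drop = FALSE]
    mean(sub[upper.tri(sub)])
}

#' Segment a correlation matrix into highly correlated blocks
#'
#' Greedy left-to-right maximal contiguous intervals of time points
#' whose mean off-diagonal pairwise correlation is at least
#' \code{threshold} (e.g. 0.85 for the experimental nanosecond series,
#' 0.90 for theoretical maps, 0.86 for femtosecond bins), interpreted
#' as the reign of one structural intermediate. From each start, the
#' farthest admissible end is taken; remaining points form singleton
#' blocks. Indices listed in \code{excluded} (e.g. a noisy map) are
#' ignored when computing means; with \code{absorbExcluded = TRUE}
#' (default) an excluded index interior to a block's span is absorbed
#' into that block, otherwise it becomes a singleton.
#'
#' @param cmat a square \linkS4class{CorrelationMatrix} (or plain
#'   symmetric matrix).
#' @param threshold minimum mean pairwise correlation in (0, 1].
#' @param excluded integer indices removed before segmentation.
#' @param absorbExcluded absorb interior excluded indices into the
#'   surrounding block.
#' @return A \linkS4class{BlockPartition}; blocks ordered, disjoint,
#'   covering all indices.
#' @export
findBlocks <- function(cmat, threshold = 0.85, excluded = integer(0),
                       absorbExcluded = TRUE) {
    m <- if (is(cmat, "CorrelationMatrix")) {
        if (!cmat@square) stop("block segmentation needs a square matrix")
        cmat@values
    } else as.matrix(cmat)
    stopifnot(nrow(m) == ncol(m), threshold > 0, threshold <= 1)
    t <- nrow(m)
    excluded <- sort(unique(as.integer(excluded)))
    kept <- setdiff(seq_len(t), excluded)
    blocksKept <- list()
    i <- 1L
    while (i <= length(kept)) {
        best <- i
        for (e in seq(i, length(kept)))
            if (meanPairCor(m, kept[i:e]) >= threshold) best <- e
        blocksKept[[length(blocksKept) + 1L]] <- kept[i:best]
        i <- best + 1L
    }
    blocks <- list()
    used <- integer(0)
    for (b in blocksKept) {
        memb <- if (absorbExcluded) seq(min(b), max(b)) else b
        memb <- setdiff(memb, used)
        # split at any remaining gaps so blocks stay contiguous
        for (piece in unname(split(memb, cumsum(c(1, diff(memb) != 1))))) {
            blocks[[length(blocks) + 1L]] <- as.integer(piece)
            used <- c(used, piece)
        }
    }
    for (e in setdiff(seq_len(t), used))
        blocks[[length(blocks) + 1L]] <- e
    ord <- order(vapply(blocks, min, numeric(1)))
    new("BlockPartition", blocks = blocks[ord], threshold = threshold,
        excluded = excluded)
}

setMethod("show", "BlockPartition", function(object) {
    cat(sprintf("BlockPartition: %d blocks, threshold %.2f\n",
                length(object@blocks), object@threshold))
    for (b in object@blocks)
        cat(sprintf("  [%d..%d] (%d)\n", min(b), max(b), length(b)))
})

#' Linear decomposition into nonnegative intermediate populations
#'
#' Factorizes the 2N x T concatenated amplitude matrix M ~ W P by
#' alternating least squares: P (k x T populations) is constrained
#' nonnegative (state populations), W (2N x k density patterns) is
#' unconstrained and may carry both signs. Initialization is
#' SVD-based, followed by seeded random restarts; the best-residual
#' solution is returned with components normalized to unit Euclidean
#' norm (scale carried by the populations).
#'
#' @param profiles ordered list of \linkS4class{AmplitudeProfile}s.
#' @param k number of components, 1 <= k <= number of profiles.
#' @param seed RNG seed for the restarts (reproducible).
#' @param nRestarts random restarts after the SVD start (default 10).
#' @param maxIter ALS iteration cap per start (default 500).
#' @param tol convergence threshold on the relative residual change
#'   (default 1e-8).
#' @return A \linkS4class{DecompositionResult}.
#' @export
decomposeProfiles <- function(profiles, k, seed = 1L, nRestarts = 10L,
                              maxIter = 500L, tol = 1e-8) {
    checkProfileSeries(profiles)
    t <- length(profiles)
    k <- as.integer(k)
    if (k < 1L) stop("k must be at least 1")
    if (k > t) stop("k must not exceed the number of time points (", t, ")")
    m <- vapply(profiles, concatAmplitudes,
                numeric(2L * length(profiles[[1]]@pos)))
    decomposeMatrix(m, k, seed = seed, nRestarts = nRestarts,
                    maxIter = maxIter, tol = tol)
}

#' @describeIn decomposeProfiles Decompose a plain 2N x T matrix.
#' @param m numeric matrix (rows: amplitude axis; columns: time).
#' @export
decomposeMatrix <- function(m, k, seed = 1L, nRestarts = 10L,
                            maxIter = 500L, tol = 1e-8) {
    stopifnot(is.matrix(m), k >= 1, k <= ncol(m))
    k <- as.integer(k)
    normM <- sqrt(sum(m^2))
    if (normM == 0) stop("cannot decompose an all-zero series")
    ## The factorization with free-signed W and nonnegative P is not
    ## unique: any nonnegative remixing of the population rows attains
    ## the same residual. Physical series have near-pure time points
    ## (a smoothly varying population passes close to each state), so
    ## the primary start picks the k most mutually novel time columns
    ## by successive projection; ALS then stays at that vertex of the
    ## zero-residual set. SVD and seeded random restarts guard against
    ## bad local minima but only replace the incumbent when they
    ## improve the residual by a meaningful margin.
    spa <- spaColumns(m, k)
    starts <- list(m[, spa, drop = FALSE])
    sv <- svd(m, nu = k, nv = k)
    starts[[2L]] <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
    oldseed <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    for (r in seq_len(nRestarts))
        starts[[r + 2L]] <- matrix(stats::rnorm(nrow(m) * k), ncol = k)
    if (!is.null(oldseed)) assign(".Random.seed", oldseed, globalenv())
    else if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    best <- NULL
    for (w0 in starts) {
        fit <- alsFit(m, w0, maxIter, tol, normM)
        if (is.null(best) ||
            fit$residual < best$residual - max(1e-9, 1e-6 * best$residual))
            best <- fit
    }
    if (!best$converged)
        warning(sprintf(
            "decomposition did not converge in %d iterations (residual %.3g)",
            maxIter, best$residual))
    w <- best$w; p <- best$p
    nrm <- sqrt(colSums(w^2))
    act <- nrm > 0
    w[, act] <- sweep(w[, act, drop = FALSE], 2, nrm[act], "/")
    p[act, ] <- sweep(p[act, , drop = FALSE], 1, nrm[act], "*")
    new("DecompositionResult", k = k, components = w, populations = p,
        residual = best$residual, seed = as.integer(seed),
        converged = best$converged)
}

# successive projection: indices of the k most mutually novel columns
# (near-pure time points under the separability assumption)
spaColumns <- function(m, k) {
    x <- m
    nrm <- sqrt(colSums(x^2))
    ok <- nrm > 0
    x[, ok] <- sweep(x[, ok, drop = FALSE], 2, nrm[ok], "/")
    picked <- integer(0)
    for (i in seq_len(k)) {
        res <- colSums(x^2)
        res[picked] <- -Inf
        j <- which.max(res)
        picked <- c(picked, j)
        u <- x[, j] / sqrt(sum(x[, j]^2))
        x <- x - u %*% (t(u) %*% x)
    }
    sort(picked)
}

# one alternating-least-squares run
alsFit <- function(m, w, maxIter, tol, normM) {
    t <- ncol(m); k <- ncol(w)
    p <- matrix(0, k, t)
    prev <- Inf; converged <- FALSE
    for (it in seq_len(maxIter)) {
        for (j in seq_len(t))
            p[, j] <- pracma::lsqnonneg(w, m[, j])$x
        pp <- p %*% t(p)
        ridge <- diag(1e-12 * max(sum(diag(pp)), 1), k)
        w <- m %*% t(p) %*% solve(pp + ridge)
        res <- sqrt(sum((m - w %*% p)^2)) / normM
        if (res < 1e-10 ||
            (is.finite(prev) && abs(prev - res) < tol * max(res, 1e-10))) {
            converged <- TRUE
            prev <- res
            break
        }
        prev <- res
    }
    list(w = w, p = p, residual = prev, converged = converged)
}

setMethod("show", "DecompositionResult", function(object) {
    cat(sprintf(
        "DecompositionResult: k=%d, residual %.3g%s, seed %d\n",
        object@k, object@residual,
        if (object@converged) "" else " (not converged)", object@seed))
})
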