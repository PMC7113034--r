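test_that("profile series runs end to end with a common atom axis", {
    ser <- plantedSeries(noiseSd = 0.2)
    mod <- makeToyStructure(1, 6, unitCell(40, 40, 40), seed = 9)
    out <- withr::local_tempdir()
    res <- runProfileSeries(ser$maps, mod, extractionParams(),
                            delays = ser$delays, labels = ser$labels,
                            outDir = out)
    expect_length(res$profiles, 13)
    # identical atom ordering across all profiles
    serials <- lapply(res$profiles, function(p) p@atoms$serial)
    expect_true(all(vapply(serials, identical, logical(1), serials[[1]])))
    # defaults are the pragmatic choices: 2.0 A radius, 3 sigma floor
    expect_equal(res$profiles[[1]]@params@radius, 2.0)
    expect_equal(res$profiles[[1]]@params@nSigma, 3.0)
    # outputs written: one CSV + sidecar per time point plus the stack
    expect_length(res$files, 14)
    expect_true(all(file.exists(res$files)))
    expect_true(file.exists(file.path(out, "profile_01.json")))
    # reruns are byte-identical (deterministic pipeline)
    md5 <- tools::md5sum(res$files)
    res2 <- runProfileSeries(ser$maps, mod, extractionParams(),
                             delays = ser$delays, labels = ser$labels,
                             outDir = out)
    expect_identical(unname(tools::md5sum(res2$files)), unname(md5))
    expect_error(runProfileSeries(list(), mod), "empty map list")
    expect_error(runProfileSeries("no/such/file.map", mod),
                 "no/such/file.map")
})

test_that("parameter sweep reproduces the floor and radius trends", {
    cell <- unitCell(30, 30, 30)
    set.seed(3)
    blobs <- lapply(1:6, function(i)
        blobSpec(runif(3, 6, 24), sample(c(-1, 1), 1) * runif(1, 3, 5),
                 runif(1, 1.0, 1.6)))
    noisy <- makeBlobMap(cell, 0.5, blobs, noiseSd = 0.6, seed = 31)
    mod <- makeToyStructure(2, 8, cell, seed = 14)
    sw <- runParameterSweep(list(noisy), mod, radii = 2,
                            nSigmas = c(0, 2, 3))
    # raising the floor strictly prunes surviving atoms
    nz <- sw$summary$mean_nonzero_atoms
    expect_true(all(diff(nz) < 0))
    # larger spheres raise the baseline on a dense-feature map
    sw2 <- runParameterSweep(list(noisy), mod, radii = c(1.5, 2, 3),
                             nSigmas = 3)
    base <- sw2$summary$mean_abs_amplitude
    expect_gte(base[sw2$summary$radius == 3],
               base[sw2$summary$radius == 2])
    # a single-cell grid equals the plain profile series
    sw3 <- runParameterSweep(list(noisy), mod, radii = 2, nSigmas = 3)
    ref <- runProfileSeries(list(noisy), mod, extractionParams())
    expect_identical(sw3$profiles[["r2.00"]][["s3.0"]][[1]]@pos,
                     ref$profiles[[1]]@pos)
})

test_that("experiment-vs-model comparison is diagonal for self-comparison", {
    ser <- plantedSeries(noiseSd = 0)
    profs <- profilesOf(ser)
    cmp <- runCompare(profs, profs)
    expect_equal(diag(cmp$cross@values), rep(1, length(profs)),
                 tolerance = 1e-14)
    # noisy copies of a well-separated series stay diagonal-dominant:
    # time points chosen so consecutive profiles differ appreciably
    comps <- list(
        list(blobSpec(c(10, 10, 10), 5, 1.2),
             blobSpec(c(12, 10, 10), -4, 1.0)),
        list(blobSpec(c(20, 20, 20), 4, 1.3),
             blobSpec(c(22, 20, 20), -5, 1.1)),
        list(blobSpec(c(30, 28, 12), 6, 1.2),
             blobSpec(c(28, 28, 12), -3, 1.2)))
    times <- c(1e-8, 1e-7, 1e-6, 1e-5, 1e-4, 1e-3)
    sep <- makeKineticSeries(kineticTruth(comps, c(2e6, 2e3), times))
    sepN <- makeKineticSeries(kineticTruth(comps, c(2e6, 2e3), times,
                                           noiseSd = 0.1, seed = 88))
    mk <- function(s) lapply(seq_along(s$maps), function(j)
        amplitudeProfile(s$maps[[j]], ser$atoms,
                         extractionParams(nSigma = 0),
                         delay = times[j], label = s$labels[j]))
    cmp2 <- runCompare(mk(sep), mk(sepN),
                       regions = list(all = seq_len(nrow(ser$atoms))))
    expect_equal(unname(cmp2$summary$row_argmax), seq_along(times))
    expect_false(cmp2$cross@square)
    expect_s3_class(cmp2$regions, "data.frame")
    expect_lte(cmp2$summary$min_correlation, cmp2$summary$max_correlation)
    # mismatched atom axes are rejected with the offender named
    short <- lapply(profs, function(p) {
        new("AmplitudeProfile", atoms = p@atoms[-3, ], pos = p@pos[-3],
            neg = p@neg[-3], nPos = p@nPos[-3], nNeg = p@nNeg[-3],
            params = p@params, mapSigma = p@mapSigma, delay = p@delay,
            label = p@label)
    })
    expect_error(runCompare(profs, short), "atom-axis mismatch")
})

test_that("correlation exports are regenerable and complete", {
    ser <- plantedSeries(noiseSd = 0.1)
    profs <- profilesOf(ser)
    cm <- correlationMatrix(profs)
    bp <- findBlocks(cm, 0.85)
    pre <- file.path(withr::local_tempdir(), "corr")
    paths <- writeCorrelation(cm, bp, pre)
    expect_true(all(file.exists(paths)))
    back <- as.matrix(utils::read.csv(paths[1], row.names = 1,
                                      check.names = FALSE))
    expect_equal(unname(back), unname(cm@values), tolerance = 1e-12)
    js <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
    expect_equal(js$threshold, 0.85)
    expect_equal(nrow(js$blocks), length(bp@blocks))
})

test_that("the command-line wrapper simulates and profiles a series", {
    cli <- system.file("scripts", "densamp.R", package = "densamp")
    expect_true(nzchar(cli) && file.exists(cli))
    out <- withr::local_tempdir()
    rscript <- file.path(R.home("bin"), "Rscript")
    st <- system2(rscript, c(cli, "simulate", "--out", out, "--seed", "4",
                             "--timepoints", "3"),
                  stdout = TRUE, stderr = TRUE)
    expect_true(file.exists(file.path(out, "map_01.map")))
    expect_true(file.exists(file.path(out, "model.pdb")))
    st2 <- system2(rscript, c(cli, "profile",
                              "--maps", paste(file.path(out,
                                  sprintf("map_%02d.map", 1:3)),
                                  collapse = ","),
                              "--model", file.path(out, "model.pdb"),
                              "--nsigma", "0", "--out", out),
                   stdout = TRUE, stderr = TRUE)
    expect_true(file.exists(file.path(out, "profiles_stack.csv")))
})
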