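test_that("points CSV round trip is bit-exact and deterministically ordered", {
    fx <- femurFixture(nImages = 3)
    path <- withr::local_tempfile(fileext = ".csv")
    writePointsCsv(fx$landmarks, path)
    lines <- readLines(path)
    expect_equal(lines[1], "image_id,point_index,x,y")
    expect_length(lines, 1L + 3L * 58L)
    back <- readPointsCsv(path, template = fx$template)
    expect_identical(back@coords, fx$landmarks@coords)
    expect_equal(imageIds(back), imageIds(fx$landmarks))
})

test_that("malformed points files are rejected with a precise message", {
    fx <- femurFixture(nImages = 2)
    path <- withr::local_tempfile(fileext = ".csv")
    writePointsCsv(fx$landmarks, path)
    lines <- readLines(path)

    # drop point 31 of the second image
    id2 <- imageIds(fx$landmarks)[2]
    drop <- paste0(id2, ",31,")
    trimmed <- lines[!startsWith(lines, drop)]
    p2 <- withr::local_tempfile(fileext = ".csv")
    writeLines(trimmed, p2)
    expect_error(readPointsCsv(p2, template = fx$template),
                 paste0(id2, ".*31"))

    # duplicate a point
    dup <- c(lines, lines[5])
    p3 <- withr::local_tempfile(fileext = ".csv")
    writeLines(dup, p3)
    expect_error(readPointsCsv(p3, template = fx$template), "duplicate")

    # non-numeric coordinate reports the offending line
    bad <- lines
    bad[4] <- sub(",([^,]*)$", ",oops", bad[4])
    p4 <- withr::local_tempfile(fileext = ".csv")
    writeLines(bad, p4)
    expect_error(readPointsCsv(p4, template = fx$template), "line 4")
})

test_that("empty landmark sets write a header-only file", {
    empty <- new("LandmarkSet",
                 coords = array(numeric(0), c(58L, 2L, 0L)),
                 imageIds = character(0), templateId = "femur58")
    path <- withr::local_tempfile(fileext = ".csv")
    writePointsCsv(empty, path)
    expect_equal(readLines(path), "image_id,point_index,x,y")
})

test_that("template exclusions reduce the markup in index order", {
    fx <- femurFixture(nImages = 2)
    red <- applyTemplateExclusions(fx$landmarks, fx$template)
    expect_equal(nPoints(red), 53L)
    keep <- retainedIndices(fx$template) + 1L
    expect_equal(red[[1]], fx$landmarks[[1]][keep, ])
    expect_error(applyTemplateExclusions(red, fx$template),
                 "already reduced")

    # empty exclusion set: identity
    t12 <- makeBaseTemplate(12)
    pop <- simulatePopulation(
        makeGroundTruthModes(t12$baseShape, 0, numeric(0),
                             template = t12$template),
        3, seed = 2)
    same <- applyTemplateExclusions(pop$landmarks, t12$template)
    expect_identical(same@coords, pop$landmarks@coords)

    # exclude only index 0: first retained point is original index 1
    t0 <- new("ShapeTemplate", templateId = "t0", nPointsMarkup = 58L,
              labels = character(0), excludedIndices = 0L,
              aliases = integer(0))
    r0 <- applyTemplateExclusions(fx$landmarks, t0)
    expect_equal(nPoints(r0), 57L)
    expect_equal(r0[[1]][1, ], fx$landmarks[[1]][2, ])
})

test_that("exclusion ledger reproduces staged accounting exactly", {
    led14 <- exclusionLedger(6162, c(
        "twins, sibs and re-invites" = 171,
        "no genetic or follow-up data" = 1255,
        "poor image quality" = 268))
    expect_equal(led14@finalCount, 4468L)
    led18 <- exclusionLedger(4746, c(
        "twins, sibs and re-invites" = 115,
        "poor image quality" = 218))
    expect_equal(led18@finalCount, 4413L)
    expect_equal(exclusionLedger(100)@finalCount, 100L)
    expect_error(exclusionLedger(10, c(a = 8, b = 5)), "negative")
    expect_error(exclusionLedger(10, c(a = -1)), "non-negative")

    # conservation property over random stage structures
    set.seed(1)
    for (i in 1:20) {
        initial <- sample(1000:5000, 1)
        rem <- sample(0:200, sample(0:5, 1), replace = TRUE)
        led <- exclusionLedger(initial, setNames(rem, seq_along(rem)))
        expect_equal(led@finalCount + sum(led@countsRemoved),
                     led@initialCount)
    }
})

test_that("shape model files round trip losslessly", {
    fx <- femurFixture(nImages = 20)
    fit <- gpa(applyTemplateExclusions(fx$landmarks, fx$template))
    model <- truncateModel(buildShapeModel(fit), 10)
    path <- withr::local_tempfile(fileext = ".txt")
    writeShapeModel(model, path)
    back <- readShapeModel(path)
    expect_equal(back@mean, model@mean, tolerance = 1e-12)
    expect_equal(back@eigenvectors, model@eigenvectors, tolerance = 1e-12)
    expect_equal(back@eigenvalues, model@eigenvalues, tolerance = 1e-12)
    expect_equal(back@scoreSds, model@scoreSds, tolerance = 1e-12)
    expect_equal(back@varianceFraction, model@varianceFraction,
                 tolerance = 1e-12)
    expect_equal(back@nTraining, model@nTraining)
    expect_equal(templateId(back), templateId(model))

    # missing required field
    lines <- readLines(path)
    p2 <- withr::local_tempfile(fileext = ".txt")
    writeLines(lines[!grepl("^eigenvalues:", lines)], p2)
    expect_error(readShapeModel(p2), "lacks.*eigenvalues")

    # truncated eigenvector block
    p3 <- withr::local_tempfile(fileext = ".txt")
    writeLines(head(lines, length(lines) - 5L), p3)
    expect_error(readShapeModel(p3), "truncated")

    # version mismatch
    p4 <- withr::local_tempfile(fileext = ".txt")
    writeLines(c(sub(" 1$", " 99", lines[1]), lines[-1]), p4)
    expect_error(readShapeModel(p4), "version")
})

test_that("a zero-mode model file is valid and projects to empty scores", {
    k2 <- 2L * 53L
    m0 <- new("ShapeModel", mean = rnorm(k2),
              eigenvectors = matrix(numeric(0), k2, 0L),
              eigenvalues = numeric(0), scoreSds = numeric(0),
              varianceFraction = numeric(0), nTraining = 2L,
              templateId = "femur58")
    path <- withr::local_tempfile(fileext = ".txt")
    writeShapeModel(m0, path)
    back <- readShapeModel(path)
    expect_equal(nModes(back), 0L)
    expect_equal(back@mean, m0@mean, tolerance = 1e-12)
    sc <- projectShapes(back, unflatten(m0@mean))
    expect_equal(dim(sc), c(1L, 0L))
})

test_that("templates round trip through JSON", {
    tpl <- makeBaseTemplate()$template
    path <- withr::local_tempfile(fileext = ".json")
    writeTemplate(tpl, path)
    back <- readTemplate(path)
    expect_equal(nPointsMarkup(back), 58L)
    expect_equal(excludedIndices(back), excludedIndices(tpl))
    expect_equal(pointLabels(back), pointLabels(tpl))
    expect_equal(back@aliases, tpl@aliases)
})
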