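# one moderately sized fitted model shared across blocks
fx <- femurFixture(nImages = 120, noise = 0.5, seed = 19)
fit <- gpa(fx$landmarks)
model <- buildShapeModel(fit)

test_that("the fitted model satisfies its structural invariants", {
    V <- eigenVectors(model)
    expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
    expect_false(is.unsorted(rev(eigenValues(model))))
    expect_equal(sum(varianceFractions(model)), 1, tolerance = 1e-8)
    expect_equal(scoreSds(model)^2, eigenValues(model), tolerance = 1e-10)
    expect_error(buildShapeModel(alignedCoords(fit)[1, , drop = FALSE]),
                 "at least two")
    expect_error(buildShapeModel(rbind(rep(1, 10), rep(1, 10))),
                 "zero total variance")
})

test_that("a single axis of variation yields one mode with all the variance", {
    mu <- rnorm(20)
    d <- rnorm(20)
    X <- rbind(mu + d, mu - d, mu + d, mu - d)
    m1 <- buildShapeModel(X)
    expect_equal(nModes(m1), 1L)
    expect_equal(varianceFractions(m1), 1)
    # deterministic sign convention: largest-magnitude entry positive
    v <- eigenVectors(m1)[, 1]
    expect_gt(v[which.max(abs(v))], 0)
    expect_equal(abs(sum(v * d / sqrt(sum(d^2)))), 1, tolerance = 1e-10)
})

test_that("training scores are standardized: mean 0, SD 1 per mode", {
    sc <- scoreTraining(model, fit)
    expect_lt(max(abs(colMeans(sc))), 1e-8)
    expect_lt(max(abs(apply(sc, 2, sd) - 1)), 1e-8)
    # the model mean scores to zero everywhere
    z <- scoreTraining(model, rbind(meanShape(model)))
    expect_lt(max(abs(z)), 1e-10)
    # a shape displaced 2 SD along mode 1 scores (2, 0, ..., 0)
    x <- meanShape(model) + 2 * scoreSds(model)[1] * eigenVectors(model)[, 1]
    s <- scoreTraining(model, rbind(x))
    expect_equal(s[1, 1], 2, tolerance = 1e-8)
    expect_lt(max(abs(s[1, -1])), 1e-8)
})

test_that("training shapes are fully reconstructed from all modes", {
    sc <- scoreTraining(model, fit)
    for (i in c(1L, 60L)) {
        rebuilt <- meanShape(model) +
            as.vector(eigenVectors(model) %*% (sc[i, ] * scoreSds(model)))
        expect_equal(rebuilt, alignedCoords(fit)[i, ], tolerance = 1e-8)
    }
})

test_that("projection reproduces training scores and ignores similarity transforms", {
    sc <- scoreTraining(model, fit)
    pr <- projectShapes(model, alignedAsLandmarkSet(fit))
    expect_lt(max(abs(pr - sc)), 1e-8)
    # raw-pixel configurations under arbitrary similarity transforms
    set.seed(2)
    p <- fx$landmarks[[3]]
    s0 <- projectShapes(model, p)
    for (i in 1:5) {
        tp <- applySimilarity(p, runif(1, -pi, pi), runif(1, 0.3, 3),
                              rnorm(2, sd = 40))
        expect_equal(projectShapes(model, tp), s0, tolerance = 1e-8)
    }
    expect_error(projectShapes(model, p[1:10, ]), "template mismatch")
})

test_that("planted modes dominate the recovered subspace", {
    # smoke-level bound at this fixture size; the sharp 5-degree bound is
    # checked at n = 500 with 0.1 px noise in the end-to-end suite
    ang <- principalAnglesDeg(fx$gt@trueModes, eigenVectors(model)[, 1:3])
    expect_lt(max(ang), 20)
    sc <- scoreTraining(model, fit)
    agreement <- abs(diag(cor(fx$trueScores, sc[, 1:3])))
    expect_true(all(agreement > 0.9))
})

test_that("projection onto a frozen reference shows displaced means and shrunk SDs", {
    mu <- meanShape(model)
    e1 <- eigenVectors(model)[, 1]
    e2 <- eigenVectors(model)[, 2]
    s <- scoreSds(model)
    set.seed(14)
    shifted <- lapply(1:60, function(i) {
        v <- mu + 2 * s[1] * e1 + rnorm(1, 0, 0.4) * s[2] * e2
        applySimilarity(unflatten(v), runif(1, -0.2, 0.2),
                        runif(1, 0.9, 1.1), runif(2, -10, 10))
    })
    ref <- truncateModel(model, 10)
    sc <- projectShapes(ref, LandmarkSet(shifted))
    m <- colMeans(sc)
    expect_gt(m[1], 1.5)                   # displaced along mode 1
    expect_lt(max(abs(m[-1])), 0.5)        # other means near zero
    expect_true(all(apply(sc, 2, sd) < 1)) # homogeneous population
})

test_that("mode reconstructions are symmetric about the mean and re-score exactly", {
    expect_equal(reconstructShape(model, 1, 0), unflatten(meanShape(model)))
    plus <- reconstructShape(model, 2, 2)
    minus <- reconstructShape(model, 2, -2)
    expect_equal((plus + minus) / 2, unflatten(meanShape(model)),
                 tolerance = 1e-10)
    # exact round trip in the aligned coordinate frame
    s <- scoreTraining(model, rbind(flatten(plus)))
    expect_equal(unname(s[1, 2]), 2, tolerance = 1e-8)
    expect_lt(max(abs(s[1, -2])), 1e-8)
    # pixel-space projection agrees up to the unit-size renormalization
    pr <- projectShapes(truncateModel(model, 10), reconstructShape(model, 1, 2))
    expect_equal(unname(pr[1, 1]), 2, tolerance = 0.01)
    expect_lt(max(abs(pr[1, -1])), 0.05)
    expect_error(reconstructShape(model, nModes(model) + 1L), "out of range")
})

test_that("variance explained accumulates and truncation preserves it", {
    M <- nModes(model)
    expect_equal(varianceExplained(model, M), 1, tolerance = 1e-8)
    expect_equal(varianceExplained(model, 0), 0)
    cum <- vapply(0:M, function(j) varianceExplained(model, j), 0)
    expect_true(all(diff(cum) >= 0))

    t10 <- truncateModel(model, 10)
    expect_equal(nModes(t10), 10L)
    expect_equal(ncol(scoreTraining(t10, fit)), 10L)
    expect_equal(varianceExplained(t10, 10), varianceExplained(model, 10))
    full <- truncateModel(model, M)
    expect_equal(eigenVectors(full), eigenVectors(model))
    expect_error(truncateModel(model, 0), "must lie in")
})
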