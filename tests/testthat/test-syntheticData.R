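test_that("default femur template has 58 labelled points with 5 exclusions", {
    tpl <- makeBaseTemplate()
    t <- tpl$template
    expect_equal(nPointsMarkup(t), 58L)
    expect_equal(sort(excludedIndices(t)), c(0L, 1L, 44L, 45L, 57L))
    expect_equal(nPointsModel(t), 53L)
    expect_equal(length(retainedIndices(t)), 53L)
    expect_equal(unname(pointLabels(t)["56"]), "Acetabular eyebrow lateral end")
    expect_equal(unname(pointLabels(t)["51"]), "Acetabular eyebrow medial end")
    expect_equal(nrow(tpl$baseShape), 58L)
    # base shape stays inside the nominal 250 x 180 pixel frame
    expect_true(all(tpl$baseShape[, 1] >= 0 & tpl$baseShape[, 1] <= 250))
    expect_true(all(tpl$baseShape[, 2] >= 0 & tpl$baseShape[, 2] <= 180))
})

test_that("generic templates resample the outline; bad sizes error", {
    tpl <- makeBaseTemplate(12)
    expect_equal(nPointsMarkup(tpl$template), 12L)
    expect_length(excludedIndices(tpl$template), 0L)
    expect_equal(nrow(tpl$baseShape), 12L)
    expect_error(makeBaseTemplate(57), "invalid template")
    expect_error(makeBaseTemplate(10), "invalid template")
})

test_that("ground-truth modes are orthonormal and similarity-free", {
    tpl <- makeBaseTemplate()
    gt <- makeGroundTruthModes(tpl$baseShape, 4, c(10, 5, 2, 1),
                               template = tpl$template, seed = 3)
    V <- gt@trueModes
    expect_lt(max(abs(crossprod(V) - diag(4))), 1e-8)
    # orthogonal to the similarity tangent space at the base shape
    ctr <- sweep(tpl$baseShape, 2, colMeans(tpl$baseShape))
    sim <- cbind(flatten(cbind(rep(1, 58), 0)), flatten(cbind(0, rep(1, 58))),
                 flatten(ctr), flatten(cbind(-ctr[, 2], ctr[, 1])))
    expect_lt(max(abs(crossprod(sim, V))) / sqrt(sum(ctr^2)), 1e-10)
    expect_error(makeGroundTruthModes(tpl$baseShape, 2 * 58 - 3,
                                      rep(1, 2 * 58 - 3)), "2k - 4")
})

test_that("population simulation is deterministic and honours degenerate settings", {
    tpl <- makeBaseTemplate()
    gt0 <- makeGroundTruthModes(tpl$baseShape, 0, numeric(0),
                                template = tpl$template)
    still <- simulatePopulation(gt0, 3, rotationRange = c(0, 0),
                                scaleRange = c(1, 1),
                                translationRange = c(0, 0),
                                markingNoiseSd = 0, seed = 9)
    for (i in 1:3)
        expect_equal(unname(still$landmarks[[i]]), unname(tpl$baseShape))

    gt <- makeGroundTruthModes(tpl$baseShape, 2, c(8, 3),
                               template = tpl$template, seed = 5)
    a <- simulatePopulation(gt, 10, seed = 77)
    b <- simulatePopulation(gt, 10, seed = 77)
    expect_identical(a$landmarks@coords, b$landmarks@coords)
    expect_identical(a$trueScores, b$trueScores)
    expect_equal(dim(a$trueScores), c(10L, 2L))
    c <- simulatePopulation(gt, 10, seed = 78)
    expect_false(identical(a$landmarks@coords, c$landmarks@coords))
    expect_error(simulatePopulation(gt, 1), "at least 2")
    expect_error(simulatePopulation(gt, 5, markingNoiseSd = -1),
                 "non-negative")
})

test_that("remarking adds controlled noise and is exact at zero", {
    fx <- femurFixture(nImages = 5, noise = 0)
    again <- simulateRemarking(fx$landmarks, 0, seed = 1)
    expect_identical(again@coords, fx$landmarks@coords)
    expect_error(simulateRemarking(fx$landmarks, -0.1), "non-negative")
    expect_identical(simulateRemarking(fx$landmarks, 1, seed = 2)@coords,
                     simulateRemarking(fx$landmarks, 1, seed = 2)@coords)
})

test_that("mean re-marking distance matches the Rayleigh closed form", {
    # both sessions carry iid N(0, sigma^2) per-coordinate noise, so each
    # point-to-point distance is Rayleigh with scale sigma*sqrt(2) and
    # expectation sigma*sqrt(pi)
    sigma <- 2
    fx <- femurFixture(nImages = 100, noise = 0)
    s1 <- simulateRemarking(fx$landmarks, sigma, seed = 21)
    s2 <- simulateRemarking(fx$landmarks, sigma, seed = 22)
    d <- unlist(lapply(seq_len(nImages(s1)),
                       function(i) pointToPoint(s1[[i]], s2[[i]])$distances))
    expected <- sigma * sqrt(pi)
    se <- sigma * sqrt(4 - pi) / sqrt(length(d))   # Rayleigh SD / sqrt(N)
    expect_lt(abs(mean(d) - expected), 4 * se)
})

test_that("correlated score simulation reproduces the target correlation", {
    R <- diag(10)
    X <- simulateCorrelatedScores(R, 1e5, seed = 8)
    C <- cor(X)
    expect_lt(max(abs(C[upper.tri(C)])), 0.02)

    R2 <- diag(2); R2[1, 2] <- R2[2, 1] <- 0.9
    X2 <- simulateCorrelatedScores(R2, 1e5, seed = 8)
    expect_lt(abs(cor(X2)[1, 2] - 0.9), 0.01)

    X3 <- simulateCorrelatedScores(diag(2), 2, seed = 1)
    expect_equal(dim(X3), c(2L, 2L))
    expect_true(all(is.finite(X3)))

    bad <- matrix(1, 3, 3)  # rank 1 but PSD: fine
    expect_silent(simulateCorrelatedScores(bad, 5, seed = 1))
    notPsd <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
    expect_error(simulateCorrelatedScores(notPsd, 5),
                 "not positive semi-definite: eigenvalue")
})
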