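# shared fixture builders; everything is generated in code at test time

flatten <- function(p) as.vector(t(p))
unflatten <- function(v) matrix(v, ncol = 2, byrow = TRUE)

rotMat <- function(theta)
    matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)

applySimilarity <- function(p, theta = 0, scale = 1, shift = c(0, 0))
    sweep(p %*% t(rotMat(theta)) * scale, 2, shift, `+`)

# small synthetic femur population with known ground truth
femurFixture <- function(nImages = 60, nModes = 3, modeSds = c(10, 5, 2),
                         noise = 0.5, seed = 42) {
    tpl <- makeBaseTemplate()
    gt <- makeGroundTruthModes(tpl$baseShape, nModes, modeSds,
                               template = tpl$template, seed = seed)
    pop <- simulatePopulation(gt, nImages, markingNoiseSd = noise,
                              seed = seed + 1L)
    list(template = tpl$template, base = tpl$baseShape, gt = gt,
         landmarks = pop$landmarks, trueScores = pop$trueScores)
}

alignedAsLandmarkSet <- function(fit)
    LandmarkSet(lapply(seq_len(nImages(fit)),
                       function(i) unflatten(alignedCoords(fit)[i, ])),
                imageIds(fit), templateId(fit))

principalAnglesDeg <- function(U, V) {
    qu <- qr.Q(qr(U)); qv <- qr.Q(qr(V))
    acos(pmin(1, svd(crossprod(qu, qv))$d)) * 180 / pi
}

totalProcrustesSS <- function(fit) sum(procrustesResiduals(fit)^2)
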