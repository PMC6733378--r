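#' Per-mode summary, correlation structure and effective tests
#'
#' Summarizes a score table the way shape-mode results are conventionally
#' reported: per-mode mean and SD (mean 0 / SD 1 when a dataset is its
#' own reference; displaced when projected onto an external reference),
#' the M x M Pearson correlation matrix of the modes, and the
#' spectral-decomposition estimate of the effective number of
#' independent modes.
#'
#' @param scores n x M score matrix (n >= 3).
#' @return a list with \code{perMode} (data.frame: mode, mean, sd),
#'   \code{correlation} (M x M matrix) and \code{effectiveTests}
#'   (an \linkS4class{EffectiveTestsResult}).
#' @export
summarizeScores <- function(scores) {
    scores <- as.matrix(scores)
    if (nrow(scores) < 3L) stop("need at least 3 score rows")
    perMode <- data.frame(
        mode = seq_len(ncol(scores)),
        mean = unname(colMeans(scores)),
        sd   = unname(apply(scores, 2L, stats::sd)))
    R <- scoreCorrelation(scores)
    list(perMode = perMode, correlation = R, effectiveTests = nyholtVeff(R))
}

#' Run the end-to-end hip shape modelling pipeline
#'
#' Orchestrates the full workflow: obtain landmarks (simulate a
#' synthetic femur population, or read a points CSV), apply staged image
#' exclusions with ledger accounting, reduce the markup to the model
#' point set, align by generalized Procrustes analysis, then either
#' build a shape model from the data (own-reference mode: training
#' scores have mean 0 and SD 1 per mode) or project onto a frozen
#' reference model read from disk (the reference is never modified).
#' Artifacts (points, aligned shapes, model, scores, ledger, summary
#' JSON, log) are written to \code{outDir}; identical config and seed
#' reproduce them byte for byte.
#'
#' @param config a named list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{pointsCsv}{input landmark file (omit when simulating).}
#'     \item{simulate}{list(nImages, nModes, modeSds, noiseSd) for the
#'       synthetic generator (used when pointsCsv is absent).}
#'     \item{templateJson}{optional template path; default is the
#'       built-in 58-point femur markup.}
#'     \item{excludeImages}{optional named list of image-id vectors,
#'       one element per exclusion stage.}
#'     \item{referenceModel}{optional path to a saved model; switches
#'       to project-only mode.}
#'     \item{nModesRetained}{modes kept in own-reference mode
#'       (default 10).}
#'     \item{mirrorX}{flip x coordinates before alignment
#'       (default FALSE).}
#'     \item{gpaTol, gpaMaxIter}{alignment convergence controls.}
#'     \item{seed}{integer; drives all randomness.}
#'     \item{outDir}{output directory.}
#'   }
#' @return (invisibly) a list with the landmarks, ledger, Procrustes
#'   fit, model, score matrix, summary and artifact paths.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    cfg <- function(name, default = NULL) config[[name]] %||% default
    outDir <- cfg("outDir") %||% stop("config$outDir is required")
    seed <- as.integer(cfg("seed", 1L))
    nRetained <- as.integer(cfg("nModesRetained", 10L))
    if (nRetained < 1L) stop("nModesRetained must be >= 1")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    created <- character(0)
    ok <- FALSE
    on.exit(if (!ok) unlink(created))  # drop partial outputs on failure
    emit <- function(path) { created <<- c(created, path); path }
    logLines <- character(0)
    note <- function(...) logLines <<- c(logLines, paste0(...))
    withStage <- function(stage, expr)
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", stage, "': ", conditionMessage(e),
                 call. = FALSE))

    template <- withStage("template", {
        if (!is.null(cfg("templateJson"))) readTemplate(cfg("templateJson"))
        else makeBaseTemplate()$template
    })
    note("template '", templateId(template), "': ",
         nPointsMarkup(template), " markup points, ",
         nPointsModel(template), " in model")

    landmarks <- withStage("input", {
        if (!is.null(cfg("pointsCsv"))) {
            readPointsCsv(cfg("pointsCsv"), template = template)
        } else {
            sim <- cfg("simulate") %||%
                stop("either pointsCsv or simulate settings are required")
            base <- makeBaseTemplate(nPointsMarkup(template))
            gt <- makeGroundTruthModes(
                base$baseShape, nModes = sim$nModes %||% 3L,
                modeSds = sim$modeSds %||% c(10, 5, 2),
                template = template, seed = seed)
            pop <- simulatePopulation(gt, nImages = sim$nImages %||% 100L,
                                      markingNoiseSd = sim$noiseSd %||% 1,
                                      seed = seed + 1L)
            writePointsCsv(pop$landmarks,
                           emit(file.path(outDir, "points.csv")))
            pop$landmarks
        }
    })
    note("input: ", nImages(landmarks), " images x ",
         nPoints(landmarks), " points")

    stages <- cfg("excludeImages", list())
    ledger <- withStage("exclusions", {
        removed <- integer(0)
        for (s in names(stages)) {
            drop <- intersect(stages[[s]], imageIds(landmarks))
            removed[s] <- length(drop)
            landmarks <- landmarks[setdiff(imageIds(landmarks), drop)]
        }
        exclusionLedger(nImages(landmarks) + sum(removed), removed)
    })
    note("exclusions: ", sum(ledger@countsRemoved), " removed across ",
         length(stages), " stage(s); ", ledger@finalCount, " retained")

    reduced <- withStage("template exclusions", {
        if (length(excludedIndices(template)) &&
            nPoints(landmarks) == nPointsMarkup(template))
            applyTemplateExclusions(landmarks, template)
        else landmarks
    })
    if (isTRUE(cfg("mirrorX"))) {
        arr <- reduced@coords
        arr[, 1, ] <- -arr[, 1, ]
        reduced <- new("LandmarkSet", coords = arr,
                       imageIds = reduced@imageIds,
                       templateId = reduced@templateId)
        note("mirrored x coordinates")
    }

    fit <- withStage("align",
        gpa(reduced, tol = cfg("gpaTol", 1e-10),
            maxIter = as.integer(cfg("gpaMaxIter", 100L))))
    note("gpa: converged = ", converged(fit), " in ", fit@iterations,
         " iterations; mean residual ",
         format(mean(procrustesResiduals(fit)), digits = 4))
    alignedSet <- LandmarkSet(
        lapply(seq_len(nImages(fit)),
               function(i) unflattenXY(fit@aligned[i, ])),
        imageIds = imageIds(fit), templateId = templateId(fit))
    writePointsCsv(alignedSet, emit(file.path(outDir, "aligned.csv")))

    refPath <- cfg("referenceModel")
    if (is.null(refPath)) {
        model <- withStage("build model", {
            m <- buildShapeModel(fit)
            truncateModel(m, min(nRetained, nModes(m)))
        })
        scores <- withStage("score", scoreTraining(model, fit))
        writeShapeModel(model, emit(file.path(outDir, "model.txt")))
        note("own-reference model: ", nModes(model), " modes retained, ",
             sprintf("%.1f%%", 100 * varianceExplained(model)),
             " of variance")
    } else {
        model <- withStage("load reference", readShapeModel(refPath))
        scores <- withStage("project", projectShapes(model, reduced))
        note("projected onto frozen reference '", templateId(model),
             "' (", nModes(model), " modes); reference unmodified")
    }

    summary <- withStage("summarize", summarizeScores(scores))

    scorePath <- emit(file.path(outDir, "scores.csv"))
    utils::write.csv(
        data.frame(image_id = rownames(scores),
                   signif(scores, 12), check.names = FALSE),
        scorePath, row.names = FALSE, quote = FALSE)
    ledgerPath <- emit(file.path(outDir, "ledger.txt"))
    writeLines(utils::capture.output(show(ledger)), ledgerPath)
    summaryPath <- emit(file.path(outDir, "summary.json"))
    jsonlite::write_json(list(
        nImages = nImages(fit),
        ledgerFinal = ledger@finalCount,
        mode = if (is.null(refPath)) "own-reference" else "reference-projection",
        nModes = nModes(model),
        varianceExplainedRetained =
            if (is.null(refPath)) varianceExplained(model) else NULL,
        perMode = summary$perMode,
        veffNyholt = veff(summary$effectiveTests),
        lossFraction = lossFraction(summary$effectiveTests)),
        summaryPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    note("scores: ", nrow(scores), " rows x ", ncol(scores), " modes; ",
         "Veff = ", sprintf("%.1f", veff(summary$effectiveTests)))
    logPath <- emit(file.path(outDir, "pipeline.log"))
    writeLines(logLines, logPath)
    ok <- TRUE
    invisible(list(landmarks = landmarks, ledger = ledger, fit = fit,
                   model = model, scores = scores, summary = summary,
                   paths = created))
}
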