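POINTS_HEADER <- c("image_id", "point_index", "x", "y")
MODEL_MAGIC <- "hipSSM-shape-model"
MODEL_VERSION <- 1L

fmtNum <- function(x) formatC(x, digits = 17, format = "g", width = 1)

#' Read landmark configurations from a points CSV file
#'
#' The points file is long format: one row per landmark with header
#' \code{image_id, point_index, x, y}; rows may appear in any order and
#' point indices are 0-based. Each image must carry a complete,
#' duplicate-free index set.
#'
#' @param path file path.
#' @param template optional \linkS4class{ShapeTemplate}; when supplied,
#'   every image must have exactly its markup point count.
#' @return a \linkS4class{LandmarkSet} with points sorted by index.
#' @export
readPointsCsv <- function(path, template = NULL) {
    raw <- utils::read.csv(path, colClasses = "character")
    if (!identical(names(raw), POINTS_HEADER))
        stop("malformed points file: expected header ",
             paste(POINTS_HEADER, collapse = ","))
    for (col in c("point_index", "x", "y")) {
        v <- suppressWarnings(as.numeric(raw[[col]]))
        bad <- which(is.na(v) & !is.na(raw[[col]]))
        if (anyNA(v))
            bad <- union(bad, which(is.na(v)))
        if (length(bad))
            stop("parse error in ", path, ": non-numeric ", col,
                 " on line ", bad[1] + 1L)
        raw[[col]] <- v
    }
    ids <- unique(raw$image_id)
    expected <- if (!is.null(template)) nPointsMarkup(template) else
        length(unique(raw$point_index))
    configs <- vector("list", length(ids))
    names(configs) <- ids
    for (id in ids) {
        rows <- raw[raw$image_id == id, ]
        idx <- rows$point_index
        if (anyDuplicated(idx))
            stop("malformed points file: duplicate point index ",
                 idx[duplicated(idx)][1], " for image ", id)
        missing <- setdiff(seq_len(expected) - 1L, idx)
        if (length(missing) || nrow(rows) != expected)
            stop("malformed points file: image ", id, " is missing point ",
                 if (length(missing)) missing[1] else "(count mismatch)")
        ord <- order(idx)
        configs[[id]] <- cbind(rows$x[ord], rows$y[ord])
    }
    LandmarkSet(configs, imageIds = ids,
                templateId = if (!is.null(template)) templateId(template)
                             else "unknown")
}

#' Write landmark configurations to a points CSV file
#'
#' Rows are emitted in deterministic order (image id, then point index)
#' with full double precision, so a write/read round trip reproduces the
#' coordinates bit-exactly.
#'
#' @param x a \linkS4class{LandmarkSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePointsCsv <- function(x, path) {
    stopifnot(is(x, "LandmarkSet"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(POINTS_HEADER, collapse = ","), con)
    k <- nPoints(x)
    for (i in seq_len(nImages(x))) {
        p <- x[[i]]
        writeLines(paste(x@imageIds[i], seq_len(k) - 1L,
                         fmtNum(p[, 1]), fmtNum(p[, 2]), sep = ","), con)
    }
    invisible(path)
}

#' Drop a template's excluded points from configurations
#'
#' Restricts each configuration to the template's retained indices,
#' preserving the original point order — e.g. the 58-point femur markup
#' reduced to the 53-point model.
#'
#' @param x a \linkS4class{LandmarkSet} with the full markup point count.
#' @param template a \linkS4class{ShapeTemplate}.
#' @return a \linkS4class{LandmarkSet} with \code{nPointsModel(template)}
#'   points per image.
#' @export
applyTemplateExclusions <- function(x, template) {
    stopifnot(is(x, "LandmarkSet"), is(template, "ShapeTemplate"))
    if (nPoints(x) != nPointsMarkup(template)) {
        if (nPoints(x) == nPointsModel(template))
            stop("configurations appear to be already reduced (",
                 nPoints(x), " points)")
        stop("point count ", nPoints(x), " does not match template markup (",
             nPointsMarkup(template), ")")
    }
    keep <- retainedIndices(template) + 1L
    new("LandmarkSet", coords = x@coords[keep, , , drop = FALSE],
        imageIds = x@imageIds, templateId = x@templateId)
}

#' Staged exclusion accounting
#'
#' Applies named exclusion stages to an initial image count and returns
#' the ledger, whose show method renders the familiar staged-exclusion
#' table (total uploaded, per-stage removals, final count).
#'
#' @param initial non-negative initial count.
#' @param stages named numeric vector (or data.frame with columns
#'   \code{stage} and \code{removed}) of per-stage removal counts.
#' @return an \linkS4class{ExclusionLedger}.
#' @examples
#' led <- exclusionLedger(6162, c("twins, sibs and re-invites" = 171,
#'                                "no genetic or follow-up data" = 1255,
#'                                "poor image quality" = 268))
#' led  # final count 4468
#' @export
exclusionLedger <- function(initial, stages = numeric(0)) {
    if (is.data.frame(stages)) {
        nm <- as.character(stages$stage)
        rem <- as.integer(stages$removed)
    } else {
        nm <- names(stages) %||% character(length(stages))
        rem <- stats::setNames(as.integer(stages), nm)
    }
    initial <- as.integer(initial)
    if (initial < 0L || any(rem < 0L))
        stop("counts must be non-negative")
    if (length(rem) && any(initial - cumsum(rem) < 0L))
        stop("running total becomes negative at stage '",
             nm[which(initial - cumsum(rem) < 0L)[1]], "'")
    new("ExclusionLedger", initialCount = initial, stageNames = nm,
        countsRemoved = rem, finalCount = initial - sum(rem))
}

#' @rdname accessors
#' @export
setMethod("nImages", "ExclusionLedger", function(x) x@finalCount)

#' Write a shape model to a plain-text file
#'
#' Self-describing key-value plus matrix-block text format with a format
#' version line; numeric values are written at full double precision so
#' a round trip is lossless.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeShapeModel <- function(model, path) {
    stopifnot(is(model, "ShapeModel"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        paste(MODEL_MAGIC, MODEL_VERSION),
        paste0("templateId: ", model@templateId),
        paste0("nPoints: ", nPoints(model)),
        paste0("nModes: ", nModes(model)),
        paste0("nTraining: ", model@nTraining),
        paste0("mean: ", paste(fmtNum(model@mean), collapse = " ")),
        paste0("eigenvalues: ",
               paste(fmtNum(model@eigenvalues), collapse = " ")),
        paste0("scoreSds: ", paste(fmtNum(model@scoreSds), collapse = " ")),
        paste0("varianceFraction: ",
               paste(fmtNum(model@varianceFraction), collapse = " ")),
        "eigenvectors:"), con)
    if (nModes(model) > 0)
        writeLines(apply(model@eigenvectors, 1L,
                         function(r) paste(fmtNum(r), collapse = " ")), con)
    invisible(path)
}

#' Read a shape model written by \code{writeShapeModel}
#'
#' @param path file path.
#' @return a \linkS4class{ShapeModel}.
#' @export
readShapeModel <- function(path) {
    lines <- readLines(path)
    if (!length(lines)) stop("truncated model file: ", path)
    head <- strsplit(lines[1], " ")[[1]]
    if (head[1] != MODEL_MAGIC)
        stop("not a shape model file: ", path)
    if (as.integer(head[2]) != MODEL_VERSION)
        stop("unsupported model file version ", head[2])
    fields <- list()
    i <- 2L
    while (i <= length(lines) && lines[i] != "eigenvectors:") {
        kv <- regmatches(lines[i], regexec("^([A-Za-z]+): ?(.*)$", lines[i]))[[1]]
        if (length(kv) != 3L) stop("malformed model file line: ", lines[i])
        fields[[kv[2]]] <- kv[3]
        i <- i + 1L
    }
    required <- c("templateId", "nPoints", "nModes", "nTraining", "mean",
                  "eigenvalues", "scoreSds", "varianceFraction")
    miss <- setdiff(required, names(fields))
    if (length(miss))
        stop("model file lacks field(s): ", paste(miss, collapse = ", "))
    if (i > length(lines)) stop("truncated model file: no eigenvector block")
    num <- function(f) as.numeric(strsplit(trimws(fields[[f]]), "\\s+")[[1]])
    k2 <- 2L * as.integer(fields$nPoints)
    M <- as.integer(fields$nModes)
    rows <- lines[seq.int(i + 1L, length.out = length(lines) - i)]
    rows <- rows[nzchar(rows)]
    if (M > 0L && length(rows) != k2)
        stop("truncated model file: expected ", k2,
             " eigenvector rows, found ", length(rows))
    V <- if (M > 0L)
        do.call(rbind, lapply(rows, function(r)
            as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    else matrix(numeric(0), k2, 0L)
    if (M > 0L && ncol(V) != M)
        stop("truncated model file: expected ", M, " eigenvector columns")
    mean <- if (nzchar(trimws(fields$mean))) num("mean") else numeric(0)
    vals <- function(f) if (nzchar(trimws(fields[[f]]))) num(f) else numeric(0)
    new("ShapeModel", mean = mean, eigenvectors = V,
        eigenvalues = vals("eigenvalues"), scoreSds = vals("scoreSds"),
        varianceFraction = vals("varianceFraction"),
        nTraining = as.integer(fields$nTraining),
        templateId = fields$templateId)
}

#' Write a shape template to JSON
#'
#' @param template a \linkS4class{ShapeTemplate}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTemplate <- function(template, path) {
    stopifnot(is(template, "ShapeTemplate"))
    obj <- list(formatVersion = 1L,
                templateId = template@templateId,
                nPointsMarkup = template@nPointsMarkup,
                labels = as.list(template@labels),
                excludedIndices = template@excludedIndices,
                aliases = as.list(template@aliases))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}

#' Read a shape template from JSON
#'
#' @param path file path.
#' @return a \linkS4class{ShapeTemplate}.
#' @export
readTemplate <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("ShapeTemplate",
        templateId = obj$templateId,
        nPointsMarkup = as.integer(obj$nPointsMarkup),
        labels = unlist(obj$labels) %||% character(0),
        excludedIndices = as.integer(obj$excludedIndices %||% integer(0)),
        aliases = vapply(obj$aliases %||% list(), as.integer, 0L))
}
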