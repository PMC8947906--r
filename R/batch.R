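#' Evaluate an estimator grid over a set of images
#'
#' Runs [segmentImage()] and [segmentationMetrics()] for every (image,
#' estimator) pair and collects one row per pair. Unsupported estimators
#' (the lognormal placeholder) and failed runs are kept as rows with NA
#' metrics and a diagnostic `status`, so counting contracts hold.
#'
#' @param images list of [GrayImage-class] objects (or a single one).
#' @param specs list of [EstimatorSpec-class] objects (or estimator strings,
#'   parsed with [parseEstimatorSpec()]).
#' @param truths optional list of ground-truth [BinaryMask-class] objects,
#'   parallel to `images` (NULL entries allowed).
#' @param imageNames optional character labels for the `image` column.
#' @return data.frame with columns `image`, `method`, `param`, `t_raw`,
#'   `mu1`, `mu2`, `IU`, `RC`, `IRD`, `JI`, `F`, `ACC`, `status`.
#' @export
batchEvaluate <- function(images, specs, truths = NULL, imageNames = NULL) {
  if (is(images, "GrayImage")) images <- list(images)
  if (is(specs, "EstimatorSpec") || is.character(specs)) specs <- as.list(specs)
  specs <- lapply(specs, function(s)
    if (is.character(s)) parseEstimatorSpec(s) else s)
  if (is.null(imageNames)) imageNames <- sprintf("image_%03d", seq_along(images))
  if (!is.null(truths) && length(truths) != length(images))
    stop("truths must be parallel to images")
  rows <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    truth <- if (is.null(truths)) NULL else truths[[i]]
    for (s in specs) {
      label <- formatEstimatorSpec(s)
      base <- data.frame(image = imageNames[i], method = s@method,
                         param = estimatorParam(s),
                         t_raw = NA_real_, mu1 = NA_real_, mu2 = NA_real_,
                         IU = NA_real_, RC = NA_real_, IRD = NA_real_,
                         JI = NA_real_, F = NA_real_, ACC = NA_real_,
                         status = "ok")
      if (s@method == "lognormal") {
        base$status <- "unsupported"
        rows[[length(rows) + 1L]] <- base
        next
      }
      row <- tryCatch({
        seg <- suppressWarnings(segmentImage(img, s))
        m <- segmentationMetrics(img, seg, truth)
        base$t_raw <- seg$result@tRaw
        base$mu1 <- seg$result@mu1
        base$mu2 <- seg$result@mu2
        base[names(m)] <- m
        base
      }, error = function(e) {
        base$status <- paste0("error: ", conditionMessage(e))
        base
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Per-estimator summary of a batch table
#'
#' Averages each metric over the images for every estimator configuration
#' (rows in the order the configurations first appear), reports the mean of
#' the unsupervised and of the supervised metric groups, and flags the best
#' configuration per metric.
#'
#' @param batch the data.frame from [batchEvaluate()].
#' @return data.frame with one row per configuration: `method`, `param`,
#'   `n_images`, the six metric means, `unsup_mean`, `sup_mean`, and `best`
#'   (comma-separated metric names this configuration maximizes; ties flag
#'   all maximizers).
#' @export
sweepSummary <- function(batch) {
  if (nrow(batch) == 0L) stop("empty image set")
  key <- paste(batch$method, batch$param, sep = "|")
  keys <- unique(key)
  metrics <- c("IU", "RC", "IRD", "JI", "F", "ACC")
  out <- do.call(rbind, lapply(keys, function(k) {
    sub <- batch[key == k, , drop = FALSE]
    means <- vapply(metrics, function(m) mean(sub[[m]]), numeric(1))
    data.frame(method = sub$method[1], param = sub$param[1],
               n_images = length(unique(sub$image)),
               as.list(means),
               unsup_mean = mean(means[c("IU", "RC", "IRD")]),
               sup_mean = mean(means[c("JI", "F", "ACC")]))
  }))
  out$best <- ""
  for (m in metrics) {
    v <- out[[m]]
    if (all(is.na(v))) next
    top <- which(v == max(v, na.rm = TRUE))
    out$best[top] <- ifelse(nzchar(out$best[top]),
                            paste(out$best[top], m, sep = ","), m)
  }
  rownames(out) <- NULL
  out
}

findTruthPath <- function(imagePath, truthDir) {
  stem <- tools::file_path_sans_ext(basename(imagePath))
  cand <- list.files(truthDir, full.names = TRUE,
                     pattern = paste0("^", stem, "_gt\\.(png|tif|tiff|pgm)$"))
  if (length(cand) >= 1L) cand[1] else NA_character_
}

readTruthMask <- function(path) {
  img <- readGrayImage(path)
  binaryMask(pixels(img) > 127L)
}

#' Segment image files from disk and write artifacts
#'
#' File-level driver: reads each input image, runs the estimator grid,
#' optionally pairs ground truth by the `<stem>_gt.<ext>` convention, and
#' writes masks (`<stem>__<estimator>.png`), per-result JSON reports, and a
#' metrics CSV with one row per (image, estimator).
#'
#' @param inputs character vector of image paths, or a single directory
#'   (all `.png`/`.tif`/`.tiff`/`.pgm` files not ending in `_gt`).
#' @param estimators character vector in the estimator grammar (see
#'   [parseEstimatorSpec()]) or a list of [EstimatorSpec-class].
#' @param outDir output directory for masks/reports/CSV (created); NULL
#'   writes nothing.
#' @param truthDir optional directory of ground-truth masks.
#' @param writeMasks,writeReports which artifacts to write when `outDir`
#'   is set.
#' @return the batch data.frame (see [batchEvaluate()]), invisibly when
#'   `outDir` is set.
#' @export
runSegment <- function(inputs, estimators, outDir = NULL, truthDir = NULL,
                       writeMasks = TRUE, writeReports = FALSE) {
  if (length(inputs) == 1L && dir.exists(inputs)) {
    inputs <- list.files(inputs, full.names = TRUE,
                         pattern = "\\.(png|tif|tiff|pgm)$")
    inputs <- inputs[!grepl("_gt\\.[^.]+$", inputs)]
  }
  if (length(inputs) == 0L) stop("empty image set")
  specs <- if (is.character(estimators))
    lapply(estimators, parseEstimatorSpec) else estimators
  images <- lapply(inputs, readGrayImage)
  names <- tools::file_path_sans_ext(basename(inputs))
  truths <- NULL
  if (!is.null(truthDir)) {
    truths <- lapply(inputs, function(p) {
      tp <- findTruthPath(p, truthDir)
      if (is.na(tp)) NULL else readTruthMask(tp)
    })
  }
  batch <- batchEvaluate(images, specs, truths = truths, imageNames = names)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(images)) {
      for (s in specs) {
        if (s@method == "lognormal") next
        tag <- gsub("[:.]", "_", formatEstimatorSpec(s))
        seg <- tryCatch(suppressWarnings(segmentImage(images[[i]], s)),
                        error = function(e) NULL)
        if (is.null(seg)) next
        if (writeMasks)
          writeMask(seg$mask,
                    file.path(outDir, sprintf("%s__%s.png", names[i], tag)))
        if (writeReports)
          thresholdResultJSON(seg$result,
                              file.path(outDir,
                                        sprintf("%s__%s.json", names[i], tag)))
      }
    }
    utils::write.csv(batch, file.path(outDir, "metrics.csv"),
                     row.names = FALSE)
    return(invisible(batch))
  }
  batch
}

#' Summarize a batch run into a per-configuration report
#'
#' Thin wrapper over [sweepSummary()] that accepts either the in-memory
#' batch table or a metrics CSV written by [runSegment()], and optionally
#' writes the summary CSV.
#'
#' @param batch data.frame or path to a metrics CSV.
#' @param csvPath optional output path for the summary CSV.
#' @return the summary data.frame.
#' @export
runSweepReport <- function(batch, csvPath = NULL) {
  if (is.character(batch)) batch <- utils::read.csv(batch)
  s <- sweepSummary(batch)
  if (!is.null(csvPath)) utils::write.csv(s, csvPath, row.names = FALSE)
  s
}
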