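# Run configuration and batch execution over directories of cells.

#' Analysis run configuration
#'
#' Collects the tunable parameters of all pipelines with their standard
#' defaults (rolling-ball radii 15/20 px, Mexican hat 3 px, median 1 px,
#' 0.8% saturation, 1 x 1 um site boxes, 17 x 17 / 13 x 13 orientation
#' kernels). Serializes losslessly to JSON; every analysis output embeds
#' the configuration hash.
#'
#' @param ... overrides of the default parameters
#' @param seed seed recorded in outputs
#' @return a list of class "RunConfig" with attributes \code{hash}
#' @export
runConfig <- function(..., seed = 1L) {
  cfg <- list(
    tubuleBackgroundRadiusPx = 15L, pairBackgroundRadiusPx = 20L,
    hatRadiusPx = 3L, medianRadiusPx = 1L, saturatedPercent = 0.8,
    roiMarginUm = 1, siteBoxUm = 1, kernel1Px = 17L, kernel2Px = 13L,
    orphanCutoffUm = 0.5, siteOrphanCutoffUm = 1.2, seed = as.integer(seed))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "RunConfig", hash = configHash(cfg))
}

configHash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             tf)
  unname(tools::md5sum(tf))
}

#' Write a run configuration to a JSON file (and read it back)
#'
#' @param cfg a \code{\link{runConfig}}
#' @param path JSON file path
#' @return the path (write) or the restored RunConfig (read)
#' @export
writeRunConfig <- function(cfg, path) {
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  v <- jsonlite::fromJSON(path)
  defs <- runConfig()
  for (nm in names(v)) {
    if (nm %in% names(defs)) storage.mode(v[[nm]]) <- storage.mode(defs[[nm]])
  }
  do.call(runConfig, c(v[setdiff(names(v), "seed")], list(seed = v$seed)))
}

resultStamp <- function(cfg) {
  list(tool = "dyadscape",
       version = as.character(utils::packageVersion("dyadscape")),
       configHash = attr(cfg, "hash"), seed = cfg$seed)
}

#' Batch tubule morphometry over a directory of TIFF images
#'
#' Analyses every matching single-page TIFF as one cell, writing a per-cell
#' JSON result and one tidy CSV row per cell. Failures are logged and
#' skipped; the \code{status} attribute of the returned data.frame is
#' non-zero when any cell failed.
#'
#' @param inputDir directory of single-cell TIFFs
#' @param pixelSizeUm pixel size applied to every image
#' @param outDir output directory (created if needed)
#' @param pattern file-name pattern (default "\\.tiff?$")
#' @param config a \code{\link{runConfig}}
#' @return data.frame of per-cell metrics (one row per analysed cell),
#'   with attribute \code{status} (0 = all cells analysed)
#' @export
runBatch <- function(inputDir, pixelSizeUm, outDir,
                     pattern = "\\.tiff?$", config = runConfig()) {
  files <- list.files(inputDir, pattern = pattern, full.names = TRUE)
  if (length(files) == 0L) stop("no input files in ", inputDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stamp <- resultStamp(config)
  rows <- list(); failures <- 0L
  for (f in files) {
    cell <- sub("\\.[^.]*$", "", basename(f))
    res <- tryCatch({
      img <- readMicrograph(f, pixelSizeUm = pixelSizeUm)
      tm <- tubuleMetrics(img,
                          backgroundRadiusPx = config$tubuleBackgroundRadiusPx,
                          saturatedPercent = config$saturatedPercent,
                          hatRadiusPx = config$hatRadiusPx,
                          medianRadiusPx = config$medianRadiusPx,
                          roiMarginUm = config$roiMarginUm)
      m <- tm$metrics
      out <- list(cell = cell,
                  densityPercent = m@densityPercent,
                  transverseFraction = m@transverseFraction,
                  longitudinalFraction = m@longitudinalFraction,
                  skeletonLengthUm = m@skeletonLengthUm,
                  roiMarginUm = config$roiMarginUm,
                  parameters = unclass(config), provenance = stamp)
      writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                                  na = "null"),
                 file.path(outDir, paste0(cell, ".json")))
      data.frame(cell = cell, densityPercent = m@densityPercent,
                 transverseFraction = m@transverseFraction,
                 longitudinalFraction = m@longitudinalFraction,
                 skeletonLengthUm = m@skeletonLengthUm)
    }, error = function(e) {
      message("cell '", cell, "' failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- failures + 1L else rows[[cell]] <- res
  }
  if (length(rows) == 0L) stop("every cell failed")
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  csv <- file.path(outDir, "cells.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  writeLines(jsonlite::toJSON(stamp, auto_unbox = TRUE),
             file.path(outDir, "run.json"))
  attr(df, "status") <- failures
  df
}
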