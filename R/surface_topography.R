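# Surface-topography indices from per-cell Z-spine annotation tables.
# (The manual SEM annotation itself is an input, not computed here.)

# validate an annotation table and coerce types
checkZSpines <- function(records) {
  need <- c("spine_id", "spine_length_um", "groove_crest_length_um",
            "has_ttubule_lumen")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) < 1L) stop("need at least one Z-spine record")
  records$spine_length_um <- as.numeric(records$spine_length_um)
  records$groove_crest_length_um <- as.numeric(records$groove_crest_length_um)
  records$has_ttubule_lumen <- as.logical(records$has_ttubule_lumen)
  for (i in seq_len(nrow(records))) {
    id <- records$spine_id[i]
    if (!is.finite(records$spine_length_um[i]) ||
        records$spine_length_um[i] <= 0)
      stop("spine '", id, "': spine_length_um must be > 0")
    if (!is.finite(records$groove_crest_length_um[i]) ||
        records$groove_crest_length_um[i] < 0)
      stop("spine '", id, "': groove_crest_length_um must be >= 0")
    if (records$groove_crest_length_um[i] > records$spine_length_um[i])
      stop("spine '", id,
           "': groove crest length exceeds the spine length")
    if (is.na(records$has_ttubule_lumen[i]))
      stop("spine '", id, "': has_ttubule_lumen must be TRUE/FALSE")
  }
  records
}

#' Read a Z-spine annotation table
#'
#' Expected CSV columns: spine_id, spine_length_um, groove_crest_length_um,
#' has_ttubule_lumen (logical or 0/1).
#'
#' @param path CSV file path
#' @return validated data.frame
#' @export
readZSpineTable <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  checkZSpines(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Z-groove index of a cell
#'
#' Total length of elevated membrane crests (which define each groove)
#' divided by the total Z-spine length of the cell (ratio of sums, i.e.
#' a cell-level index).
#'
#' @param records Z-spine annotation data.frame
#' @return fraction in [0, 1]
#' @export
zGrooveIndexFromRecords <- function(records) {
  records <- checkZSpines(records)
  sum(records$groove_crest_length_um) / sum(records$spine_length_um)
}

#' Fraction of Z-spines with a visible t-tubule lumen
#'
#' @param records Z-spine annotation data.frame
#' @return fraction in [0, 1]
#' @export
tTubuleOpeningFractionFromRecords <- function(records) {
  records <- checkZSpines(records)
  mean(records$has_ttubule_lumen)
}

#' Both surface-topography indices of a cell
#'
#' @param records Z-spine annotation data.frame (or a CSV path)
#' @return a \linkS4class{TopographyMetrics}
#' @export
topographyMetrics <- function(records) {
  if (is.character(records)) records <- readZSpineTable(records)
  records <- checkZSpines(records)
  new("TopographyMetrics",
      zGrooveIndex = zGrooveIndexFromRecords(records),
      tTubuleOpeningFraction = tTubuleOpeningFractionFromRecords(records),
      nSpines = nrow(records))
}
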