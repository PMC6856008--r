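# Aggregation of per-cell features to per-field medians, per-well values,
# and the percent-change-vs-negative-control (PMC) profile matrix.

#' Mapping from profile parameter names to cell-record columns
#'
#' The measured parameters of the profile matrix and the per-cell feature
#' column each is the median of. "count nuclei" is special-cased (cell
#' count per field, summed per well).
#'
#' @return Named character vector (parameter name -> cellFeatures column).
#' @export
parameterMap <- function() {
  c("cells eccentricity" = "eccentricity",
    "Nuclei Median Intensity Snail/Slug" = "median_FITC_nucleus",
    "Cytoplasm Median Intensity Snail/Slug" = "median_FITC_cytoplasm",
    "cell area" = "area_um2",
    "cell solidity" = "solidity",
    "number of neighboring cells" = "n_neighbors",
    "percentage of intercellular contact" = "percent_touching")
}

#' Per-field medians of the cell features
#'
#' Collapses a per-cell feature table (carrying `well` and `field`
#' identity columns) to one row per field: the median of every mapped
#' parameter over the field's cells, plus `count nuclei` (the number of
#' cells). Empty fields yield a count of 0 and missing medians.
#'
#' @param cellRecords data.frame from [cellFeatures()] with added `well`
#'   and `field` columns; may have zero rows.
#' @param fields Optional data.frame(well, field) enumerating all imaged
#'   fields, so fields without any cell still appear.
#' @param params Parameter mapping; default [parameterMap()] restricted to
#'   columns present.
#' @return data.frame: well, field, `count nuclei`, one column per
#'   parameter.
#' @export
fieldSummaries <- function(cellRecords, fields = NULL,
                           params = parameterMap()) {
  params <- params[params %in% names(cellRecords)]
  if (is.null(fields)) {
    stopIfNot(nrow(cellRecords) > 0L,
              "no cell records and no field enumeration given")
    fields <- unique(cellRecords[c("well", "field")])
  }
  fields <- fields[order(fields$well, fields$field), , drop = FALSE]
  out <- data.frame(well = fields$well, field = fields$field,
                    stringsAsFactors = FALSE)
  key <- paste(cellRecords$well, cellRecords$field, sep = "\r")
  fkey <- paste(fields$well, fields$field, sep = "\r")
  groups <- split(seq_len(nrow(cellRecords)), key)
  out[["count nuclei"]] <- vapply(fkey, function(k)
    length(groups[[k]]), integer(1L), USE.NAMES = FALSE)
  for (p in names(params)) {
    col <- params[[p]]
    out[[p]] <- vapply(fkey, function(k) {
      ii <- groups[[k]]
      if (length(ii) == 0L) return(NA_real_)
      median(cellRecords[[col]][ii], na.rm = TRUE)
    }, numeric(1L), USE.NAMES = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Per-well parameter values from field summaries
#'
#' The per-well value of each parameter is the median across the well's
#' fields of the field medians; the per-well `count nuclei` is the *sum*
#' of the field counts. Wells whose total cell count falls below
#' `minCellsQc` (or whose fields are all empty) are flagged as failing QC.
#'
#' @param summaries Output of [fieldSummaries()].
#' @param minCellsQc Minimum total cells per well (default 50).
#' @return data.frame: well, `count nuclei`, parameter columns, `qc_pass`,
#'   `qc_reason`.
#' @export
aggregateWells <- function(summaries, minCellsQc = 50) {
  params <- setdiff(names(summaries), c("well", "field", "count nuclei"))
  wells <- unique(summaries$well)
  out <- data.frame(well = wells, stringsAsFactors = FALSE)
  bywell <- split(seq_len(nrow(summaries)), summaries$well)[wells]
  out[["count nuclei"]] <- vapply(bywell, function(ii)
    sum(summaries[["count nuclei"]][ii]), numeric(1L), USE.NAMES = FALSE)
  for (p in params) {
    out[[p]] <- vapply(bywell, function(ii) {
      v <- summaries[[p]][ii]
      if (all(is.na(v))) NA_real_ else median(v, na.rm = TRUE)
    }, numeric(1L), USE.NAMES = FALSE)
  }
  out$qc_pass <- out[["count nuclei"]] >= minCellsQc
  out$qc_reason <- ifelse(out$qc_pass, "",
    ifelse(out[["count nuclei"]] == 0, "all fields empty",
           sprintf("total cells %d < %d", out[["count nuclei"]],
                   as.integer(minCellsQc))))
  rownames(out) <- NULL
  out
}

#' Percent change versus the negative control (PMC profile matrix)
#'
#' For every treatment and parameter computes
#' 100 x (combine(treatment wells) - combine(control wells)) /
#' combine(control wells), after dropping wells that failed QC.
#' Parameters whose control reference is 0 are dropped with a warning.
#' Both drops are recorded in the QC log.
#'
#' @param wellValues Output of [aggregateWells()].
#' @param layout data.frame(well, treatment, replicate).
#' @param controlLabel Negative-control treatment label.
#' @param combine "mean" (default, the conventional percent-of-control
#'   combiner) or "median".
#' @param includeControl Keep the control row (identically ~0) in the
#'   matrix; default TRUE.
#' @return A [ProfileMatrix-class].
#' @export
percentChangeMatrix <- function(wellValues, layout, controlLabel,
                                combine = c("mean", "median"),
                                includeControl = TRUE) {
  combine <- match.arg(combine)
  comb <- if (combine == "mean") mean else median
  stopIfNot(controlLabel %in% layout$treatment,
            "control label absent from layout")
  wv <- merge(wellValues, layout[c("well", "treatment")], by = "well")
  log <- data.frame(item = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  failed <- !wv$qc_pass
  if (any(failed))
    log <- rbind(log, data.frame(item = paste0("well ", wv$well[failed]),
                                 reason = wv$qc_reason[failed]))
  wv <- wv[!failed, , drop = FALSE]
  stopIfNot(any(wv$treatment == controlLabel),
            "no control well passes QC")
  params <- setdiff(names(wv),
                    c("well", "treatment", "qc_pass", "qc_reason"))
  treatments <- unique(layout$treatment)
  if (!includeControl) treatments <- setdiff(treatments, controlLabel)
  ctrl <- wv[wv$treatment == controlLabel, , drop = FALSE]
  keep <- character(0)
  for (p in params) {
    ref <- comb(ctrl[[p]][!is.na(ctrl[[p]])])
    if (!is.finite(ref) || ref == 0) {
      warning("parameter '", p, "' dropped: control reference is 0 or ",
              "undefined", call. = FALSE)
      log <- rbind(log, data.frame(item = paste0("parameter ", p),
                                   reason = "control reference 0/undefined"))
    } else keep <- c(keep, p)
  }
  vals <- matrix(NA_real_, length(treatments), length(keep),
                 dimnames = list(treatments, keep))
  reps <- matrix(0L, length(treatments), length(keep),
                 dimnames = list(treatments, keep))
  for (p in keep) {
    ref <- comb(ctrl[[p]][!is.na(ctrl[[p]])])
    for (tr in treatments) {
      v <- wv[[p]][wv$treatment == tr]
      v <- v[!is.na(v)]
      if (length(v) == 0L) {
        vals[tr, p] <- NA_real_
      } else {
        vals[tr, p] <- 100 * (comb(v) - ref) / ref
        reps[tr, p] <- length(v)
      }
    }
  }
  bad <- rowSums(!is.finite(vals)) > 0
  if (any(bad)) {
    log <- rbind(log, data.frame(
      item = paste0("treatment ", treatments[bad]),
      reason = "no passing well for some parameter"))
    vals <- vals[!bad, , drop = FALSE]
    reps <- reps[!bad, , drop = FALSE]
  }
  new("ProfileMatrix", values = vals, replicateN = reps,
      controlLabel = controlLabel, qcLog = log)
}
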