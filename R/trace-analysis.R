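#' Compute a single cell's ERK activity trace from tracking rows
#'
#' Forms the per-frame cytoplasm/nucleus KTR intensity ratio for one cell.
#' Frames with nonpositive nuclear or cytoplasmic intensity are treated as
#' segmentation errors: they are excluded from the ratio and the trace is
#' flagged `segmentation_error`.
#'
#' @param track data.frame of tracking rows for one cell with columns
#'   `time_min`, `nuc_ktr`, `cyt_ktr` (and optionally `cell_id`).
#' @param totalFrames number of frames in the whole experiment, used for
#'   the coverage fraction; defaults to the number of rows supplied.
#' @param flags additional upstream QC flags to attach (e.g.
#'   `"track_switch"` from the tracking software).
#' @return an [ActivityTrace].
#' @export
#' @examples
#' tr <- data.frame(time_min = c(0, 5, 10), nuc_ktr = c(100, 100, 100),
#'                  cyt_ktr = c(200, 150, 100))
#' ratioValues(computeActivityTrace(tr))
computeActivityTrace <- function(track, totalFrames = nrow(track),
                                 flags = character(0)) {
  need <- c("time_min", "nuc_ktr", "cyt_ktr")
  if (!all(need %in% names(track)))
    stop("track must contain columns ", paste(need, collapse = ", "))
  if (length(unique(track$cell_id)) > 1)
    stop("computeActivityTrace expects rows for a single cell")
  ord <- order(track$time_min)
  track <- track[ord, , drop = FALSE]
  bad <- !is.finite(track$nuc_ktr) | !is.finite(track$cyt_ktr) |
    track$nuc_ktr <= 0 | track$cyt_ktr <= 0
  if (all(bad)) stop("all frames invalid: empty trace")
  if (any(bad)) flags <- union(flags, "segmentation_error")
  keep <- track[!bad, , drop = FALSE]
  id <- if ("cell_id" %in% names(track)) as.character(track$cell_id[1])
        else NA_character_
  new("ActivityTrace", cellId = id, timeMin = keep$time_min,
      ratio = keep$cyt_ktr / keep$nuc_ktr,
      coverage = nrow(keep) / max(totalFrames, nrow(track)),
      flags = flags)
}

#' Split a tracking table into per-cell activity traces
#'
#' @param tracks a tracking table (see [readTrackTable()] for the schema).
#' @return named list of [ActivityTrace] objects, one per cell; cells whose
#'   frames are all invalid are dropped with a warning.
#' @export
tracksToTraces <- function(tracks) {
  totalFrames <- length(unique(tracks$frame))
  out <- list()
  for (id in unique(tracks$cell_id)) {
    rows <- tracks[tracks$cell_id == id, , drop = FALSE]
    fl <- character(0)
    if ("flags" %in% names(rows))
      fl <- setdiff(unique(unlist(strsplit(rows$flags, ";"))), "")
    tr <- tryCatch(computeActivityTrace(rows, totalFrames, flags = fl),
                   error = function(e) NULL)
    if (is.null(tr)) warning("cell ", id, " dropped: no valid frames")
    else out[[id]] <- tr
  }
  out
}

#' Clean activity traces by coverage and tracking-quality rules
#'
#' Applies the minimal trace-cleaning rules used for single-cell KTR data:
#' cells whose tracks switched between two objects, cells whose ratios were
#' affected by segmentation errors, and cells tracked for less than a
#' minimum fraction of the time course are excluded.  The coverage cutoff
#' defaults to two thirds and can be relaxed for fast-moving conditions
#' where tracks are systematically shorter.
#'
#' @param traces list of [ActivityTrace] objects.
#' @param minCoverage minimum coverage fraction to retain a trace.
#' @return list with `retained` (list of traces) and `log` (data.frame:
#'   cell_id, reason in `{switch, segmentation, short}`), one row per
#'   excluded trace.  Cleaning is idempotent.
#' @export
cleanTraces <- function(traces, minCoverage = 2 / 3) {
  reasons <- character(0); ids <- character(0)
  keep <- logical(length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    reason <- NA_character_
    if ("track_switch" %in% traceFlags(tr)) reason <- "switch"
    else if ("segmentation_error" %in% traceFlags(tr)) reason <- "segmentation"
    else if (coverage(tr) < minCoverage) reason <- "short"
    keep[i] <- is.na(reason)
    if (!is.na(reason)) {
      ids <- c(ids, cellId(tr)); reasons <- c(reasons, reason)
    }
  }
  list(retained = traces[keep],
       log = data.frame(cell_id = ids, reason = reasons,
                        stringsAsFactors = FALSE))
}

#' Kinase localization fold change (final over basal N/C ratio)
#'
#' Ratio of the mean nucleus/cytoplasm localization ratio over the final
#' window to that over the basal window — the per-cell summary of nuclear
#' translocation of the tagged kinase.
#'
#' @param loc a [LocalizationTrace].
#' @param basalWindowMin length of the basal window at the trace start,
#'   minutes.
#' @param finalWindowMin length of the final window at the trace end,
#'   minutes.
#' @return fold change (dimensionless scalar).
#' @export
localizationFoldChange <- function(loc, basalWindowMin = 60,
                                   finalWindowMin = 60) {
  t <- timeMin(loc); x <- ratioValues(loc)
  basal <- x[t <= min(t) + basalWindowMin]
  final <- x[t >= max(t) - finalWindowMin]
  if (!length(basal) || !length(final))
    stop("basal and final windows must be non-empty")
  mb <- mean(basal)
  if (mb <= 0) stop("basal mean must be > 0")
  mean(final) / mb
}

#' Migration fold change (final over basal distance traveled)
#'
#' Path length (sum of frame-to-frame step lengths) in the final window
#' divided by that in the basal window, per cell.
#'
#' @param track data.frame for one cell with `time_min`, `x_um`, `y_um`.
#' @param basalWindowMin,finalWindowMin window lengths in minutes.
#' @return fold change, or `NA` (undefined) when the basal path length is
#'   zero.
#' @export
migrationFoldChange <- function(track, basalWindowMin = 60,
                                finalWindowMin = 60) {
  ord <- order(track$time_min)
  t <- track$time_min[ord]; x <- track$x_um[ord]; y <- track$y_um[ord]
  pathIn <- function(win) {
    i <- which(t >= win[1] & t <= win[2])
    if (length(i) < 2) return(NA_real_)
    sum(sqrt(diff(x[i])^2 + diff(y[i])^2))
  }
  basal <- pathIn(c(min(t), min(t) + basalWindowMin))
  final <- pathIn(c(max(t) - finalWindowMin, max(t)))
  if (is.na(basal) || is.na(final) || basal == 0) return(NA_real_)
  final / basal
}

#' Thresholds for dynamics classification
#'
#' @param dutySustained duty-cycle cutoff above which a cell is called
#'   sustained.
#' @param minPeaks minimum called peaks for a pulsatile call.
#' @param activityThreshold C/N ratio above which a frame counts as active
#'   (duty-cycle numerator).
#' @param finalWindowMin window at the trace end for the final-window mean
#'   feature, minutes.
#' @return named list of thresholds.
#' @export
dynamicsThresholds <- function(dutySustained = 0.8, minPeaks = 2,
                               activityThreshold = 1.25,
                               finalWindowMin = 60) {
  list(dutySustained = dutySustained, minPeaks = minPeaks,
       activityThreshold = activityThreshold,
       finalWindowMin = finalWindowMin)
}

#' Classify single-cell ERK dynamics as pulsatile, sustained or quiescent
#'
#' Pure function of trace features: `sustained` when the duty cycle
#' (fraction of frames above `activityThreshold`, over `windowMin` if
#' given) reaches `dutySustained`; otherwise `pulsatile` when at least
#' `minPeaks` peaks were called; otherwise `quiescent`.
#'
#' @param peaks a [PeakSet] computed on `trace`.
#' @param trace the corresponding [ActivityTrace].
#' @param thresholds a [dynamicsThresholds()] list.
#' @param windowMin optional length-2 time window (minutes) over which the
#'   duty cycle is computed; default the whole trace.
#' @return a [DynamicsCall].
#' @export
classifyDynamics <- function(peaks, trace,
                             thresholds = dynamicsThresholds(),
                             windowMin = NULL) {
  t <- timeMin(trace); x <- ratioValues(trace)
  if (!is.null(windowMin)) {
    i <- t >= windowMin[1] & t <= windowMin[2]
    t <- t[i]; x <- x[i]
  }
  if (!length(x)) stop("empty classification window")
  duty <- mean(x > thresholds$activityThreshold)
  finalMean <- mean(x[t >= max(t) - thresholds$finalWindowMin])
  label <- if (duty >= thresholds$dutySustained) "sustained"
           else if (peakCount(peaks) >= thresholds$minPeaks) "pulsatile"
           else "quiescent"
  new("DynamicsCall", cellId = cellId(trace), label = label,
      features = c(peak_count = peakCount(peaks), duty_cycle = duty,
                   final_window_mean = finalMean))
}

#' Per-frame population summary of activity traces
#'
#' Aligns traces on the union of their frame times and returns the mean and
#' the 25th-75th percentile band per frame (the usual population display of
#' single-cell KTR data); cells absent at a frame are omitted from that
#' frame's statistics.
#'
#' @param traces list of [ActivityTrace] objects.
#' @return data.frame with `time_min`, `mean`, `q25`, `q75`, `n`.
#' @export
summarizePopulation <- function(traces) {
  stopifnot(length(traces) >= 1)
  times <- sort(unique(unlist(lapply(traces, timeMin))))
  vals <- matrix(NA_real_, length(times), length(traces))
  for (j in seq_along(traces)) {
    tr <- traces[[j]]
    vals[match(timeMin(tr), times), j] <- ratioValues(tr)
  }
  data.frame(
    time_min = times,
    mean = apply(vals, 1, mean, na.rm = TRUE),
    q25 = apply(vals, 1, stats::quantile, probs = 0.25, na.rm = TRUE,
                names = FALSE),
    q75 = apply(vals, 1, stats::quantile, probs = 0.75, na.rm = TRUE,
                names = FALSE),
    n = apply(vals, 1, function(v) sum(!is.na(v))))
}
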