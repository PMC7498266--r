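trackTableColumns <- c("cell_id", "frame", "time_min", "x_um", "y_um",
                       "nuc_ktr", "cyt_ktr", "nuc_loc", "cyt_loc",
                       "population", "valid")

#' Write a tracking table to CSV
#'
#' @param tracks tracking data.frame with the documented column set.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrackTable <- function(tracks, path) {
  miss <- setdiff(trackTableColumns, names(tracks))
  if (length(miss))
    stop("tracking table is missing columns: ", paste(miss, collapse = ", "))
  utils::write.csv(tracks[, trackTableColumns], path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a tracking table CSV
#'
#' Reads the per-cell, per-frame tracking schema (`cell_id, frame,
#' time_min, x_um, y_um, nuc_ktr, cyt_ktr, nuc_loc, cyt_loc, population,
#' valid`).  Rows with malformed fields — non-finite positions or times,
#' negative intensities, or `valid = FALSE` — are rejected and reported in
#' the `rejected` attribute with their line numbers.
#'
#' @param path CSV file path.
#' @return validated data.frame; attribute `rejected` is a data.frame of
#'   `line`, `reason` for dropped rows.
#' @export
readTrackTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(trackTableColumns, names(raw))
  if (length(miss))
    stop("schema error: missing mandatory column(s) ",
         paste(miss, collapse = ", "))
  numCols <- c("frame", "time_min", "x_um", "y_um", "nuc_ktr", "cyt_ktr",
               "nuc_loc", "cyt_loc")
  for (cl in numCols) raw[[cl]] <- suppressWarnings(as.numeric(raw[[cl]]))
  raw$valid <- as.logical(raw$valid)
  reason <- rep(NA_character_, nrow(raw))
  badNum <- Reduce(`|`, lapply(numCols, function(cl) !is.finite(raw[[cl]])))
  reason[badNum] <- "malformed numeric field"
  negInt <- !badNum & (raw$nuc_ktr < 0 | raw$cyt_ktr < 0 |
                         raw$nuc_loc < 0 | raw$cyt_loc < 0)
  reason[negInt] <- "negative intensity"
  notValid <- is.na(reason) & (is.na(raw$valid) | !raw$valid)
  reason[notValid] <- "flagged invalid"
  keep <- is.na(reason)
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  # +1 for the header line
  attr(out, "rejected") <- data.frame(line = which(!keep) + 1L,
                                      reason = reason[!keep],
                                      stringsAsFactors = FALSE)
  out
}

#' Write a multi-channel z-stack as a multi-page TIFF with YAML sidecar
#'
#' Pages are written channel-major (all z planes of channel 1, then
#' channel 2, ...).  Acquisition metadata (channel count, z step, z
#' origin) goes to a YAML sidecar at `<path>.yaml`.  Voxel values must be
#' 16-bit integer counts (0-65535), as produced by [simulateZStack()];
#' the round trip through [readStack()] is lossless.
#'
#' @param stack integer array `[channel, z, y, x]`.
#' @param path output TIFF path.
#' @param zStepUm z step in micrometers.
#' @param zMinUm z coordinate of the lowest plane.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path, zStepUm = 1, zMinUm = 0) {
  d <- dim(stack)
  if (length(d) != 4) stop("stack must be a 4-d [channel, z, y, x] array")
  if (any(stack < 0) || any(stack > 65535))
    stop("voxel values must lie in [0, 65535]")
  pages <- list()
  for (ch in seq_len(d[1])) for (iz in seq_len(d[2]))
    pages[[length(pages) + 1L]] <- stack[ch, iz, , ] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(channels = d[1], nz = d[2], ny = d[3], nx = d[4],
                        z_step_um = zStepUm, z_min_um = zMinUm,
                        page_order = "channel_major"),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a multi-channel z-stack TIFF
#'
#' Reconstructs the `[channel, z, y, x]` integer array written by
#' [writeStack()].  Metadata comes from the YAML sidecar; when the sidecar
#' is absent, explicit `channels`/`zStepUm` arguments take over (with a
#' warning).  Explicit arguments always win over the sidecar.
#'
#' @param path TIFF file path.
#' @param sidecar sidecar path (default `<path>.yaml`).
#' @param channels channel count override.
#' @param zStepUm z-step override, micrometers.
#' @return integer array `[channel, z, y, x]` with attributes `zStepUm`
#'   and `zMinUm`.
#' @export
readStack <- function(path, sidecar = paste0(path, ".yaml"),
                      channels = NULL, zStepUm = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- list()
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
  } else if (is.null(channels) || is.null(zStepUm)) {
    stop("no sidecar at ", sidecar,
         " and no explicit channels/zStepUm given")
  } else {
    warning("sidecar missing; using explicit channels/zStepUm arguments")
  }
  if (!is.null(channels)) meta$channels <- channels
  if (!is.null(zStepUm)) meta$z_step_um <- zStepUm
  if (is.null(meta$z_min_um)) meta$z_min_um <- 0
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nCh <- meta$channels
  if (length(pages) %% nCh != 0)
    stop("page count ", length(pages), " not divisible by channel count ",
         nCh)
  nz <- length(pages) %/% nCh
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  stack <- array(0L, dim = c(nCh, nz, ny, nx))
  k <- 1L
  for (ch in seq_len(nCh)) for (iz in seq_len(nz)) {
    stack[ch, iz, , ] <- as.integer(round(pages[[k]] * 65535))
    k <- k + 1L
  }
  attr(stack, "zStepUm") <- meta$z_step_um
  attr(stack, "zMinUm") <- meta$z_min_um
  stack
}

#' Write / read ground-truth annotations as JSON
#'
#' @param truth a ground-truth list as produced by the simulators.
#' @param path JSON file path.
#' @return `path` invisibly for the writer; the parsed list for the
#'   reader.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", na = "null")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
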