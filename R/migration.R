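#' Centroid of the inducible-cell group at a reference frame
#'
#' @param tracks tracking table (schema of [readTrackTable()]).
#' @param frame reference frame number (default the first frame present).
#' @return length-2 numeric `c(x_um, y_um)`.
#' @export
findInducibleCenter <- function(tracks, frame = min(tracks$frame)) {
  rows <- tracks[tracks$frame == frame &
                   tracks$population == "inducible", , drop = FALSE]
  if (!nrow(rows)) stop("no inducible cells at frame ", frame)
  c(x_um = mean(rows$x_um), y_um = mean(rows$y_um))
}

#' Select neighboring cells within a square window around the center
#'
#' Restricts analysis to neighboring (non-inducible) cells whose position
#' at the reference frame lies within the axis-aligned square
#' `center +/- halfWidthUm` in both axes (a 200 x 200 um window by
#' default).  Inducible cells are always excluded.
#'
#' @param tracks tracking table.
#' @param centerXy length-2 window center, micrometers.
#' @param halfWidthUm half the window side, micrometers.
#' @param frame reference frame at which positions are evaluated.
#' @return the tracking-table subset for all frames of the selected cells
#'   (possibly empty).
#' @export
selectNeighborsInWindow <- function(tracks, centerXy, halfWidthUm = 100,
                                    frame = min(tracks$frame)) {
  at <- tracks[tracks$frame == frame, , drop = FALSE]
  inWin <- abs(at$x_um - centerXy[1]) <= halfWidthUm &
           abs(at$y_um - centerXy[2]) <= halfWidthUm &
           at$population != "inducible"
  ids <- at$cell_id[inWin]
  tracks[tracks$cell_id %in% ids, , drop = FALSE]
}

#' Per-interval displacement vectors of one cell
#'
#' Positional changes over consecutive non-overlapping intervals (20 min by
#' default) within an optional epoch.  Intervals spanning a gap in the
#' track are skipped.
#'
#' @param track tracking rows for one cell (`time_min`, `x_um`, `y_um`).
#' @param intervalMin interval length in minutes; must be a multiple of the
#'   frame interval.
#' @param epochMin optional length-2 time window (minutes) restricting the
#'   intervals considered.
#' @return data.frame with `t_start_min`, `x_um`, `y_um` (start position),
#'   `dx_um`, `dy_um` (displacement); zero rows if nothing qualifies.
#' @export
intervalDisplacements <- function(track, intervalMin = 20,
                                  epochMin = NULL) {
  ord <- order(track$time_min)
  t <- track$time_min[ord]; x <- track$x_um[ord]; y <- track$y_um[ord]
  if (!is.null(epochMin)) {
    i <- t >= epochMin[1] & t <= epochMin[2]
    t <- t[i]; x <- x[i]; y <- y[i]
  }
  out <- list()
  if (length(t) >= 2) {
    frameInt <- inferFrameInterval(t)
    if (abs(intervalMin / frameInt - round(intervalMin / frameInt)) > 1e-6)
      stop("frame interval must divide intervalMin")
    start <- t[1]
    while (start + intervalMin <= t[length(t)]) {
      i0 <- match(TRUE, abs(t - start) < 1e-9)
      i1 <- match(TRUE, abs(t - (start + intervalMin)) < 1e-9)
      if (!is.na(i0) && !is.na(i1)) {
        out[[length(out) + 1L]] <- data.frame(
          t_start_min = start, x_um = x[i0], y_um = y[i0],
          dx_um = x[i1] - x[i0], dy_um = y[i1] - y[i0])
      }
      start <- start + intervalMin
    }
  }
  if (!length(out))
    return(data.frame(t_start_min = numeric(0), x_um = numeric(0),
                      y_um = numeric(0), dx_um = numeric(0),
                      dy_um = numeric(0)))
  do.call(rbind, out)
}

#' Migration angle relative to the inducible-cell center
#'
#' Unsigned angle between a displacement vector and the direction from the
#' cell's position toward the center: 0 deg is motion directly toward the
#' center, 180 deg directly away, 90 deg orthogonal.  Angles are folded to
#' `[0, 180]` because the toward/away statistic is symmetric about the
#' center axis.
#'
#' @param positionXy length-2 position at the interval start, micrometers.
#' @param displacementXy length-2 displacement vector, micrometers.
#' @param centerXy length-2 center, micrometers.
#' @return angle in degrees, or `NA` for a zero displacement (undefined;
#'   callers drop such observations).
#' @export
migrationAngle <- function(positionXy, displacementXy, centerXy) {
  nd <- sqrt(sum(displacementXy^2))
  if (nd == 0) return(NA_real_)
  u <- c(centerXy[1] - positionXy[1], centerXy[2] - positionXy[2])
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(NA_real_)
  cosang <- sum(displacementXy * u) / (nd * nu)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Collect migration angles for one condition and epoch
#'
#' Full windowed-angle workflow: find the inducible-cell center, select
#' neighbors in the square window, take non-overlapping interval
#' displacements within the epoch, and convert each to an angle relative
#' to the center.  Zero displacements are dropped (logged in the result's
#' attributes).
#'
#' @param tracks tracking table.
#' @param epochMin length-2 time window in minutes.
#' @param condition,epoch labels stored in the returned [AngleSample].
#' @param intervalMin displacement interval, minutes.
#' @param halfWidthUm neighbor-selection window half-width, micrometers.
#' @param centerXy optional precomputed center; default the inducible
#'   centroid at the epoch start frame.
#' @return an [AngleSample]; attribute `dropped` counts zero-displacement
#'   observations.
#' @export
collectAngles <- function(tracks, epochMin, condition = "cond",
                          epoch = "after", intervalMin = 20,
                          halfWidthUm = 100, centerXy = NULL) {
  frames <- tracks$frame[tracks$time_min >= epochMin[1]]
  if (!length(frames)) stop("epoch contains no frames")
  refFrame <- min(frames)
  if (is.null(centerXy)) centerXy <- findInducibleCenter(tracks, refFrame)
  sub <- selectNeighborsInWindow(tracks, centerXy, halfWidthUm, refFrame)
  angles <- numeric(0); cells <- character(0); dropped <- 0L
  for (id in unique(sub$cell_id)) {
    disp <- intervalDisplacements(sub[sub$cell_id == id, , drop = FALSE],
                                  intervalMin, epochMin)
    for (k in seq_len(nrow(disp))) {
      a <- migrationAngle(c(disp$x_um[k], disp$y_um[k]),
                          c(disp$dx_um[k], disp$dy_um[k]), centerXy)
      if (is.na(a)) dropped <- dropped + 1L
      else { angles <- c(angles, a); cells <- c(cells, id) }
    }
  }
  out <- new("AngleSample", condition = condition, epoch = epoch,
             anglesDeg = angles, nCells = length(unique(cells)))
  attr(out, "dropped") <- dropped
  out
}

#' Radial histogram of migration angles
#'
#' Equal-width bins over `[0, 180]` degrees, right-open except the last
#' bin; counts always sum to the number of observations.
#'
#' @param sample an [AngleSample].
#' @param nBins number of bins (>= 2).
#' @return data.frame with `bin_lo_deg`, `bin_hi_deg`, `count`.
#' @export
radialHistogram <- function(sample, nBins = 12) {
  stopifnot(nBins >= 2)
  a <- angles(sample)
  edges <- seq(0, 180, length.out = nBins + 1)
  idx <- pmin(findInterval(a, edges, rightmost.closed = TRUE), nBins)
  counts <- tabulate(idx, nbins = nBins)
  data.frame(bin_lo_deg = edges[-length(edges)], bin_hi_deg = edges[-1],
             count = counts)
}

#' Subsampled two-sample Kolmogorov-Smirnov test
#'
#' Significance procedure for very large angle samples, where a classical
#' KS test is overpowered: in each of `nIter` iterations a fixed-size
#' subsample is drawn without replacement independently from each group, a
#' two-sample KS test is computed, and the median p-value over iterations
#' is reported with star coding.  When a group is smaller than `nSub` the
#' whole group is used.  With `nIter = 1` and `nSub` at least both sample
#' sizes the procedure reduces to the classical two-sample KS test.
#'
#' @param a,b [AngleSample] objects (or bare numeric vectors of angles).
#' @param nIter number of subsampling iterations.
#' @param nSub subsample size per group.
#' @param seed integer seed for reproducible subsampling; iteration seeds
#'   are derived from it.
#' @return a [SubsamplingKSResult].
#' @export
#' @examples
#' a <- runif(3000, 0, 180); b <- runif(3000, 0, 180)
#' medianP(subsampledKsTest(a, b, nIter = 50, nSub = 500, seed = 1))
subsampledKsTest <- function(a, b, nIter = 1000, nSub = 1000, seed = NULL) {
  av <- if (is(a, "AngleSample")) angles(a) else as.numeric(a)
  bv <- if (is(b, "AngleSample")) angles(b) else as.numeric(b)
  if (!length(av) || !length(bv)) stop("both samples must be non-empty")
  nA <- min(nSub, length(av)); nB <- min(nSub, length(bv))
  withSeed(seed, {
    D <- numeric(nIter); P <- numeric(nIter)
    for (i in seq_len(nIter)) {
      sa <- if (nA < length(av)) av[sample.int(length(av), nA)] else av
      sb <- if (nB < length(bv)) bv[sample.int(length(bv), nB)] else bv
      kt <- suppressWarnings(stats::ks.test(sa, sb, exact = FALSE))
      D[i] <- unname(kt$statistic); P[i] <- kt$p.value
    }
    mp <- stats::median(P)
    new("SubsamplingKSResult", medianP = mp, nIterations = as.integer(nIter),
        subsampleSize = as.integer(c(nA, nB)), statD = D, pValues = P,
        stars = pStars(mp))
  })
}
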