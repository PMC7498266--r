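# Independent oracles used to freeze expected values.  These deliberately
# share no code with the package implementation.

# Brute-force peak scan for noiseless traces: raw local maxima (ties
# toward the earlier frame), rise from the raw minimum since the previous
# local maximum, slope, and a subsequent fall before the trace end.
oraclePeakScan <- function(t, x, minAmplitude = 0.15, minSlope = 0.005,
                           fallFraction = 0.5) {
  n <- length(x)
  isMax <- logical(n)
  for (i in 2:(n - 1))
    isMax[i] <- x[i] > x[i - 1] && x[i] >= x[i + 1]
  maxIdx <- which(isMax)
  count <- 0L; times <- numeric(0)
  prevMax <- 0L
  for (i in maxIdx) {
    seg <- (prevMax + 1L):i
    vmin <- min(x[seg])
    rise <- x[i] - vmin
    # onset: last pre-apex frame within 10% of the rise above the valley
    on <- seg[x[seg] <= vmin + 0.1 * rise]
    j <- if (length(on)) max(on) else seg[which.min(x[seg])]
    slope <- if (t[i] > t[j]) rise / (t[i] - t[j]) else 0
    fall <- x[i] - min(x[i:n])
    if (rise > minAmplitude && slope > minSlope &&
        fall >= fallFraction * rise) {
      count <- count + 1L
      times <- c(times, t[i])
    }
    prevMax <- i
  }
  list(count = count, times = times)
}

# Dense grid search for the least-squares Gaussian profile fit: for each
# (mu, sigma) on a grid, amplitude and offset are solved by linear least
# squares; coarse-to-fine refinement down to 0.005 um.
oracleGridGaussian <- function(z, y) {
  rssAt <- function(mu, sg) {
    g <- exp(-(z - mu)^2 / (2 * sg^2))
    X <- cbind(g, 1)
    beta <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                     error = function(e) NULL)
    if (is.null(beta)) return(Inf)
    sum((y - X %*% beta)^2)
  }
  best <- c(mu = mean(z), sg = diff(range(z)) / 4)
  stepMu <- 0.5; stepSg <- 0.25
  muGrid <- seq(min(z), max(z), by = stepMu)
  sgGrid <- seq(0.5, diff(range(z)) / 2, by = stepSg)
  rss <- outer(muGrid, sgGrid, Vectorize(rssAt))
  k <- arrayInd(which.min(rss), dim(rss))
  best <- c(mu = muGrid[k[1]], sg = sgGrid[k[2]])
  for (res in c(0.05, 0.005)) {
    muGrid <- seq(best["mu"] - 5 * res * 10, best["mu"] + 5 * res * 10,
                  by = res)
    sgGrid <- seq(max(0.1, best["sg"] - 5 * res * 10),
                  best["sg"] + 5 * res * 10, by = res)
    rss <- outer(muGrid, sgGrid, Vectorize(rssAt))
    k <- arrayInd(which.min(rss), dim(rss))
    best <- c(mu = muGrid[k[1]], sg = sgGrid[k[2]])
  }
  list(mean = unname(best["mu"]), sigma = unname(best["sg"]))
}

# Construct an ActivityTrace directly from time/ratio vectors.
makeTrace <- function(t, x, id = "cell", coverage = 1,
                      flags = character(0)) {
  new("ActivityTrace", cellId = id, timeMin = as.numeric(t),
      ratio = as.numeric(x), coverage = coverage, flags = flags)
}

# Noiseless multi-pulse template trace with known apex times.
makePulseTrace <- function(peakTimes, amplitude = 0.5, widthMin = 25,
                           baseline = 1, durationMin = 360,
                           frameIntervalMin = 5) {
  t <- seq(0, durationMin, by = frameIntervalMin)
  s <- widthMin / (2 * sqrt(2 * log(2)))
  y <- rep(baseline, length(t))
  for (tp in peakTimes) y <- y + amplitude * exp(-(t - tp)^2 / (2 * s^2))
  makeTrace(t, y)
}
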