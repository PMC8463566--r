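#' Melting temperature from a thermal-shift melt curve
#'
#' Tm is the temperature at the maximum of the first derivative of the melt
#' curve. The fluorescence trace is smoothed by a centred moving average of
#' `smoothingWidth` points, differentiated by central differences, and the
#' peak position is refined by parabolic interpolation through the three
#' points around the discrete maximum. A derivative maximum sitting on a
#' scan boundary is flagged unreliable (no transition inside the scan).
#'
#' @param temperature Strictly increasing temperature grid (degrees C), at
#'   least 20 points.
#' @param fluorescence Fluorescence readings (AU).
#' @param smoothingWidth Moving-average width in points, odd (default 5).
#' @return List with `tm` (degrees C) and `boundary` (logical flag).
#' @export
estimateTm <- function(temperature, fluorescence, smoothingWidth = 5) {
  stopifnot(length(temperature) == length(fluorescence),
            length(temperature) >= 20, all(diff(temperature) > 0),
            smoothingWidth >= 1)
  if (smoothingWidth %% 2 == 0) smoothingWidth <- smoothingWidth + 1
  sm <- if (smoothingWidth > 1) {
    as.numeric(stats::filter(fluorescence,
                             rep(1 / smoothingWidth, smoothingWidth),
                             sides = 2))
  } else {
    fluorescence
  }
  ok <- which(!is.na(sm))
  t <- temperature[ok]
  y <- sm[ok]
  n <- length(t)
  # central differences on the interior, then smooth the derivative with the
  # same moving average: the raw derivative amplifies reader noise
  d <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  td <- t[2:(n - 1)]
  if (smoothingWidth > 1 && length(d) > smoothingWidth) {
    ds <- as.numeric(stats::filter(d, rep(1 / smoothingWidth,
                                          smoothingWidth), sides = 2))
    keep <- !is.na(ds)
    d <- ds[keep]
    td <- td[keep]
  }
  i <- which.max(d)
  # flat traces have no transition: the derivative peak is meaningless
  flat <- (max(d) - min(d)) <=
    1e-6 * (abs(max(d)) + abs(min(d)) + .Machine$double.eps)
  boundary <- flat || i == 1L || i == length(d)
  tm <- td[i]
  if (!boundary) {
    # parabola through (i-1, i, i+1) for sub-grid peak location
    denom <- d[i - 1] - 2 * d[i] + d[i + 1]
    if (abs(denom) > .Machine$double.eps) {
      shift <- 0.5 * (d[i - 1] - d[i + 1]) / denom
      shift <- max(min(shift, 1), -1)
      tm <- td[i] + shift * (td[min(i + 1, length(td))] - td[i])
    }
  }
  list(tm = tm, boundary = boundary)
}

#' Tm estimates and delta-Tm for replicate melt curves
#'
#' @param meltData data.frame with columns `enzyme`, `variant`, `replicate`,
#'   `temperature_c`, `fluorescence`.
#' @param wtVariant Label of the wild-type variant (default "WT").
#' @param smoothingWidth Passed to [estimateTm()].
#' @return data.frame with `enzyme`, `variant`, `replicate`, `tm`,
#'   `boundary`, `delta_tm` (vs the same enzyme's wild-type replicate mean;
#'   NA when no wild type was measured).
#' @export
estimateTmSet <- function(meltData, wtVariant = "WT", smoothingWidth = 5) {
  key <- interaction(meltData$enzyme, meltData$variant, meltData$replicate,
                     drop = TRUE)
  rows <- lapply(split(meltData, key), function(d) {
    est <- estimateTm(d$temperature_c, d$fluorescence, smoothingWidth)
    data.frame(enzyme = d$enzyme[1], variant = d$variant[1],
               replicate = d$replicate[1], tm = est$tm,
               boundary = est$boundary)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$delta_tm <- NA_real_
  for (e in unique(out$enzyme)) {
    wtMean <- mean(out$tm[out$enzyme == e & out$variant == wtVariant])
    out$delta_tm[out$enzyme == e] <- out$tm[out$enzyme == e] - wtMean
  }
  out
}

#' Classify folding from replicate melting temperatures
#'
#' A variant is `"unchanged"` when the mean shift from the wild-type mean is
#' below `threshold` (1 degree C by default) in absolute value, or when a
#' Welch test against the wild-type replicate Tms is not significant;
#' otherwise the sign of the mean shift decides between `"destabilized"` and
#' `"stabilized"`.
#'
#' @param mutantTms,wtTms Replicate Tm vectors (degrees C), at least 3 each.
#' @param threshold Minimum |mean delta-Tm| (default 1).
#' @param alpha Welch-test level (default 0.05).
#' @return List with `class`, `mean_delta_tm`, `p_value`.
#' @export
classifyFolding <- function(mutantTms, wtTms, threshold = 1, alpha = 0.05) {
  stopifnot(length(mutantTms) >= 3, length(wtTms) >= 3)
  deltas <- mutantTms - mean(wtTms)
  wt <- welchTest(mutantTms, wtTms)
  cls <- if (abs(mean(deltas)) < threshold || wt$p_value >= alpha) {
    "unchanged"
  } else if (mean(deltas) < 0) "destabilized" else "stabilized"
  list(class = cls, mean_delta_tm = mean(deltas), p_value = wt$p_value)
}

#' Initial reaction rate from a kinetic trace
#'
#' Slope of the early linear phase: over windows anchored at the first
#' point with at least `minPoints` readings, the window with the best R^2 is
#' chosen (ties resolved toward the longest window, to use as much of the
#' linear phase as possible) and its OLS slope is divided by the protein
#' concentration. Sign is preserved (substrate decrease gives a negative
#' rate, product formation a positive one). A trace whose best window has
#' R^2 below `r2Min` is flagged unreliable.
#'
#' @param time Time grid (min), strictly increasing.
#' @param signal Absorbance readings (AU).
#' @param proteinConc Protein concentration (mg/mL), > 0.
#' @param minPoints Minimum window size (default 5).
#' @param r2Min Minimum acceptable window R^2 (default 0.9).
#' @return List with `rate` (AU/min per mg/mL), `r_squared`, `window`
#'   (c(t_start, t_end)), `unreliable`.
#' @export
initialRate <- function(time, signal, proteinConc, minPoints = 5,
                        r2Min = 0.9) {
  proteinConc <- unique(proteinConc)
  stopifnot(length(time) == length(signal), length(proteinConc) == 1L,
            proteinConc > 0, all(diff(time) > 0))
  n <- length(time)
  if (n < minPoints) stop("need >= ", minPoints, " points")
  ends <- seq(minPoints, n)
  stats <- vapply(ends, function(j) {
    t <- time[1:j]; y <- signal[1:j]
    sxx <- sum((t - mean(t))^2)
    sxy <- sum((t - mean(t)) * (y - mean(y)))
    syy <- sum((y - mean(y))^2)
    slope <- sxy / sxx
    r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 0
    c(slope, r2)
  }, numeric(2))
  r2 <- stats[2, ]
  best <- max(r2)
  j <- max(which(r2 >= best - 1e-12))
  list(rate = stats[1, j] / proteinConc,
       r_squared = r2[j],
       window = c(time[1], time[ends[j]]),
       unreliable = best < r2Min)
}

#' Relative enzymatic activity of a mutant
#'
#' Mean mutant initial rate divided by the mean wild-type rate, with the
#' standard deviation propagated by the delta method and a Welch p-value on
#' the replicate rates.
#'
#' @param mutantRates,wtRates Replicate initial rates, at least 3 each.
#' @return List with `ratio`, `sd`, `p_value`.
#' @export
relativeActivity <- function(mutantRates, wtRates) {
  stopifnot(length(mutantRates) >= 3, length(wtRates) >= 3)
  mw <- mean(wtRates)
  if (abs(mw) < .Machine$double.eps^0.5 * max(abs(wtRates), 1)) {
    stop("wild-type inactive: mean wild-type rate is ~0")
  }
  mm <- mean(mutantRates)
  ratio <- mm / mw
  # delta-method propagation; for a dead mutant (mean 0) the relative term
  # degenerates, so fall back to the mutant sd scaled by the wild-type mean
  sdProp <- if (mm == 0) sd(mutantRates) / abs(mw) else
    abs(ratio) * sqrt((sd(mutantRates) / mm)^2 + (sd(wtRates) / mw)^2)
  wt <- welchTest(mutantRates, wtRates)
  list(ratio = ratio, sd = sdProp, p_value = wt$p_value)
}
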