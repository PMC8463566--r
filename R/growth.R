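#' Fit an exponential growth rate to one OD600 curve
#'
#' Rolling-regression estimate of the maximum specific growth rate:
#' ordinary least squares on (time, ln OD) over sliding windows of at least
#' `minWindowPoints` consecutive readings spanning at least `minWindowSpan`
#' hours. Among the windows whose R^2 comes within `r2Tolerance` of the
#' best achieved R^2, the steepest (maximum-slope) window is selected, with
#' ties going to the earliest window. The R^2 screen rejects windows that
#' mix growth phases or are noise-dominated; the slope criterion then picks
#' the exponential phase rather than a smooth but already saturating
#' stretch of the curve, whose near-perfect linearity would otherwise win.
#' Readings at or below `odFloor` are discarded before the log transform
#' (blank-well noise). On a noiseless exponential every window is eligible
#' and has the same slope, so the fit is exact.
#'
#' @param time Numeric vector of times (h), strictly increasing.
#' @param od Numeric vector of OD600 readings.
#' @param minWindowPoints Minimum readings per window (default 12, two
#'   hours at the standard 10-min sampling interval).
#' @param minWindowSpan Minimum window span in hours (default 1).
#' @param odFloor OD600 readings at or below this are dropped (default 0.01).
#' @param r2Tolerance Windows with R^2 within this margin of the maximum
#'   compete on slope (default 0.01).
#' @return List with `mu` (1/h), `window` (c(t_start, t_end)), `r_squared`,
#'   `n_points` and `low_r2` (TRUE when the best window has R^2 < 0.95).
#' @examples
#' t <- seq(0, 6, by = 1/6)
#' fitGrowthRate(t, 0.05 * exp(0.6 * t))$mu # 0.6
#' @export
fitGrowthRate <- function(time, od, minWindowPoints = 12, minWindowSpan = 1,
                          odFloor = 0.01, r2Tolerance = 0.01) {
  stopifnot(length(time) == length(od))
  keep <- is.finite(od) & od > odFloor
  t <- time[keep]
  y <- log(od[keep])
  n <- length(t)
  if (n < minWindowPoints) {
    stop("no-growth/insufficient-data: ", n, " usable points after flooring (",
         minWindowPoints, " required)")
  }
  # all windows [i, j] with at least minWindowPoints points, in
  # (start, end) order so the first maximum is the earliest window
  starts <- rep(seq_len(n - minWindowPoints + 1L),
                times = (n - minWindowPoints + 1L):1L)
  ends <- unlist(lapply(seq_len(n - minWindowPoints + 1L),
                        function(i) seq(i + minWindowPoints - 1L, n)))
  span <- t[ends] - t[starts]
  if (any(span >= minWindowSpan)) {
    starts <- starts[span >= minWindowSpan]
    ends <- ends[span >= minWindowSpan]
  }
  cs <- function(v) cumsum(c(0, v))
  Sx <- cs(t); Sy <- cs(y); Sxx <- cs(t * t); Syy <- cs(y * y); Sxy <- cs(t * y)
  nn <- ends - starts + 1L
  sx <- Sx[ends + 1L] - Sx[starts]
  sy <- Sy[ends + 1L] - Sy[starts]
  sxx <- Sxx[ends + 1L] - Sxx[starts]
  syy <- Syy[ends + 1L] - Syy[starts]
  sxy <- Sxy[ends + 1L] - Sxy[starts]
  ssx <- nn * sxx - sx^2
  ssy <- nn * syy - sy^2
  sxyc <- nn * sxy - sx * sy
  slope <- ifelse(ssx > 0, sxyc / ssx, 0)
  r2 <- ifelse(ssx > 0 & ssy > .Machine$double.eps * abs(syy),
               sxyc^2 / (ssx * ssy), 0)
  eligible <- which(r2 >= max(r2) - r2Tolerance)
  best <- eligible[which(
    slope[eligible] >= max(slope[eligible]) - 1e-9)[1L]]
  list(mu = slope[best],
       window = c(t[starts[best]], t[ends[best]]),
       r_squared = r2[best],
       n_points = nn[best],
       low_r2 = r2[best] < 0.95)
}

#' Fit growth rates for every replicate curve in a set
#'
#' @param gcs A [GrowthCurveSet-class].
#' @inheritParams fitGrowthRate
#' @return data.frame with columns `strain`, `condition`, `replicate`, `mu`,
#'   `t_start`, `t_end`, `r_squared`, `n_points`, `low_r2`, `failed`. Curves
#'   with too few usable points (no-growth wells) get `failed = TRUE` and
#'   `mu = NA`.
#' @export
fitGrowthRates <- function(gcs, minWindowPoints = 12, minWindowSpan = 1,
                           odFloor = 0.01, r2Tolerance = 0.01) {
  cc <- growthCurves(gcs)
  key <- interaction(cc$strain, cc$condition, cc$replicate, drop = TRUE)
  rows <- lapply(split(cc, key), function(d) {
    fit <- tryCatch(
      fitGrowthRate(d$time_h, d$od600, minWindowPoints, minWindowSpan,
                    odFloor, r2Tolerance),
      error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(strain = d$strain[1], condition = d$condition[1],
                 replicate = d$replicate[1], mu = NA_real_,
                 t_start = NA_real_, t_end = NA_real_,
                 r_squared = NA_real_, n_points = 0L, low_r2 = NA,
                 failed = TRUE)
    } else {
      data.frame(strain = d$strain[1], condition = d$condition[1],
                 replicate = d$replicate[1], mu = fit$mu,
                 t_start = fit$window[1], t_end = fit$window[2],
                 r_squared = fit$r_squared, n_points = fit$n_points,
                 low_r2 = fit$low_r2, failed = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare mutant growth rates to the wild type
#'
#' Welch two-sample t-test on replicate growth rates plus the headline rule:
#' a phenotype is significant when the relative rate differs from 1 by at
#' least `minChange` (strictly more when `changeOp = ">"`) and p < `alpha`.
#'
#' @param mutantMus,wtMus Numeric vectors of replicate growth rates (1/h),
#'   at least 2 each.
#' @param alpha Significance level (default 0.05).
#' @param minChange Minimum relative change (default 0.10).
#' @param changeOp Comparison operator for the change rule, `">="` (default)
#'   or `">"`.
#' @return List with `relative_rate`, `p_value`, `significant`, `n_mutant`,
#'   `n_wt`.
#' @export
compareToWildtype <- function(mutantMus, wtMus, alpha = 0.05,
                              minChange = 0.10, changeOp = c(">=", ">")) {
  changeOp <- match.arg(changeOp)
  wt <- welchTest(mutantMus, wtMus)
  rel <- wt$mean_x / wt$mean_y
  change <- abs(rel - 1)
  # tiny epsilon so that an exact 10% change is classified by the operator,
  # not by floating-point representation error
  eps <- 1e-9
  bigEnough <- if (changeOp == ">=") change >= minChange - eps else
    change > minChange + eps
  list(relative_rate = rel, p_value = wt$p_value,
       significant = bigEnough && wt$p_value < alpha,
       n_mutant = length(mutantMus), n_wt = length(wtMus))
}

#' Growth comparisons for every mutant strain and condition
#'
#' Pools replicate growth-rate estimates per strain and condition and runs
#' [compareToWildtype()] against the wild-type strain of the same condition.
#' A strain whose every replicate curve failed to fit while the wild type
#' grew is flagged `lethal` with relative rate 0 and counted significant
#' (condition-specific lethality is the strongest growth phenotype).
#'
#' @param estimates data.frame from [fitGrowthRates()].
#' @param wtStrain Wild-type strain label (default "WT").
#' @inheritParams compareToWildtype
#' @return data.frame with one row per mutant strain x condition.
#' @export
growthComparisons <- function(estimates, wtStrain = "WT", alpha = 0.05,
                              minChange = 0.10, changeOp = c(">=", ">")) {
  changeOp <- match.arg(changeOp)
  rows <- list()
  for (cond in unique(estimates$condition)) {
    est <- estimates[estimates$condition == cond, ]
    wtMus <- est$mu[est$strain == wtStrain & !est$failed]
    if (length(wtMus) < 2L) {
      stop("need >= 2 wild-type replicate fits in condition ", cond)
    }
    for (s in setdiff(unique(est$strain), wtStrain)) {
      mus <- est$mu[est$strain == s & !est$failed]
      nCurves <- sum(est$strain == s)
      if (length(mus) == 0L && nCurves > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          strain = s, condition = cond, relative_rate = 0,
          p_value = 0, significant = TRUE, lethal = TRUE,
          n_mutant = 0L, n_wt = length(wtMus))
        next
      }
      if (length(mus) < 2L) next
      cmp <- compareToWildtype(mus, wtMus, alpha, minChange, changeOp)
      rows[[length(rows) + 1L]] <- data.frame(
        strain = s, condition = cond, relative_rate = cmp$relative_rate,
        p_value = cmp$p_value, significant = cmp$significant, lethal = FALSE,
        n_mutant = cmp$n_mutant, n_wt = cmp$n_wt)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Site-level growth-phenotype matrix
#'
#' Maps strain-level growth comparisons onto phosphosites and reports, per
#' site, whether any of its mutants shows a significant growth phenotype in
#' at least one condition (OR over mutant types and conditions), together
#' with the full per-mutant per-condition grid.
#'
#' @param comparisons data.frame from [growthComparisons()].
#' @param siteTable data.frame with columns `site_id`, `strain`,
#'   `mutant_type` (values "mimetic"/"abolishing"; knockout strains are not
#'   part of the site-level OR).
#' @return List with `sites` (data.frame `site_id`, `phenotype`; `NA` means
#'   not determined) and `grid` (comparisons joined with site annotation).
#' @export
phenotypeMatrix <- function(comparisons, siteTable) {
  grid <- merge(siteTable, comparisons, by = "strain")
  sites <- unique(siteTable$site_id)
  flag <- vapply(sites, function(sid) {
    g <- grid[grid$site_id == sid, ]
    if (nrow(g) == 0L) NA else any(g$significant)
  }, logical(1))
  list(sites = data.frame(site_id = sites, phenotype = unname(flag)),
       grid = grid)
}
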