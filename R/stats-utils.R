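#' Welch two-sample t-test with degenerate conventions
#'
#' Two-sided two-sample t-test assuming unequal variances
#' (Welch-Satterthwaite degrees of freedom). When both groups have zero
#' variance the test statistic is undefined; by convention p = 1 if the
#' means are equal and p = 0 if they differ (a deterministic difference).
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return List with `statistic`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
welchTest <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("welchTest needs at least 2 finite values per group")
  }
  mx <- mean(x); my <- mean(y)
  vx <- var(x); vy <- var(y)
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    p <- if (mx == my) 1 else 0
    return(list(statistic = if (mx == my) 0 else Inf * sign(mx - my),
                df = NA_real_, p_value = p, mean_x = mx, mean_y = my))
  }
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = tstat, df = df, p_value = 2 * pt(-abs(tstat), df),
       mean_x = mx, mean_y = my)
}

# Row-wise Welch test for an ions x samples matrix split into two groups.
# Same degenerate conventions as welchTest. Returns a data.frame.
.rowWelch <- function(xmat, ymat) {
  nx <- ncol(xmat); ny <- ncol(ymat)
  mx <- rowMeans(xmat); my <- rowMeans(ymat)
  vx <- rowSums((xmat - mx)^2) / (nx - 1)
  vy <- rowSums((ymat - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(tstat), df)
  degen <- se2 == 0
  if (any(degen)) {
    p[degen] <- ifelse(mx[degen] == my[degen], 1, 0)
    tstat[degen] <- ifelse(mx[degen] == my[degen], 0, Inf)
    df[degen] <- NA_real_
  }
  data.frame(statistic = tstat, df = df, p_value = p,
             mean_x = mx, mean_y = my)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks (midranks for ties) are correlated with Pearson's formula;
#' the two-sided p-value uses the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearmanCorrelation <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("spearmanCorrelation needs at least 3 complete pairs")
  rho <- cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
  if (is.na(rho)) return(list(rho = NA_real_, p_value = NA_real_, n = n))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}
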