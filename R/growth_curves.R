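#' Maximal growth rate from an optical-density time series
#'
#' For every window of 5 consecutive measurements, the growth rate is the
#' least-squares slope of log2(OD) against time; the reported maximal rate is
#' the 98th percentile (linear interpolation between order statistics) of the
#' window rates, which is robust to single-point outliers that would corrupt
#' the plain maximum.
#'
#' @param time_h Measurement times in hours (strictly increasing).
#' @param od Optical densities, same length as \code{time_h} (at least 5
#'   points); values are floored at \code{floor} before the log.
#' @param window Window width in points (default 5).
#' @param prob Percentile of window rates reported (default 0.98).
#' @param floor OD floor applied before the log (default 1e-3).
#' @return List with \code{rate} (log2 OD per hour) and \code{n_windows}.
#' @export
max_growth_rate <- function(time_h, od, window = 5L, prob = 0.98,
                            floor = 1e-3) {
  n <- length(time_h)
  if (length(od) != n) stop("time_h and od must have equal length")
  if (n < window) stop("need at least ", window, " points")
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  y <- log2(pmax(od, floor))
  n_win <- n - window + 1L
  slopes <- numeric(n_win)
  for (i in seq_len(n_win)) {
    idx <- i:(i + window - 1L)
    tt <- time_h[idx]
    yy <- y[idx]
    slopes[i] <- sum((tt - mean(tt)) * (yy - mean(yy))) /
      sum((tt - mean(tt))^2)
  }
  list(rate = unname(quantile(slopes, prob, type = 7)), n_windows = n_win)
}

#' Growth rates for a long-format OD table
#'
#' @param od_df Data.frame with columns \code{strain}, \code{condition},
#'   \code{replicate}, \code{time_h}, \code{od}.
#' @param ... Passed to \code{\link{max_growth_rate}}.
#' @return Data.frame with one row per strain x condition x replicate:
#'   \code{rate}, \code{n_windows}.
#' @export
growth_rates <- function(od_df, ...) {
  grp <- paste(od_df$strain, od_df$condition, od_df$replicate, sep = "\r")
  res <- do.call(rbind, lapply(split(od_df, grp), function(g) {
    g <- g[order(g$time_h), ]
    r <- max_growth_rate(g$time_h, g$od, ...)
    data.frame(strain = g$strain[1L], condition = g$condition[1L],
               replicate = g$replicate[1L], rate = r$rate,
               n_windows = r$n_windows, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Fragment interaction score from growth rates
#'
#' Normalizes a strain's growth rate by the rate of the matched control strain
#' carrying the same binding domain but no prey fragment. The default is the
#' plain ratio; a difference convention is available.
#'
#' @param rate_strain Growth rate(s) of the fragment strain.
#' @param rate_control Growth rate of the no-fragment control (> 0 for the
#'   ratio convention).
#' @param method \code{"ratio"} (default) or \code{"difference"}.
#' @return Normalized interaction score(s).
#' @export
fragment_interaction_score <- function(rate_strain, rate_control,
                                       method = c("ratio", "difference")) {
  method <- match.arg(method)
  if (method == "ratio") {
    if (any(rate_control <= 0)) stop("control rate must be positive")
    rate_strain / rate_control
  } else {
    rate_strain - rate_control
  }
}

#' Compare growth rates between two groups (Student's t)
#'
#' One-sided or two-sided equal-variance Student's t-test of replicate growth
#' rates; family-wise BH adjustment is left to the caller (or use the
#' data.frame interface \code{\link{compare_growth_table}}).
#'
#' @param x,y Numeric vectors of replicate rates (>= 2 each).
#' @param alternative \code{"two.sided"}, \code{"less"} or \code{"greater"}
#'   (x relative to y).
#' @return List with \code{t} and \code{p}.
#' @export
compare_growth <- function(x, y, alternative = c("two.sided", "less",
                                                 "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 replicates per group")
  tt <- t.test(x, y, alternative = alternative, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' @rdname compare_growth
#' @param rates Data.frame with columns \code{strain} and \code{rate}.
#' @param reference Reference strain name.
#' @param alpha Significance level applied after BH adjustment.
#' @export
compare_growth_table <- function(rates, reference,
                                 alternative = c("two.sided", "less",
                                                 "greater"), alpha = 0.05) {
  alternative <- match.arg(alternative)
  if (!reference %in% rates$strain) stop("reference strain not found")
  ref <- rates$rate[rates$strain == reference]
  groups <- split(rates$rate, rates$strain)
  groups <- groups[names(groups) != reference]
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  res <- do.call(rbind, lapply(names(groups), function(k) {
    ct <- compare_growth(groups[[k]], ref, alternative)
    data.frame(strain = k, n = length(groups[[k]]), t = ct$t, p = ct$p,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- bh_fdr(res$p)
  res$significant <- res$p_adj < alpha
  res
}
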