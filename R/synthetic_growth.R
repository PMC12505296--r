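#' Simulate an optical-density growth trajectory
#'
#' Exponential growth at a constant rate on the log2 scale, capped at a
#' carrying capacity, with additive Gaussian measurement noise and a small
#' positive floor (blank-corrected readings can dip below zero):
#' \code{OD(t) = min(od0 * 2^(rate * t), capacity) + noise}, floored.
#'
#' @param rate Growth rate in log2 OD per hour (>= 0).
#' @param od0 Initial optical density (> 0; default 0.05).
#' @param duration_h Duration in hours (default 72, the standard plate-reader
#'   run).
#' @param interval_min Measurement interval in minutes (default 15).
#' @param noise_sd Measurement noise: with \code{noise_type = "proportional"}
#'   (default) the coefficient of variation (sd as a fraction of the current
#'   OD); with \code{"absolute"} the sd in OD units. Default 0.
#' @param noise_type Noise convention (see \code{noise_sd}).
#' @param capacity Carrying capacity (default 1.5 OD).
#' @param floor Lower bound applied after adding noise (default 1e-3).
#' @param seed Optional integer seed.
#' @return Data.frame with columns \code{time_h} and \code{od}.
#' @export
simulate_od <- function(rate, od0 = 0.05, duration_h = 72,
                        interval_min = 15, noise_sd = 0,
                        noise_type = c("proportional", "absolute"),
                        capacity = 1.5, floor = 1e-3, seed = NULL) {
  noise_type <- match.arg(noise_type)
  if (rate < 0) stop("rate must be >= 0")
  if (od0 <= 0) stop("od0 must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483647L)
  t <- seq(0, duration_h, by = interval_min / 60)
  od <- pmin(od0 * 2^(rate * t), capacity)
  if (noise_sd > 0) {
    sd <- if (noise_type == "proportional") noise_sd * od else noise_sd
    od <- od + rnorm(length(t), 0, sd)
  }
  data.frame(time_h = t, od = pmax(od, floor))
}

#' Simulate a colony-array PCA plate set
#'
#' Builds 1,536-format (or any rows x columns) colony grids: the outer
#' \code{border} rows and columns carry a well-growing control pair (as on
#' real arrays, to absorb edge effects), and interior positions carry the
#' supplied bait/prey pairs in equal numbers in a seeded random arrangement
#' (arrays are randomized so position effects do not alias with particular
#' interactions). Colony size is an exponential-scale signal,
#' \code{size = base * 2^true_score * row_bias * col_bias * plate_factor *
#' noise}, with multiplicative log-normal noise.
#'
#' @param true_scores Data.frame with columns \code{bait}, \code{prey},
#'   \code{score} (log2-scale planted interaction strengths).
#' @param n_plates Number of plates (default 1).
#' @param n_row,n_col Grid dimensions (default 32 x 48 = 1,536).
#' @param border Width of the control border (default 2).
#' @param plate_factors Multiplicative plate effects, length \code{n_plates}
#'   (default all 1).
#' @param row_bias_sd,col_bias_sd Standard deviation (log2 units) of
#'   per-row/per-column multiplicative position biases (default 0).
#' @param noise_sd Standard deviation (log2 units) of per-colony noise
#'   (default 0).
#' @param fail_rate Probability that a colony fails diploid selection
#'   (\code{grew = FALSE}, size 0; default 0).
#' @param base_size Baseline colony size in arbitrary units (default 256).
#' @param seed Optional integer seed.
#' @return Data.frame with columns \code{plate}, \code{row}, \code{col},
#'   \code{bait}, \code{prey}, \code{size}, \code{border}, \code{grew}.
#' @export
simulate_colony_grid <- function(true_scores, n_plates = 1L, n_row = 32L,
                                 n_col = 48L, border = 2L,
                                 plate_factors = rep(1, n_plates),
                                 row_bias_sd = 0, col_bias_sd = 0,
                                 noise_sd = 0, fail_rate = 0,
                                 base_size = 256, seed = NULL) {
  stopifnot(all(c("bait", "prey", "score") %in% names(true_scores)))
  if (length(plate_factors) != n_plates)
    stop("plate_factors must have length n_plates")
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483647L)
  out <- vector("list", n_plates)
  n_pairs <- nrow(true_scores)
  for (p in seq_len(n_plates)) {
    g <- expand.grid(row = seq_len(n_row), col = seq_len(n_col))
    g$plate <- p
    g$border <- g$row <= border | g$row > n_row - border |
      g$col <= border | g$col > n_col - border
    g$bait <- "border_control"
    g$prey <- "border_control"
    g$score <- 1  # border control pair grows well
    interior <- which(!g$border)
    pair_idx <- sample(rep_len(seq_len(n_pairs), length(interior)))
    g$bait[interior] <- true_scores$bait[pair_idx]
    g$prey[interior] <- true_scores$prey[pair_idx]
    g$score[interior] <- true_scores$score[pair_idx]
    row_f <- 2^rnorm(n_row, 0, row_bias_sd)
    col_f <- 2^rnorm(n_col, 0, col_bias_sd)
    l2 <- log2(base_size) + g$score + log2(row_f[g$row]) +
      log2(col_f[g$col]) + log2(plate_factors[p]) +
      rnorm(nrow(g), 0, noise_sd)
    g$size <- 2^l2
    g$grew <- runif(nrow(g)) >= fail_rate
    g$size[!g$grew] <- 0
    out[[p]] <- g[c("plate", "row", "col", "bait", "prey", "size", "border",
                    "grew")]
  }
  do.call(rbind, out)
}
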