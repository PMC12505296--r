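#' Filter a colony grid before scoring
#'
#' Removes colonies that failed to grow at the end of diploid selection
#' (assay failures, not weak interactions) and the border control positions.
#'
#' @param grid Colony grid (see \code{\link{simulate_colony_grid}} for
#'   columns).
#' @return Filtered grid; the numbers removed are attached as attributes
#'   \code{n_not_grown} and \code{n_border}.
#' @export
filter_colonies <- function(grid) {
  stopifnot(all(c("grew", "border") %in% names(grid)))
  n_not_grown <- sum(!grid$grew)
  n_border <- sum(grid$border & grid$grew)
  out <- grid[grid$grew & !grid$border, ]
  rownames(out) <- NULL
  attr(out, "n_not_grown") <- n_not_grown
  attr(out, "n_border") <- n_border
  out
}

#' Normalize colony sizes for plate and position bias
#'
#' Colony sizes are log2 transformed (zeros become missing), centered by the
#' plate median, then corrected by row/column median polish within each plate
#' (default one iteration): multiplicative plate, row and column biases become
#' additive offsets on the log2 scale and are removed by the successive median
#' subtractions.
#'
#' @param grid Colony grid with columns \code{plate}, \code{row}, \code{col},
#'   \code{size}.
#' @param iterations Median-polish iterations per plate (default 1).
#' @param min_colonies Plates with fewer usable colonies are skipped with a
#'   warning (their normalized values are \code{NA}; default 8).
#' @return \code{grid} with an added \code{norm_log2} column.
#' @export
normalize_colony_sizes <- function(grid, iterations = 1L, min_colonies = 8L) {
  l2 <- ifelse(grid$size > 0, log2(grid$size), NA_real_)
  out <- rep(NA_real_, nrow(grid))
  for (p in unique(grid$plate)) {
    i <- which(grid$plate == p)
    v <- l2[i]
    if (sum(!is.na(v)) < min_colonies) {
      warning("plate ", p, " has fewer than ", min_colonies,
              " colonies; skipped")
      next
    }
    v <- v - median(v, na.rm = TRUE)
    rows <- grid$row[i]
    cols <- grid$col[i]
    for (k in seq_len(iterations)) {
      rmed <- tapply(v, rows, median, na.rm = TRUE)
      v <- v - rmed[as.character(rows)]
      cmed <- tapply(v, cols, median, na.rm = TRUE)
      v <- v - cmed[as.character(cols)]
    }
    out[i] <- v
  }
  grid$norm_log2 <- unname(out)
  grid
}

#' Rescale normalized colony scores against reference interactions
#'
#' Affine map sending the median of the stuffer (no-binding) reference to 0
#' and the median of the wild-type reference interaction to 1, applied to all
#' records.
#'
#' @param grid Grid with a \code{norm_log2} column
#'   (\code{\link{normalize_colony_sizes}}).
#' @param wt_bait,wt_prey Bait/prey labels of the wild-type reference pair.
#' @param stuffer_prey Prey label of the stuffer control (same bait).
#' @return \code{grid} with an added \code{score} column.
#' @export
rescale_colony_scores <- function(grid, wt_bait = "Sho1", wt_prey = "Pbs2",
                                  stuffer_prey = "Pbs2-stuffer") {
  wt <- grid$norm_log2[grid$bait == wt_bait & grid$prey == wt_prey]
  st <- grid$norm_log2[grid$bait == wt_bait & grid$prey == stuffer_prey]
  if (!length(wt) || !length(st)) stop("reference interactions missing")
  m_wt <- median(wt, na.rm = TRUE)
  m_st <- median(st, na.rm = TRUE)
  if (is.na(m_wt) || is.na(m_st) || m_wt == m_st)
    stop("reference medians missing or coincident")
  grid$score <- (grid$norm_log2 - m_st) / (m_wt - m_st)
  grid
}

#' Filter, normalize and rescale a colony grid
#'
#' Convenience wrapper: \code{\link{filter_colonies}},
#' \code{\link{normalize_colony_sizes}}, \code{\link{rescale_colony_scores}}.
#'
#' @param grid Raw colony grid.
#' @param ... Passed to \code{\link{rescale_colony_scores}}.
#' @param iterations Median-polish iterations (default 1).
#' @return Scored grid.
#' @export
colony_scores <- function(grid, iterations = 1L, ...) {
  rescale_colony_scores(
    normalize_colony_sizes(filter_colonies(grid), iterations = iterations),
    ...)
}

#' Compare each bait to a reference bait
#'
#' Per bait: one-sided Mann-Whitney U test (alternative: scores lower than the
#' reference bait's) on colony scores for the same prey, BH-adjusted across
#' baits.
#'
#' @param scores Scored grid (\code{\link{colony_scores}}).
#' @param reference_bait Reference bait label.
#' @param prey Prey to compare on (default: all records of each bait).
#' @param alpha Significance level (default 0.05).
#' @param min_replicates Minimum scores per bait (default 5).
#' @return Data.frame with \code{bait}, \code{n}, \code{U}, \code{p},
#'   \code{p_adj}, \code{weaker}.
#' @export
compare_baits <- function(scores, reference_bait, prey = NULL, alpha = 0.05,
                          min_replicates = 5L) {
  if (!is.null(prey)) scores <- scores[scores$prey == prey, ]
  if (!reference_bait %in% scores$bait) stop("reference bait missing")
  ref <- scores$score[scores$bait == reference_bait & !is.na(scores$score)]
  groups <- split(scores$score[!is.na(scores$score)],
                  scores$bait[!is.na(scores$score)])
  groups <- groups[names(groups) != reference_bait]
  groups <- groups[vapply(groups, length, 1L) >= min_replicates]
  if (!length(groups))
    return(data.frame(bait = character(0), n = integer(0), U = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      weaker = logical(0)))
  res <- do.call(rbind, lapply(names(groups), function(k) {
    mw <- mann_whitney_u(groups[[k]], ref, alternative = "less")
    data.frame(bait = k, n = length(groups[[k]]), U = mw$U, p = mw$p,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- bh_fdr(res$p)
  res$weaker <- res$p_adj < alpha
  res
}
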