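#' Mann-Whitney U test
#'
#' Rank-sum test with average ranks for ties. The p-value is computed from the
#' exact null distribution of U whenever the data contain no ties (replicate
#' scores are continuous, so this is the usual path and keeps full resolution
#' when a small group is tested against a large pool); with ties it falls back
#' to the normal approximation with tie correction and continuity correction.
#' Delegates to \code{\link[stats]{wilcox.test}}.
#'
#' @param x,y Numeric samples (nonempty).
#' @param alternative \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"} (x relative to y).
#' @return List with \code{U} (the U statistic of \code{x}) and \code{p}.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("samples must be nonempty")
  no_ties <- !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                     exact = no_ties, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: sort p ascending, \code{adj_i = min_{j >= i}
#' (p_j * m / j)} capped at 1, original order restored (delegates to
#' \code{\link[stats]{p.adjust}}).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# replicate-level scores of one class of control variants, split per variant
control_split <- function(scores, class) {
  s <- scores[scores$variant_class == class & scores$pass_count_filter &
                !is.na(scores$scaled_score), ]
  split(s$scaled_score, paste0(s$codon_position, ":", s$mutant_codon))
}

#' Flag aberrant control (nonsense/silent) variants
#'
#' Each nonsense (resp. silent) codon variant is compared to the pooled scores
#' of all other variants of the same class (two-sided Mann-Whitney U test,
#' unadjusted P < alpha, as this screen is applied per variant). Flagged
#' variants are removed from the score dataset and from the rescaling anchors
#' on the second scoring pass.
#'
#' @param scores Score table (\code{\link{score_counts}}).
#' @param alpha Significance level (default 0.05).
#' @param min_scores Minimum replicate-level scores per variant to test
#'   (default 2).
#' @return Data.frame with \code{variant_key}, \code{variant_class}, \code{n},
#'   \code{U}, \code{p}, \code{flagged}. Classes with fewer than two variants
#'   are not tested.
#' @export
flag_control_outliers <- function(scores, alpha = 0.05, min_scores = 2L) {
  out <- list()
  for (cls in c("nonsense", "silent")) {
    groups <- control_split(scores, cls)
    if (length(groups) < 2L) next
    for (k in names(groups)) {
      x <- groups[[k]]
      if (length(x) < min_scores) next
      y <- unlist(groups[setdiff(names(groups), k)], use.names = FALSE)
      mw <- mann_whitney_u(x, y)
      out[[length(out) + 1L]] <- data.frame(
        variant_key = k, variant_class = cls, n = length(x), U = mw$U,
        p = mw$p, flagged = mw$p < alpha, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(variant_key = character(0),
                      variant_class = character(0), n = integer(0),
                      U = numeric(0), p = numeric(0), flagged = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# replicate-level scaled scores per missense amino-acid change
missense_split <- function(scores) {
  s <- scores[scores$variant_class == "missense" & scores$pass_count_filter &
                !is.na(scores$scaled_score), ]
  split(s$scaled_score, s$aa_change_key)
}

pooled_class_scores <- function(scores, classes) {
  s <- scores[scores$variant_class %in% classes & scores$pass_count_filter &
                !is.na(scores$scaled_score), ]
  s$scaled_score
}

#' Flag mutants with growth defects in the no-methotrexate control
#'
#' In the methotrexate-free control (with osmotic stress), growth does not
#' depend on reporter complementation, but nonsense mutants of the kinase drop
#' out because they lack the pathway function; a healthy missense mutant is
#' therefore clearly separated from the nonsense pool. Each missense
#' amino-acid change is compared to the pooled nonsense scores (two-sided
#' Mann-Whitney U), p-values are BH-adjusted across missense mutants, and
#' mutants NOT significantly different from nonsense (adjusted p > alpha) are
#' removed from the interaction-score dataset: absence of separation from the
#' loss-of-function pool marks a proliferation defect.
#'
#' @param control_scores Score table for the no-methotrexate condition.
#' @param alpha Significance level (default 0.05).
#' @return Data.frame with \code{aa_change_key}, \code{n}, \code{U}, \code{p},
#'   \code{p_adj}, \code{flagged} (TRUE = remove).
#' @export
flag_control_condition_defects <- function(control_scores, alpha = 0.05) {
  nonsense <- pooled_class_scores(control_scores, "nonsense")
  if (length(nonsense) == 0L)
    stop("no nonsense scores in the control condition")
  groups <- missense_split(control_scores)
  res <- do.call(rbind, lapply(names(groups), function(k) {
    mw <- mann_whitney_u(groups[[k]], nonsense)
    data.frame(aa_change_key = k, n = length(groups[[k]]), U = mw$U,
               p = mw$p, stringsAsFactors = FALSE)
  }))
  res$p_adj <- bh_fdr(res$p)
  res$flagged <- res$p_adj > alpha
  res
}

#' Flag abundance-affected mutants via the control bait
#'
#' The control-bait assay (Hog1) reports local abundance of the prey
#' independently of the binding motif: mutants whose control-bait scores
#' differ from the wild-type + silent pool changed abundance or stability, not
#' (only) binding, and are excluded from the binding dataset. Per missense
#' amino-acid change: two-sided Mann-Whitney U against the pooled wild-type +
#' silent control-bait scores, BH across mutants, flagged when adjusted
#' p < alpha.
#'
#' @param hog1_scores Score table for the control (abundance) bait.
#' @param alpha Significance level (default 0.05).
#' @return Data.frame with \code{aa_change_key}, \code{n}, \code{U}, \code{p},
#'   \code{p_adj}, \code{flagged}.
#' @export
flag_abundance_mutants <- function(hog1_scores, alpha = 0.05) {
  pool <- pooled_class_scores(hog1_scores, c("wt_identical", "silent"))
  if (length(pool) == 0L) stop("empty wild-type + silent pool")
  groups <- missense_split(hog1_scores)
  res <- do.call(rbind, lapply(names(groups), function(k) {
    mw <- mann_whitney_u(groups[[k]], pool)
    data.frame(aa_change_key = k, n = length(groups[[k]]), U = mw$U,
               p = mw$p, stringsAsFactors = FALSE)
  }))
  res$p_adj <- bh_fdr(res$p)
  res$flagged <- res$p_adj < alpha
  res
}

#' Classify missense mutants against the wild-type pool
#'
#' Per missense amino-acid change: two-sided Mann-Whitney U test of its
#' replicate-level scaled scores against the pooled wild-type + silent scores,
#' BH adjustment across mutants, then classification: adjusted p < alpha and
#' median score > 0 is \code{"stronger"}; adjusted p < alpha and median < 0 is
#' \code{"weaker"}; otherwise \code{"not_different"}.
#'
#' @param sho1_scores Score table for the binding bait.
#' @param alpha Significance level (default 0.05).
#' @param min_contrib Minimum replicate-level scores per mutant (default 3).
#' @return Data.frame with \code{aa_change_key}, \code{n}, \code{score}
#'   (median), \code{U}, \code{p}, \code{p_adj}, \code{classification}.
#' @export
classify_mutants <- function(sho1_scores, alpha = 0.05, min_contrib = 3L) {
  pool <- pooled_class_scores(sho1_scores, c("wt_identical", "silent"))
  if (length(pool) == 0L) stop("empty wild-type + silent pool")
  groups <- missense_split(sho1_scores)
  groups <- groups[vapply(groups, length, 1L) >= min_contrib]
  res <- do.call(rbind, lapply(names(groups), function(k) {
    x <- groups[[k]]
    mw <- mann_whitney_u(x, pool)
    data.frame(aa_change_key = k, n = length(x), score = median(x),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    return(data.frame(aa_change_key = character(0), n = integer(0),
                      score = numeric(0), U = numeric(0), p = numeric(0),
                      p_adj = numeric(0), classification = character(0)))
  res$p_adj <- bh_fdr(res$p)
  res$classification <- ifelse(res$p_adj >= alpha, "not_different",
                        ifelse(res$score > 0, "stronger",
                        ifelse(res$score < 0, "weaker", "not_different")))
  res
}

#' Welch's t-test of selection coefficients against the wild type
#'
#' Per mutant: Welch two-sample t-test (unequal variances,
#' Welch-Satterthwaite degrees of freedom) of its replicate selection
#' coefficients against the wild-type replicates, BH-adjusted across mutants.
#'
#' @param s_table Data.frame with columns \code{mutant} and \code{s}
#'   (replicate-level selection coefficients).
#' @param wt_s Numeric vector of wild-type replicate selection coefficients
#'   (>= 2 values).
#' @param alpha Significance level (default 0.05).
#' @return Data.frame with \code{mutant}, \code{n}, \code{t}, \code{p},
#'   \code{p_adj}, \code{significant}.
#' @export
proliferation_test <- function(s_table, wt_s, alpha = 0.05) {
  if (length(wt_s) < 2L) stop("need >= 2 wild-type replicates")
  groups <- split(s_table$s, s_table$mutant)
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  res <- do.call(rbind, lapply(names(groups), function(k) {
    tt <- t.test(groups[[k]], wt_s, var.equal = FALSE)
    data.frame(mutant = k, n = length(groups[[k]]),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- bh_fdr(res$p)
  res$significant <- res$p_adj < alpha
  res
}

#' Run the full filter and classification cascade
#'
#' Order of operations: count filter (during scoring); control-outlier
#' flagging on nonsense and silent variants, with flagged variants removed and
#' the rescaling re-run without them as anchors; control-condition defect
#' removal (when a no-methotrexate condition is present); abundance exclusion
#' via the control bait (when present); classification of the remaining
#' missense mutants against the wild-type pool; aggregation to amino-acid
#' scores. Re-running the cascade on its own output is idempotent.
#'
#' @param counts Count table covering the binding bait and, optionally, the
#'   control bait and a no-methotrexate condition.
#' @param design A \code{\link{library_design}} (currently informational).
#' @param binding_bait,control_bait Bait labels (defaults \code{"Sho1"},
#'   \code{"Hog1"}).
#' @param classify_condition Condition whose scores are classified; default:
#'   the methotrexate + sorbitol condition when present, else the first
#'   methotrexate condition.
#' @param control_condition No-methotrexate condition used for the defect
#'   filter (default \code{"noMTX_sorbitol"} when present).
#' @param min_reads,min_contrib,alpha,wt_policy,pseudocount See the individual
#'   stages.
#' @param exclude_keys Amino-acid change keys excluded up front by manual QC.
#' @return List with \code{scores} (replicate-level, post-cascade),
#'   \code{aa_scores} (aggregated, with classification merged),
#'   \code{classification}, \code{flags} (per-stage test tables) and
#'   \code{summary} (variant counts at each stage).
#' @export
filter_cascade <- function(counts, design = NULL, binding_bait = "Sho1",
                           control_bait = "Hog1", classify_condition = NULL,
                           control_condition = NULL, min_reads = 20L,
                           min_contrib = 3L, alpha = 0.05,
                           wt_policy = c("wt_silent", "wt_identical"),
                           pseudocount = 0.5, exclude_keys = character()) {
  wt_policy <- match.arg(wt_policy)
  scores <- score_counts(counts, min_reads = min_reads,
                         pseudocount = pseudocount, wt_policy = wt_policy)
  conds <- unique(scores$condition)
  if (is.null(classify_condition))
    classify_condition <- if ("MTX_sorbitol" %in% conds) "MTX_sorbitol"
                          else grep("^MTX", conds, value = TRUE)[1L]
  if (is.null(control_condition))
    control_condition <- intersect(c("noMTX_sorbitol", "noMTX"), conds)[1L]
  summary <- list(n_scored = length(unique(
    paste0(scores$codon_position, ":", scores$mutant_codon))))

  # 1. control outliers -> drop and re-anchor
  mtx_binding <- scores$bait == binding_bait &
    scores$condition == classify_condition
  outliers <- flag_control_outliers(scores[mtx_binding, ], alpha = alpha)
  bad_keys <- outliers$variant_key[outliers$flagged]
  summary$n_control_outliers <- length(bad_keys)
  scores <- score_counts(counts, min_reads = min_reads,
                         pseudocount = pseudocount, wt_policy = wt_policy,
                         exclude_anchor_keys = bad_keys)
  scores <- scores[!(paste0(scores$codon_position, ":",
                            scores$mutant_codon) %in% bad_keys), ]
  if (length(exclude_keys))
    scores <- scores[!(scores$aa_change_key %in% exclude_keys), ]

  # 2. control-condition defects
  defect_flags <- NULL
  if (!is.na(control_condition) && length(control_condition) == 1L &&
      control_condition %in% conds) {
    ctrl <- scores[scores$bait == binding_bait &
                     scores$condition == control_condition, ]
    if (length(pooled_class_scores(ctrl, "nonsense")) > 0) {
      defect_flags <- flag_control_condition_defects(ctrl, alpha = alpha)
      drop <- defect_flags$aa_change_key[defect_flags$flagged]
      summary$n_control_condition_defects <- length(drop)
      scores <- scores[!(scores$aa_change_key %in% drop &
                           scores$variant_class == "missense"), ]
    }
  }

  # 3. abundance exclusion via the control bait; abundance is condition-
  # independent, so replicate scores from every methotrexate condition are
  # pooled (each library is rescaled to the common frame first)
  abundance_flags <- NULL
  if (control_bait %in% scores$bait) {
    hog <- scores[scores$bait == control_bait &
                    grepl("^MTX", scores$condition), ]
    abundance_flags <- flag_abundance_mutants(hog, alpha = alpha)
    drop <- abundance_flags$aa_change_key[abundance_flags$flagged]
    summary$n_abundance_excluded <- length(drop)
    scores <- scores[!(scores$bait == binding_bait &
                         scores$aa_change_key %in% drop &
                         scores$variant_class == "missense"), ]
  }

  # 4. classification of the binding dataset
  cls_scores <- scores[scores$bait == binding_bait &
                         scores$condition == classify_condition, ]
  classification <- classify_mutants(cls_scores, alpha = alpha,
                                     min_contrib = min_contrib)
  summary$n_classified <- nrow(classification)
  summary$n_stronger <- sum(classification$classification == "stronger")
  summary$n_weaker <- sum(classification$classification == "weaker")

  aa_scores <- aggregate_aa(scores, min_contrib = min_contrib)
  aa_scores$classification <- classification$classification[
    match(aa_scores$aa_change_key, classification$aa_change_key)]
  aa_scores$classification[!(aa_scores$bait == binding_bait &
                               aa_scores$condition == classify_condition)] <-
    NA_character_

  list(scores = scores, aa_scores = aa_scores,
       classification = classification,
       flags = list(control_outliers = outliers,
                    control_condition_defects = defect_flags,
                    abundance = abundance_flags),
       summary = summary)
}
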