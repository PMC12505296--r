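#' Raw interaction score: log2 frequency fold change
#'
#' The interaction score of a variant is the log2 fold change of its pool
#' frequency between the pre-selection library (after diploid selection,
#' immediately before methotrexate) and the end of the final methotrexate
#' cycle. A pseudocount is added to counts (not depths) so the score is finite
#' for variants that drop out:
#' \code{log2((c_post + p)/D_post) - log2((c_pre + p)/D_pre)}.
#'
#' @param c_pre,c_post Read counts before/after selection.
#' @param d_pre,d_post Sample depths (must be positive).
#' @param pseudocount Pseudocount p (default 0.5).
#' @return Numeric vector of raw scores.
#' @export
raw_interaction_score <- function(c_pre, d_pre, c_post, d_post,
                                  pseudocount = 0.5) {
  if (any(d_pre <= 0) || any(d_post <= 0)) stop("depths must be positive")
  log2((c_post + pseudocount) / d_post) -
    log2((c_pre + pseudocount) / d_pre)
}

#' Count-based quality filter
#'
#' Variants with fewer than \code{min_reads} reads in the pre-selection sample
#' (after diploid selection) are flagged out: low pre-selection counts inflate
#' apparent fold changes. Failing records are excluded from rescaling anchors
#' and from aggregation.
#'
#' @param c_pre Pre-selection read counts.
#' @param min_reads Threshold (default 20: a variant passes with 20 or more
#'   reads).
#' @return Logical vector of pass flags.
#' @export
apply_count_filter <- function(c_pre, min_reads = 20L) {
  c_pre >= min_reads
}

#' Rescale raw scores to the wild-type = 0 / nonsense median = -1 frame
#'
#' Within one sequencing library (one bait x condition x replicate), scores
#' are put on a common scale by the affine map
#' \code{scaled = (raw - W) / (W - N)}, where W is the median raw score of the
#' wild-type anchor (wild-type-identical plus silent variants by default) and
#' N the median raw score of nonsense variants, both over records passing the
#' count filter. After the map, the wild-type anchor value sits at 0 and the
#' nonsense median at -1 exactly.
#'
#' @param raw Raw scores for one library.
#' @param variant_class Variant classes parallel to \code{raw}.
#' @param pass Count-filter flags parallel to \code{raw} (default all pass).
#' @param wt_policy \code{"wt_silent"} (default) anchors on wild-type plus
#'   synonymous variants; \code{"wt_identical"} on the wild type alone.
#' @param exclude Logical vector marking records excluded from the anchors
#'   (e.g. control outliers flagged by \code{\link{flag_control_outliers}}).
#' @return Numeric vector of scaled scores (all \code{NA} with a warning if
#'   the anchors are missing or degenerate).
#' @export
rescale_scores <- function(raw, variant_class, pass = TRUE,
                           wt_policy = c("wt_silent", "wt_identical"),
                           exclude = FALSE) {
  wt_policy <- match.arg(wt_policy)
  pass <- rep_len(pass, length(raw))
  exclude <- rep_len(exclude, length(raw))
  wt_classes <- if (wt_policy == "wt_silent") c("wt_identical", "silent")
                else "wt_identical"
  ok <- pass & !exclude & !is.na(raw)
  w <- median(raw[ok & variant_class %in% wt_classes])
  n <- median(raw[ok & variant_class == "nonsense"])
  if (is.na(w) || is.na(n) || w == n) {
    warning("rescaling anchors missing or degenerate; scaled scores set to NA")
    return(rep(NA_real_, length(raw)))
  }
  (raw - w) / (w - n)
}

#' Score a count table
#'
#' Joins pre- and post-selection samples per bait and replicate, computes raw
#' interaction scores, applies the pre-selection count filter and rescales
#' each library (bait x condition x replicate) to the wild-type = 0 /
#' nonsense median = -1 frame.
#'
#' @param counts Count table (\code{\link{simulate_counts}} or
#'   \code{\link{call_variants}} layout). Special-class rows
#'   (\code{multi_codon}, \code{indel_other}) are ignored.
#' @param min_reads Pre-selection count threshold (default 20).
#' @param pseudocount Pseudocount on counts (default 0.5).
#' @param wt_policy Wild-type anchor policy (see \code{\link{rescale_scores}}).
#' @param exclude_anchor_keys Variant keys
#'   (\code{"<codon_position>:<mutant_codon>"}) excluded from rescaling
#'   anchors, e.g. control outliers.
#' @return Score table: one row per variant x library with columns
#'   \code{bait}, \code{condition}, \code{replicate}, variant annotation,
#'   \code{c_pre}, \code{c_post}, \code{raw_score}, \code{scaled_score},
#'   \code{pass_count_filter}.
#' @export
score_counts <- function(counts, min_reads = 20L, pseudocount = 0.5,
                         wt_policy = c("wt_silent", "wt_identical"),
                         exclude_anchor_keys = character()) {
  wt_policy <- match.arg(wt_policy)
  counts <- counts[counts$variant_class %in%
                     c("wt_identical", "silent", "missense", "nonsense"), ]
  pre <- counts[counts$timepoint == "pre", ]
  post <- counts[counts$timepoint == "post", ]
  if (nrow(pre) == 0L || nrow(post) == 0L)
    stop("count table must contain pre and post timepoints")
  vk <- function(df) paste(df$bait, df$replicate, df$codon_position,
                           df$mutant_codon)
  idx <- match(vk(post), vk(pre))
  if (anyNA(idx)) stop("post-selection variants missing from pre-selection")
  out <- data.frame(bait = post$bait, condition = post$condition,
                    replicate = post$replicate,
                    post[c("codon_position", "wt_codon", "mutant_codon",
                           "wt_aa", "mut_aa", "variant_class",
                           "aa_change_key")],
                    c_pre = pre$count[idx], c_post = post$count,
                    stringsAsFactors = FALSE)
  out$raw_score <- raw_interaction_score(pre$count[idx], pre$depth[idx],
                                         post$count, post$depth, pseudocount)
  out$pass_count_filter <- apply_count_filter(out$c_pre, min_reads)
  excl <- paste0(out$codon_position, ":", out$mutant_codon) %in%
    exclude_anchor_keys
  lib <- paste(out$bait, out$condition, out$replicate)
  out$scaled_score <- NA_real_
  for (l in unique(lib)) {
    i <- lib == l
    out$scaled_score[i] <- rescale_scores(out$raw_score[i],
                                          out$variant_class[i],
                                          out$pass_count_filter[i],
                                          wt_policy, exclude = excl[i])
  }
  out
}

#' Aggregate codon-variant scores to amino-acid changes
#'
#' Pools the scaled scores of every synonymous codon variant across replicates
#' within the same bait and condition, and reports the median when at least
#' \code{min_contrib} replicate-level scores survive the count filter (medians
#' of even pools are midpoints of the two central values).
#'
#' @param scores Score table from \code{\link{score_counts}}.
#' @param min_contrib Minimum pooled scores per amino-acid change (default 3).
#' @return Data.frame with one row per (bait, condition, amino-acid change):
#'   \code{aa_change_key}, \code{codon_position}, \code{wt_aa}, \code{mut_aa},
#'   \code{aa_class}, \code{score} (median), \code{n_contributing}.
#' @export
aggregate_aa <- function(scores, min_contrib = 3L) {
  keep <- scores$pass_count_filter & !is.na(scores$scaled_score)
  s <- scores[keep, ]
  if (nrow(s) == 0L)
    return(data.frame(bait = character(0), condition = character(0),
                      aa_change_key = character(0),
                      codon_position = integer(0), wt_aa = character(0),
                      mut_aa = character(0), aa_class = character(0),
                      score = numeric(0), n_contributing = integer(0)))
  s$aa_class <- ifelse(s$mut_aa == "*", "nonsense",
                ifelse(s$mut_aa == s$wt_aa, "wt_silent", "missense"))
  grp <- paste(s$bait, s$condition, s$aa_change_key, sep = "\r")
  agg <- do.call(rbind, lapply(split(s, grp), function(g) {
    data.frame(bait = g$bait[1L], condition = g$condition[1L],
               aa_change_key = g$aa_change_key[1L],
               codon_position = g$codon_position[1L], wt_aa = g$wt_aa[1L],
               mut_aa = g$mut_aa[1L], aa_class = g$aa_class[1L],
               score = median(g$scaled_score),
               n_contributing = nrow(g), stringsAsFactors = FALSE)
  }))
  agg <- agg[agg$n_contributing >= min_contrib, ]
  agg <- agg[order(agg$bait, agg$condition, agg$codon_position,
                   agg$mut_aa), ]
  rownames(agg) <- NULL
  agg
}

#' Generations from optical-density fold change
#'
#' The number of generations in a growth cycle is the log2 fold change in
#' optical density across the cycle.
#'
#' @param od_start,od_end Optical densities (> 0) at the start and end of the
#'   cycle.
#' @return Numeric vector of generations; vectorized over cycles (sum the
#'   result across cycles of a multi-cycle assay).
#' @export
generations_from_od <- function(od_start, od_end) {
  if (any(od_start <= 0) || any(od_end <= 0))
    stop("optical densities must be positive")
  log2(od_end / od_start)
}

#' Selection coefficient from a pooled competition
#'
#' Per-generation, wild-type-relative log2 fitness:
#' \code{s = (log2(f_v_end/f_v_start) - log2(f_wt_end/f_wt_start)) / g}.
#' For multi-cycle assays, compare the first pre-selection sample with the
#' final post-selection sample and use the summed generations.
#'
#' @param f_v_start,f_v_end Variant frequencies (pseudocounted, > 0).
#' @param f_wt_start,f_wt_end Wild-type frequencies.
#' @param g Total generations (> 0).
#' @return Selection coefficient(s) per generation.
#' @export
selection_coefficient <- function(f_v_start, f_v_end, f_wt_start, f_wt_end,
                                  g) {
  if (any(g <= 0)) stop("g must be positive")
  if (any(c(f_v_start, f_v_end, f_wt_start, f_wt_end) <= 0))
    stop("frequencies must be positive (apply a pseudocount first)")
  (log2(f_v_end / f_v_start) - log2(f_wt_end / f_wt_start)) / g
}

#' Spearman correlation of aggregated scores between two conditions
#'
#' @param aa_scores_a,aa_scores_b Aggregated score tables
#'   (\code{\link{aggregate_aa}} output, or any data.frame with
#'   \code{aa_change_key} and \code{score}).
#' @return List with \code{rho} (Spearman rank correlation, average ranks for
#'   ties) and \code{n} (shared amino-acid changes). Fewer than 3 shared keys
#'   is an error.
#' @export
correlate_conditions <- function(aa_scores_a, aa_scores_b) {
  m <- merge(aa_scores_a[c("aa_change_key", "score")],
             aa_scores_b[c("aa_change_key", "score")],
             by = "aa_change_key", suffixes = c("_a", "_b"))
  if (nrow(m) < 3L) stop("fewer than 3 shared amino-acid changes")
  list(rho = cor(m$score_a, m$score_b, method = "spearman"), n = nrow(m))
}
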