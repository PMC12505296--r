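#' Simulation parameters for the synthetic competition assay
#'
#' The generator emulates a pooled DHFR-PCA competition: a library of
#' single-codon variants carried by two bait strains (Sho1, reporting binding
#' plus abundance; Hog1, reporting abundance only), grown through repeated
#' methotrexate selection cycles under four conditions
#' (\code{MTX_sorbitol}, \code{MTX}, \code{noMTX_sorbitol}, \code{noMTX}).
#' Selection acts multiplicatively per generation: a variant with selection
#' coefficient s changes frequency in proportion to \code{2^(s * g)} over g
#' generations. Pre-selection pool composition is a Dirichlet perturbation of
#' the uniform frequency vector, and sequencing samples reads multinomially.
#'
#' Defaults mirror the assay design: 3 replicate pools, two 96-h methotrexate
#' cycles each growing from a 0.1 OD inoculum (4 generations per cycle), a
#' read depth of 1e5 per sample, and a 1.5x amplification of binding effects
#' under sorbitol (osmotic stress induces the pathway and strengthens the
#' interaction).
#'
#' @param seed Integer seed; all randomness in the generator derives from it.
#' @param read_depth Reads sampled per sequencing library.
#' @param n_replicates Number of replicate pools (default 3).
#' @param conditions Subset of
#'   \code{c("MTX_sorbitol","MTX","noMTX_sorbitol","noMTX")}.
#' @param baits Bait strains; \code{"Sho1"} responds to binding effects,
#'   any other bait (e.g. \code{"Hog1"}) only to abundance effects.
#' @param generations_per_cycle Generations per selection cycle (log2 OD fold
#'   change; default 4).
#' @param n_cycles Number of selection cycles (default 2).
#' @param error_rate Per-base sequencing error rate for read emission
#'   (default 0.001; must be in [0, 0.05]).
#' @param dirichlet_alpha Concentration of the Dirichlet perturbation of the
#'   initial pool (larger = closer to uniform; default 50).
#' @param sorbitol_multiplier Scalar (> 1) applied to binding effects under
#'   methotrexate with sorbitol (default 1.5).
#' @param s_null Magnitude of the per-generation fitness deficit of nonsense
#'   variants under methotrexate (default 0.125, so that the wild-type to
#'   nonsense gap spans one log2 unit over the default 8 generations).
#' @param barcode_length Barcode length for read emission (default 6).
#' @return A list of class \code{"sim_params"}.
#' @export
sim_params <- function(seed = 1L, read_depth = 1e5, n_replicates = 3L,
                       conditions = c("MTX_sorbitol", "MTX",
                                      "noMTX_sorbitol", "noMTX"),
                       baits = c("Sho1", "Hog1"),
                       generations_per_cycle = 4, n_cycles = 2L,
                       error_rate = 0.001, dirichlet_alpha = 50,
                       sorbitol_multiplier = 1.5, s_null = 0.125,
                       barcode_length = 6L) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (read_depth <= 0) stop("read_depth must be positive")
  if (generations_per_cycle <= 0) stop("generations_per_cycle must be > 0")
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must be in [0, 0.05]")
  structure(list(seed = as.integer(seed), read_depth = read_depth,
                 n_replicates = as.integer(n_replicates),
                 conditions = conditions, baits = baits,
                 generations_per_cycle = generations_per_cycle,
                 n_cycles = as.integer(n_cycles), error_rate = error_rate,
                 dirichlet_alpha = dirichlet_alpha,
                 sorbitol_multiplier = sorbitol_multiplier, s_null = s_null,
                 barcode_length = as.integer(barcode_length)),
            class = "sim_params")
}

#' Plant per-variant fitness effects
#'
#' Draws one effect triple per amino-acid change and copies it to every
#' synonymous codon variant, so that aggregation across synonymous codons is
#' meaningful:
#' \describe{
#'   \item{b}{binding effect per generation, applied under methotrexate with
#'     the Sho1 bait only. Missense changes draw from a mixture: a fraction
#'     \code{prop_stronger} bind more strongly (positive), \code{prop_weaker}
#'     more weakly (negative, down to and past the nonsense floor), and the
#'     remainder are near-neutral with a small continuous spread.}
#'   \item{a}{abundance effect per generation, applied under methotrexate with
#'     every bait (the complementation signal scales with the amount of
#'     fusion protein). Nonsense variants lose the C-terminal reporter
#'     fragment entirely, so their whole deficit (\code{-s_null}) is carried
#'     on this channel and shows up with both baits.}
#'   \item{ctrl}{fitness in the no-methotrexate + sorbitol control, where
#'     growth requires an intact osmotic-stress pathway rather than reporter
#'     complementation. Nonsense variants (pathway loss of function) carry
#'     \code{-s_null}; a configurable fraction of missense changes can share
#'     this defect to exercise the control-condition filter.}
#' }
#' Wild-type and silent variants have all effects equal to zero.
#'
#' @param design A \code{\link{library_design}}.
#' @param params A \code{\link{sim_params}}.
#' @param prop_stronger,prop_weaker Fractions of missense amino-acid changes
#'   with positive / negative binding effects (defaults 0.1 and 0.6).
#' @param prop_abundance Fraction of missense changes given an abundance
#'   effect (default 0).
#' @param abundance_effect Abundance effect size in units of \code{s_null}
#'   (default -1: strongly destabilizing mutations lose the fusion protein and
#'   with it the reporter signal on both baits, like nonsense variants do).
#' @param prop_control_defect Fraction of missense changes sharing the
#'   control-condition growth defect (default 0).
#' @return Data.frame with one row per enumerated variant: annotation columns
#'   plus \code{b}, \code{a}, \code{ctrl}.
#' @export
simulate_effects <- function(design, params = sim_params(),
                             prop_stronger = 0.1, prop_weaker = 0.6,
                             prop_abundance = 0, abundance_effect = -1,
                             prop_control_defect = 0) {
  stopifnot(inherits(design, "library_design"))
  set.seed(params$seed %% 2147483647L)
  v <- enumerate_variants(design)
  s0 <- params$s_null
  keys <- unique(v$aa_change_key[v$variant_class == "missense"])
  u <- runif(length(keys))
  b_aa <- ifelse(u < prop_stronger, s0 * runif(length(keys), 0.1, 0.6),
          ifelse(u < prop_stronger + prop_weaker,
                 -s0 * runif(length(keys), 0.1, 1.3),
                 s0 * rnorm(length(keys), 0, 0.05)))
  a_aa <- ifelse(runif(length(keys)) < prop_abundance, abundance_effect * s0, 0)
  ctrl_aa <- ifelse(runif(length(keys)) < prop_control_defect, -s0, 0)
  idx <- match(v$aa_change_key, keys)
  v$b <- ifelse(is.na(idx), 0, b_aa[idx])
  v$a <- ifelse(is.na(idx), 0, a_aa[idx])
  v$ctrl <- ifelse(is.na(idx), 0, ctrl_aa[idx])
  nons <- v$variant_class == "nonsense"
  v$b[nons] <- 0
  v$a[nons] <- -s0
  v$ctrl[nons] <- -s0
  v
}

# Per-generation selection coefficient of each variant in a given sample
# context. Binding effects act only under MTX with the Sho1 bait (amplified by
# sorbitol); abundance effects act under MTX with every bait; the control
# channel acts only without MTX under sorbitol; plain medium is neutral.
variant_fitness <- function(effects, bait, condition, params) {
  mtx <- grepl("^MTX", condition)
  sorb <- grepl("sorbitol", condition)
  if (mtx) {
    b <- if (identical(bait, "Sho1"))
      effects$b * (if (sorb) params$sorbitol_multiplier else 1)
    else 0
    b + effects$a
  } else {
    if (sorb) effects$ctrl else rep(0, nrow(effects))
  }
}

#' Simulate pre- and post-selection variant count tables
#'
#' For each bait and replicate, draws an initial frequency vector f0 from a
#' Dirichlet perturbation of the uniform distribution and samples the
#' pre-selection library multinomially at the configured depth. For each
#' condition, expected post-selection frequencies are proportional to
#' \code{f0 * 2^(s * g * n_cycles)} with s from \code{\link{variant_fitness}},
#' and the post-selection library is sampled multinomially. Deterministic
#' under a fixed seed.
#'
#' @param design A \code{\link{library_design}}.
#' @param effects Data.frame from \code{\link{simulate_effects}} (must cover
#'   every enumerated variant).
#' @param params A \code{\link{sim_params}}.
#' @return A count table: one row per sample x variant with columns
#'   \code{sample_id}, \code{bait}, \code{condition} (\code{"none"} for
#'   pre-selection samples), \code{replicate}, \code{timepoint},
#'   variant annotation, \code{count}, \code{depth}, \code{frequency}.
#' @export
simulate_counts <- function(design, effects, params = sim_params()) {
  stopifnot(inherits(design, "library_design"), inherits(params, "sim_params"))
  v <- variant_table(design)
  key <- paste(v$codon_position, v$mutant_codon)
  ek <- paste(effects$codon_position, effects$mutant_codon)
  if (!all(key %in% ek))
    stop("effects missing for ", sum(!(key %in% ek)), " variant(s)")
  effects <- effects[match(key, ek), ]
  set.seed((params$seed + 1L) %% 2147483647L)
  g_total <- params$generations_per_cycle * params$n_cycles
  n_var <- nrow(v)
  out <- list()
  for (bait in params$baits) {
    for (rep_i in seq_len(params$n_replicates)) {
      f0 <- rgamma(n_var, shape = params$dirichlet_alpha, rate = 1)
      f0 <- f0 / sum(f0)
      stopifnot(abs(sum(f0) - 1) < 1e-12)
      pre_counts <- as.integer(rmultinom(1L, params$read_depth, f0))
      out[[length(out) + 1L]] <- sample_rows(
        v, bait, "none", rep_i, "pre", pre_counts)
      for (cond in params$conditions) {
        s <- variant_fitness(effects, bait, cond, params)
        f1 <- f0 * 2^(s * g_total)
        f1 <- f1 / sum(f1)
        post_counts <- as.integer(rmultinom(1L, params$read_depth, f1))
        out[[length(out) + 1L]] <- sample_rows(
          v, bait, cond, rep_i, "post", post_counts)
      }
    }
  }
  do.call(rbind, out)
}

sample_rows <- function(v, bait, condition, replicate, timepoint, counts) {
  depth <- sum(counts)
  data.frame(sample_id = paste(bait, condition, paste0("r", replicate),
                               timepoint, sep = "_"),
             bait = bait, condition = condition,
             replicate = as.integer(replicate), timepoint = timepoint,
             v, count = counts, depth = depth,
             frequency = if (depth > 0) counts / depth else NA_real_,
             stringsAsFactors = FALSE)
}
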