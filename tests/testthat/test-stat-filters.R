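test_that("Mann-Whitney exact p agrees with full enumeration", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)   # 2 of the 20 labelings are as extreme
  # identical multisets: p = 1 two-sided
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1.5, 2.5, 0.5))$p > 0.6, TRUE)
  # symmetry under swapping samples
  set.seed(2)
  x <- rnorm(4); y <- rnorm(5)
  expect_equal(mann_whitney_u(x, y)$p, mann_whitney_u(y, x)$p)
  # exhaustive agreement with the enumeration oracle, all nx+ny <= 10
  set.seed(7)
  for (nx in 1:5) for (ny in 1:5) {
    x <- rnorm(nx); y <- rnorm(ny)
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(mann_whitney_u(x, y, alt)$p,
                   mw_exact_oracle(x, y, alt)$p,
                   info = paste(nx, ny, alt))
    }
  }
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("BH adjustment reproduces the step-up by hand", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(1)
  p <- runif(50)
  adj <- bh_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj <= 1 & adj >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

make_scores <- function(class_scores, reps = 3) {
  # class_scores: named list variant_key -> c(class, mean); builds a
  # replicate-level score table with small deterministic jitter
  rows <- list()
  i <- 0
  for (k in names(class_scores)) {
    i <- i + 1
    cls <- class_scores[[k]][[1]]
    mu <- as.numeric(class_scores[[k]][[2]])
    pos <- 10L + i
    rows[[i]] <- data.frame(
      bait = "Sho1", condition = "MTX", replicate = seq_len(reps),
      codon_position = pos, wt_codon = "AAA", mutant_codon = k,
      wt_aa = "K", mut_aa = if (cls == "nonsense") "*" else
        if (cls %in% c("silent", "wt_identical")) "K" else "W",
      variant_class = cls,
      aa_change_key = paste0("K-", pos, "-",
                             if (cls == "nonsense") "*" else
                               if (cls %in% c("silent", "wt_identical")) "K"
                             else "W"),
      c_pre = 100L, c_post = 100L, raw_score = mu,
      pass_count_filter = TRUE,
      scaled_score = mu + seq(-0.02, 0.02, length.out = reps),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

test_that("control outliers are flagged per variant at unadjusted alpha", {
  set.seed(11)
  controls <- c(setNames(lapply(1:20, function(i) list("nonsense", -1)),
                         paste0("N", 1:20)),
                list(OUT = list("nonsense", 0.5)))
  sc <- make_scores(controls, reps = 6)
  null_rows <- sc$mutant_codon != "OUT"
  sc$scaled_score[null_rows] <- -1 + rnorm(sum(null_rows), 0, 0.05)
  fl <- flag_control_outliers(sc)
  expect_true(fl$flagged[grepl(":OUT", fl$variant_key)])
  # an unadjusted 5% screen admits occasional false flags among 20 nulls
  expect_lte(sum(fl$flagged) - 1, 2)
  # a class with a single variant is not tested
  one <- make_scores(list(S1 = list("silent", 0)))
  expect_equal(nrow(flag_control_outliers(one)), 0)
})

test_that("null control variants are flagged at about the nominal rate", {
  set.seed(13)
  rates <- replicate(60, {
    controls <- setNames(
      lapply(1:12, function(i) list("nonsense", rnorm(1, -1, 0.1))),
      paste0("N", 1:12))
    sc <- make_scores(controls, reps = 4)
    # add replicate noise from the same distribution
    sc$scaled_score <- rnorm(nrow(sc), -1, 0.1)
    mean(flag_control_outliers(sc)$flagged)
  })
  expect_lt(abs(mean(rates) - 0.05), 0.035)
})

test_that("control-condition defect removal keeps mutants unlike nonsense", {
  set.seed(17)
  tab <- c(setNames(lapply(1:10, function(i) list("nonsense", -1)),
                    paste0("N", 1:10)),
           list(GOOD = list("missense", 0), BAD = list("missense", -1)))
  sc <- make_scores(tab, reps = 4)
  sc$scaled_score <- sc$scaled_score + rnorm(nrow(sc), 0, 0.03)
  fl <- flag_control_condition_defects(sc)
  expect_false(fl$flagged[fl$aa_change_key ==
                            sc$aa_change_key[sc$mutant_codon == "GOOD"][1]])
  expect_true(fl$flagged[fl$aa_change_key ==
                           sc$aa_change_key[sc$mutant_codon == "BAD"][1]])
  expect_error(flag_control_condition_defects(make_scores(
    list(M = list("missense", 0)))), "nonsense")
})

test_that("abundance and binding effects separate on the control bait", {
  d <- example_design("NNK")
  p <- sim_params(seed = 23, read_depth = 3e4,
                  conditions = c("MTX_sorbitol", "MTX"))
  eff <- simulate_effects(d, p, prop_abundance = 0.1)
  cnt <- simulate_counts(d, eff, p)
  sc <- score_counts(cnt)
  hog <- sc[sc$bait == "Hog1" & grepl("^MTX", sc$condition), ]
  fl <- flag_abundance_mutants(hog)
  truth <- unique(eff[eff$variant_class == "missense",
                      c("aa_change_key", "a", "b")])
  m <- merge(fl, truth, by = "aa_change_key")
  expect_gt(mean(m$flagged[m$a != 0]), 0.9)
  expect_lt(mean(m$flagged[m$a == 0 & m$b != 0]), 0.05)
  # wild type itself is never flagged (it is not a missense key)
  expect_false(any(grepl("-K$", fl$aa_change_key[fl$flagged]) &
                     fl$aa_change_key[fl$flagged] == "K-93-K"))
})

test_that("classification splits stronger/weaker/not-different by sign", {
  set.seed(19)
  tab <- c(setNames(lapply(1:8, function(i) list("silent", 0)),
                    paste0("S", 1:8)),
           list(UP = list("missense", 0.9)))
  sc <- make_scores(tab, reps = 4)
  sc$scaled_score <- sc$scaled_score + rnorm(nrow(sc), 0, 0.05)
  cl <- classify_mutants(sc)
  expect_equal(cl$classification[grepl("W$", cl$aa_change_key)], "stronger")
  # mutant indistinguishable from the pool
  tab2 <- c(setNames(lapply(1:8, function(i) list("silent", 0)),
                     paste0("S", 1:8)),
            list(MID = list("missense", 0)))
  sc2 <- make_scores(tab2, reps = 4)
  sc2$scaled_score <- sc2$scaled_score + rnorm(nrow(sc2), 0, 0.05)
  cl2 <- classify_mutants(sc2)
  expect_equal(cl2$classification, "not_different")
})

test_that("classified fractions recover planted effect fractions", {
  d <- example_design("NNK")
  p <- sim_params(seed = 29, read_depth = 1e5, conditions = "MTX_sorbitol",
                  baits = "Sho1")
  eff <- simulate_effects(d, p, prop_stronger = 0.1, prop_weaker = 0.6)
  cnt <- simulate_counts(d, eff, p)
  sc <- score_counts(cnt)
  cl <- classify_mutants(sc[sc$condition == "MTX_sorbitol", ])
  truth <- unique(eff[eff$variant_class == "missense",
                      c("aa_change_key", "b")])
  m <- merge(cl, truth, by = "aa_change_key")
  # planted positives/negatives are classified with matching sign
  strong <- m$b > 0.05 * p$s_null * 2
  weak <- m$b < -0.2 * p$s_null
  expect_gt(mean(m$classification[weak] == "weaker"), 0.9)
  expect_gt(mean(m$classification[m$b > 0.1 * p$s_null] == "stronger"), 0.7)
  expect_lt(mean(m$classification[abs(m$b) < 0.02 * p$s_null] != "not_different"),
            0.3)
})

test_that("proliferation test uses Welch's t with BH across mutants", {
  wt <- c(0.001, -0.002, 0.0005, 0.0008, -0.001, 0.0002)
  st <- rbind(
    data.frame(mutant = "neutral", s = wt + 1e-4),
    data.frame(mutant = "nonsense", s = c(-0.12, -0.11, -0.13, -0.10,
                                          -0.115, -0.125)))
  res <- proliferation_test(st, wt)
  expect_false(res$significant[res$mutant == "neutral"])
  expect_true(res$significant[res$mutant == "nonsense"])
  # equal samples give t = 0
  tt <- t.test(c(1, 2, 3), c(1, 2, 3), var.equal = FALSE)
  expect_equal(unname(tt$statistic), 0)
  expect_error(proliferation_test(st, 0.1), ">= 2")
})

test_that("the filter cascade is order-stable and idempotent", {
  d <- example_design("NNK")
  p <- sim_params(seed = 37, read_depth = 2e4,
                  conditions = c("MTX_sorbitol", "noMTX_sorbitol"))
  eff <- simulate_effects(d, p, prop_abundance = 0.05,
                          prop_control_defect = 0.05)
  cnt <- simulate_counts(d, eff, p)
  f1 <- filter_cascade(cnt, d)
  expect_true(all(c("n_scored", "n_control_outliers", "n_classified") %in%
                    names(f1$summary)))
  # removed amino-acid changes stay removed from the binding dataset
  removed <- f1$flags$abundance$aa_change_key[f1$flags$abundance$flagged]
  expect_false(any(removed %in%
                     f1$scores$aa_change_key[f1$scores$bait == "Sho1" &
                       f1$scores$variant_class == "missense"]))
  # re-running on the same inputs reproduces the same outputs
  f2 <- filter_cascade(cnt, d)
  expect_identical(f1$aa_scores, f2$aa_scores)
  expect_identical(f1$summary, f2$summary)
})
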