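test_that("window-percentile estimator is exact on clean exponentials", {
  tr <- simulate_od(0.2, od0 = 0.05, duration_h = 20, noise_sd = 0,
                    capacity = Inf)
  r <- max_growth_rate(tr$time_h, tr$od)
  expect_equal(r$rate, 0.2, tolerance = 1e-10)
  expect_equal(r$n_windows, nrow(tr) - 4)
  flat <- simulate_od(0, od0 = 0.3, noise_sd = 0)
  expect_equal(max_growth_rate(flat$time_h, flat$od)$rate, 0)
  expect_error(max_growth_rate(1:4, rep(1, 4)), "at least 5")
  expect_error(max_growth_rate(c(1, 2, 2, 3, 4), rep(1, 5)), "increasing")
})

test_that("a single 10x spike barely moves the percentile estimate", {
  tr <- simulate_od(0.2, od0 = 0.05, duration_h = 30, noise_sd = 0)
  od <- tr$od
  od[60] <- od[60] * 10
  est <- max_growth_rate(tr$time_h, od)$rate
  expect_lt(abs(est - 0.2) / 0.2, 0.05)
  # the plain maximum fails on the same series
  y <- log2(od)
  wmax <- max(vapply(seq_len(length(y) - 4), function(i) {
    tt <- tr$time_h[i:(i + 4)]
    sum((tt - mean(tt)) * (y[i:(i + 4)] - mean(y[i:(i + 4)]))) /
      sum((tt - mean(tt))^2)
  }, numeric(1)))
  expect_gt(abs(wmax - 0.2) / 0.2, 0.05)
})

test_that("rate estimation is invariant to OD scaling", {
  tr <- simulate_od(0.15, od0 = 0.05, duration_h = 30, noise_sd = 0.02,
                    seed = 3)
  r1 <- max_growth_rate(tr$time_h, tr$od, floor = 0)$rate
  r2 <- max_growth_rate(tr$time_h, tr$od * 7.3, floor = 0)$rate
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("saturation windows never raise the estimate above exponential", {
  tr <- simulate_od(0.3, od0 = 0.05, duration_h = 72, noise_sd = 0)
  expect_lte(max_growth_rate(tr$time_h, tr$od)$rate, 0.3 + 1e-9)
})

test_that("fragment scores normalize against the no-fragment control", {
  expect_equal(fragment_interaction_score(0.2, 0.2), 1)
  expect_equal(fragment_interaction_score(0.4, 0.2), 2)
  expect_equal(fragment_interaction_score(0.4, 0.25, method = "difference"),
               0.15)
  expect_error(fragment_interaction_score(0.1, 0), "positive")
  # planted 1.5x fragment with mild noise
  set.seed(8)
  rates_frag <- vapply(1:6, function(i) {
    tr <- simulate_od(0.15, od0 = 0.05, duration_h = 30, noise_sd = 0.002)
    max_growth_rate(tr$time_h, tr$od)$rate
  }, numeric(1))
  rates_ctrl <- vapply(1:6, function(i) {
    tr <- simulate_od(0.1, od0 = 0.05, duration_h = 30, noise_sd = 0.002)
    max_growth_rate(tr$time_h, tr$od)$rate
  }, numeric(1))
  expect_equal(fragment_interaction_score(mean(rates_frag), mean(rates_ctrl)),
               1.5, tolerance = 0.05)
})

test_that("growth comparisons use Student's t with pooled variance", {
  ct <- compare_growth(c(2, 3, 4), c(4, 5, 6))
  expect_equal(ct$t, -2.449, tolerance = 1e-3)  # sp^2 = 1, t = -2/sqrt(2/3)
  same <- compare_growth(c(1, 2, 3), c(1, 2, 3), alternative = "less")
  expect_equal(same$p, 0.5)
  far <- compare_growth(c(10, 10.1, 9.9), c(1, 1.1, 0.9),
                        alternative = "greater")
  expect_lt(far$p, 1e-6)
  rates <- data.frame(strain = rep(c("wt", "m1", "m2"), each = 3),
                      rate = c(2, 3, 4, 4, 5, 6, 2.1, 3.1, 3.9))
  res <- compare_growth_table(rates, "wt")
  expect_setequal(res$strain, c("m1", "m2"))
  expect_true(all(res$p_adj >= res$p - 1e-15))
})

test_that("growth_rates handles long tables per strain and replicate", {
  od <- rbind(
    cbind(simulate_od(0.2, duration_h = 20, noise_sd = 0, capacity = Inf),
          strain = "a", condition = "MTX", replicate = 1),
    cbind(simulate_od(0.1, duration_h = 20, noise_sd = 0, capacity = Inf),
          strain = "b", condition = "MTX", replicate = 1))
  gr <- growth_rates(od)
  expect_equal(gr$rate[gr$strain == "a"], 0.2, tolerance = 1e-10)
  expect_equal(gr$rate[gr$strain == "b"], 0.1, tolerance = 1e-10)
})

test_that("colony filtering drops failures and border controls", {
  ts <- data.frame(bait = "Sho1", prey = c("Pbs2", "Pbs2-stuffer"),
                   score = c(1, 0))
  g <- simulate_colony_grid(ts, n_row = 8, n_col = 8, border = 2,
                            noise_sd = 0, seed = 2)
  g$grew[c(5, 20, 30)] <- FALSE
  f <- filter_colonies(g)
  expect_equal(attr(f, "n_not_grown"), 3)
  expect_false(any(f$border))
  expect_equal(nrow(f), sum(!g$border & g$grew))
  all_grew <- simulate_colony_grid(ts, n_row = 8, n_col = 8, noise_sd = 0)
  expect_equal(nrow(filter_colonies(all_grew)), sum(!all_grew$border))
})

test_that("normalization removes plate, row and column bias", {
  ts <- data.frame(bait = rep("Sho1", 4),
                   prey = c("Pbs2", "Pbs2-stuffer", "m1", "m2"),
                   score = c(1, 0, 0.5, -0.2))
  g <- simulate_colony_grid(ts, n_plates = 2, n_row = 12, n_col = 16,
                            plate_factors = c(1, 2), noise_sd = 0, seed = 4)
  norm <- normalize_colony_sizes(filter_colonies(g))
  med <- tapply(norm$norm_log2, norm$plate, median, na.rm = TRUE)
  expect_lt(abs(diff(med)), 1e-12)
  # a planted row gradient x{1,2,4} is removed exactly by the row median
  # polish on a row/column-balanced layout
  g2 <- expand.grid(row = 1:9, col = 1:12)
  g2$plate <- 1L
  pair <- (g2$row + g2$col) %% 4L + 1L
  g2$size <- 256 * 2^c(1, 0, 0.5, -0.2)[pair] *
    c(1, 2, 4)[((g2$row - 1L) %% 3L) + 1L]
  n2 <- normalize_colony_sizes(g2)
  rmed <- tapply(n2$norm_log2, n2$row, median)
  expect_lt(max(abs(rmed - median(rmed))), 1e-12)
  # an unbiased, row/column-balanced grid is only shifted: ranks preserved
  g3 <- expand.grid(row = 1:8, col = 1:12)
  g3$plate <- 1L
  pair <- (g3$row + g3$col) %% 4L + 1L   # balanced within every row and column
  g3$size <- 256 * 2^c(1, 0, 0.5, -0.2)[pair]
  n3 <- normalize_colony_sizes(g3)
  expect_equal(order(n3$norm_log2), order(log2(g3$size)))
  expect_warning(normalize_colony_sizes(
    data.frame(plate = 1, row = 1:3, col = 1, size = 2^c(1, 2, 3))),
    "fewer than")
})

test_that("rescaled reference medians hit 1 and 0 exactly", {
  ts <- data.frame(bait = "Sho1",
                   prey = c("Pbs2", "Pbs2-stuffer", "m1"),
                   score = c(1, 0, 0.5))
  g <- simulate_colony_grid(ts, n_row = 16, n_col = 24, noise_sd = 0.1,
                            row_bias_sd = 0.15, col_bias_sd = 0.15, seed = 7)
  cs <- colony_scores(g)
  expect_equal(median(cs$score[cs$prey == "Pbs2"]), 1, tolerance = 1e-12)
  expect_equal(median(cs$score[cs$prey == "Pbs2-stuffer"]), 0,
               tolerance = 1e-12)
  halfway <- (median(cs$norm_log2[cs$prey == "Pbs2"]) +
                median(cs$norm_log2[cs$prey == "Pbs2-stuffer"])) / 2
  expect_equal((halfway - median(cs$norm_log2[cs$prey == "Pbs2-stuffer"])) /
                 (median(cs$norm_log2[cs$prey == "Pbs2"]) -
                    median(cs$norm_log2[cs$prey == "Pbs2-stuffer"])), 0.5)
  # invariance to a global multiplicative size change
  g2 <- g
  g2$size <- g2$size * 11
  cs2 <- colony_scores(g2)
  expect_equal(cs$score, cs2$score, tolerance = 1e-10)
})

test_that("bait comparison flags weaker binders one-sidedly", {
  set.seed(12)
  sc <- data.frame(
    bait = rep(c("Sho1", "weak", "same"), each = 6),
    prey = "Pbs2",
    score = c(rnorm(6, 1, 0.05), rnorm(6, 0.2, 0.05), rnorm(6, 1, 0.05)))
  res <- compare_baits(sc, "Sho1")
  expect_true(res$weaker[res$bait == "weak"])
  expect_false(res$weaker[res$bait == "same"])
  # complete separation at n = 6 vs 6 survives BH in a small family
  expect_lt(res$p_adj[res$bait == "weak"], 0.05)
  expect_error(compare_baits(sc, "nope"), "reference")
})
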