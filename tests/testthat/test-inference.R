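two_group_dataset <- function(a_vals, b_vals, cause = "contamination") {
  n <- length(a_vals) + length(b_vals)
  months <- all_months(2000:2009)[seq_len(n)]
  slaughtered <- 1e6
  make_records(
    months, slaughtered = 0,
    counts = setNames(list(round(slaughtered * c(a_vals, b_vals) / 100)), cause),
    turkey = c(rep(1e4, length(a_vals)), rep(0, length(b_vals))),
    griller = 0
  ) |>
    dplyr::mutate(slaughtered_heavy = slaughtered - slaughtered_turkey) |>
    condemnation_data()
}

test_that("identical group distributions give a null comparison", {
  vals <- c(1, 2, 3, 4, 5)
  ds <- two_group_dataset(vals, vals)
  gc <- compare_groups(ds, "contamination")
  expect_equal(gc$rank_biserial, 0)
  expect_gt(gc$p_value, 0.9)
  expect_equal(gc$summary$n, c(5L, 5L))
  expect_equal(gc$summary$se, gc$summary$sd / sqrt(gc$summary$n))
})

test_that("complete separation yields a rank-biserial of exactly one", {
  ds <- two_group_dataset(a_vals = c(0.8, 0.9, 1.1, 0.75, 0.95),
                          b_vals = c(0.001, 0.002, 0.0015))
  gc <- compare_groups(ds, "contamination")
  expect_equal(gc$rank_biserial, 1)
  expect_lt(gc$p_value, 0.001)
  expect_gt(gc$point_biserial, 0)
})

test_that("the effect-size sign is positive when Group A exceeds Group B", {
  ds_b_high <- two_group_dataset(a_vals = c(1, 1.2, 0.9, 1.1),
                                 b_vals = c(3, 3.5, 2.8))
  gc <- compare_groups(ds_b_high, "contamination")
  expect_lt(gc$rank_biserial, 0)
  expect_lt(gc$point_biserial, 0)
  expect_error(compare_groups(two_group_dataset(c(1, 2), 3), "contamination"),
               "insufficient data")
})

test_that("rank-biserial equals the pair-counting oracle (100 random instances)", {
  set.seed(31)
  for (i in 1:100) {
    x <- round(runif(sample(3:15, 1), 0, 10), sample(0:2, 1))  # forces ties
    y <- round(runif(sample(3:15, 1), 0, 10), sample(0:2, 1))
    expect_equal(rank_biserial(x, y), brute_rank_biserial(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Mukaka strength bands label correlations correctly", {
  expect_equal(
    correlation_strength(c(0.95, 0.722, 0.541, 0.35, 0.1, -0.722, NA)),
    c("very high", "high", "moderate", "low", "negligible", "high", NA))
  # band edges are inclusive on the lower bound
  expect_equal(correlation_strength(c(0.9, 0.7, 0.5, 0.3)),
               c("very high", "high", "moderate", "low"))
})

test_that("Spearman matrix is symmetric, unit-diagonal, graded, and NA-safe", {
  set.seed(8)
  n <- 24
  base <- sort(runif(n, 0.001, 0.01))
  r <- make_records(all_months(2000:2001), slaughtered = 1e5,
                    counts = list(
                      dermatosis = round(1e5 * base),
                      septicemia = round(1e5 * base^1.3),   # co-monotone
                      arthritis = sample(10:500, n),
                      cellulitis = 42))                     # constant
  ds <- condemnation_data(r)
  rep_ <- spearman_matrix(ds, c("dermatosis", "septicemia", "arthritis",
                                "cellulitis"))
  expect_equal(rep_$rho, t(rep_$rho))
  expect_equal(rep_$rho["dermatosis", "septicemia"], 1)
  expect_equal(rep_$strength["dermatosis", "septicemia"], "very high")
  expect_equal(diag(rep_$rho)[c("dermatosis", "arthritis")], c(dermatosis = 1, arthritis = 1))
  expect_true(all(is.na(rep_$rho["cellulitis", ])))
  expect_true(all(abs(rep_$rho) <= 1, na.rm = TRUE))
})

test_that("Spearman matrix equals brute-force rank-then-Pearson correlation", {
  set.seed(12)
  for (i in 1:100) {
    m <- matrix(sample(1:50, 8 * 3, replace = TRUE), nrow = 8)
    r <- make_records(all_months(2000)[1:8], slaughtered = 1000,
                      counts = list(dermatosis = m[, 1], septicemia = m[, 2],
                                    arthritis = m[, 3]))
    rep_ <- spearman_matrix(condemnation_data(r),
                            c("dermatosis", "septicemia", "arthritis"))
    ranks <- apply(m / 1000, 2, rank)
    oracle <- stats::cor(ranks, method = "pearson")
    dimnames(oracle) <- dimnames(rep_$rho)
    skip_cols <- apply(m, 2, function(v) length(unique(v)) == 1)
    if (any(skip_cols)) next
    expect_equal(rep_$rho, oracle, tolerance = 1e-12)
  }
})

ratio_table <- function(mat) {
  # mat: years x 12 matrix of ratios
  tibble::tibble(
    year = rep(seq_len(nrow(mat)) + 1999, times = 12),
    month = rep(1:12, each = nrow(mat)),
    ratio = as.vector(mat)
  )
}

test_that("Tukey month contrasts are null when all ratios are equal", {
  rt <- ratio_table(matrix(1, nrow = 5, ncol = 12))
  ma <- asi_month_anova(rt)
  expect_equal(nrow(ma$tukey), 66)
  expect_true(all(ma$tukey$p_adj == 1))
})

test_that("Tukey intervals match the closed-form studentized-range oracle", {
  set.seed(21)
  x1 <- rnorm(6, mean = 1.00, sd = 0.05)
  x2 <- rnorm(6, mean = 1.30, sd = 0.05)
  rt <- tibble::tibble(year = rep(2000:2005, 2),
                       month = rep(c(1, 7), each = 6),
                       ratio = c(x1, x2))
  ma <- asi_month_anova(rt)
  # hand-computed two-group Tukey: q = |diff| / sqrt(MSE/2 * (1/n1 + 1/n2))
  mse <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / 10
  q <- abs(mean(x2) - mean(x1)) / sqrt(mse / 2 * (1 / 6 + 1 / 6))
  p_oracle <- 1 - ptukey(q, nmeans = 2, df = 10)
  expect_equal(ma$tukey$estimate, mean(x2) - mean(x1), tolerance = 1e-12)
  expect_equal(ma$tukey$p_adj, p_oracle, tolerance = 1e-9)
})

test_that("months with a single replicate year are dropped with a warning", {
  rt <- ratio_table(matrix(rnorm(36, 1, 0.1), nrow = 3))
  rt <- rbind(rt[rt$month != 12 | rt$year == 2000, ])
  expect_warning(ma <- asi_month_anova(rt), "dropping calendar month")
  expect_false(any(c(ma$tukey$month_a, ma$tukey$month_b) == 12))
  expect_equal(nrow(ma$tukey), choose(11, 2))
})

test_that("one-sample test against 1 behaves at its boundaries and matches the t formula", {
  rt <- tibble::tibble(month = rep(1, 3), year = 2000:2002,
                       ratio = c(1, 1, 1))
  expect_error(asi_vs_one(rt, 1), "degenerate")
  rt2 <- tibble::tibble(month = rep(2, 3), year = 2000:2002,
                        ratio = c(1.1, 0.9, 1.0))
  res <- asi_vs_one(rt2, 2)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  x <- c(0.96, 0.95, 0.94, 0.95)
  rt3 <- tibble::tibble(month = rep(3, 4), year = 2000:2003, ratio = x)
  res3 <- asi_vs_one(rt3, 3)
  t_oracle <- (mean(x) - 1) / (sd(x) / sqrt(4))
  expect_equal(res3$t, t_oracle, tolerance = 1e-12)
  expect_equal(res3$p_value, 2 * pt(-abs(t_oracle), df = 3), tolerance = 1e-12)
  expect_equal(res3$n, 4)
})

test_that("asi_vs_one_all reports every month and NA for degenerate ones", {
  mat <- matrix(rnorm(24, 1, 0.05), nrow = 2)
  mat[, 4] <- 1
  out <- asi_vs_one_all(ratio_table(mat))
  expect_equal(out$month, 1:12)
  expect_true(is.na(out$p_value[out$month == 4]))
  expect_true(all(!is.na(out$p_value[out$month != 4])))
})
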